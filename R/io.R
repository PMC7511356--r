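#' Build a UTR record set from identifiers and sequences
#'
#' @param transcript_id Character vector of unique identifiers.
#' @param sequence Character vector of sequences (normalized with
#'   [normalize_sequence()]).
#' @return Data frame with columns `transcript_id`, `sequence`, `length`.
#' @export
utr_record <- function(transcript_id, sequence) {
  sequence <- normalize_sequence(sequence)
  attr(sequence, "n_nonstandard") <- NULL
  data.frame(transcript_id = unname(as.character(transcript_id)),
             sequence = unname(as.character(sequence)),
             length = unname(nchar(sequence)),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

validate_utr_set <- function(utrs) {
  need <- c("transcript_id", "sequence", "length")
  if (!is.data.frame(utrs) || !all(need %in% names(utrs)) || nrow(utrs) == 0L) {
    stop_validation("UTR set must be a non-empty data frame with columns ",
                    paste(need, collapse = ", "))
  }
  if (anyDuplicated(utrs$transcript_id)) {
    stop_validation("duplicated transcript identifiers in UTR set")
  }
  if (!all(utrs$length == nchar(utrs$sequence))) {
    stop_validation("UTR length column disagrees with sequence lengths")
  }
  utrs
}

#' Read 3'-UTR sequences from a FASTA file
#'
#' Multi-record, wrapped-line FASTA; sequences are normalized to uppercase
#' RNA (T to U). The identifier is the first whitespace-delimited token of
#' the header. Duplicated identifiers are an error.
#'
#' @param path Path to a FASTA file.
#' @return A UTR set (see [utr_record()]).
#' @export
read_utr_fasta <- function(path) {
  if (!file.exists(path)) stop_validation("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    stop_validation("malformed FASTA '", path, "': ",
                                    conditionMessage(e))
                  })
  if (length(set) == 0L) stop_validation("FASTA '", path, "' has no records")
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop_validation("duplicated FASTA identifiers in '", path, "': ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  utr_record(ids, as.character(set))
}

#' Write a UTR set to FASTA
#'
#' @param utrs A UTR set.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_utr_fasta <- function(utrs, path, width = 70L) {
  utrs <- validate_utr_set(utrs)
  set <- Biostrings::BStringSet(stats::setNames(utrs$sequence, utrs$transcript_id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# shared TSV conventions: tab-separated, header, no quoting, "." for NA
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a transcript-by-sample count matrix from TSV
#'
#' First column `transcript_id`, one column per sample, integer counts.
#'
#' @param path Path to the TSV file.
#' @return Integer matrix with transcript rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 2L || names(df)[1L] != "transcript_id") {
    stop_validation("count matrix '", path,
                    "': first column must be transcript_id, then >= 1 sample")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (anyNA(m) || any(m < 0) || any(m != round(m))) {
    stop_validation("count matrix '", path,
                    "' must contain only non-negative integers")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df$transcript_id)
  if (anyDuplicated(rownames(m))) {
    stop_validation("duplicated transcript identifiers in '", path, "'")
  }
  m
}

#' Write a count matrix to TSV
#' @param counts Integer matrix (transcripts x samples).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(transcript_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a sample sheet assigning samples to IP or control
#'
#' @param path TSV with columns `sample_id`, `group` (values `IP`/`control`).
#' @return Data frame with columns `sample_id`, `group`.
#' @export
read_sample_design <- function(path) {
  df <- read_tsv(path)
  validate_design(df)
}

validate_design <- function(design) {
  if (!is.data.frame(design) || !all(c("sample_id", "group") %in% names(design))) {
    stop_validation("sample design needs columns sample_id and group")
  }
  design$sample_id <- as.character(design$sample_id)
  design$group <- as.character(design$group)
  if (anyDuplicated(design$sample_id)) {
    stop_validation("duplicated sample_id in design")
  }
  if (!all(design$group %in% c("IP", "control"))) {
    stop_validation("design group must be 'IP' or 'control'")
  }
  if (!any(design$group == "IP") || !any(design$group == "control")) {
    stop_validation("design needs at least one IP and one control sample")
  }
  design
}

#' Per-pattern motif track for a UTR set
#'
#' Every literal pattern match across all UTRs, in 1-based inclusive
#' coordinates (overlaps included).
#'
#' @param utrs A UTR set.
#' @param catalog List of [motif_class()] objects.
#' @return Data frame: `transcript_id`, `class`, `pattern`, `start`, `end`.
#' @export
motif_track <- function(utrs, catalog = motif_catalog()) {
  catalog <- validate_catalog(catalog)
  utrs <- validate_utr_set(utrs)
  rows <- list()
  for (cls in catalog) {
    for (pat in cls$patterns) {
      starts <- pattern_starts(utrs$sequence, pat)
      n <- lengths(starts)
      if (sum(n) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = rep(utrs$transcript_id, n),
        class = cls$name, pattern = pat,
        start = unlist(starts, use.names = FALSE),
        end = unlist(starts, use.names = FALSE) + nchar(pat) - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(transcript_id = character(), class = character(),
                      pattern = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  track <- do.call(rbind, rows)
  track <- track[order(track$transcript_id, track$start, track$class,
                       track$pattern), , drop = FALSE]
  rownames(track) <- NULL
  track
}

#' Write a motif position track as BED6
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open per the BED standard. Name is `class:pattern`, score 0,
#' strand `+` (scanning is sense-strand only).
#'
#' @param track A track data frame from [motif_track()] (columns
#'   `transcript_id`, `class`, `pattern`, `start`, `end`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed_track <- function(track, path) {
  bed <- data.frame(
    chrom = track$transcript_id,
    chromStart = track$start - 1L,
    chromEnd = track$end,
    name = paste0(track$class, ":", track$pattern),
    score = 0L,
    strand = "+",
    stringsAsFactors = FALSE
  )
  if (nrow(bed)) bed <- bed[order(bed$chrom, bed$chromStart), , drop = FALSE]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
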