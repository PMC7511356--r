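#' Define a motif class of literal RNA patterns
#'
#' A motif class is a named set of literal RNA patterns (e.g. the consensus
#' CPE variants). Patterns are matched exactly, sense strand only; a
#' 3'-UTR position counts once per class even when several patterns of the
#' class start there.
#'
#' @param name Class name (unique within a catalog).
#' @param patterns Character vector of RNA patterns over {A,C,G,U},
#'   each at least 4 nt long.
#' @return An object of class `motif_class`.
#' @export
motif_class <- function(name, patterns) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_validation("motif class name must be a non-empty string")
  }
  if (!is.character(patterns) || length(patterns) == 0L) {
    stop_validation("motif class '", name, "' needs at least one pattern")
  }
  patterns <- toupper(patterns)
  if (any(nchar(patterns) < 4L)) {
    stop_validation("motif class '", name, "': all patterns must be >= 4 nt")
  }
  if (any(grepl("[^ACGU]", patterns))) {
    stop_validation("motif class '", name, "': patterns must use only A, C, G, U")
  }
  structure(list(name = name, patterns = unique(patterns)), class = "motif_class")
}

#' The four CPE-related element classes
#'
#' Returns the catalog of 3'-UTR elements bound up with CPEB-mediated
#' translational control:
#' \describe{
#'   \item{CPEC}{consensus cytoplasmic polyadenylation element,
#'     `UUUUA(1-2)U` expanded to the literals `UUUUAU`, `UUUUAAU`}
#'   \item{CPENC}{non-consensus CPE: `UUUUAAAU`, `UUUUACU`, `UUUUCAU`}
#'   \item{Hex}{polyadenylation hexanucleotide: `AAUAAA`, `AUUAAA`}
#'   \item{PBE}{Pumilio-binding element: `UGUAAAUA`, `UGUAUAUA`}
#' }
#'
#' @return A named list of [motif_class()] objects.
#' @export
#' @examples
#' names(motif_catalog())
motif_catalog <- function() {
  classes <- list(
    motif_class("CPEC",  c("UUUUAU", "UUUUAAU")),
    motif_class("CPENC", c("UUUUAAAU", "UUUUACU", "UUUUCAU")),
    motif_class("Hex",   c("AAUAAA", "AUUAAA")),
    motif_class("PBE",   c("UGUAAAUA", "UGUAUAUA"))
  )
  stats::setNames(classes, vapply(classes, `[[`, "", "name"))
}

validate_catalog <- function(catalog) {
  if (!is.list(catalog) || length(catalog) == 0L) {
    stop_validation("catalog must be a non-empty list of motif_class objects")
  }
  nm <- vapply(catalog, function(x) {
    if (!inherits(x, "motif_class")) {
      stop_validation("catalog entries must be motif_class objects")
    }
    x$name
  }, "")
  if (anyDuplicated(nm)) stop_validation("motif class names must be unique")
  stats::setNames(catalog, nm)
}

#' Normalize a nucleotide sequence to uppercase RNA
#'
#' Uppercases and converts T to U. Characters outside {A,C,G,U} (ambiguity
#' codes, gaps, anything else) are preserved but counted in the
#' `n_nonstandard` attribute; they can never take part in a motif match.
#'
#' @param raw Character vector of sequences.
#' @return Character vector of normalized RNA sequences with an integer
#'   attribute `n_nonstandard` (per-element count of non-ACGU characters).
#' @export
#' @examples
#' normalize_sequence("acgt")  # "ACGU"
normalize_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) == 0L || anyNA(raw) || any(!nzchar(raw))) {
    stop_validation("sequences must be non-empty, non-NA character strings")
  }
  out <- chartr("acgtuT", "ACGUUU", toupper(raw))
  flagged <- nchar(gsub("[ACGU]", "", out))
  attr(out, "n_nonstandard") <- as.integer(flagged)
  out
}

# all 1-based start positions of a literal pattern in each sequence,
# overlapping occurrences included (zero-width lookahead)
pattern_starts <- function(seqs, pattern) {
  hits <- gregexpr(paste0("(?=", pattern, ")"), seqs, perl = TRUE)
  lapply(hits, function(h) {
    v <- as.integer(h)
    v[v > 0L]
  })
}

# per class: sorted unique start positions per sequence
class_starts <- function(seqs, cls) {
  per_pattern <- lapply(cls$patterns, function(p) pattern_starts(seqs, p))
  lapply(seq_along(seqs), function(i) {
    sort(unique(unlist(lapply(per_pattern, `[[`, i), use.names = FALSE)))
  })
}

#' Scan a set of 3'-UTRs for motif classes
#'
#' Counts, for each UTR and each class, the distinct 1-based start positions
#' at which at least one pattern of the class matches. Overlapping matches at
#' different starts all count; a start hit by two patterns of the same class
#' counts once. Matching is literal and sense-strand only.
#'
#' @param utrs A UTR set: data frame with columns `transcript_id`, `sequence`
#'   (normalized RNA; see [normalize_sequence()]), `length`.
#' @param catalog List of [motif_class()] objects, default [motif_catalog()].
#' @return An object of class `motif_scan`: list with `profiles` (data frame:
#'   `transcript_id`, `utr_length`, one `<class>_count` and `<class>_density`
#'   column per class, densities per kilobase) and `positions` (per class, a
#'   list of integer start vectors parallel to `profiles`).
#' @export
scan_utrs <- function(utrs, catalog = motif_catalog()) {
  catalog <- validate_catalog(catalog)
  utrs <- validate_utr_set(utrs)
  seqs <- utrs$sequence
  profiles <- data.frame(
    transcript_id = utrs$transcript_id,
    utr_length = utrs$length,
    stringsAsFactors = FALSE
  )
  positions <- list()
  for (nm in names(catalog)) {
    pos <- class_starts(seqs, catalog[[nm]])
    positions[[nm]] <- pos
    counts <- lengths(pos)
    profiles[[paste0(nm, "_count")]] <- counts
    profiles[[paste0(nm, "_density")]] <- counts * 1000 / utrs$length
  }
  structure(list(profiles = profiles, positions = positions,
                 classes = names(catalog)),
            class = "motif_scan")
}

#' Scan a single UTR record
#'
#' Single-transcript counterpart of [scan_utrs()].
#'
#' @param utr A one-row UTR set (see [utr_record()]) or a list with
#'   `transcript_id`, `sequence`, `length`.
#' @param catalog List of [motif_class()] objects.
#' @return A `motif_profile`: list with `transcript_id`, `utr_length`,
#'   named integer `counts`, named list `positions` (sorted 1-based starts),
#'   and named numeric `densities` (per kilobase).
#' @export
#' @examples
#' p <- scan_sequence(utr_record("x", "UUUUAUUUUAU"))
#' p$counts[["CPEC"]]      # 2
#' p$positions[["CPEC"]]   # 1 6
scan_sequence <- function(utr, catalog = motif_catalog()) {
  if (is.list(utr) && !is.data.frame(utr)) {
    utr <- utr_record(utr$transcript_id, utr$sequence)
  }
  scan <- scan_utrs(utr, catalog)
  counts <- vapply(scan$positions, function(p) length(p[[1L]]), 0L)
  structure(list(
    transcript_id = scan$profiles$transcript_id[1L],
    utr_length = scan$profiles$utr_length[1L],
    counts = counts,
    positions = lapply(scan$positions, `[[`, 1L),
    densities = counts * 1000 / scan$profiles$utr_length[1L]
  ), class = "motif_profile")
}

#' Motif density per kilobase of UTR
#'
#' @param counts Named or unnamed non-negative counts.
#' @param utr_length UTR length in nucleotides; must be positive.
#' @return `counts * 1000 / utr_length`.
#' @export
density_per_kb <- function(counts, utr_length) {
  if (!is.numeric(utr_length) || length(utr_length) != 1L ||
      is.na(utr_length) || utr_length <= 0) {
    stop_validation("utr_length must be a single positive number")
  }
  counts * 1000 / utr_length
}

#' Positional motif map and clusters for one UTR
#'
#' Lists every pattern match (class, pattern, 1-based inclusive start/end)
#' and partitions the pooled matches into clusters: maximal runs in which
#' consecutive match starts differ by at most `cluster_gap` nucleotides.
#' Cluster intervals run from the first match start to the last match end
#' within the run.
#'
#' @param utr A one-row UTR set or list (as in [scan_sequence()]).
#' @param catalog List of [motif_class()] objects.
#' @param cluster_gap Positive gap threshold in nucleotides (default 400).
#' @return List with `track` (data frame: `class`, `pattern`, `start`, `end`)
#'   and `clusters` (data frame: `start`, `end`, `n_matches`).
#' @export
motif_map <- function(utr, catalog = motif_catalog(), cluster_gap = 400) {
  if (!is.numeric(cluster_gap) || length(cluster_gap) != 1L ||
      is.na(cluster_gap) || cluster_gap <= 0) {
    stop_config("cluster_gap must be a single positive number")
  }
  catalog <- validate_catalog(catalog)
  if (is.list(utr) && !is.data.frame(utr)) {
    utr <- utr_record(utr$transcript_id, utr$sequence)
  }
  utr <- validate_utr_set(utr)
  seq1 <- utr$sequence[1L]
  rows <- list()
  for (cls in catalog) {
    for (pat in cls$patterns) {
      starts <- pattern_starts(seq1, pat)[[1L]]
      if (length(starts)) {
        rows[[length(rows) + 1L]] <- data.frame(
          class = cls$name, pattern = pat,
          start = starts, end = starts + nchar(pat) - 1L,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  empty_track <- data.frame(class = character(), pattern = character(),
                            start = integer(), end = integer(),
                            stringsAsFactors = FALSE)
  empty_clusters <- data.frame(start = integer(), end = integer(),
                               n_matches = integer())
  if (length(rows) == 0L) {
    return(list(track = empty_track, clusters = empty_clusters))
  }
  track <- do.call(rbind, rows)
  track <- track[order(track$start, track$class, track$pattern), , drop = FALSE]
  rownames(track) <- NULL

  starts <- track$start
  brk <- c(0L, cumsum(diff(starts) > cluster_gap))
  clusters <- do.call(rbind, lapply(split(seq_along(starts), brk), function(i) {
    data.frame(start = min(track$start[i]), end = max(track$end[i]),
               n_matches = length(i))
  }))
  rownames(clusters) <- NULL
  list(track = track, clusters = clusters)
}
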