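#' Configuration of the synthetic RIP-Seq data generator
#'
#' Defines the study conditions the generator emulates: a transcript
#' population in which a "binder" subset has (i) longer 3'-UTRs, (ii) higher
#' planted CPE-element densities, and (iii) IP-sample count enrichment, on a
#' negative-binomial count background.
#'
#' @param n_transcripts Number of transcripts (positive integer).
#' @param binder_fraction Proportion of binders in \[0, 1\].
#' @param ip_fold_change Enrichment multiplier (> 0) applied to binder means
#'   in IP samples.
#' @param dispersion Negative-binomial dispersion alpha (>= 0) in
#'   `var = mu + alpha * mu^2`; 0 gives Poisson counts.
#' @param n_ip,n_control Replicate counts (>= 1) per group.
#' @param depth Expected reads per sample (library size before jitter).
#' @param utr_length_log_mean,utr_length_log_sd Named numeric vectors with
#'   entries `binder` and `nonbinder`: log-normal meanlog/sdlog of UTR length
#'   per group. Defaults give median lengths 1200 nt (binders) vs 800 nt
#'   (non-binders), a 1.5-fold median ratio.
#' @param motif_rate_per_kb Named list with entries `binder` and `nonbinder`,
#'   each a named numeric vector of per-kilobase planting rates per motif
#'   class. Defaults plant binders at twice the non-binder rate for every
#'   class.
#' @param base_composition Named probabilities over A, C, G, U summing to 1;
#'   default is mildly AU-rich, as 3'-UTRs are.
#' @param library_jitter_sd sdlog of per-sample log-normal library-size
#'   jitter.
#' @param seed Integer seed; every generator call is fully determined by it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_transcripts = 2000,
                             binder_fraction = 0.1,
                             ip_fold_change = 4,
                             dispersion = 0.1,
                             n_ip = 3,
                             n_control = 3,
                             depth = 2e6,
                             utr_length_log_mean = c(binder = log(1200),
                                                     nonbinder = log(800)),
                             utr_length_log_sd = c(binder = 0.6,
                                                   nonbinder = 0.6),
                             motif_rate_per_kb = list(
                               binder = c(CPEC = 1.0, CPENC = 0.6,
                                          Hex = 1.0, PBE = 0.4),
                               nonbinder = c(CPEC = 0.5, CPENC = 0.3,
                                             Hex = 0.5, PBE = 0.2)),
                             base_composition = c(A = 0.3, C = 0.2,
                                                  G = 0.2, U = 0.3),
                             library_jitter_sd = 0.05,
                             seed = 1L) {
  assert_scalar_number(n_transcripts, "n_transcripts", lower = 1)
  if (n_transcripts != round(n_transcripts)) {
    stop_config("n_transcripts must be an integer")
  }
  assert_scalar_number(binder_fraction, "binder_fraction", 0, 1)
  assert_scalar_number(ip_fold_change, "ip_fold_change", lower = 1e-12)
  assert_scalar_number(dispersion, "dispersion", lower = 0)
  assert_scalar_number(n_ip, "n_ip", lower = 1)
  assert_scalar_number(n_control, "n_control", lower = 1)
  assert_scalar_number(depth, "depth", lower = 1)
  assert_scalar_number(library_jitter_sd, "library_jitter_sd", lower = 0)
  assert_scalar_number(seed, "seed")
  for (g in c("binder", "nonbinder")) {
    if (!g %in% names(utr_length_log_mean) || !g %in% names(utr_length_log_sd)) {
      stop_config("utr_length_log_mean/sd need entries 'binder' and 'nonbinder'")
    }
    if (!g %in% names(motif_rate_per_kb)) {
      stop_config("motif_rate_per_kb needs entries 'binder' and 'nonbinder'")
    }
    if (any(motif_rate_per_kb[[g]] < 0)) {
      stop_config("motif planting rates must be non-negative")
    }
  }
  if (!setequal(names(base_composition), c("A", "C", "G", "U")) ||
      any(base_composition < 0) ||
      abs(sum(base_composition) - 1) > 1e-9) {
    stop_config("base_composition must be probabilities over A, C, G, U ",
                "summing to 1")
  }
  structure(list(
    n_transcripts = as.integer(n_transcripts),
    binder_fraction = binder_fraction,
    ip_fold_change = ip_fold_change,
    dispersion = dispersion,
    n_ip = as.integer(n_ip),
    n_control = as.integer(n_control),
    depth = depth,
    utr_length_log_mean = utr_length_log_mean,
    utr_length_log_sd = utr_length_log_sd,
    motif_rate_per_kb = motif_rate_per_kb,
    base_composition = base_composition[c("A", "C", "G", "U")],
    library_jitter_sd = library_jitter_sd,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# plant literal motifs by substitution at uniform random positions; never
# overwrite a previously planted motif (max 100 retries per plant, then skip
# with a warning)
plant_motifs <- function(seq1, rates_per_kb, catalog, max_retries = 100L) {
  len <- nchar(seq1)
  chars <- strsplit(seq1, "", fixed = TRUE)[[1L]]
  occupied <- logical(len)
  n_skipped <- 0L
  planted <- stats::setNames(integer(length(catalog)), names(catalog))
  for (nm in names(rates_per_kb)) {
    rate <- rates_per_kb[[nm]]
    if (rate <= 0 || is.null(catalog[[nm]])) next
    pats <- catalog[[nm]]$patterns
    n_plant <- stats::rpois(1L, rate * len / 1000)
    for (j in seq_len(n_plant)) {
      pat <- pats[sample.int(length(pats), 1L)]
      k <- nchar(pat)
      if (len < k) break
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        pos <- sample.int(len - k + 1L, 1L)
        span <- pos:(pos + k - 1L)
        if (!any(occupied[span])) {
          chars[span] <- strsplit(pat, "", fixed = TRUE)[[1L]]
          occupied[span] <- TRUE
          placed <- TRUE
          planted[[nm]] <- planted[[nm]] + 1L
          break
        }
      }
      if (!placed) n_skipped <- n_skipped + 1L
    }
  }
  if (n_skipped > 0L) {
    warning("motif planting: ", n_skipped,
            " placement(s) skipped after retry limit", call. = FALSE)
  }
  list(sequence = paste(chars, collapse = ""), planted = planted)
}

#' Generate a synthetic 3'-UTR set with ground-truth binder labels
#'
#' UTR lengths are drawn log-normal per label group (floored at 50 nt);
#' background residues are i.i.d. from `base_composition`; motifs are planted
#' as literal substitutions at uniform positions at the configured per-kb
#' rate per class, never overwriting a previously planted motif. Fully
#' deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @param catalog Motif catalog used for planting (default [motif_catalog()]).
#' @return List with `utrs` (a UTR set, see [utr_record()]), `labels`
#'   (data frame: `transcript_id`, `is_binder`), and `planted` (integer
#'   matrix of successfully planted motifs per transcript and class; a lower
#'   bound on scanned counts, since scanning can also hit
#'   background-generated motifs).
#' @export
generate_utr_set <- function(config, catalog = motif_catalog()) {
  stopifnot(inherits(config, "generator_config"))
  catalog <- validate_catalog(catalog)
  n <- config$n_transcripts
  n_binder <- round(n * config$binder_fraction)
  is_binder <- c(rep(TRUE, n_binder), rep(FALSE, n - n_binder))
  ids <- sprintf("tx%05d", seq_len(n))
  withr::with_seed(config$seed, {
    grp <- ifelse(is_binder, "binder", "nonbinder")
    len <- pmax(50L, as.integer(round(stats::rlnorm(
      n,
      meanlog = config$utr_length_log_mean[grp],
      sdlog = config$utr_length_log_sd[grp]
    ))))
    bases <- c("A", "C", "G", "U")
    seqs <- character(n)
    planted <- matrix(0L, nrow = n, ncol = length(catalog),
                      dimnames = list(ids, names(catalog)))
    for (i in seq_len(n)) {
      raw <- paste(sample(bases, len[i], replace = TRUE,
                          prob = config$base_composition), collapse = "")
      res <- plant_motifs(raw, config$motif_rate_per_kb[[grp[i]]], catalog)
      seqs[i] <- res$sequence
      planted[i, names(res$planted)] <- res$planted
    }
  })
  list(
    utrs = utr_record(ids, seqs),
    labels = data.frame(transcript_id = ids, is_binder = is_binder,
                        stringsAsFactors = FALSE),
    planted = planted
  )
}

#' Generate a synthetic RIP-Seq count matrix
#'
#' Per-transcript control means come from a log-normal expression profile
#' scaled to `depth` reads per sample; IP means are the control means times
#' `ip_fold_change` for binders (times 1 otherwise). Counts are negative
#' binomial with `var = mu + dispersion * mu^2`; per-sample log-normal
#' library-size jitter is applied. Deterministic given `config$seed` (an
#' independent stream from [generate_utr_set()], offset by 1).
#'
#' @param labels Data frame with `transcript_id`, `is_binder` (from
#'   [generate_utr_set()]).
#' @param config A [generator_config()].
#' @return List with `counts` (integer matrix, transcripts x samples) and
#'   `design` (data frame: `sample_id`, `group`).
#' @export
generate_count_matrix <- function(labels, config) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.data.frame(labels) || nrow(labels) == 0L ||
      !all(c("transcript_id", "is_binder") %in% names(labels))) {
    stop_config("labels must be a non-empty data frame with transcript_id ",
                "and is_binder")
  }
  if (config$n_ip < 1L || config$n_control < 1L) {
    stop_config("n_ip and n_control must be >= 1")
  }
  n <- nrow(labels)
  n_s <- config$n_ip + config$n_control
  design <- data.frame(
    sample_id = c(sprintf("IP_%d", seq_len(config$n_ip)),
                  sprintf("control_%d", seq_len(config$n_control))),
    group = c(rep("IP", config$n_ip), rep("control", config$n_control)),
    stringsAsFactors = FALSE
  )
  withr::with_seed(config$seed + 1L, {
    expr <- stats::rlnorm(n, meanlog = 1, sdlog = 1.2)
    q_control <- expr / sum(expr) * config$depth
    q_ip <- q_control * ifelse(labels$is_binder, config$ip_fold_change, 1)
    jitter <- stats::rlnorm(n_s, meanlog = 0, sdlog = config$library_jitter_sd)
    mu <- cbind(
      q_ip %o% jitter[seq_len(config$n_ip)],
      q_control %o% jitter[config$n_ip + seq_len(config$n_control)]
    )
    counts <- if (config$dispersion > 0) {
      matrix(stats::rnbinom(n * n_s, mu = mu, size = 1 / config$dispersion),
             nrow = n)
    } else {
      matrix(stats::rpois(n * n_s, lambda = mu), nrow = n)
    }
  })
  storage.mode(counts) <- "integer"
  rownames(counts) <- labels$transcript_id
  colnames(counts) <- design$sample_id
  list(counts = counts, design = design)
}

#' Write a simulated dataset to disk
#'
#' Writes the generator outputs in the pipeline's canonical plain-text
#' formats: FASTA UTRs, TSV count matrix, TSV sample sheet, and TSV truth
#' labels.
#'
#' @param sim List with `utrs`, `labels`, `counts`, `design` (combined
#'   output of [generate_utr_set()] and [generate_count_matrix()]).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_simulated_data <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(outdir, "utrs.fasta"),
    counts = file.path(outdir, "counts.tsv"),
    design = file.path(outdir, "design.tsv"),
    truth = file.path(outdir, "truth_labels.tsv")
  )
  write_utr_fasta(sim$utrs, paths[["fasta"]])
  write_count_matrix(sim$counts, paths[["counts"]])
  write_tsv(sim$design, paths[["design"]])
  write_tsv(sim$labels, paths[["truth"]])
  invisible(paths)
}
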