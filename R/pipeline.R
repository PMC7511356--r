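#' Build or validate a pipeline run configuration
#'
#' A run is driven either by real input files (`inputs`: paths `fasta`,
#' `counts`, `design`) or by a generator block (`generator`: arguments of
#' [generator_config()]); exactly one of the two must be present. Threshold
#' defaults are the analysis defaults: `lfc_min = 0`, `fdr_max = 0.01`,
#' `k = 3`, `cluster_gap = 400`.
#'
#' @param config Named list (e.g. parsed from YAML).
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(config) {
  if (!is.list(config)) stop_config("run config must be a list")
  has_inputs <- !is.null(config$inputs)
  has_gen <- !is.null(config$generator)
  if (has_inputs == has_gen) {
    stop_config("exactly one of 'inputs' and 'generator' must be present")
  }
  if (has_inputs) {
    need <- c("fasta", "counts", "design")
    if (!all(need %in% names(config$inputs))) {
      stop_config("inputs block needs paths: ", paste(need, collapse = ", "))
    }
  }
  th <- config$thresholds %||% list()
  config$thresholds <- list(
    lfc_min = th$lfc_min %||% 0,
    fdr_max = th$fdr_max %||% 0.01,
    k = th$k %||% 3,
    cluster_gap = th$cluster_gap %||% 400
  )
  assert_scalar_number(config$thresholds$fdr_max, "fdr_max", 0, 1)
  assert_scalar_number(config$thresholds$lfc_min, "lfc_min")
  assert_scalar_number(config$thresholds$k, "k", lower = -1)
  assert_scalar_number(config$thresholds$cluster_gap, "cluster_gap",
                       lower = 1e-12)
  config$score <- isTRUE(config$score)
  config$seed <- as.integer(config$seed %||% 1L)
  if (is.null(config$outdir)) stop_config("run config needs an outdir")
  if (has_gen) {
    gen <- config$generator
    gen$seed <- gen$seed %||% config$seed
    config$generator_config <- do.call(generator_config, normalize_gen_block(gen))
  }
  structure(config, class = "run_config")
}

# YAML represents the grouped generator fields as nested maps; flatten them
# back to the named vectors/lists generator_config() expects
normalize_gen_block <- function(gen) {
  for (fld in c("utr_length_log_mean", "utr_length_log_sd",
                "base_composition")) {
    if (!is.null(gen[[fld]])) gen[[fld]] <- unlist(gen[[fld]])
  }
  if (!is.null(gen$motif_rate_per_kb)) {
    gen$motif_rate_per_kb <- lapply(gen$motif_rate_per_kb, unlist)
  }
  gen
}

#' Load a run configuration from a YAML file
#'
#' @param path Path to a YAML run configuration.
#' @return Validated `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  run_config(yaml::read_yaml(path))
}

#' Load and reconcile pipeline inputs
#'
#' Reads the UTR FASTA, the count matrix, and the sample sheet, and
#' reconciles transcript identifiers: transcripts present in the counts but
#' absent from the FASTA are carried through binder calling and dropped from
#' motif statistics (the number is logged); an empty identifier intersection
#' is fatal. When the configuration has a generator block, inputs are
#' produced in memory and also written to `outdir`.
#'
#' @param config A `run_config`.
#' @param quiet Suppress log messages.
#' @return List with `utrs`, `counts`, `design`, `truth` (generator runs
#'   only, else NULL), and `n_missing_utr` (count-only transcripts).
#' @export
load_inputs <- function(config, quiet = FALSE) {
  config <- if (inherits(config, "run_config")) config else run_config(config)
  truth <- NULL
  if (!is.null(config$generator_config)) {
    gc <- config$generator_config
    utr <- generate_utr_set(gc)
    cm <- generate_count_matrix(utr$labels, gc)
    sim <- list(utrs = utr$utrs, labels = utr$labels,
                counts = cm$counts, design = cm$design)
    write_simulated_data(sim, config$outdir)
    utrs <- utr$utrs; counts <- cm$counts; design <- cm$design
    truth <- utr$labels
  } else {
    utrs <- read_utr_fasta(config$inputs$fasta)
    counts <- read_count_matrix(config$inputs$counts)
    design <- read_sample_design(config$inputs$design)
  }
  common <- intersect(rownames(counts), utrs$transcript_id)
  if (length(common) == 0L) {
    stop_validation("no transcript identifiers shared between counts and FASTA")
  }
  n_missing <- sum(!rownames(counts) %in% utrs$transcript_id)
  if (n_missing > 0L && !quiet) {
    message(n_missing, " transcript(s) in counts lack a UTR sequence; ",
            "kept for binder calling, dropped from motif statistics")
  }
  extra_utr <- sum(!utrs$transcript_id %in% rownames(counts))
  if (extra_utr > 0L && !quiet) {
    message(extra_utr, " UTR record(s) have no counts; ignored")
  }
  utrs <- utrs[utrs$transcript_id %in% rownames(counts), , drop = FALSE]
  list(utrs = utrs, counts = counts, design = design, truth = truth,
       n_missing_utr = n_missing)
}

report_to_list <- function(report) {
  list(
    n = as.list(report$n),
    k = report$k,
    classes = lapply(report$classes, function(cl) list(
      table = cl$table,
      odds_ratio = if (is.infinite(cl$odds_ratio)) "Inf" else cl$odds_ratio,
      fisher_p = cl$fisher_p
    )),
    ranksum = report$ranksum
  )
}

#' Run the full RIP-Seq target-spectrum pipeline
#'
#' Executes simulate/load, binder calling, motif scanning, and the
#' binder-vs-non-binder comparison in order, writing every stage's table
#' plus a run manifest (configuration echo and hash, seed, per-stage record
#' counts, output checksums). Identical configuration and seed give
#' byte-identical outputs.
#'
#' @param config A `run_config`, a plain list, or a path to a YAML file.
#' @param quiet Suppress log messages.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- load_run_config(config)
  config <- if (inherits(config, "run_config")) config else run_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (!quiet) message("[ripcpe] ", ...)
  stage <- "load_inputs"
  manifest <- list(package = "ripcpe",
                   version = as.character(utils::packageVersion("ripcpe")),
                   seed = config$seed,
                   thresholds = config$thresholds,
                   score = config$score)
  result <- tryCatch({
    log_msg("stage load_inputs")
    inputs <- load_inputs(config, quiet = quiet)

    stage <- "call_binders"
    log_msg("stage call_binders (", nrow(inputs$counts), " transcripts)")
    enr <- rip_enrichment(inputs$counts, inputs$design,
                          lfc_min = config$thresholds$lfc_min,
                          fdr_max = config$thresholds$fdr_max)
    enrichment_path <- file.path(outdir, "enrichment.tsv")
    write_tsv(enr, enrichment_path)

    stage <- "scan"
    log_msg("stage scan (", nrow(inputs$utrs), " UTRs)")
    scan <- scan_utrs(inputs$utrs)
    profiles_path <- file.path(outdir, "profiles.tsv")
    write_tsv(scan$profiles, profiles_path)
    track <- motif_track(inputs$utrs)
    bed_path <- file.path(outdir, "motifs.bed")
    write_bed_track(track, bed_path)

    stage <- "compare"
    labels <- data.frame(transcript_id = enr$transcript_id,
                         is_binder = enr$is_binder,
                         stringsAsFactors = FALSE)
    log_msg("stage compare (", sum(labels$is_binder[labels$transcript_id %in%
            scan$profiles$transcript_id]), " binders among scanned)")
    report <- compare_binders(scan$profiles, labels, k = config$thresholds$k)
    report_path <- file.path(outdir, "comparison.json")
    jsonlite::write_json(report_to_list(report), report_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    score_path <- NULL
    if (config$score) {
      stage <- "score"
      log_msg("stage score")
      model <- binder_score(scan$profiles, labels)
      score_path <- file.path(outdir, "binder_scores.tsv")
      write_tsv(model$scores, score_path)
    }

    stage <- "manifest"
    cfg_plain <- unclass(config)
    cfg_plain$generator_config <- NULL
    # hash the scientific configuration, not where it is written
    cfg_hashable <- cfg_plain
    cfg_hashable$outdir <- NULL
    cfg_json <- jsonlite::toJSON(cfg_hashable, auto_unbox = TRUE, digits = NA)
    tmp <- tempfile(); writeLines(as.character(cfg_json), tmp)
    manifest$config <- cfg_plain
    manifest$config_md5 <- unname(tools::md5sum(tmp))
    unlink(tmp)
    outputs <- c(enrichment = enrichment_path, profiles = profiles_path,
                 bed = bed_path, comparison = report_path)
    if (!is.null(score_path)) outputs <- c(outputs, scores = score_path)
    if (!is.null(inputs$truth)) {
      outputs <- c(outputs,
                   fasta = file.path(outdir, "utrs.fasta"),
                   counts = file.path(outdir, "counts.tsv"),
                   design = file.path(outdir, "design.tsv"),
                   truth = file.path(outdir, "truth_labels.tsv"))
    }
    manifest$stages <- list(
      load_inputs = list(n_transcripts = nrow(inputs$counts),
                         n_utrs = nrow(inputs$utrs),
                         n_missing_utr = inputs$n_missing_utr),
      call_binders = list(n_records = nrow(enr),
                          n_binders = sum(enr$is_binder)),
      scan = list(n_profiles = nrow(scan$profiles),
                  n_track_rows = nrow(track)),
      compare = list(n_binder = unname(report$n["binder"]),
                     n_nonbinder = unname(report$n["nonbinder"]))
    )
    manifest$outputs <- lapply(outputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
    manifest_path <- file.path(outdir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    log_msg("done: ", manifest_path)
    manifest
  }, error = function(e) {
    stop(errorCondition(
      paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)),
      class = c("ripcpe_pipeline_error", class(e))
    ))
  })
  invisible(result)
}
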