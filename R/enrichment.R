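#' Median-of-ratios size factors
#'
#' Per-sample scaling constants computed as the median, over transcripts with
#' a positive geometric mean, of the ratio of the sample's count to that
#' geometric mean; factors are rescaled to geometric mean 1. When no
#' transcript is positive in every sample, geometric means are taken over
#' positive counts only (the "poscounts" fallback).
#'
#' @param counts Non-negative integer matrix, transcripts x samples.
#' @return Named positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L || all(counts == 0)) {
    stop_validation("cannot normalize an empty or all-zero count matrix")
  }
  logc <- log(counts)
  loggeo <- rowMeans(logc)                     # -Inf if any zero in the row
  use <- is.finite(loggeo)
  if (!any(use)) {
    loggeo <- apply(counts, 1L, function(r) {
      if (all(r == 0)) -Inf else mean(log(r[r > 0]))
    })
    use <- is.finite(loggeo)
  }
  ratios <- logc[use, , drop = FALSE] - loggeo[use]
  logf <- apply(ratios, 2L, function(col) stats::median(col[is.finite(col)]))
  if (anyNA(logf)) {
    stop_validation("size factor undefined for some sample (no usable counts)")
  }
  f <- exp(logf - mean(logf))                  # geometric mean 1
  stats::setNames(f, colnames(counts))
}

#' Per-transcript method-of-moments NB dispersion
#'
#' On size-factor-normalized counts, estimates the negative-binomial
#' dispersion alpha in `var = mu + alpha * mu^2` from within-group moments:
#' per group, `(s^2 - mean) / mean^2`, combined across groups weighted by
#' within-group degrees of freedom, floored at `alpha_floor`. Transcripts
#' with zero mean get `alpha_floor` and are excluded from testing downstream.
#'
#' @param counts Count matrix (transcripts x samples).
#' @param design Sample design (see [read_sample_design()]).
#' @param factors Size factors from [size_factors()].
#' @param alpha_floor Lower bound on the estimate (default 1e-8).
#' @return Named numeric vector of per-transcript dispersion estimates.
#' @export
estimate_dispersion <- function(counts, design, factors, alpha_floor = 1e-8) {
  design <- validate_design(design)
  counts <- align_counts_design(counts, design)
  norm <- sweep(counts, 2L, factors[colnames(counts)], "/")
  groups <- split(seq_len(ncol(norm)), design$group[match(colnames(norm),
                                                          design$sample_id)])
  if (!any(vapply(groups, length, 0L) >= 2L)) {
    stop_validation("dispersion estimation needs >= 2 samples in some group")
  }
  num <- rep(0, nrow(norm))
  den <- rep(0, nrow(norm))
  for (idx in groups) {
    if (length(idx) < 2L) next
    sub <- norm[, idx, drop = FALSE]
    m <- rowMeans(sub)
    v <- row_vars(sub)
    ok <- m > 0
    w <- length(idx) - 1L
    num[ok] <- num[ok] + w * (v[ok] - m[ok]) / m[ok]^2
    den[ok] <- den[ok] + w
  }
  alpha <- ifelse(den > 0, num / pmax(den, 1), alpha_floor)
  stats::setNames(pmax(alpha_floor, alpha), rownames(counts))
}

#' Moderate per-transcript dispersions for testing
#'
#' With few replicates the per-transcript moment estimator is very noisy;
#' plugging it straight into a Wald test gives heavy-tailed statistics.
#' `method = "common"` replaces every estimate by the mean over expressed
#' transcripts (a common-dispersion plug-in; the mean, unlike the median, is
#' close to unbiased for the right-skewed moment estimates);
#' `method = "per_transcript"` returns the input unchanged.
#'
#' @param dispersions Output of [estimate_dispersion()].
#' @param expressed Logical vector marking transcripts with nonzero counts
#'   (default all).
#' @param method `"common"` or `"per_transcript"`.
#' @return Numeric vector of dispersions for use in [test_enrichment()].
#' @export
moderate_dispersion <- function(dispersions,
                                expressed = rep(TRUE, length(dispersions)),
                                method = c("common", "per_transcript")) {
  method <- match.arg(method)
  if (method == "per_transcript") return(dispersions)
  if (!any(expressed)) return(dispersions)
  common <- mean(dispersions[expressed])
  stats::setNames(rep(common, length(dispersions)), names(dispersions))
}

align_counts_design <- function(counts, design) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    stop_validation("count matrix must have sample column names")
  }
  if (!setequal(colnames(counts), design$sample_id)) {
    stop_validation("count matrix samples and design sample_id must match")
  }
  counts
}

#' Negative-binomial Wald test of IP-vs-control enrichment
#'
#' Per transcript: group means of normalized counts; `log2fc =
#' log2((mean_IP + c) / (mean_control + c))` with pseudocount `c`; the
#' standard error comes from the delta-method NB variance of the log-ratio
#' of group means (`Var(mean_g) = (1/n_g^2) * sum_s (q_g / f_s + alpha *
#' q_g^2)`), and the two-sided p-value from the standard normal. Transcripts
#' with all-zero counts are reported with `pvalue = NA` and `log2fc = 0` and
#' are excluded from the FDR batch.
#'
#' @param counts Count matrix (transcripts x samples).
#' @param design Sample design.
#' @param factors Size factors.
#' @param dispersions Per-transcript dispersions (possibly moderated).
#' @param pseudocount Pseudocount `c` added to each group mean (default 0.5
#'   normalized counts).
#' @return Data frame of enrichment records: `transcript_id`, `base_mean`,
#'   `log2fc`, `se_log2fc`, `pvalue` (no q-values yet; see [adjust_fdr()]).
#' @export
test_enrichment <- function(counts, design, factors, dispersions,
                            pseudocount = 0.5) {
  design <- validate_design(design)
  counts <- align_counts_design(counts, design)
  if (length(dispersions) != nrow(counts)) {
    stop_validation("need one dispersion per transcript")
  }
  f <- factors[colnames(counts)]
  norm <- sweep(counts, 2L, f, "/")
  grp <- design$group[match(colnames(counts), design$sample_id)]
  ip <- grp == "IP"
  n_ip <- sum(ip)
  n_ct <- sum(!ip)
  m_ip <- rowMeans(norm[, ip, drop = FALSE])
  m_ct <- rowMeans(norm[, !ip, drop = FALSE])
  c0 <- pseudocount

  log2fc <- log2((m_ip + c0) / (m_ct + c0))
  # Var of a normalized-count group mean under NB(mu = f_s q, var = mu + a mu^2)
  v_ip <- (m_ip * sum(1 / f[ip]) + n_ip * dispersions * m_ip^2) / n_ip^2
  v_ct <- (m_ct * sum(1 / f[!ip]) + n_ct * dispersions * m_ct^2) / n_ct^2
  se <- sqrt((v_ip / (m_ip + c0)^2 + v_ct / (m_ct + c0)^2)) / log(2)

  z <- ifelse(se > 0, log2fc / se, ifelse(log2fc == 0, 0, Inf * sign(log2fc)))
  pvalue <- 2 * stats::pnorm(-abs(z))

  allzero <- rowSums(counts) == 0
  log2fc[allzero] <- 0
  se[allzero] <- NA_real_
  pvalue[allzero] <- NA_real_

  data.frame(
    transcript_id = rownames(counts),
    base_mean = rowMeans(norm),
    log2fc = log2fc,
    se_log2fc = se,
    pvalue = pvalue,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up BH adjustment over the non-NA p-values; NA stays NA (filtered
#' transcripts are not part of the FDR batch).
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\], NA allowed.
#' @return Numeric vector of q-values, same length and NA pattern.
#' @export
adjust_fdr <- function(pvalues) {
  if (!is.numeric(pvalues)) stop_validation("p-values must be numeric")
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop_validation("p-values must lie in [0, 1]")
  }
  q <- rep(NA_real_, length(pvalues))
  q[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  q
}

#' Classify binder transcripts
#'
#' A transcript is a binder when `log2fc > lfc_min` and `qvalue < fdr_max`
#' (defaults: enrichment direction only, FDR < 0.01). Transcripts with NA
#' p-values are non-binders.
#'
#' @param records Enrichment data frame with at least `log2fc`; a `qvalue`
#'   column is added from `pvalue` if absent.
#' @param lfc_min Minimum log2 fold change (strict, default 0).
#' @param fdr_max Maximum BH q-value (strict, default 0.01).
#' @return `records` with columns `qvalue` and `is_binder`.
#' @export
call_binders <- function(records, lfc_min = 0, fdr_max = 0.01) {
  if (!is.data.frame(records)) stop_validation("records must be a data frame")
  if (nrow(records) == 0L) {
    records$qvalue <- numeric(0)
    records$is_binder <- logical(0)
    return(records)
  }
  if (is.null(records$qvalue)) records$qvalue <- adjust_fdr(records$pvalue)
  records$is_binder <- !is.na(records$qvalue) &
    records$log2fc > lfc_min & records$qvalue < fdr_max
  records
}

#' One-call IP-vs-control enrichment analysis
#'
#' Runs normalization, dispersion estimation (with common-dispersion
#' moderation by default), the NB Wald test, BH adjustment, and binder
#' classification.
#'
#' @inheritParams test_enrichment
#' @inheritParams call_binders
#' @param dispersion_method Passed to [moderate_dispersion()].
#' @return Enrichment data frame with `qvalue` and `is_binder` set.
#' @export
rip_enrichment <- function(counts, design, lfc_min = 0, fdr_max = 0.01,
                           dispersion_method = c("common", "per_transcript"),
                           pseudocount = 0.5) {
  dispersion_method <- match.arg(dispersion_method)
  design <- validate_design(design)
  counts <- align_counts_design(counts, design)
  f <- size_factors(counts)
  disp <- estimate_dispersion(counts, design, f)
  disp <- moderate_dispersion(disp, expressed = rowSums(counts) > 0,
                              method = dispersion_method)
  rec <- test_enrichment(counts, design, f, disp, pseudocount = pseudocount)
  call_binders(rec, lfc_min = lfc_min, fdr_max = fdr_max)
}
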