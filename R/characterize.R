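#' Binder-vs-non-binder contingency table for one element class
#'
#' 2x2 table of transcripts with element count above versus at-or-below a
#' threshold, split by binder status. Rows are `binder`/`nonbinder`, columns
#' `high` (count > k, strict) and `low`.
#'
#' @param profiles Motif profile data frame (from [scan_utrs()]`$profiles`)
#'   with a `<class>_count` column.
#' @param labels Data frame with `transcript_id`, `is_binder`.
#' @param class Element class name (e.g. `"CPEC"`).
#' @param k Count threshold (default 3, the "more than three elements" rule).
#' @return 2x2 integer matrix with dimnames.
#' @export
threshold_table <- function(profiles, labels, class, k = 3) {
  col <- paste0(class, "_count")
  if (!col %in% names(profiles)) {
    stop_validation("class '", class, "' absent from profiles")
  }
  merged <- merge_labels(profiles, labels)
  high <- merged[[col]] > k
  tab <- rbind(
    binder = c(sum(high & merged$is_binder), sum(!high & merged$is_binder)),
    nonbinder = c(sum(high & !merged$is_binder), sum(!high & !merged$is_binder))
  )
  colnames(tab) <- c("high", "low")
  storage.mode(tab) <- "integer"
  tab
}

merge_labels <- function(profiles, labels) {
  if (!all(c("transcript_id", "is_binder") %in% names(labels))) {
    stop_validation("labels need transcript_id and is_binder columns")
  }
  m <- match(profiles$transcript_id, labels$transcript_id)
  if (anyNA(m)) {
    stop_validation("every profiled transcript needs a binder label")
  }
  profiles$is_binder <- as.logical(labels$is_binder[m])
  profiles
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' The p-value sums, over all tables with the observed margins, the
#' hypergeometric probabilities no greater than that of the observed table
#' (the minimum-likelihood two-sided rule). The odds ratio is the sample
#' odds ratio `(a*d)/(b*c)`: infinite when `b*c = 0` with `a*d > 0`, and 1
#' when both products are 0.
#'
#' @param tab 2x2 matrix of non-negative integer cells
#'   (`[[a, b], [c, d]]`, rows = groups).
#' @return List with `odds_ratio` and `p` (two-sided).
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || anyNA(tab) || any(tab < 0) ||
      any(tab != round(tab))) {
    stop_validation("fisher_exact needs a 2x2 table of non-negative integers")
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b          # row-1 total
  n2 <- c_ + d        # row-2 total
  k <- a + c_         # column-1 total
  odds <- if (b * c_ == 0) {
    if (a * d > 0) Inf else 1
  } else {
    (a * d) / (b * c_)
  }
  if (m + n2 == 0L || k == 0L || k == m + n2) {
    return(list(odds_ratio = odds, p = 1))
  }
  support <- max(0L, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  list(odds_ratio = odds, p = p)
}

#' Mann-Whitney rank-sum test
#'
#' U statistic with midranks for ties. When the pooled size is at most 12
#' and there are no ties, the two-sided p-value is exact (enumeration of all
#' rank assignments, doubling rule); otherwise a normal approximation with
#' tie correction and continuity correction is used. Fully tied data give
#' p = 1.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `U` (for `x`), `p` (two-sided), and `exact` (logical).
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L || anyNA(x) || anyNA(y)) {
    stop_validation("rank_sum_test needs two non-empty samples without NA")
  }
  nx <- length(x); ny <- length(y); N <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (N <= 12L && !ties) {
    cmb <- utils::combn(N, nx)
    U_all <- colSums(matrix(cmb, nrow = nx)) - nx * (nx + 1) / 2
    p <- min(1, 2 * min(mean(U_all <= U), mean(U_all >= U)))
    return(list(U = U, p = p, exact = TRUE))
  }
  tie_tab <- table(pooled)
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, exact = FALSE))
  z <- U - nx * ny / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), exact = FALSE)
}

#' Binder-vs-non-binder comparison report
#'
#' Assembles, per element class, the `count > k` contingency table with its
#' Fisher exact test, and rank-sum comparisons of per-kilobase densities
#' (CPEC and CPENC by default) and UTR length between binders and
#' non-binders — the comparative statistics of the target-spectrum analysis.
#'
#' @param profiles Motif profile data frame (with `<class>_count`,
#'   `<class>_density`, `utr_length`).
#' @param labels Data frame with `transcript_id`, `is_binder`.
#' @param k Count threshold for the contingency tables (default 3).
#' @param density_classes Classes whose per-kb densities get rank-sum tests.
#' @return An object of class `binder_comparison`: list with `n` (group
#'   sizes), `classes` (per class: `table`, `odds_ratio`, `fisher_p`) and
#'   `ranksum` (per feature: `U`, `p`, `median_binder`, `median_nonbinder`).
#' @export
compare_binders <- function(profiles, labels, k = 3,
                            density_classes = c("CPEC", "CPENC")) {
  merged <- merge_labels(profiles, labels)
  n_b <- sum(merged$is_binder)
  n_nb <- sum(!merged$is_binder)
  if (n_b == 0L || n_nb == 0L) {
    stop_validation("comparison needs at least one binder and one non-binder")
  }
  count_cols <- grep("_count$", names(profiles), value = TRUE)
  classes <- sub("_count$", "", count_cols)
  class_results <- lapply(classes, function(cl) {
    tab <- threshold_table(profiles, labels, cl, k = k)
    ft <- fisher_exact(tab)
    list(table = tab, odds_ratio = ft$odds_ratio, fisher_p = ft$p)
  })
  names(class_results) <- classes

  feature_cols <- c(stats::setNames(paste0(density_classes, "_density"),
                                    paste0(density_classes, "_density")),
                    utr_length = "utr_length")
  ranksum <- lapply(feature_cols, function(col) {
    if (!col %in% names(merged)) {
      stop_validation("feature '", col, "' absent from profiles")
    }
    xb <- merged[[col]][merged$is_binder]
    xn <- merged[[col]][!merged$is_binder]
    rs <- rank_sum_test(xb, xn)
    list(U = rs$U, p = rs$p,
         median_binder = stats::median(xb),
         median_nonbinder = stats::median(xn))
  })

  structure(list(
    n = c(binder = n_b, nonbinder = n_nb),
    k = k,
    classes = class_results,
    ranksum = ranksum
  ), class = "binder_comparison")
}

# deterministic ridge-penalized logistic regression by Newton iteration with
# step halving; objective = mean negative log-likelihood + lambda/2 * |beta|^2
# (intercept unpenalized), so duplicating every record leaves the fit unchanged
ridge_logistic <- function(X, y, lambda, maxit = 200L, tol = 1e-10) {
  n <- nrow(X)
  X1 <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X1)
  pen <- c(0, rep(lambda, p - 1L))
  obj <- function(beta) {
    eta <- drop(X1 %*% beta)
    mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      sum(pen * beta^2) / 2
  }
  beta <- rep(0, p)
  f0 <- obj(beta)
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X1, mu - y)) / n + pen * beta
    W <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X1 * W, X1) / n + diag(pen + 1e-12, p)
    step <- solve(H, grad)
    t_ <- 1
    repeat {
      beta_new <- beta - t_ * step
      f_new <- obj(beta_new)
      if (f_new <= f0 + 1e-12 || t_ < 1e-8) break
      t_ <- t_ / 2
    }
    moved <- max(abs(beta_new - beta))
    beta <- beta_new
    f0 <- f_new
    if (moved < tol) break
  }
  stats::setNames(beta, colnames(X1))
}

#' Logistic binder-probability score from UTR features
#'
#' Fits a deterministic L2-penalized logistic regression of the binder flag
#' on log10 UTR length and the per-class per-kilobase densities — the
#' "longer UTR, more CPEs" signal turned into a predictive score. Reports
#' in-sample probabilities and held-out probabilities from deterministic
#' 5-fold splits (folds assigned cyclically by row order). Constant features
#' are dropped with a warning.
#'
#' @param profiles Motif profile data frame.
#' @param labels Data frame with `transcript_id`, `is_binder`.
#' @param lambda Ridge penalty on the mean log-likelihood scale
#'   (default 1e-3).
#' @param nfolds Number of deterministic cross-validation folds (default 5).
#' @return An object of class `binder_score_model`: list with
#'   `coefficients`, `features`, `lambda`, and `scores` (data frame:
#'   `transcript_id`, `is_binder`, `prob_insample`, `prob_heldout`, `fold`).
#' @export
binder_score <- function(profiles, labels, lambda = 1e-3, nfolds = 5L) {
  merged <- merge_labels(profiles, labels)
  if (!any(merged$is_binder) || all(merged$is_binder)) {
    stop_validation("binder score needs both classes present")
  }
  density_cols <- grep("_density$", names(merged), value = TRUE)
  X <- cbind(log10_utr_length = log10(merged$utr_length),
             as.matrix(merged[, density_cols, drop = FALSE]))
  if (any(!is.finite(X))) stop_validation("binder score features must be finite")
  constant <- apply(X, 2L, function(col) max(col) - min(col) == 0)
  if (any(constant)) {
    warning("dropping constant feature(s): ",
            paste(colnames(X)[constant], collapse = ", "), call. = FALSE)
    X <- X[, !constant, drop = FALSE]
  }
  y <- as.numeric(merged$is_binder)
  n <- nrow(X)

  fit <- ridge_logistic(X, y, lambda)
  prob_in <- drop(stats::plogis(cbind(1, X) %*% fit))

  fold <- rep_len(seq_len(nfolds), n)
  prob_out <- rep(NA_real_, n)
  for (fd in seq_len(nfolds)) {
    hold <- fold == fd
    if (all(hold) || !any(hold)) next
    ytr <- y[!hold]
    if (all(ytr == 0) || all(ytr == 1)) {
      prob_out[hold] <- mean(ytr)
      next
    }
    b <- ridge_logistic(X[!hold, , drop = FALSE], ytr, lambda)
    prob_out[hold] <- drop(stats::plogis(cbind(1, X[hold, , drop = FALSE]) %*% b))
  }

  structure(list(
    coefficients = fit,
    features = colnames(X),
    lambda = lambda,
    scores = data.frame(
      transcript_id = merged$transcript_id,
      is_binder = merged$is_binder,
      prob_insample = prob_in,
      prob_heldout = prob_out,
      fold = fold,
      stringsAsFactors = FALSE
    )
  ), class = "binder_score_model")
}
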