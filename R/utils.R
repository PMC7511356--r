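# internal helpers shared across modules

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("ripcpe_config_error", "error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("ripcpe_validation_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop_config(name, " must be a single number in [", lower, ", ", upper, "]")
  }
  invisible(x)
}

# per-transcript sample variance across the columns of a matrix (denominator n-1)
row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

# area under the ROC curve via the rank-sum identity
auc_score <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop_validation("AUC needs both positive and negative labels")
  }
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
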