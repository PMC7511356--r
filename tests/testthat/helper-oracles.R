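# Independent brute-force oracles, deliberately implemented with different
# machinery than the package (character slicing, explicit enumeration,
# closed-form step-up) so that agreement is informative.

# sliding-window scanner: all 1-based starts where any pattern of the class
# matches, by direct substring comparison
oracle_class_starts <- function(sequence, patterns) {
  L <- nchar(sequence)
  hits <- integer(0)
  for (pat in patterns) {
    k <- nchar(pat)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    match <- substring(sequence, starts, starts + k - 1L) == pat
    hits <- c(hits, starts[match])
  }
  sort(unique(hits))
}

oracle_scan <- function(sequence, catalog = motif_catalog()) {
  lapply(catalog, function(cls) oracle_class_starts(sequence, cls$patterns))
}

# two-sided Fisher p by full enumeration of tables with the observed margins,
# probabilities from log-binomial coefficients
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n2 <- c_ + d; k <- a + c_
  support <- max(0, k - n2):min(k, m)
  logp <- lchoose(m, support) + lchoose(n2, k - support) - lchoose(m + n2, k)
  probs <- exp(logp)
  p_obs <- exp(lchoose(m, a) + lchoose(n2, k - a) - lchoose(m + n2, k))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# exact two-sided rank-sum p by enumeration of all rank assignments
oracle_ranksum_p <- function(x, y) {
  nx <- length(x); N <- nx + length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  U_all <- apply(utils::combn(N, nx), 2, sum) - nx * (nx + 1) / 2
  min(1, 2 * min(mean(U_all <= U), mean(U_all >= U)))
}

# BH step-up by the closed form q_(i) = min_{j >= i} p_(j) * n / j
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}

random_rna <- function(n, len_range = c(50L, 5000L),
                       prob = c(0.25, 0.25, 0.25, 0.25)) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE, prob = prob),
          collapse = "")
  }, "")
}

# small generator configuration for fast tests
small_config <- function(...) {
  args <- utils::modifyList(list(n_transcripts = 200, depth = 2e5, seed = 42),
                            list(...))
  do.call(generator_config, args)
}

make_labels <- function(n, n_binder) {
  data.frame(transcript_id = sprintf("tx%05d", seq_len(n)),
             is_binder = rep(c(TRUE, FALSE), c(n_binder, n - n_binder)),
             stringsAsFactors = FALSE)
}
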