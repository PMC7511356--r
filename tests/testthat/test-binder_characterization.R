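profiles_from_counts <- function(counts, lengths = NULL) {
  n <- length(counts)
  lengths <- lengths %||% rep(1000, n)
  data.frame(transcript_id = sprintf("t%02d", seq_len(n)),
             utr_length = lengths,
             CPEC_count = counts,
             CPEC_density = counts * 1000 / lengths,
             stringsAsFactors = FALSE)
}

test_that("threshold tables tally strict count > k per group", {
  prof <- profiles_from_counts(c(4, 4, 1, 2, 5, 0, 1))
  labs <- data.frame(transcript_id = prof$transcript_id,
                     is_binder = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  tab <- threshold_table(prof, labs, "CPEC", k = 3)
  expect_equal(unname(tab), rbind(c(2L, 1L), c(1L, 3L)))
  expect_equal(rowSums(tab), c(binder = 3, nonbinder = 4))

  # all counts zero: high column empty
  prof0 <- profiles_from_counts(rep(0, 5))
  labs0 <- data.frame(transcript_id = prof0$transcript_id,
                      is_binder = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(threshold_table(prof0, labs0, "CPEC", k = 0)[, "high"]),
               c(0L, 0L))
  # vacuous threshold puts everything in the high column
  expect_equal(unname(threshold_table(prof0, labs0, "CPEC", k = -1)[, "low"]),
               c(0L, 0L))
  expect_error(threshold_table(prof0, labs0, "Hex"),
               class = "ripcpe_validation_error")
})

test_that("Fisher worked examples match full enumeration", {
  r <- fisher_exact(rbind(c(3, 1), c(1, 3)))
  expect_equal(r$p, 34 / 70, tolerance = 1e-12)
  expect_equal(r$odds_ratio, 9)

  expect_equal(fisher_exact(rbind(c(0, 5), c(0, 5)))$p, 1)
  expect_equal(fisher_exact(rbind(c(5, 0), c(0, 5)))$p, 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact(rbind(c(5, 0), c(0, 5)))$odds_ratio, Inf)
  expect_error(fisher_exact(rbind(c(-1, 2), c(3, 4))),
               class = "ripcpe_validation_error")
})

test_that("Fisher p equals the enumeration oracle and fisher.test on random tables", {
  set.seed(71)
  for (i in 1:200) {
    n_tot <- sample(4:40, 1)
    a <- sample(0:n_tot, 1)
    b <- sample(0:(n_tot - a), 1)
    c_ <- sample(0:(n_tot - a - b), 1)
    d <- n_tot - a - b - c_
    tab <- rbind(c(a, b), c(c_, d))
    p <- fisher_exact(tab)$p
    expect_equal(p, oracle_fisher_p(tab), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("rank-sum exact branch matches enumeration; ties fall back cleanly", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_true(r$exact)
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  expect_equal(r$U, 0)

  expect_equal(rank_sum_test(c(5, 5, 5), c(5, 5, 5))$p, 1)

  set.seed(81)
  for (i in 1:30) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    z <- sample(1000, nx + ny)  # untied
    x <- z[seq_len(nx)]; y <- z[-seq_len(nx)]
    r <- rank_sum_test(x, y)
    expect_true(r$exact)
    expect_equal(r$p, oracle_ranksum_p(x, y), tolerance = 1e-12)
    expect_equal(r$p, stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
    # symmetry
    expect_equal(rank_sum_test(y, x)$p, r$p, tolerance = 1e-12)
  }
})

test_that("the normal approximation tracks the exact branch and wilcox.test", {
  set.seed(91)
  for (i in 1:10) {
    z <- sample(10000, 24)  # nx = ny = 12, pooled 24 -> approximate branch
    x <- z[1:12]; y <- z[13:24]
    r <- rank_sum_test(x, y)
    expect_false(r$exact)
    expect_lt(abs(r$p - oracle_ranksum_p(x, y)), 0.01)
    expect_equal(r$p,
                 stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-9)
  }
  # tied data agree with wilcox.test's tie-corrected approximation
  x <- c(1, 2, 2, 3, 5, 5, 6); y <- c(2, 4, 4, 5, 7, 8)
  expect_equal(rank_sum_test(x, y)$p,
               stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("compare_binders needs both groups and is order-invariant", {
  cfg <- small_config(n_transcripts = 300, binder_fraction = 0.3)
  g <- generate_utr_set(cfg)
  prof <- scan_utrs(g$utrs)$profiles
  expect_error(
    compare_binders(prof, transform(g$labels, is_binder = FALSE)),
    class = "ripcpe_validation_error")

  rep1 <- compare_binders(prof, g$labels)
  perm <- sample(nrow(prof))
  rep2 <- compare_binders(prof[perm, ], g$labels)
  expect_equal(rep1$classes, rep2$classes)
  expect_equal(rep1$ranksum, rep2$ranksum)
})

test_that("swapping group labels transposes tables and inverts odds ratios", {
  cfg <- small_config(n_transcripts = 300, binder_fraction = 0.3)
  g <- generate_utr_set(cfg)
  prof <- scan_utrs(g$utrs)$profiles
  rep1 <- compare_binders(prof, g$labels)
  flipped <- transform(g$labels, is_binder = !is_binder)
  rep2 <- compare_binders(prof, flipped)
  for (cl in names(rep1$classes)) {
    expect_equal(unname(rep2$classes[[cl]]$table),
                 unname(rep1$classes[[cl]]$table[2:1, ]))
    or1 <- rep1$classes[[cl]]$odds_ratio
    or2 <- rep2$classes[[cl]]$odds_ratio
    if (is.finite(or1) && or1 > 0) expect_equal(or2, 1 / or1)
    expect_equal(rep2$classes[[cl]]$fisher_p, rep1$classes[[cl]]$fisher_p,
                 tolerance = 1e-12)
  }
})

test_that("random labels on identical profiles give null-calibrated p-values", {
  cfg <- small_config(n_transcripts = 400, binder_fraction = 0)
  g <- generate_utr_set(cfg)
  prof <- scan_utrs(g$utrs)$profiles
  set.seed(111)
  reps <- 60
  p_len <- numeric(reps)
  for (i in seq_len(reps)) {
    labs <- data.frame(transcript_id = prof$transcript_id,
                       is_binder = sample(rep(c(TRUE, FALSE), c(100, 300))))
    p_len[i] <- compare_binders(prof, labs)$ranksum$utr_length$p
  }
  # nominal rate: about 5% of permutation-null p-values below 0.05
  expect_lt(mean(p_len < 0.05), 0.15)
  expect_gt(mean(p_len < 0.9), 0.5)
})

test_that("planted binder structure yields the expected comparative signal", {
  cfg <- generator_config(n_transcripts = 2000, seed = 121)
  g <- generate_utr_set(cfg)
  prof <- scan_utrs(g$utrs)$profiles
  rep_ <- compare_binders(prof, g$labels)
  expect_gt(rep_$classes$CPEC$odds_ratio, 1)
  expect_lt(rep_$classes$CPEC$fisher_p, 0.001)
  expect_lt(rep_$ranksum$CPEC_density$p, 0.001)
  expect_lt(rep_$ranksum$utr_length$p, 0.001)
  expect_gt(rep_$ranksum$utr_length$median_binder,
            rep_$ranksum$utr_length$median_nonbinder)
})

test_that("uninformative features give the base rate as predicted probability", {
  n <- 80
  prof <- data.frame(transcript_id = sprintf("t%02d", 1:n),
                     utr_length = rep(1000, n),
                     CPEC_count = rep(2, n),
                     CPEC_density = rep(2, n))
  labs <- data.frame(transcript_id = prof$transcript_id,
                     is_binder = rep(c(TRUE, FALSE), c(20, 60)))
  expect_warning(model <- binder_score(prof, labs), "constant")
  expect_true(all(abs(model$scores$prob_insample - 0.25) < 1e-6))
})

test_that("duplicating every record leaves the coefficients unchanged", {
  cfg <- small_config(n_transcripts = 200, binder_fraction = 0.25)
  g <- generate_utr_set(cfg)
  prof <- scan_utrs(g$utrs)$profiles
  m1 <- binder_score(prof, g$labels)
  prof2 <- rbind(prof, transform(prof, transcript_id = paste0(transcript_id, "_dup")))
  labs2 <- rbind(g$labels, transform(g$labels,
                                     transcript_id = paste0(transcript_id, "_dup")))
  m2 <- binder_score(prof2, labs2)
  expect_equal(m2$coefficients, m1$coefficients, tolerance = 1e-6)
})

test_that("the ridge fit agrees with glmnet at the same penalty", {
  skip_if_not_installed("glmnet")
  cfg <- small_config(n_transcripts = 500, binder_fraction = 0.3)
  g <- generate_utr_set(cfg)
  prof <- scan_utrs(g$utrs)$profiles
  m <- binder_score(prof, g$labels, lambda = 0.01)
  density_cols <- grep("_density$", names(prof), value = TRUE)
  X <- cbind(log10(prof$utr_length), as.matrix(prof[, density_cols]))
  gl <- glmnet::glmnet(X, as.numeric(g$labels$is_binder), family = "binomial",
                       alpha = 0, lambda = 0.01, standardize = FALSE,
                       thresh = 1e-12)
  ref <- c(as.numeric(gl$a0), as.numeric(gl$beta))
  expect_equal(unname(m$coefficients), ref, tolerance = 1e-3)
})

test_that("planted density and length effects are learnable out of sample", {
  cfg <- generator_config(n_transcripts = 1000, seed = 131)
  g <- generate_utr_set(cfg)
  prof <- scan_utrs(g$utrs)$profiles
  model <- binder_score(prof, g$labels)
  sc <- model$scores
  expect_true(all(sc$prob_heldout > 0 & sc$prob_heldout < 1))
  auc <- auc_score(sc$prob_heldout, sc$is_binder)
  expect_gt(auc, 0.5)
  expect_gt(median(sc$prob_heldout[sc$is_binder]),
            median(sc$prob_heldout[!sc$is_binder]))
})
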