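test_that("population vector is the event-averaged epoch mean", {
  set.seed(3)
  tm <- trace_matrix(matrix(rnorm(5 * 4000), 5), 20)
  tens <- extract_peri_event(tm, c(50, 100), window = c(-4, 0))
  ep <- epoch_window("pre", -2, 0)
  em <- epoch_mean(tens, ep)
  expect_equal(population_vector(tens, ep, events = 1L), em[, 1])
  expect_equal(population_vector(tens, ep), (em[, 1] + em[, 2]) / 2)
  ones <- extract_peri_event(trace_matrix(matrix(1, 5, 4000), 20),
                             50, c(-4, 0))
  expect_equal(population_vector(ones, ep), rep(1, 5))
  expect_error(population_vector(tens, ep, events = integer(0)), "empty")
})

test_that("PV correlation hits +/-1 on proportional activity and ~0 on noise", {
  set.seed(6)
  pv <- rnorm(20)
  n_bins <- 100L
  v <- matrix(0, 20, 4 * n_bins)
  # bin k activity = pv * k (positive multiples) for first half, -pv after
  for (k in seq_len(n_bins)) v[, 2 * k - 1] <- v[, 2 * k] <- pv * k
  for (k in seq_len(n_bins)) {
    i <- 2 * (n_bins + k)
    v[, i - 1] <- v[, i] <- -pv * k
  }
  ser <- pv_correlation_series(pv, trace_matrix(v, 20), bin_s = 0.1)
  expect_equal(ser$r[1:n_bins], rep(1, n_bins), tolerance = 1e-10)
  expect_equal(ser$r[(n_bins + 1):(2 * n_bins)], rep(-1, n_bins),
               tolerance = 1e-10)
  expect_equal(ser$bin_s, 0.1)
  # white-noise null calibration
  n_neur <- 50L
  vn <- matrix(rnorm(n_neur * 2000), n_neur)
  sern <- pv_correlation_series(rnorm(n_neur), trace_matrix(vn, 20))
  expect_lt(mean(abs(sern$r), na.rm = TRUE), 3 / sqrt(n_neur))
  expect_error(pv_correlation_series(rnorm(2),
                                     trace_matrix(vn[1:2, , drop = FALSE],
                                                  20)),
               "3 neurons")
})

test_that("PV block contrast extracts per-trial window means", {
  # constant series: identical means, t = 0
  ser <- structure(list(r = rep(0.4, 600),
                        time_s = (1:600 - 0.5) * 0.1, bin_s = 0.1),
                   class = "pv_series")
  anchors <- c(10, 20, 30, 40)
  blocks <- c(1L, 1L, 2L, 3L)
  ct <- pv_block_contrast(ser, anchors, blocks,
                          epoch_window("pre", -4, 0))
  expect_equal(ct$mean_safe, 0.4)
  expect_equal(ct$mean_risky, 0.4)
  expect_equal(ct$t_statistic, 0)
  expect_error(pv_block_contrast(ser, c(10, 20), c(1L, 1L),
                                 epoch_window("pre", -4, 0)),
               "risky")
  # paired t helper
  pt <- paired_block_t(c(1, 1), c(1, 1))
  expect_equal(pt$t_statistic, 0)
  pt2 <- paired_block_t(c(0.5, 0.6, 0.55, 0.62), c(0.2, 0.25, 0.22, 0.3))
  expect_lt(pt2$p_value, 0.05)
})

test_that("pairwise correlations and group summaries behave", {
  x <- rbind(sin(1:100), sin(1:100), -sin(1:100), cos(1:100))
  pc <- pairwise_ensemble_correlations(x, groups = c("a", "a", "b", "b"))
  expect_equal(pc$matrix[1, 2], 1)
  expect_equal(pc$matrix[1, 3], -1)
  expect_true(isSymmetric(pc$matrix))
  expect_equal(diag(pc$matrix), rep(1, 4))
  s <- pc$summary
  within_a <- s[s$group_a == "a" & s$group_b == "a", ]
  across <- s[s$group_a == "a" & s$group_b == "b", ]
  expect_equal(within_a$frac_pos, 1)
  expect_gt(across$frac_neg, within_a$frac_neg)
  expect_warning(pairwise_ensemble_correlations(rbind(x, rep(1, 100))),
                 "constant")
})

test_that("behavior-activity correlations separate coupled ensembles", {
  set.seed(21)
  n_tr <- 60L
  lat <- rlnorm(n_tr, 0, 0.4)
  n_per <- 40L
  coupled <- t(sapply(seq_len(n_per),
                      function(i) -lat + rnorm(n_tr, 0, 1)))
  indep <- matrix(rnorm(n_per * n_tr), n_per)
  em <- rbind(coupled, indep)
  res <- behavior_activity_correlation(em, lat, seq_len(n_per),
                                       n_per + seq_len(n_per))
  expect_lt(mean(res$r[seq_len(n_per)]), mean(res$r[n_per + seq_len(n_per)]))
  expect_lt(res$ks_p, 0.01)
  expect_lt(res$t_p, 0.01)
  # exact r = -1 for a noiseless anti-coupled neuron
  em2 <- rbind(-lat, rnorm(n_tr))
  r2 <- behavior_activity_correlation(em2, lat, 1L, 2L)$r
  expect_equal(r2[1], -1)
  expect_lt(abs(r2[2]), 2 / sqrt(n_tr) * 2)
  expect_error(behavior_activity_correlation(em, rep(1, n_tr), 1:2, 3:4),
               "constant")
  expect_error(behavior_activity_correlation(em[, 1:5], lat[1:5], 1L, 2L),
               "10 trials")
})

test_that("min-run filtering removes short runs by construction", {
  m <- c(rep(TRUE, 3), rep(FALSE, 2), rep(TRUE, 10), FALSE, TRUE)
  out <- apply_min_run(m, 10L)
  expect_equal(sum(out), 10L)
  r <- rle(out)
  expect_true(all(r$lengths[r$values] >= 10L))
  sm <- significance_mask(m, alpha = 0.001, min_run = 10L,
                          n_resamples = 100L)
  expect_true(all(rle(sm$significant)$lengths[rle(sm$significant)$values]
                  >= 10L))
})

test_that("permutation time-series test finds offsets and respects nulls", {
  set.seed(31)
  n_bins <- 60L
  a <- matrix(rnorm(20 * n_bins), 20)
  # identical groups: empty mask
  m0 <- permutation_timeseries_test(a, a, n_perm = 300L, alpha = 0.01,
                                    min_run = 5L, seed = 1L)
  expect_false(any(m0$significant))
  # offset group over bins 21:40: mask covers the offset window
  b <- matrix(rnorm(20 * n_bins), 20)
  b[, 21:40] <- b[, 21:40] + 10
  m1 <- permutation_timeseries_test(a, b, n_perm = 300L, alpha = 0.01,
                                    min_run = 10L, seed = 1L)
  expect_true(all(m1$significant[21:40]))
  expect_false(any(m1$significant[1:15]))
  expect_warning(permutation_timeseries_test(a, b, n_perm = 100L,
                                             alpha = 0.001, min_run = 5L),
                 "floor")
})

test_that("permutation p-values are super-uniform under exchangeability", {
  set.seed(32)
  hits <- 0L
  n_rep <- 60L
  for (k in seq_len(n_rep)) {
    a <- matrix(rnorm(10 * 30), 10)
    b <- matrix(rnorm(10 * 30), 10)
    m <- permutation_timeseries_test(a, b, n_perm = 200L, alpha = 0.05,
                                     min_run = 1L, seed = k)
    hits <- hits + sum(m$p < 0.05)
  }
  # per-bin rate at alpha=0.05 should not exceed ~alpha
  expect_lt(hits / (n_rep * 30), 0.08)
})

test_that("bootstrap difference-from-zero masks trivial cases correctly", {
  z <- matrix(0, 10, 30)
  m0 <- bootstrap_diff_from_zero(z, n_boot = 200L, alpha = 0.01,
                                 min_run = 5L, seed = 1L)
  expect_false(any(m0$significant))
  ones <- matrix(-1, 10, 30)
  m1 <- bootstrap_diff_from_zero(ones, n_boot = 200L, alpha = 0.01,
                                 min_run = 5L, seed = 1L)
  expect_true(all(m1$significant))
  expect_true(all(m1$upper < 0))
})

test_that("PCA divergence: identity gives empty mask, orthogonal drive is found", {
  set.seed(41)
  n <- 30L
  tb <- 120L
  base <- matrix(rnorm(n * tb, 0, 0.3), n)
  # identical inputs
  r0 <- pca_trajectory_divergence(base, base, n_null = 30L, min_run = 5L,
                                  seed = 1L)
  expect_equal(max(r0$distance), 0, tolerance = 1e-10)
  expect_false(any(r0$mask$significant))
  # two orthogonal ensembles: group 1 active in A, group 2 in B, bins 40:80
  a <- base
  b <- matrix(rnorm(n * tb, 0, 0.3), n)
  a[1:15, 40:80] <- a[1:15, 40:80] + 4
  b[16:30, 40:80] <- b[16:30, 40:80] + 4
  r1 <- pca_trajectory_divergence(a, b, n_null = 60L, min_run = 10L,
                                  seed = 2L)
  expect_true(any(r1$mask$significant[45:75]))
  expect_false(any(r1$mask$significant[1:20]))
  # variance ordering of the projections
  va <- apply(rbind(r1$projection_a, r1$projection_b), 2, var)
  expect_gte(va[1], va[2])
  expect_equal(r1$effective_alpha, 1 / 61)
})
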