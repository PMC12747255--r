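make_event_tensor <- function(n_noise = 5L, n_signal = 1L, n_events = 12L,
                              amplitude = 3, sign = 1, noise_sd = 1,
                              seed = 1L) {
  # signal neurons get a square bump inside the pre-choice window on every
  # event; noise neurons are white
  set.seed(seed)
  rate <- 20
  n <- n_noise + n_signal
  ev <- seq(30, by = 25, length.out = n_events)
  v <- matrix(rnorm(n * 20000, 0, noise_sd), n)
  if (n_signal > 0L) {
    for (tt in ev) {
      idx <- (round((tt - 3) * rate) + 1L):(round((tt - 1) * rate))
      v[seq_len(n_signal), idx] <- v[seq_len(n_signal), idx, drop = FALSE] +
        sign * amplitude
    }
  }
  zscore_per_trial(extract_peri_event(trace_matrix(v, rate), ev,
                                      c(-10, 10)))
}

test_that("strong positive responders are members; negative-going are not", {
  ep <- standard_epoch("pre_choice")
  tens <- make_event_tensor(n_noise = 4L, n_signal = 2L, amplitude = 5)
  a <- identify_ensemble(tens, ep, n_shuffle = 400L, seed = 2L)
  expect_true(all(a$member[1:2]))
  # same magnitude, negative-going: excluded regardless of exceedance
  tneg <- make_event_tensor(n_noise = 4L, n_signal = 2L, amplitude = 5,
                            sign = -1)
  aneg <- identify_ensemble(tneg, ep, n_shuffle = 400L, seed = 2L)
  expect_false(any(aneg$member[1:2]))
  expect_true(all(aneg$evaluable))
})

test_that("the 1.5-SD rule has a small, seed-stable false-positive rate", {
  ep <- standard_epoch("pre_choice")
  # 300 pure-noise neurons in batches
  rates <- vapply(1:4, function(k) {
    tens <- make_event_tensor(n_noise = 75L, n_signal = 0L,
                              seed = 40L + k)
    a <- identify_ensemble(tens, ep, n_shuffle = 300L, seed = k)
    mean(a$member)
  }, numeric(1))
  expect_lt(mean(rates), 0.12)
  expect_lt(sd(rates), 0.06)
})

test_that("membership is monotone in transient amplitude", {
  ep <- standard_epoch("pre_choice")
  amps <- c(0.5, 2, 6)
  got <- vapply(amps, function(a) {
    tens <- make_event_tensor(n_noise = 0L, n_signal = 3L, amplitude = a,
                              seed = 7L)
    sum(identify_ensemble(tens, ep, n_shuffle = 300L, seed = 3L)$member)
  }, numeric(1))
  expect_true(all(diff(got) >= 0))
  expect_equal(got[3], 3)
})

test_that("too few events marks a category not-evaluable instead of absent", {
  tens <- make_event_tensor(n_noise = 2L, n_signal = 1L, n_events = 3L)
  a <- identify_ensemble(tens, standard_epoch("pre_choice"),
                         n_shuffle = 100L, min_events = 5L)
  expect_true(all(!a$evaluable))
  expect_true(all(is.na(a$member)))
})

test_that("identification is reproducible given a seed", {
  tens <- make_event_tensor()
  ep <- standard_epoch("pre_choice")
  a1 <- identify_ensemble(tens, ep, n_shuffle = 200L, seed = 5L)
  a2 <- identify_ensemble(tens, ep, n_shuffle = 200L, seed = 5L)
  expect_identical(a1$null_mean, a2$null_mean)
  # permutation shuffle variant runs and agrees on the obvious member
  tens_s <- make_event_tensor(n_noise = 2L, n_signal = 1L, amplitude = 6)
  ap <- identify_ensemble(tens_s, ep, n_shuffle = 100L, seed = 5L,
                          shuffle = "permute")
  expect_true(ap$member[1])
})

test_that("exclusive labels resolve single, mixed and absent memberships", {
  fake <- function(members) {
    structure(data.frame(neuron = seq_along(members),
                         empirical = 1, null_mean = 0, null_sd = 1,
                         member = members, evaluable = TRUE),
              class = c("ensemble_assignment", "data.frame"))
  }
  lab <- exclusive_labels(list(pre_choice = fake(c(TRUE, TRUE, FALSE)),
                               post_choice_rew = fake(c(FALSE, TRUE, FALSE)),
                               consum = fake(c(FALSE, TRUE, FALSE))))
  expect_equal(lab, c("pre_choice", "mixed", "none"))
  expect_error(exclusive_labels(list(a = fake(TRUE),
                                     b = fake(c(TRUE, FALSE)))),
               "different neuron sets")
})

test_that("trial-count matching subsamples without replacement, seeded", {
  a <- 1:22
  b <- 101:144
  m1 <- match_trial_counts(a, b, seed = 3L)
  m2 <- match_trial_counts(a, b, seed = 3L)
  expect_identical(m1, m2)
  expect_equal(length(m1), 22L)
  expect_true(all(m1 %in% b))
  expect_false(any(duplicated(m1)))
  expect_identical(match_trial_counts(a, a + 0L, seed = 1L), a)
  expect_error(match_trial_counts(b, a), "smaller")
  # unbiasedness: each event retained with equal frequency over seeds
  counts <- integer(length(b))
  n_rep <- 400L
  for (s in seq_len(n_rep))
    counts[match_trial_counts(a, b, seed = s) - 100L] <-
      counts[match_trial_counts(a, b, seed = s) - 100L] + 1L
  gof <- chisq.test(counts)
  expect_gt(gof$p.value, 0.01)
})

test_that("dynamics classification follows the membership cross-table", {
  fake <- function(members) {
    structure(data.frame(neuron = seq_along(members), empirical = 1,
                         null_mean = 0, null_sd = 1, member = members,
                         evaluable = TRUE),
              class = c("ensemble_assignment", "data.frame"))
  }
  dyn <- classify_dynamics(fake(c(TRUE, TRUE, FALSE, FALSE)),
                           fake(c(TRUE, FALSE, TRUE, FALSE)))
  expect_equal(dyn$per_neuron$status,
               c("conserved", "lost", "new", "never"))
  expect_equal(unname(dyn$fractions),
               c(0.25, 0.25, 0.25, 0.25))
  expect_equal(unname(dyn$fractions_of_safe), c(0.5, 0.5))
  expect_error(classify_dynamics(fake(TRUE), fake(c(TRUE, FALSE))),
               "different neuron sets")
})

test_that("k-means with correlation distance recovers constructed archetypes", {
  set.seed(12)
  arch <- rbind(c(5, 0, 0), c(0, 5, 0), c(0, 0, 5))
  x <- arch[rep(1:3, each = 10), ] + matrix(rnorm(90, 0, 0.2), 30)
  lab <- kmeans_epoch_clusters(x, n_clusters = 3L, seed = 1L)
  # perfect recovery up to label permutation
  expect_equal(length(unique(lab)), 3L)
  truth <- rep(1:3, each = 10)
  expect_equal(max(table(truth, lab)) * 3, 30)
  for (g in 1:3)
    expect_equal(length(unique(lab[truth == g])), 1L)
  # independent check: stats::kmeans on row-standardized profiles agrees
  u <- t(apply(x, 1, function(r) (r - mean(r)) / sd(r)))
  km <- kmeans(u, centers = 3, nstart = 20)
  expect_equal(max(table(km$cluster, lab)) * 3, 30)
  # degenerate inputs
  expect_warning(
    lab2 <- kmeans_epoch_clusters(rbind(x, c(2, 2, 2)), 3L, seed = 1L),
    "constant")
  expect_true(is.na(lab2[31]))
  expect_equal(unique(kmeans_epoch_clusters(x, 1L, seed = 1L)), 1L)
})

test_that("proportion tests: closed-form z, chi-square identity, guards", {
  same <- compare_proportions(50, 100, 50, 100, "two_proportion_z")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  big <- compare_proportions(90, 100, 10, 100, "two_proportion_z")
  # closed form: pp = 0.5, se = sqrt(0.5*0.5*0.02), z = 0.8/se
  expect_equal(big$statistic, 0.8 / sqrt(0.5 * 0.5 * 0.02),
               tolerance = 1e-12)
  expect_lt(big$p_value, 1e-6)
  chi <- compare_proportions(30, 80, 50, 90, "chi_square")
  z <- compare_proportions(30, 80, 50, 90, "two_proportion_z")
  expect_equal(chi$statistic, z$statistic^2, tolerance = 1e-12)
  # agreement with stats::prop.test (no continuity correction)
  pt <- prop.test(c(30, 50), c(80, 90), correct = FALSE)
  expect_equal(chi$statistic, unname(pt$statistic), tolerance = 1e-12)
  expect_equal(chi$p_value, pt$p.value, tolerance = 1e-12)
  expect_warning(compare_proportions(1, 10, 2, 10, "chi_square"),
                 "expected count")
  expect_error(compare_proportions(5, 4, 1, 10), "0 <= x <= n")
})
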