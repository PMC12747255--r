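test_that("RDT schedule carries exact block structure and forced shocks", {
  cfg <- task_config()
  for (seed in c(1L, 7L, 42L)) {
    sch <- build_rdt_schedule(cfg, seed = seed)
    expect_equal(nrow(sch), 90L)
    expect_equal(as.vector(table(sch$block)), rep(30L, 3L))
    expect_equal(as.vector(tapply(sch$kind == "free", sch$block, sum)),
                 rep(22L, 3L))
    # forced shocks exact per block, never in expectation
    expect_equal(as.vector(tapply(sch$scheduled_punish, sch$block, sum)),
                 c(0L, 2L, 3L))
    # forced sides balanced 4/4 with no long repeats, before the free slots
    for (b in 1:3) {
      blk <- sch[sch$block == b, ]
      forced <- blk$kind[1:8]
      expect_true(all(forced != "free"))
      expect_equal(sum(forced == "forced_left"), 4L)
      expect_true(max(rle(forced)$lengths) <= 3L)
      expect_true(all(blk$kind[9:30] == "free"))
    }
    # scheduled shocks only on forced large-side slots
    large_kind <- paste0("forced_", attr(sch, "large_side"))
    expect_true(all(sch$kind[sch$scheduled_punish] == large_kind))
  }
})

test_that("schedules are deterministic given (config, seed)", {
  s1 <- build_rdt_schedule(task_config(), seed = 5L)
  s2 <- build_rdt_schedule(task_config(), seed = 5L)
  expect_identical(s1, s2)
  s3 <- build_rdt_schedule(task_config(), seed = 6L)
  expect_false(identical(s1$kind, s3$kind) &&
                 identical(which(s1$scheduled_punish),
                           which(s3$scheduled_punish)))
})

test_that("invalid configurations are rejected by name", {
  expect_error(task_config(forced_shock_counts = c(0L, 5L, 3L)),
               "forced_shock_counts")
  expect_error(task_config(block_punish_prob = c(0, 0.5, 1.5)),
               "block_punish_prob")
  expect_error(task_config(forced_per_block = 10L), "trials_per_block")
})

test_that("RM schedule is the zero-risk variant with identical structure", {
  sch <- build_rm_schedule(task_config(), seed = 3L)
  expect_equal(nrow(sch), 90L)
  expect_equal(sum(sch$scheduled_punish), 0L)
  expect_true(all(sch$punish_prob[sch$kind == "free"] == 0))
  one <- build_rm_schedule(task_config(n_blocks = 1L,
                                       block_punish_prob = 0,
                                       forced_shock_counts = 0L),
                           seed = 1L)
  expect_equal(nrow(one), 30L)
})

test_that("progressive-ratio requirements grow by 4 per reward", {
  expect_equal(build_pr_requirements(3), c(4L, 8L, 12L))
  expect_equal(build_pr_requirements(1), 4L)
  expect_equal(build_pr_requirements(10)[10], 40L)
  expect_error(build_pr_requirements(0), "count")
})

test_that("shock ladder has 25 intensities stepping 0.02 mA to 0.50, 10 s apart", {
  lad <- build_shock_ladder()
  expect_equal(nrow(lad), 25L)
  expect_equal(max(lad$intensity_mA), 0.50)
  expect_equal(diff(lad$intensity_mA), rep(0.02, 24L), tolerance = 1e-12)
  expect_equal(diff(lad$t_s), rep(10, 24L))
})

test_that("choice percentages follow the /22 formula, blocks independent", {
  s_all <- tiny_session(choices = rep("large", 22), punished = rep(FALSE, 22),
                        blocks = rep(1L, 22))
  expect_equal(choice_percentages(s_all)$large_pct, 100)
  s_none <- tiny_session(choices = rep("small", 22),
                         punished = rep(FALSE, 22), blocks = rep(1L, 22))
  expect_equal(choice_percentages(s_none)$large_pct, 0)
  s_half <- tiny_session(choices = rep(c("large", "small"), 11),
                         punished = rep(FALSE, 22), blocks = rep(1L, 22))
  pct <- choice_percentages(s_half)
  expect_equal(pct$large_pct, 50)
  expect_equal(pct$large_pct + pct$small_pct, 100)
})

test_that("latencies are simple timestamp differences with NA propagation", {
  s <- tiny_session()
  lat <- latencies(s)
  expect_equal(lat$choice_latency_s, rep(2, 3))
  expect_equal(lat$collection_latency_s, rep(1, 3))
  expect_equal(lat$consumption_s, rep(2, 3))
  # initiation latency: gap to the next trial's initiation; none for the last
  expect_equal(sum(!is.na(lat$initiation_latency_s)), 2L)
  expect_equal(lat$initiation_latency_s[1], 20 - 5)
  # a simulated session yields N completed trials and N-1 initiation gaps
  ses <- default_session(seed = 21L)
  l2 <- latencies(ses)
  comp <- l2[ses$trials$choice != "omission", ]
  expect_equal(sum(!is.na(comp$initiation_latency_s)), nrow(comp) - 1L)
  expect_true(all(comp$choice_latency_s >= 0))
})

test_that("non-monotone timestamps raise a data-integrity error", {
  s <- tiny_session()
  s$trials$t_collect[2] <- s$trials$t_choice[2] - 0.5
  expect_error(latencies(s), "trial")
  bad <- tiny_session()
  bad$trials$t_choice[1] <- bad$trials$t_init[1] - 1
  expect_error(behavioral_session(bad$schedule, bad$trials), "non-monotone")
})

test_that("latency bootstrap flags catch gross exceedance, not ties", {
  # identical latencies: degenerate bootstrap, nothing can exceed the CI
  expect_equal(sum(latency_bootstrap_flags(rep(1, 40), 1:30, seed = 1L)),
               0L)
  # constant safe block, one enormous risky latency
  x <- c(rep(1, 30), 1, 100, 1)
  fl <- latency_bootstrap_flags(x, 1:30, seed = 1L)
  expect_true(fl[32])
  expect_equal(sum(fl), 1L)
  # shift risky trials by +3 safe SDs: nearly all flagged
  set.seed(99)
  safe <- rlnorm(30, log(1), 0.3)
  shift <- 3 * sd(safe)
  risky <- rlnorm(60, log(1), 0.3) + shift
  fl2 <- latency_bootstrap_flags(c(safe, risky), 1:30, seed = 2L)
  expect_gte(mean(fl2[31:90]), 0.9)
  expect_error(latency_bootstrap_flags(c(NA, NA, 1), 1:2), "safe block")
})

test_that("abort counts partition by block and target", {
  s <- tiny_session(choices = rep("large", 6), punished = rep(FALSE, 6),
                    blocks = rep(1:3, each = 2))
  expect_equal(abort_counts(s)$large, c(0L, 0L, 0L))
  s$aborts <- data.frame(trial_index = c(5L, 5L, 6L, 1L),
                         t_abort = c(85.5, 85.8, 105.5, 5.5),
                         target = c("large", "large", "large", "small"))
  ac <- abort_counts(s)
  expect_equal(ac$large[ac$block == 3], 3L)
  expect_equal(ac$small[ac$block == 1], 1L)
  expect_equal(sum(ac$large) + sum(ac$small), nrow(s$aborts))
  s$aborts$target[1] <- "screen"
  expect_error(abort_counts(s), "unknown abort target")
})

test_that("risk-averse agents abort more in risky blocks", {
  pol <- agent_policy(abort_base_p = 0.05, abort_post_punish_p = 0.5)
  risky_minus_safe <- vapply(1:8, function(s) {
    ses <- default_session(seed = 100L + s, policy = pol)
    ac <- abort_counts(ses)
    sum(ac$large[ac$block >= 2]) - ac$large[ac$block == 1]
  }, numeric(1))
  expect_gt(mean(risky_minus_safe), 0)
})

test_that("punishment-abort contingency counts sum over punished trials", {
  s <- tiny_session(choices = c("large", "large", "large", "small"),
                    punished = c(TRUE, TRUE, FALSE, FALSE),
                    blocks = rep(1L, 4))
  # abort on trial 2 (successor of punished trial 1)
  s$aborts <- data.frame(trial_index = 2L, t_abort = 25.5,
                         target = "large")
  ct <- punishment_abort_contingency(s)
  expect_equal(ct$followed_by_abort, 1L)
  expect_equal(ct$followed_by_choice, 1L)
  expect_equal(ct$followed_by_abort + ct$followed_by_choice, 2L)
  s0 <- tiny_session(punished = c(FALSE, FALSE, FALSE))
  expect_error(punishment_abort_contingency(s0), "no punished trials")
  # binomial check: post-punishment abort probability 0.8 shows up in counts
  pol <- agent_policy(abort_post_punish_p = 0.8, abort_base_p = 0.02)
  counts <- vapply(1:6, function(s) {
    ses <- default_session(seed = 300L + s, policy = pol)
    ct <- punishment_abort_contingency(ses)
    ct$followed_by_abort / (ct$followed_by_abort + ct$followed_by_choice)
  }, numeric(1))
  expect_gt(mean(counts), 0.6)
})

test_that("Savitzky-Golay smoothing reproduces low-order polynomials", {
  fr <- 0:99
  cubic <- data.frame(frame = fr, x = 0.001 * fr^3 - 0.05 * fr^2 + fr,
                      y = 2 - 0.002 * fr^3)
  sm <- smooth_track(cubic)
  inner <- 13:87  # edges use shorter effective fits
  expect_equal(sm$x[inner], cubic$x[inner], tolerance = 1e-6)
  expect_equal(sm$y[inner], cubic$y[inner], tolerance = 1e-6)
  const <- data.frame(frame = fr, x = rep(2, 100), y = rep(-1, 100))
  expect_equal(smooth_track(const)$x, const$x, tolerance = 1e-9)
  # noise reduction on a line
  set.seed(5)
  noisy <- data.frame(frame = fr, x = fr + rnorm(100), y = rnorm(100))
  smn <- smooth_track(noisy)
  expect_lt(var(smn$x - fr), var(noisy$x - fr))
  expect_error(smooth_track(noisy[1:10, ]), "window")
})

test_that("path length sums Euclidean steps and is additive at frames", {
  still <- data.frame(frame = 0:9, x = rep(1, 10), y = rep(2, 10))
  expect_equal(path_length(still), 0)
  seg <- data.frame(frame = 0:1, x = c(0, 3), y = c(0, 4))
  expect_equal(path_length(seg), 5)
  ell <- data.frame(frame = 0:2, x = c(0, 1, 1), y = c(0, 0, 1))
  expect_equal(path_length(ell), 2)
  # additivity when split at a sampled frame
  set.seed(8)
  tr <- data.frame(frame = 0:49, x = cumsum(rnorm(50)),
                   y = cumsum(rnorm(50)))
  expect_equal(path_length(tr, 0, 20) + path_length(tr, 20, 49),
               path_length(tr, 0, 49))
  expect_error(path_length(tr, 100, 200), "2 frames")
})
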