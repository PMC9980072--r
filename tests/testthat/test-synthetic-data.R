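test_that("bout schedules are valid, deterministic, and respect limits", {
  cfg <- session_config(seed = 9)
  b1 <- sample_bout_schedule(cfg)
  b2 <- sample_bout_schedule(cfg)
  expect_identical(b1, b2)                       # determinism
  expect_true(all(b1$start_s >= 5))
  expect_true(all(b1$end_s <= cfg$session_duration_s - 5))
  expect_true(all(bout_durations(b1) > 0))
  # no grooming requested (infinite mean gap)
  cfg0 <- session_config(mean_ibi_s = Inf, seed = 9)
  expect_equal(nrow(sample_bout_schedule(cfg0)), 0)
  # session too short for a bout warns and returns empty
  cfgs <- session_config(session_duration_s = 12, seed = 9)
  expect_warning(bs <- sample_bout_schedule(cfgs), "short")
  expect_equal(nrow(bs), 0)
})

test_that("realized grooming fraction concentrates near the target", {
  fr <- vapply(1:15, function(i) {
    cfg <- session_config(seed = 400 + i)
    b <- sample_bout_schedule(cfg)
    bout_total_time(b) / cfg$session_duration_s
  }, numeric(1))
  expect_gte(mean(fr), 0.029)   # +/- 30% of the 4.1% target
  expect_lte(mean(fr), 0.053)
})

test_that("spike generator: rates, gains, and determinism", {
  cfg <- session_config(session_duration_s = 7200, n_spn = 1, n_fsi = 0,
                        spn_rate_range = c(4, 4), seed = 12)
  g <- generate_spikes(cfg, grooming_bouts())
  rate <- nrow(g$spikes$spikes) / 7200
  expect_lt(abs(rate - 4), 3 * sqrt(4 / 7200))   # within 3 Poisson SE
  # step_up gain: in-bout vs out-of-bout rate ratio ~ gain
  cfg2 <- session_config(session_duration_s = 7200, n_spn = 12, n_fsi = 0,
                         n_ensembles = 1, ensemble_sizes = 12,
                         response_profiles = "step_up", modulation_gain = 5,
                         shared_jitter_sd = 0, seed = 13)
  b <- sample_bout_schedule(cfg2)
  g2 <- generate_spikes(cfg2, b)
  tin <- bout_total_time(b); tout <- 7200 - tin
  tt <- g2$spikes$spikes$time_s
  inb <- rep(FALSE, length(tt))
  for (i in seq_len(nrow(b))) inb <- inb | (tt >= b$start_s[i] & tt < b$end_s[i])
  ratio <- (sum(inb) / tin) / (sum(!inb) / tout)
  expect_lt(abs(ratio - 5) / 5, 0.1)
  # byte-identical regeneration under the same seed
  g3 <- generate_spikes(cfg2, b)
  expect_identical(g2$spikes$spikes, g3$spikes$spikes)
  expect_error(generate_spikes(session_config(modulation_gain = -1)),
               "modulation_gain")
})

test_that("same-ensemble pairs are more correlated and spatially closer", {
  s <- planted_session()
  gm <- build_grooming_matrix(s$spikes, merge_close_bouts(s$bouts, 3))
  gt <- s$ground_truth$ensemble_membership
  r <- cor(t(gm$norm))
  same <- outer(gt, gt, function(a, b) !is.na(a) & !is.na(b) & a == b)
  diff_ens <- outer(gt, gt, function(a, b) !is.na(a) & !is.na(b) & a != b)
  expect_gt(mean(r[same & upper.tri(r)]), mean(r[diff_ens & upper.tri(r)]))
  # spatial structure: same-ensemble pairs closer on the probe
  pos <- s$units[, c("x_um", "depth_um")]
  d <- as.matrix(dist(pos))
  expect_lt(mean(d[same & upper.tri(d)]), mean(d[!same & upper.tri(d)]))
})

test_that("generated pose satisfies grooming predicates exactly in bouts", {
  b <- grooming_bouts(c(4, 20), c(10, 26))
  tr <- generate_pose(b, duration_s = 30, jitter_sd = 0, seed = 14)
  feat <- compute_postural_features(tr)
  thr <- heuristic_thresholds()
  tt <- (seq_len(nrow(feat)) - 1) / tr$frame_rate_hz
  inb <- (tt >= 4 & tt < 10) | (tt >= 20 & tt < 26)
  ok <- feat$snout_height > thr$min_snout_height &
    feat$eyes_mid_to_hind_mid < thr$max_eyes_hind_dist &
    feat$paws_mid_to_snout < thr$max_paws_snout_dist &
    feat$paws_mid_to_eyes_mid < thr$max_paws_eyes_dist &
    feat$paws_mid_height > thr$min_paws_height
  expect_identical(ok, inb)
})
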