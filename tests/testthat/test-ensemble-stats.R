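fake_assignment <- function(cluster) {
  structure(list(cluster = cluster, unit_ids = names(cluster)),
            class = "ensemble_assignment")
}

fake_gm <- function(m) {
  structure(list(norm = m, counts = m, segment = rep(1L, ncol(m)),
                 bin_size_s = 1.5, unit_ids = rownames(m)),
            class = "grooming_matrix")
}

test_that("distribution_auc equals exhaustive pair counting", {
  expect_equal(distribution_auc(c(0.9, 0.8), c(0.1, 0.2)), 1)
  expect_equal(distribution_auc(1:5, 1:5), 0.5)
  set.seed(71)
  for (i in 1:100) {
    x <- sample(1:8, sample(2:10, 1), replace = TRUE) + sample(c(0, 0.5), 1)
    y <- sample(1:8, sample(2:10, 1), replace = TRUE)
    expect_equal(distribution_auc(x, y), auc_bruteforce(x, y))
    expect_equal(distribution_auc(x, y), 1 - distribution_auc(y, x))
  }
})

test_that("pairwise correlation split respects membership and combinatorics", {
  set.seed(72)
  m <- matrix(rnorm(8 * 50), 8, dimnames = list(sprintf("u%d", 1:8)))
  m[2, ] <- m[1, ]   # identical pair in the same cluster
  cl <- c(1L, 1L, 2L, 2L, NA, NA, NA, NA)
  names(cl) <- rownames(m)
  cs <- pairwise_correlation_split(fake_gm(m), fake_assignment(cl))
  expect_true(any(abs(cs$within - 1) < 1e-12))
  expect_equal(length(cs$within) + length(cs$between), choose(8, 2))
  expect_equal(length(cs$within), 2)      # pairs (1,2) and (3,4)
  # planted sessions: within > between on the grooming matrix
  s <- planted_session()
  gm <- build_grooming_matrix(s$spikes, merge_close_bouts(s$bouts, 3))
  gt <- s$ground_truth$ensemble_membership
  cs2 <- pairwise_correlation_split(gm, fake_assignment(gt))
  expect_gt(mean(cs2$within), mean(cs2$between))
})

test_that("grooming-restricted AUC contrast exceeds whole-session AUC", {
  # shared slow drift gives the graded background correlations of real
  # recordings; without it both AUCs saturate at 1 and the contrast is void
  cfg <- session_config(session_duration_s = 3600, n_spn = 30, n_fsi = 4,
                        n_ensembles = 3, ensemble_sizes = c(5, 6, 7),
                        response_profiles = c("step_up", "transient_start",
                                              "transient_end"),
                        common_drift_sd = 0.2, seed = 301)
  s <- simulate_session(cfg)
  mb <- merge_close_bouts(s$bouts, 3)
  gm <- build_grooming_matrix(s$spikes, mb)
  sm <- build_session_matrix(s$spikes)
  a <- fake_assignment(s$ground_truth$ensemble_membership)
  g <- pairwise_correlation_split(gm, a)
  w <- pairwise_correlation_split(sm, a)
  auc_g <- distribution_auc(g$within, g$between)
  auc_w <- distribution_auc(w$within, w$between)
  expect_gt(auc_g, auc_w)
  expect_gt(auc_g, 0.5)
})

test_that("pairwise distances split by membership; co-located units at 0", {
  pos <- data.frame(unit_id = c("a", "b", "c", "d"),
                    x_um = c(0, 0, 200, 0), depth_um = c(50, 50, 50, 350))
  cl <- c(a = 1L, b = 1L, c = NA, d = NA)
  ds <- pairwise_distance_split(pos, fake_assignment(cl))
  expect_equal(ds$within, 0)               # co-located pair
  expect_true(200 %in% ds$between)         # adjacent shanks, same depth
  expect_equal(length(ds$between), 5)
})

test_that("time warping is exact for affine traces and preserves constants", {
  bins <- 200
  act <- matrix(seq(0, 1, length.out = bins), 1)     # global linear ramp
  b <- grooming_bouts(120, 150)                       # core 20 bins at 1.5 s
  w <- timewarp_bout_activity(act, b, 1.5, target_len_bins = 40)
  core <- w$traces[1, 1, (w$n_flank_bins + 1):(w$n_flank_bins + 40)]
  # linear ramp stays linear at the new resolution
  expect_equal(diff(core), rep(diff(core)[1], 39), tolerance = 1e-12)
  expect_equal(min(core), act[1, 81], tolerance = 1e-12)
  # constant core stays constant; identity when already target length
  actc <- matrix(5, 1, bins)
  wc <- timewarp_bout_activity(actc, b, 1.5, target_len_bins = 40)
  expect_true(all(wc$traces == 5))
  wi <- timewarp_bout_activity(act, b, 1.5, target_len_bins = 20)
  expect_equal(w2 <- wi$traces[1, 1, 4:23], act[1, 81:100],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("bootstrap band is ordered, calibrated, and detects planted steps", {
  s <- planted_session()
  mb <- merge_close_bouts(s$bouts, 3)
  ba <- bin_spikes(s$spikes, 1.5)
  mm <- groomensembles:::minmax_rows(ba$counts)
  gt <- s$ground_truth$ensemble_membership
  pool <- bout_durations(mb)
  # unmodulated ensemble: mean of non-ensemble units
  act0 <- colMeans(mm[is.na(gt), , drop = FALSE])
  w0 <- timewarp_bout_activity(act0, mb, 1.5)
  b0 <- bootstrap_null(act0, s$spikes$duration_s, pool, 1.5,
                       w0$target_len_bins, n = 400, exclude_bouts = mb,
                       seed = 81)
  expect_true(all(b0$p2.5 <= b0$p97.5))
  expect_true(all(b0$p2.5 <= b0$mean & b0$mean <= b0$p97.5))
  obs0 <- apply(w0$traces[1, , , drop = FALSE], 3, mean)
  expect_gte(band_significance(obs0, b0)$inside_fraction, 0.9)
  # planted step_up ensemble escapes over the core
  act1 <- colMeans(mm[which(gt == 1), , drop = FALSE])
  w1 <- timewarp_bout_activity(act1, mb, 1.5)
  b1 <- bootstrap_null(act1, s$spikes$duration_s, pool, 1.5,
                       w1$target_len_bins, n = 400, exclude_bouts = mb,
                       seed = 82)
  obs1 <- apply(w1$traces[1, , , drop = FALSE], 3, mean)
  sig <- band_significance(obs1, b1)
  expect_true(sig$significant)
  core_idx <- (w1$n_flank_bins + 1):(w1$n_flank_bins + w1$target_len_bins)
  expect_gte(mean(obs1[core_idx] > b1$p97.5[core_idx]), 0.5)
})

test_that("peak times land where the planted profiles put them", {
  s <- planted_session()
  mb <- merge_close_bouts(s$bouts, 3)
  ba <- bin_spikes(s$spikes, 1.5)
  mm <- groomensembles:::minmax_rows(ba$counts)
  gt <- s$ground_truth$ensemble_membership
  act <- rbind(colMeans(mm[which(gt == 1), ]),   # step_up
               colMeans(mm[which(gt == 2), ]),   # transient_start
               colMeans(mm[which(gt == 3), ]))   # transient_end
  w <- timewarp_bout_activity(act, mb, 1.5)
  pk <- ensemble_peak_times(w)
  expect_true(pk$peak_norm_time[1] >= 0 & pk$peak_norm_time[1] <= 1)
  expect_lte(pk$peak_norm_time[2], 0.25)   # start transient: early
  expect_gte(pk$peak_norm_time[3], 0.75)   # end transient: late
  # tie-break on a constant trace: earliest bin
  wc <- w; wc$traces[1, , ] <- 1
  expect_equal(ensemble_peak_times(wc)$peak_bin[1], 1)
})

test_that("fraction of active units counts members above threshold", {
  counts <- rbind(a = c(0, 2, 1), b = c(0, 0, 3), c = c(0, 1, 0),
                  d = c(5, 5, 5))
  gm <- fake_gm(counts)
  a <- fake_assignment(c(a = 1L, b = 1L, c = 1L, d = NA))
  fa <- fraction_active_units(gm, a)
  expect_equal(unname(fa[1, ]), c(0, 2 / 3, 2 / 3))
})

test_that("cluster summary fits respond to unit-count scaling", {
  mk_asg <- function(n_units, n_clusters) {
    cl <- rep(NA_integer_, n_units)
    idx <- 1
    for (k in seq_len(n_clusters)) { cl[idx:(idx + 3)] <- k; idx <- idx + 4 }
    names(cl) <- sprintf("s%d_u%d", n_units, seq_len(n_units))
    fake_assignment(cl)
  }
  # cluster count exactly linear in unit count -> R^2 = 1
  asgs <- lapply(c(40, 60, 80, 100), function(n) mk_asg(n, n / 20))
  cs <- suppressWarnings(cluster_summary(asgs))   # lm: perfect fit
  expect_equal(cs$fits$clusters_vs_units[["r_squared"]], 1, tolerance = 1e-9)
  expect_gt(cs$fits$clusters_vs_units[["slope"]], 0)
  # identical cluster counts regardless of units -> R^2 = 0
  asgs2 <- lapply(c(40, 60, 80, 100), function(n) mk_asg(n, 3))
  cs2 <- cluster_summary(asgs2)
  expect_equal(cs2$fits$clusters_vs_units[["r_squared"]], 0)
  expect_equal(cs2$per_session$n_clusters, rep(3, 4))
  expect_equal(cs2$per_session$median_size, rep(4, 4))
})
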