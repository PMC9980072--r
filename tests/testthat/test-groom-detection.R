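make_track <- function(coords_list, fps = 125) {
  # coords_list: list of keypoint -> length-3 vector, recycled per frame
  n <- length(coords_list)
  kps <- names(coords_list[[1]])
  co <- array(NA_real_, c(n, length(kps), 3),
              dimnames = list(NULL, kps, c("x", "y", "z")))
  for (f in seq_len(n)) for (k in kps) co[f, k, ] <- coords_list[[f]][[k]]
  pose3d_track(co, fps)
}

test_that("postural features reproduce hand-computed geometry", {
  frame <- list(snout = c(1, 0, 4),
                paw_L = c(0, 0, 0), paw_R = c(2, 0, 0),
                eye_L = c(0, 0, 3), eye_R = c(2, 0, 3),
                hind_L = c(0, 6, 0), hind_R = c(2, 6, 0))
  tr <- make_track(rep(list(frame), 5))
  f <- compute_postural_features(tr)
  expect_equal(f$paws_mid_to_snout, rep(4, 5))          # (1,0,0) to (1,0,4)
  expect_equal(f$eyes_mid_to_hind_mid, rep(sqrt(45), 5))  # sqrt(36 + 9)
  expect_equal(f$snout_height, rep(4, 5))
  expect_equal(f$body_speed, rep(0, 5))                 # stationary
})

test_that("missing keypoints error; low confidence marks features missing", {
  frame <- list(snout = c(0, 0, 4), paw_L = c(0, 0, 0), paw_R = c(0, 0, 0),
                eye_L = c(0, 0, 3), eye_R = c(0, 0, 3),
                hind_L = c(0, 6, 0), hind_R = c(0, 6, 0))
  co <- array(0, c(3, 6, 3),
              dimnames = list(NULL, names(frame)[-1], c("x", "y", "z")))
  expect_error(compute_postural_features(pose3d_track(co, 125)), "snout")

  tr <- make_track(rep(list(frame), 4))
  conf <- matrix(1, 4, 7); conf[2, 1] <- 0.3   # snout uncertain in frame 2
  tr$confidence <- conf
  f <- compute_postural_features(tr)
  expect_true(is.na(f$snout_height[2]))
  expect_false(anyNA(f$snout_height[-2]))
})

test_that("flags_to_bouts applies the merge and minimum-duration rules", {
  fps <- 10
  flag <- rep(FALSE, 200)
  flag[101:110] <- TRUE          # [10.0, 11.0) s
  flag[119:135] <- TRUE          # [11.8, 13.5) s, gap 0.8 s < 1.2 s
  b <- flags_to_bouts(flag, fps, merge_window_s = 1.2, min_bout_s = 2)
  expect_equal(nrow(b), 1)
  expect_equal(c(b$start_s, b$end_s), c(10.0, 13.5))

  flag2 <- rep(FALSE, 100); flag2[11:25] <- TRUE   # 1.5 s run: discarded
  expect_equal(nrow(flags_to_bouts(flag2, fps)), 0)
  expect_equal(nrow(flags_to_bouts(rep(FALSE, 50), fps)), 0)

  # property: output always satisfies the bout invariants
  set.seed(11)
  for (i in 1:30) {
    fl <- runif(300) < 0.3
    b <- flags_to_bouts(fl, 25)
    if (nrow(b) > 1) {
      expect_true(all(diff(b$start_s) > 0))
      expect_true(all(b$start_s[-1] >= b$end_s[-nrow(b)]))
    }
    expect_true(all(bout_durations(b) >= 2))
    expect_true(all(b$start_s[-1] - b$end_s[-nrow(b)] >= 1.2))
  }
})

test_that("synthetic pose closed loop recovers planted bouts", {
  cfg <- session_config(session_duration_s = 600, seed = 31)
  b <- sample_bout_schedule(cfg)
  expect_gt(nrow(b), 0)
  tr <- generate_pose(b, duration_s = 600, jitter_sd = 0, seed = 32)
  det <- detect_grooming(compute_postural_features(tr),
                         frame_rate_hz = tr$frame_rate_hz)
  expect_gte(jaccard_agreement(det, b, 600), 0.95)
  # empty schedule: no frame satisfies the grooming predicates
  tr0 <- generate_pose(grooming_bouts(), duration_s = 20, seed = 33)
  det0 <- detect_grooming(compute_postural_features(tr0),
                          frame_rate_hz = 125)
  expect_equal(nrow(det0), 0)
  expect_equal(dim(tr0$coords)[2], 15)
})

test_that("pose CSV round-trips through long format", {
  b <- grooming_bouts(2, 5)
  tr <- generate_pose(b, duration_s = 8, frame_rate_hz = 25, seed = 34)
  path <- tempfile(fileext = ".csv")
  write_pose_csv(tr, path)
  tr2 <- read_pose_csv(path, frame_rate_hz = 25)
  expect_equal(dim(tr2$coords), dim(tr$coords))
  expect_equal(sort(dimnames(tr2$coords)[[2]]), sort(dimnames(tr$coords)[[2]]))
  for (k in dimnames(tr$coords)[[2]])
    expect_equal(tr2$coords[, k, ], tr$coords[, k, ], tolerance = 1e-12)
  unlink(path)
})
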