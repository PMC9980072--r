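test_that("grooming matrix geometry: padding, binning, normalization", {
  set.seed(61)
  n <- 30
  tt <- runif(4000, 0, 600)
  sd1 <- spike_data(tt, sample(sprintf("u%02d", 1:n), 4000, replace = TRUE),
                    600, units = data.frame(unit_id = sprintf("u%02d", 1:n)))
  b <- grooming_bouts(100, 112.5)          # 12.5 s bout -> 22.5 s padded
  gm <- build_grooming_matrix(sd1, b)
  expect_equal(ncol(gm$norm), 15)          # 22.5 / 1.5
  expect_equal(gm$bin_start_times_s[1], 95)
  # min-max: every non-constant row hits 0 and 1 before smoothing
  raw <- gm$counts
  for (i in seq_len(nrow(raw))) {
    if (var(raw[i, ]) > 0) {
      nr <- (raw[i, ] - min(raw[i, ])) / diff(range(raw[i, ]))
      expect_equal(range(nr), c(0, 1))
    }
  }
  # constant row stays constant through normalization + smoothing
  sd2 <- sd1
  gm2 <- build_grooming_matrix(sd1, b)
  expect_true(all(abs(gm2$norm[apply(gm2$counts, 1, var) == 0, ]) < 1e-12))
  # unit-count gate
  sd3 <- subset_units(sd1, sprintf("u%02d", 1:10))
  expect_error(build_grooming_matrix(sd3, b), "at least 30")
  # overlapping padded bouts merge into one segment
  b2 <- grooming_bouts(c(100, 118), c(110, 130))  # pads overlap at 115/113
  gm3 <- build_grooming_matrix(sd1, b2)
  expect_equal(length(unique(gm3$segment)), 1)
})

test_that("eigenvalue test finds planted duplicates and respects the null", {
  set.seed(62)
  mk_gm <- function(counts) {
    structure(list(counts = counts, norm = counts,
                   segment = rep(1L, ncol(counts)), bin_size_s = 1.5,
                   unit_ids = rownames(counts)),
              class = "grooming_matrix")
  }
  x <- matrix(rpois(20 * 200, 4), 20)
  rownames(x) <- sprintf("u%02d", 1:20)
  x[2, ] <- x[1, ]                      # two identical rows force structure
  est <- estimate_ensemble_count(mk_gm(x), n_shuffles = 300, seed = 1)
  expect_gte(est$n_significant, 1)
  expect_equal(est$n_significant,
               sum(est$eigenvalues > est$null_threshold))
  # zero-variance row dropped with warning
  x2 <- matrix(rpois(10 * 100, 4), 10)
  rownames(x2) <- sprintf("u%02d", 1:10)
  x2[3, ] <- 0
  expect_warning(estimate_ensemble_count(mk_gm(x2), n_shuffles = 50, seed = 2),
                 "zero-variance")
})

test_that("meta-k-means: identical copies co-assign at 1 and cluster together", {
  set.seed(63)
  base <- matrix(runif(20 * 60), 20)
  base[1:5, ] <- matrix(base[1, ], 5, 60, byrow = TRUE)  # one unit copied 5x
  rownames(base) <- sprintf("u%02d", 1:20)
  gm <- structure(list(norm = base, counts = base,
                       segment = rep(1L, 60), bin_size_s = 1.5,
                       unit_ids = rownames(base)),
                  class = "grooming_matrix")
  asg <- meta_kmeans(gm, n_runs = 100, seed = 5)
  expect_true(all(asg$coassignment[1:5, 1:5] == 1))
  expect_equal(length(unique(asg$cluster[1:5])), 1)
  expect_false(anyNA(asg$cluster[1:5]))
  # coassignment is symmetric with unit diagonal
  expect_equal(asg$coassignment, t(asg$coassignment))
  expect_true(all(diag(asg$coassignment) == 1))
  expect_error(meta_kmeans(gm, k_init = 2, n_runs = 2,
                           seed = 1), NA)  # k_init override accepted
})

test_that("meta-k-means recovers planted ensembles and ignores noise", {
  s <- planted_session()
  gm <- build_grooming_matrix(s$spikes, merge_close_bouts(s$bouts, 3))
  asg <- meta_kmeans(gm, n_runs = 300, seed = 7)
  gt <- s$ground_truth$ensemble_membership
  pl <- which(!is.na(gt))
  # every planted ensemble maps onto exactly one detected cluster
  for (k in unique(gt[pl])) {
    det <- asg$cluster[names(which(gt == k))]
    expect_false(anyNA(det))
    expect_equal(length(unique(det)), 1)
  }
  # clusters of the three profiles are distinct
  reps <- vapply(unique(gt[pl]), function(k)
    asg$cluster[[names(which(gt == k))[1]]], integer(1))
  expect_equal(length(unique(reps)), 3)
  # full pipeline determinism given (data, seed)
  asg2 <- meta_kmeans(gm, n_runs = 300, seed = 7)
  expect_identical(asg$cluster, asg2$cluster)
  expect_identical(asg$coassignment, asg2$coassignment)
})

test_that("unit reordering permutes assignments without changing content", {
  s <- planted_session()
  gm <- build_grooming_matrix(s$spikes, merge_close_bouts(s$bouts, 3))
  perm <- sample(nrow(gm$norm))
  gmp <- gm
  gmp$norm <- gm$norm[perm, ]
  gmp$counts <- gm$counts[perm, ]
  gmp$unit_ids <- gm$unit_ids[perm]
  a1 <- meta_kmeans(gm, n_runs = 100, seed = 9)
  a2 <- meta_kmeans(gmp, n_runs = 100, seed = 9)
  # same unit pairs end up together regardless of input order
  ids <- names(a1$cluster)
  same1 <- outer(a1$cluster[ids], a1$cluster[ids],
                 function(a, b) !is.na(a) & !is.na(b) & a == b)
  same2 <- outer(a2$cluster[ids], a2$cluster[ids],
                 function(a, b) !is.na(a) & !is.na(b) & a == b)
  agree <- mean(same1 == same2)
  expect_gte(agree, 0.95)   # k-means draws differ; partitions nearly equal
})
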