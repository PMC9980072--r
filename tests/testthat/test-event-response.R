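toy_spikes <- function(times, duration = 100) {
  spike_data(times, rep("u1", length(times)), duration,
             units = data.frame(unit_id = "u1"))
}

test_that("bin_spikes uses half-open bins and conserves counts", {
  sd1 <- toy_spikes(rep(0.1, 10), 10)
  ba <- bin_spikes(sd1, 0.5, 0, 10)
  expect_equal(unname(ba$counts[1, 1]), 10)
  expect_equal(sum(ba$counts), 10)
  # spike exactly on an edge falls into the right-hand bin
  sd2 <- toy_spikes(c(0.5, 1.0), 10)
  ba2 <- bin_spikes(sd2, 0.5, 0, 10)
  expect_equal(unname(ba2$counts[1, 1:3]), c(0, 1, 1))
  # conservation over random spike sets, arbitrary windows
  set.seed(3)
  for (i in 1:20) {
    tt <- runif(200, 0, 50)
    sd3 <- toy_spikes(tt, 50)
    ba3 <- bin_spikes(sd3, runif(1, 0.1, 3), t0 = 5, t1 = 37)
    expect_equal(sum(ba3$counts), sum(tt >= 5 & tt < 37))
  }
})

test_that("event_triggered_average aligns events between bins 19 and 20", {
  # single event: profile equals that event's binned counts
  tt <- c(49.9, 50.1, 52.6)   # around event at 50
  sd1 <- toy_spikes(tt, 100)
  pr <- event_triggered_average(sd1, 50)
  expect_equal(ncol(pr$mean_response), 40)
  expect_equal(unname(pr$mean_response[1, 20]), 1)  # [-0.25, 0) bin
  expect_equal(unname(pr$mean_response[1, 21]), 1)  # [0, 0.25) bin
  expect_equal(unname(pr$mean_response[1, 31]), 1)  # [2.5, 2.75) bin
  expect_equal(sum(pr$mean_response), 3)
  expect_error(event_triggered_average(sd1, numeric(0)), "events")
  # events near the session edge are excluded
  pr2 <- event_triggered_average(sd1, c(2, 50))
  expect_equal(pr2$n_events_used, 1)
})

test_that("homogeneous unit has a flat profile; planted step shows a step", {
  set.seed(21)
  dur <- 3000; rate <- 5
  sd1 <- toy_spikes(sort(runif(rpois(1, rate * dur), 0, dur)), dur)
  events <- seq(20, dur - 20, by = 25)
  pr <- event_triggered_average(sd1, events)
  expected <- rate * 0.25
  expect_true(all(abs(pr$mean_response - expected) <
                    4 * sqrt(expected / length(events))))
  s <- planted_session()
  iso <- select_isolated_bouts(merge_close_bouts(s$bouts, 3))
  step_ids <- names(which(s$ground_truth$ensemble_membership == 1))
  pr2 <- event_triggered_average(s$spikes, iso$start_s)
  m <- pr2$mean_response[step_ids, , drop = FALSE]
  expect_gt(mean(m[, 21:40]), mean(m[, 1:20]))   # post > pre for step_up
})

test_that("flag_grooming_modulated matches a brute-force recomputation", {
  brute <- function(times, bouts, alignment) {
    ev <- if (alignment == "start") bouts$start_s else bouts$end_s
    ev <- ev[ev >= 5]
    per_bin <- sapply(seq_len(20), function(k) {
      lo <- -5 + (k - 1) * 0.5; hi <- lo + 0.5
      mean(sapply(ev, function(e)
        sum(times >= e + lo & times < e + hi)))
    })
    if (alignment == "start") base <- per_bin[1:6] else base <- per_bin[15:20]
    test <- per_bin[9:12]
    if (sd(base) == 0) mean(test) > mean(base)
    else mean(test) > mean(base) + 2 * sd(base)
  }
  set.seed(33)
  for (i in 1:100) {
    n_b <- sample(2:4, 1)
    starts <- sort(runif(n_b, 10, 160))
    while (any(diff(starts) < 25)) starts <- sort(runif(n_b, 10, 160))
    bouts <- grooming_bouts(starts, starts + runif(n_b, 4, 10))
    times <- sort(runif(150, 0, 200))
    al <- sample(c("start", "end"), 1)
    sd1 <- toy_spikes(times, 200)
    expect_equal(unname(flag_grooming_modulated(sd1, bouts, al)),
                 brute(times, bouts, al))
  }
  # silent unit is never flagged
  expect_false(unname(flag_grooming_modulated(
    toy_spikes(numeric(0), 100), grooming_bouts(40, 55), "start")))
})

test_that("pca typing separates planted step and transient populations", {
  set.seed(44)
  n <- 60; nb <- 40
  step <- c(rep(0, 20), rep(1, 20))
  transient <- c(rep(0, 16), rep(1, 8), rep(0, 16))
  cls <- rep(c("step", "transient"), each = n / 2)
  m <- t(vapply(cls, function(c)
    (if (c == "step") step else transient) + rnorm(nb, 0, 0.15),
    numeric(nb)))
  rownames(m) <- sprintf("u%02d", seq_len(n))
  pr <- structure(list(mean_response = m, unit_ids = rownames(m),
                       n_events_used = 10), class = "response_profile")
  ty <- pca_response_types(pr)
  expect_gte(ty$explained_variance_fraction[1],
             ty$explained_variance_fraction[2])
  expect_true(all(ty$explained_variance_fraction >= 0 &
                    ty$explained_variance_fraction <= 1))
  # best mapping of (group x sign) cells onto the two planted classes
  cell <- paste(ty$group, ty$sign)
  acc <- sum(apply(table(cell, cls), 1, max)) / n
  expect_gte(acc, 0.9)
  # mirrored pairs: equal-magnitude opposite-sign weights
  a <- step + 0.01 * rnorm(nb); c <- transient + 0.01 * rnorm(nb)
  m2 <- rbind(a = a, b = 1 - a, c = c, d = 1 - c)
  pr2 <- structure(list(mean_response = m2), class = "response_profile")
  ty2 <- pca_response_types(pr2)
  expect_equal(ty2$weights["a", 1], -ty2$weights["b", 1], tolerance = 1e-6)
  expect_equal(ty2$weights["c", 2], -ty2$weights["d", 2], tolerance = 1e-6)
})

test_that("pca reconstruction from all components restores the z-scored matrix", {
  set.seed(55)
  m <- matrix(rnorm(30 * 40), 30)
  rownames(m) <- sprintf("u%02d", 1:30)
  z <- t(scale(t(m)))
  p <- prcomp(z, center = TRUE)
  rec <- p$x %*% t(p$rotation) + matrix(p$center, 30, 40, byrow = TRUE)
  expect_equal(rec, z, tolerance = 1e-9, ignore_attr = TRUE)
})
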