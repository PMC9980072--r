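#' @title Synthetic session generator
#' @description Generates striatal grooming sessions with planted ground
#'   truth: a bout schedule matching target grooming statistics, Poisson
#'   spike trains with planted co-active ensembles and transition-locked
#'   response profiles, waveform features and probe positions consistent
#'   with the putative cell-type rule, and a 3D pose track whose postural
#'   geometry makes the grooming heuristics true exactly during bouts.
#' @name synthetic_data
NULL

RESPONSE_PROFILES <- c("step_up", "step_down", "transient_start",
                       "transient_end", "sustained_suppressed", "none")

#' Session configuration for the synthetic generator
#'
#' Defaults emulate the recorded conditions: two-hour sessions in which
#' about 4.1% of the time is spent grooming, with a mean bout of 12.4 s and
#' a mean inter-bout interval of 4.3 min (258 s). Bout durations are
#' log-normal (right-skewed, dispersion \code{bout_log_sd}), gaps
#' exponential.
#'
#' @param session_duration_s session length (default 7200 s).
#' @param n_spn,n_fsi unit counts (defaults 54 SPN + 6 FSI).
#' @param n_ensembles number of planted ensembles (default 0).
#' @param ensemble_sizes integer vector of member counts per ensemble.
#' @param response_profiles per-ensemble profile from
#'   \code{step_up, step_down, transient_start, transient_end,
#'   sustained_suppressed, none}.
#' @param spn_rate_range,fsi_rate_range baseline-rate draw ranges (Hz).
#' @param modulation_gain multiplicative rate change during each profile's
#'   active epoch (default 5; must be > 0).
#' @param shared_jitter_sd log-sd of the per-(ensemble, bout) shared
#'   multiplicative gain jitter that models bout-to-bout participation
#'   variability and creates within-ensemble co-activity beyond epoch
#'   gating (default 0.6; 0 disables).
#' @param common_drift_sd log-sd of a slow multiplicative rate drift shared
#'   by every unit (arousal/state fluctuations; timescale
#'   \code{drift_timescale_s}). Default 0: units are independent apart from
#'   planted ensembles. A small value (e.g. 0.2) produces the graded
#'   background correlations of real recordings, at the cost of a genuine
#'   common covariance component.
#' @param drift_timescale_s smoothing timescale of the shared drift
#'   (default 60 s).
#' @param groom_fraction target fraction of session grooming (default
#'   0.041; validation target implied by the bout/gap means).
#' @param mean_bout_s mean bout duration (default 12.4 s).
#' @param mean_ibi_s mean inter-bout interval (default 258 s).
#' @param bout_log_sd log-sd of the bout-duration log-normal (default 0.75).
#' @param spatial_structure place same-ensemble units close on the probe
#'   (default TRUE).
#' @param seed integer seed.
#' @return list of class \code{session_config}.
#' @export
session_config <- function(session_duration_s = 7200,
                           n_spn = 54, n_fsi = 6,
                           n_ensembles = 0,
                           ensemble_sizes = rep(6, n_ensembles),
                           response_profiles = rep(c("step_up",
                                                     "transient_start",
                                                     "transient_end",
                                                     "step_down",
                                                     "sustained_suppressed"),
                                                   length.out = n_ensembles),
                           spn_rate_range = c(0.2, 8),
                           fsi_rate_range = c(5, 25),
                           modulation_gain = 5,
                           shared_jitter_sd = 0.6,
                           common_drift_sd = 0,
                           drift_timescale_s = 60,
                           groom_fraction = 0.041,
                           mean_bout_s = 12.4,
                           mean_ibi_s = 258,
                           bout_log_sd = 0.75,
                           spatial_structure = TRUE,
                           seed = 1L) {
  stopifnot(session_duration_s > 0, n_spn >= 0, n_fsi >= 0,
            groom_fraction > 0, groom_fraction < 0.5,
            all(spn_rate_range > 0), all(fsi_rate_range > 0),
            mean_bout_s > 0, mean_ibi_s > 0,
            length(ensemble_sizes) == n_ensembles,
            length(response_profiles) == n_ensembles,
            all(response_profiles %in% RESPONSE_PROFILES))
  if (modulation_gain <= 0) stop("modulation_gain must be > 0")
  if (sum(ensemble_sizes) > n_spn + n_fsi)
    stop("sum(ensemble_sizes) exceeds the number of units")
  structure(as.list(environment()), class = "session_config")
}

#' Sample a grooming bout schedule
#'
#' Alternates exponential gaps (mean \code{mean_ibi_s}) with log-normal
#' bout durations (mean \code{mean_bout_s}, log-sd \code{bout_log_sd}),
#' keeping every bout inside \code{[5, session_duration_s - 5]}. For
#' sessions of an hour or more the realized grooming fraction concentrates
#' near \code{mean_bout_s / (mean_bout_s + mean_ibi_s)} (about 0.046 at
#' the defaults, inside +/- 30% of the 0.041 target). An infinite
#' \code{mean_ibi_s} yields no bouts; a session too short to fit a single
#' bout yields an empty schedule with a warning.
#'
#' @param cfg \code{session_config}.
#' @param seed optional integer seed (defaults to \code{cfg$seed}).
#' @return \code{grooming_bouts}.
#' @export
sample_bout_schedule <- function(cfg, seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  dur <- cfg$session_duration_s
  meanlog <- log(cfg$mean_bout_s) - cfg$bout_log_sd^2 / 2
  s <- c(); e <- c()
  t <- 5
  repeat {
    gap <- if (is.finite(cfg$mean_ibi_s)) stats::rexp(1, 1 / cfg$mean_ibi_s)
           else Inf
    start <- t + gap
    if (!is.finite(start) || start >= dur - 5) break
    len <- stats::rlnorm(1, meanlog, cfg$bout_log_sd)
    if (start + len > dur - 5) break
    s <- c(s, start); e <- c(e, start + len)
    t <- start + len
  }
  if (length(s) == 0 && is.finite(cfg$mean_ibi_s) &&
      dur < 5 + cfg$mean_ibi_s / 4)
    warning("session too short to fit a grooming bout; empty schedule")
  grooming_bouts(s, e)
}

# Active-epoch intervals for one ensemble profile, given the bout schedule.
# Returns data.frame(start, end, log_gain_sign) where sign -1 = suppression.
profile_epochs <- function(profile, bouts, duration_s) {
  if (profile == "none" || nrow(bouts) == 0)
    return(data.frame(start = numeric(0), end = numeric(0), up = logical(0)))
  switch(profile,
    step_up = data.frame(start = bouts$start_s, end = bouts$end_s, up = TRUE),
    step_down = data.frame(start = bouts$start_s, end = bouts$end_s,
                           up = FALSE),
    transient_start = data.frame(start = pmax(0, bouts$start_s - 1),
                                 end = pmin(duration_s, bouts$start_s + 1),
                                 up = TRUE),
    transient_end = data.frame(start = pmax(0, bouts$end_s - 1),
                               end = pmin(duration_s, bouts$end_s + 1),
                               up = TRUE),
    sustained_suppressed = data.frame(start = bouts$start_s,
                                      end = pmin(duration_s, bouts$end_s + 5),
                                      up = FALSE))
}

# Sample an inhomogeneous Poisson train with piecewise-constant rate.
# epochs: data.frame(start, end, mult) of rate-multiplier windows
# (multiplicative where they overlap). block_edges/block_mult optionally
# add a piecewise-constant shared modulation tiling [0, duration].
piecewise_poisson <- function(baseline, duration_s, epochs,
                              block_edges = NULL, block_mult = NULL) {
  cuts <- sort(unique(c(0, duration_s, epochs$start, epochs$end,
                        block_edges)))
  cuts <- cuts[cuts >= 0 & cuts <= duration_s]
  t0 <- cuts[-length(cuts)]; t1 <- cuts[-1]
  mult <- rep(1, length(t0))
  mid <- (t0 + t1) / 2
  if (!is.null(block_edges))
    mult <- block_mult[findInterval(mid, block_edges)]
  if (nrow(epochs)) {
    for (i in seq_len(nrow(epochs))) {
      inside <- mid >= epochs$start[i] & mid < epochs$end[i]
      mult[inside] <- mult[inside] * epochs$mult[i]
    }
  }
  lens <- t1 - t0
  counts <- stats::rpois(length(t0), baseline * mult * lens)
  times <- unlist(lapply(which(counts > 0), function(i)
    stats::runif(counts[i], t0[i], t1[i])))
  sort(times)
}

#' Generate spike trains with planted ensembles
#'
#' Each unit is an inhomogeneous Poisson train: baseline rate multiplied by
#' \code{modulation_gain} during its ensemble's active epoch (step
#' profiles: the whole bout; transient profiles: +/- 1 s around the
#' transition; suppressed profiles: \code{1/gain}). Units in the same
#' ensemble share the epoch and a per-(ensemble, bout) multiplicative
#' jitter so their co-activity exceeds epoch-gating chance. Waveform
#' features are drawn inside the putative-type regions and baseline rates
#' of modulated SPNs are capped so that realized session-mean rates stay
#' within the SPN rule, making \code{\link{classify_unit}} reproduce the
#' planted labels. With \code{spatial_structure}, ensemble members are
#' placed near a shared probe location.
#'
#' @param cfg \code{session_config}.
#' @param bouts \code{grooming_bouts} (within the session).
#' @param seed optional integer seed (defaults to \code{cfg$seed + 1}).
#' @return list with \code{spikes} (\code{spike_data}, metadata attached),
#'   \code{units} (feature/position table with \code{label}), and
#'   \code{ground_truth} (\code{unit_labels}, \code{ensemble_membership},
#'   \code{profile_per_ensemble}, \code{true_bouts}).
#' @export
generate_spikes <- function(cfg, bouts, seed = cfg$seed + 1L) {
  if (!is.null(seed)) set.seed(seed)
  bouts <- as_grooming_bouts(bouts)
  if (nrow(bouts) && max(bouts$end_s) > cfg$session_duration_s)
    stop("bouts extend past the session")
  n <- cfg$n_spn + cfg$n_fsi
  type <- c(rep("SPN", cfg$n_spn), rep("FSI", cfg$n_fsi))
  ids <- sprintf("u%03d", seq_len(n))

  base <- ifelse(type == "SPN",
                 stats::runif(n, cfg$spn_rate_range[1], cfg$spn_rate_range[2]),
                 stats::runif(n, cfg$fsi_rate_range[1], cfg$fsi_rate_range[2]))
  lo_spn <- mean(cfg$spn_rate_range)  # suppressed members need tonic rates
  lo_fsi <- mean(cfg$fsi_rate_range)

  # ensemble membership: SPNs first (striatal ensembles are SPN-dominated)
  member <- rep(NA_integer_, n)
  if (cfg$n_ensembles > 0) {
    pool <- c(which(type == "SPN"), which(type == "FSI"))
    idx <- 1
    for (k in seq_len(cfg$n_ensembles)) {
      take <- pool[idx:(idx + cfg$ensemble_sizes[k] - 1)]
      member[take] <- k
      idx <- idx + cfg$ensemble_sizes[k]
    }
  }

  # suppression is only observable in tonically active units: redraw
  # suppressed-ensemble members from the upper half of their rate range
  groom_frac <- bout_total_time(bouts) / cfg$session_duration_s
  for (k in seq_len(cfg$n_ensembles)) {
    prof <- cfg$response_profiles[k]
    if (prof %in% c("step_down", "sustained_suppressed")) {
      mem <- which(member == k)
      base[mem] <- pmax(base[mem], ifelse(type[mem] == "SPN", lo_spn, lo_fsi))
      next
    }
    if (prof == "none") next
    # cap baselines of excited SPNs so session-mean rate stays <= 10 Hz;
    # the factor absorbs the expected shared-jitter inflation plus margin
    frac <- if (prof == "step_up") groom_frac
            else 2 * nrow(bouts) / cfg$session_duration_s
    g_eff <- cfg$modulation_gain * exp(cfg$shared_jitter_sd^2 / 2) * 1.5
    cap <- 9.5 / (1 + (g_eff - 1) * frac)
    mem <- which(member == k & type == "SPN")
    base[mem] <- pmin(base[mem], cap)
  }

  # per-(ensemble, bout) shared gain jitter
  jit <- NULL
  if (cfg$n_ensembles > 0 && nrow(bouts) > 0)
    jit <- matrix(exp(stats::rnorm(cfg$n_ensembles * nrow(bouts),
                                   0, cfg$shared_jitter_sd)),
                  cfg$n_ensembles, nrow(bouts))

  # shared slow rate drift (log-normal, smoothed white noise, mean-one)
  block_edges <- NULL; block_mult <- NULL
  if (cfg$common_drift_sd > 0) {
    block_s <- 5
    nb_blk <- ceiling(cfg$session_duration_s / block_s)
    z <- stats::rnorm(nb_blk)
    z <- gauss_smooth_rows(matrix(z, 1), cfg$drift_timescale_s / block_s)[1, ]
    z <- z / stats::sd(z) * cfg$common_drift_sd
    block_edges <- block_s * (seq_len(nb_blk) - 1)
    block_mult <- exp(z - cfg$common_drift_sd^2 / 2)
  }

  spike_t <- vector("list", n)
  for (i in seq_len(n)) {
    ep <- data.frame(start = numeric(0), end = numeric(0), mult = numeric(0))
    if (!is.na(member[i])) {
      k <- member[i]
      pe <- profile_epochs(cfg$response_profiles[k], bouts,
                           cfg$session_duration_s)
      if (nrow(pe)) {
        g <- ifelse(pe$up, cfg$modulation_gain, 1 / cfg$modulation_gain)
        if (!is.null(jit)) g <- g * jit[k, seq_len(nrow(pe))]
        ep <- data.frame(start = pe$start, end = pe$end, mult = g)
      }
    }
    spike_t[[i]] <- piecewise_poisson(base[i], cfg$session_duration_s, ep,
                                      block_edges, block_mult)
  }
  nsp <- lengths(spike_t)

  # waveform features inside the putative-type regions
  width <- ifelse(type == "SPN", stats::runif(n, 180, 300),
                  stats::runif(n, 80, 140))
  pv <- ifelse(type == "SPN", stats::runif(n, 550, 900),
               stats::runif(n, 250, 450))

  # probe geometry: 4 shanks at 200 um pitch, 600 um of depth
  shank_x <- c(0, 200, 400, 600)
  x_um <- sample(shank_x, n, replace = TRUE)
  depth_um <- stats::runif(n, 0, 600)
  if (cfg$spatial_structure && cfg$n_ensembles > 0) {
    for (k in seq_len(cfg$n_ensembles)) {
      cx <- sample(shank_x, 1); cd <- stats::runif(1, 100, 500)
      mem <- which(member == k)
      x_um[mem] <- cx
      depth_um[mem] <- pmin(600, pmax(0, cd + stats::rnorm(length(mem), 0, 40)))
    }
  }

  units <- data.frame(unit_id = ids, label = type,
                      x_um = x_um, depth_um = depth_um,
                      peak_width_us = width, peak_valley_us = pv,
                      mean_rate_hz = nsp / cfg$session_duration_s,
                      baseline_rate_hz = base,
                      ensemble = member, stringsAsFactors = FALSE)
  sd <- spike_data(unlist(spike_t), rep(ids, nsp), cfg$session_duration_s,
                   units = units)
  gt <- list(unit_labels = stats::setNames(type, ids),
             ensemble_membership = stats::setNames(member, ids),
             profile_per_ensemble = cfg$response_profiles,
             true_bouts = bouts)
  list(spikes = sd, units = units, ground_truth = gt)
}

# Arena geometry templates (millimetres). The grooming template satisfies
# every default heuristic with wide margins; the locomotion template
# violates the snout-height and paw-height predicates.
.pose_template <- function(grooming) {
  if (grooming) {
    rbind(snout      = c(0,   0, 32),
          eye_L      = c(-3, -2, 30), eye_R      = c(3, -2, 30),
          ear_L      = c(-5, -4, 29), ear_R      = c(5, -4, 29),
          shoulder_L = c(-6,  4, 20), shoulder_R = c(6,  4, 20),
          elbow_L    = c(-5,  3, 24), elbow_R    = c(5,  3, 24),
          wrist_L    = c(-4,  2, 26), wrist_R    = c(4,  2, 26),
          paw_L      = c(-3,  1, 28), paw_R      = c(3,  1, 28),
          hind_L     = c(-6, 15,  0), hind_R     = c(6, 15,  0))
  } else {
    rbind(snout      = c(0, -25,  6),
          eye_L      = c(-3, -22, 8), eye_R      = c(3, -22, 8),
          ear_L      = c(-5, -20, 9), ear_R      = c(5, -20, 9),
          shoulder_L = c(-6, -12, 10), shoulder_R = c(6, -12, 10),
          elbow_L    = c(-5, -12, 6), elbow_R    = c(5, -12, 6),
          wrist_L    = c(-4, -11, 3), wrist_R    = c(4, -11, 3),
          paw_L      = c(-5, -10, 1), paw_R      = c(5, -10, 1),
          hind_L     = c(-5,  15, 0), hind_R     = c(5,  15, 0))
  }
}

#' Generate a 3D pose track consistent with a bout schedule
#'
#' Produces 15 named keypoints per frame in a millimetre arena frame.
#' During bouts the posture is the grooming template (snout raised, paws
#' near the snout, body compressed) so every default heuristic predicate
#' holds; outside bouts the mouse locomotes with a low snout and grounded
#' paws, violating the rearing and paw-height predicates. Optional
#' isotropic Gaussian jitter is added to every keypoint coordinate.
#'
#' @param bouts \code{grooming_bouts}.
#' @param duration_s track duration (default: 5 s past the last bout).
#' @param frame_rate_hz frame rate (default 125 fps).
#' @param jitter_sd keypoint jitter sd in arena units (default 0).
#' @param seed optional integer seed.
#' @return \code{pose3d_track}.
#' @export
generate_pose <- function(bouts, duration_s = NULL, frame_rate_hz = 125,
                          jitter_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(frame_rate_hz > 0)
  bouts <- as_grooming_bouts(bouts)
  if (is.null(duration_s))
    duration_s <- if (nrow(bouts)) max(bouts$end_s) + 5 else 60
  n <- floor(duration_s * frame_rate_hz)
  tt <- (seq_len(n) - 1) / frame_rate_hz
  in_bout <- rep(FALSE, n)
  for (i in seq_len(nrow(bouts)))
    in_bout <- in_bout | (tt >= bouts$start_s[i] & tt < bouts$end_s[i])

  # slow wandering body centre; stationary during grooming
  cx <- 150 + 80 * sin(2 * pi * tt / 37)
  cy <- 150 + 80 * cos(2 * pi * tt / 53)
  cx[in_bout] <- stats::approx(tt[!in_bout], cx[!in_bout], xout = tt[in_bout],
                               rule = 2)$y
  cy[in_bout] <- stats::approx(tt[!in_bout], cy[!in_bout], xout = tt[in_bout],
                               rule = 2)$y
  # hold the centre fixed within each bout (grooming is stationary)
  for (i in seq_len(nrow(bouts))) {
    idx <- which(tt >= bouts$start_s[i] & tt < bouts$end_s[i])
    if (length(idx)) { cx[idx] <- cx[idx[1]]; cy[idx] <- cy[idx[1]] }
  }

  tg <- .pose_template(TRUE); tw <- .pose_template(FALSE)
  kps <- rownames(tg)
  co <- array(0, c(n, length(kps), 3), dimnames = list(NULL, kps,
                                                       c("x", "y", "z")))
  for (k in seq_along(kps)) {
    tmpl <- ifelse(in_bout, 1, 0)
    co[, k, 1] <- cx + ifelse(in_bout, tg[k, 1], tw[k, 1])
    co[, k, 2] <- cy + ifelse(in_bout, tg[k, 2], tw[k, 2])
    co[, k, 3] <- ifelse(in_bout, tg[k, 3], tw[k, 3])
  }
  if (jitter_sd > 0)
    co <- co + stats::rnorm(length(co), 0, jitter_sd)
  pose3d_track(co, frame_rate_hz)
}

#' Simulate a complete synthetic session
#'
#' Runs the three generators (bout schedule, spikes, optional pose) with
#' child seeds derived from \code{cfg$seed} and returns a session bundle.
#'
#' @param cfg \code{session_config}.
#' @param with_pose also generate the 3D pose track (default FALSE; pose at
#'   125 fps is large for long sessions).
#' @param pose_jitter_sd keypoint jitter passed to
#'   \code{\link{generate_pose}}.
#' @return list of class \code{session_bundle}: \code{spikes},
#'   \code{units}, \code{bouts}, \code{pose} (or NULL),
#'   \code{ground_truth}, \code{config}.
#' @export
simulate_session <- function(cfg, with_pose = FALSE, pose_jitter_sd = 0) {
  bouts <- sample_bout_schedule(cfg, seed = cfg$seed)
  gen <- generate_spikes(cfg, bouts, seed = cfg$seed + 1L)
  pose <- NULL
  if (with_pose)
    pose <- generate_pose(bouts, duration_s = cfg$session_duration_s,
                          jitter_sd = pose_jitter_sd, seed = cfg$seed + 2L)
  structure(list(spikes = gen$spikes, units = gen$units, bouts = bouts,
                 pose = pose, ground_truth = gen$ground_truth, config = cfg),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf(
    "<session_bundle: %d units, %d spikes, %d bout(s), %.0f s%s>\n",
    length(x$spikes$unit_ids), nrow(x$spikes$spikes), nrow(x$bouts),
    x$config$session_duration_s,
    if (is.null(x$pose)) "" else ", with pose"))
  invisible(x)
}
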