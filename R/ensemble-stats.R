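#' @title Ensemble characterization
#' @description Within/between-ensemble correlation and distance contrasts,
#'   rank-based AUC, time-warped bout activity, duration-matched bootstrap
#'   null bands, peak times, active-unit fractions, and cross-session
#'   cluster summaries.
#' @name ensemble_stats
NULL

#' Split pairwise unit correlations by ensemble membership
#'
#' Pearson correlation for every unordered unit pair on the rows of the
#' given activity matrix, split into pairs whose two units share a cluster
#' (\code{within}) and all other pairs, including those involving
#' unassigned units (\code{between}). Pairs involving a zero-variance unit
#' are skipped and counted.
#'
#' @param gm \code{grooming_matrix} (grooming-restricted or whole-session).
#' @param a \code{ensemble_assignment}.
#' @return list with numeric vectors \code{within}, \code{between}, and
#'   \code{n_skipped}.
#' @export
pairwise_correlation_split <- function(gm, a) {
  x <- gm$norm
  cl <- a$cluster[match(rownames(x), names(a$cluster))]
  if (!any(!is.na(cl)) || max(table(cl[!is.na(cl)])) < 2)
    stop("need at least one cluster with >= 2 units")
  v <- apply(x, 1, stats::var)
  ok <- v > 0
  r <- stats::cor(t(x[ok, , drop = FALSE]))
  cl_ok <- cl[ok]
  iu <- which(upper.tri(r), arr.ind = TRUE)
  same <- !is.na(cl_ok[iu[, 1]]) & !is.na(cl_ok[iu[, 2]]) &
    cl_ok[iu[, 1]] == cl_ok[iu[, 2]]
  n_all <- choose(nrow(x), 2)
  list(within = r[iu[same, , drop = FALSE]],
       between = r[iu[!same, , drop = FALSE]],
       n_skipped = n_all - nrow(iu))
}

#' Rank-based AUC between two samples
#'
#' Probability that a random draw from \code{x} exceeds a random draw from
#' \code{y}, with ties counted one half (the Mann-Whitney construction).
#' Satisfies \code{distribution_auc(x, y) == 1 - distribution_auc(y, x)}.
#'
#' @param x,y non-empty numeric samples.
#' @return AUC in \code{[0, 1]}.
#' @export
#' @examples
#' distribution_auc(c(0.9, 0.8), c(0.1, 0.2))  # 1
distribution_auc <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  nx <- length(x); ny <- length(y)
  rk <- rank(c(x, y))
  (sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2) / (nx * ny)
}

#' Split pairwise unit distances by ensemble membership
#'
#' Euclidean distance in the probe plane (shank-axis position x depth) for
#' every unordered unit pair, split as in
#' \code{\link{pairwise_correlation_split}}. Pairs with a missing position
#' are skipped.
#'
#' @param positions data.frame with \code{unit_id}, \code{x_um},
#'   \code{depth_um}.
#' @param a \code{ensemble_assignment}.
#' @return list with \code{within}, \code{between}, \code{n_skipped}.
#' @export
pairwise_distance_split <- function(positions, a) {
  ids <- names(a$cluster)
  pos <- positions[match(ids, positions$unit_id), c("x_um", "depth_um")]
  cl <- a$cluster
  n <- length(ids)
  within <- c(); between <- c(); skipped <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (anyNA(pos[i, ]) || anyNA(pos[j, ])) { skipped <- skipped + 1L; next }
    d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    if (!is.na(cl[i]) && !is.na(cl[j]) && cl[i] == cl[j])
      within <- c(within, d)
    else between <- c(between, d)
  }
  list(within = within, between = between, n_skipped = skipped)
}

#' Mean +/- SEM of cumulative distance distributions across sessions
#'
#' Evaluates each session's within- and between-ensemble distance ECDFs on
#' a common grid and averages across sessions.
#'
#' @param splits list of per-session results from
#'   \code{\link{pairwise_distance_split}}.
#' @param grid evaluation grid (default: 100 points spanning all values).
#' @return data.frame with \code{distance}, \code{within_mean},
#'   \code{within_sem}, \code{between_mean}, \code{between_sem}.
#' @export
distance_cdf_summary <- function(splits, grid = NULL) {
  allv <- unlist(lapply(splits, function(s) c(s$within, s$between)))
  if (is.null(grid)) grid <- seq(0, max(allv), length.out = 100)
  ecdfs <- function(field) {
    m <- vapply(splits, function(s) stats::ecdf(s[[field]])(grid),
                numeric(length(grid)))
    list(mean = rowMeans(m),
         sem = apply(m, 1, stats::sd) / sqrt(length(splits)))
  }
  w <- ecdfs("within"); b <- ecdfs("between")
  data.frame(distance = grid, within_mean = w$mean, within_sem = w$sem,
             between_mean = b$mean, between_sem = b$sem)
}

# Extract the (flank, core, flank) bin-count trace for one window from a
# session-wide activity matrix and warp the core to target_len_bins.
.warp_window <- function(row, bin_size_s, start_s, end_s, pad_s,
                         target_len_bins) {
  n_flank <- floor(pad_s / bin_size_s)
  b0 <- floor(start_s / bin_size_s)          # first core bin
  b1 <- ceiling(end_s / bin_size_s) - 1      # last core bin
  core <- row[(b0 + 1):(b1 + 1)]
  pre <- row[(b0 - n_flank + 1):b0]
  post <- row[(b1 + 2):(b1 + 1 + n_flank)]
  if (length(core) < 2) {
    warped <- rep(core[1], target_len_bins)  # degenerate short core
  } else {
    warped <- stats::approx(seq_along(core), core,
                            xout = seq(1, length(core),
                                       length.out = target_len_bins))$y
  }
  c(pre, warped, post)
}

#' Linearly time-warp per-bout activity onto a common base
#'
#' Each bout's core activity (between start and end) is linearly rescaled
#' onto \code{target_len_bins} equally spaced points; the flanking
#' \code{pad_s} seconds before and after the bout are copied unwarped. The
#' default target length is the median core bin count over the supplied
#' bouts.
#'
#' @param activity numeric matrix, rows x session time bins (e.g. ensemble
#'   mean rows of a session-wide binned matrix), with \code{bin_size_s}.
#' @param bouts \code{grooming_bouts}.
#' @param bin_size_s bin width of \code{activity} columns (bin k covers
#'   \code{[k*bin, (k+1)*bin)} from session start).
#' @param target_len_bins warped core length; \code{NULL} = median core
#'   length.
#' @param pad_s unwarped flank duration (default 5 s).
#' @return \code{warped_activity}: list with \code{traces} (array
#'   rows x bouts x total bins), \code{n_flank_bins},
#'   \code{target_len_bins}, \code{norm_time} (bin centres on a normalized
#'   axis: core maps to \code{[0, 1]}).
#' @export
timewarp_bout_activity <- function(activity, bouts, bin_size_s,
                                   target_len_bins = NULL, pad_s = 5) {
  bouts <- as_grooming_bouts(bouts)
  if (is.matrix(activity) == FALSE) activity <- matrix(activity, nrow = 1)
  n_flank <- floor(pad_s / bin_size_s)
  core_len <- function(s, e) ceiling(e / bin_size_s) - floor(s / bin_size_s)
  lens <- mapply(core_len, bouts$start_s, bouts$end_s)
  if (is.null(target_len_bins))
    target_len_bins <- max(2L, as.integer(stats::median(lens)))
  stopifnot(target_len_bins >= 2)
  # only bouts fully inside the matrix with flanks
  nb <- ncol(activity)
  ok <- floor(bouts$start_s / bin_size_s) - n_flank >= 0 &
    ceiling(bouts$end_s / bin_size_s) + n_flank <= nb
  bouts <- bouts[ok, , drop = FALSE]
  if (nrow(bouts) == 0) stop("no bout fits within the activity matrix")
  total <- 2 * n_flank + target_len_bins
  tr <- array(NA_real_, c(nrow(activity), nrow(bouts), total))
  for (r in seq_len(nrow(activity)))
    for (b in seq_len(nrow(bouts)))
      tr[r, b, ] <- .warp_window(activity[r, ], bin_size_s,
                                 bouts$start_s[b], bouts$end_s[b], pad_s,
                                 target_len_bins)
  # normalized axis: core maps to [0, 1], flanks extend beyond on each side
  norm_time <- c(-(n_flank:1 - 0.5) / n_flank * (pad_s / 5),
                 (seq_len(target_len_bins) - 0.5) / target_len_bins,
                 1 + (seq_len(n_flank) - 0.5) / n_flank * (pad_s / 5))
  structure(list(traces = tr, n_flank_bins = n_flank,
                 target_len_bins = target_len_bins, norm_time = norm_time,
                 bin_size_s = bin_size_s),
            class = "warped_activity")
}

#' Bootstrap null band for warped ensemble activity
#'
#' Builds the null distribution of time-warped activity from
#' \code{n} random windows: start times uniform on
#' \code{[5, session_duration - 5 - duration]}, durations drawn with
#' replacement from the observed bout-duration pool. Each window is
#' processed identically to a real bout (flanks, binning, warping on the
#' same activity matrix), and per-warped-bin mean, 2.5th and 97.5th
#' percentiles are reported. When \code{exclude_bouts} is supplied, windows
#' intersecting those intervals are rejected and resampled, so the band
#' describes duration-matched grooming-free activity. With grooming
#' occupying a few percent of the session, more than 2.5\% of unrestricted
#' windows overlap bouts and the upper percentile saturates at bout-level
#' activity, leaving the band test without power; exclusion restores the
#' intended baseline reference.
#'
#' @param activity single row (vector) or 1-row matrix of session-binned
#'   activity (e.g. an ensemble mean).
#' @param session_duration_s session duration (s).
#' @param bout_duration_pool observed bout durations (s) to resample.
#' @param bin_size_s bin width of \code{activity}.
#' @param target_len_bins warped core length (must match the observed
#'   trace).
#' @param n number of random windows (default 1000).
#' @param pad_s flank duration (default 5 s).
#' @param exclude_bouts optional \code{grooming_bouts}; windows
#'   intersecting them are resampled.
#' @param seed optional integer seed.
#' @return \code{bootstrap_null}: list with \code{mean}, \code{p2.5},
#'   \code{p97.5} (per warped bin), \code{n}.
#' @export
bootstrap_null <- function(activity, session_duration_s, bout_duration_pool,
                           bin_size_s, target_len_bins, n = 1000, pad_s = 5,
                           exclude_bouts = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(bout_duration_pool) > 0)
  act <- if (is.matrix(activity)) activity[1, ] else as.numeric(activity)
  n_flank <- floor(pad_s / bin_size_s)
  total <- 2 * n_flank + target_len_bins
  nbins <- length(act)
  traces <- matrix(NA_real_, n, total)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:100) {
      dur <- sample(bout_duration_pool, 1)
      if (session_duration_s - 5 - dur <= 5) next
      st <- stats::runif(1, 5, session_duration_s - 5 - dur)
      b0 <- floor(st / bin_size_s); b1 <- ceiling((st + dur) / bin_size_s) - 1
      if (b0 - n_flank < 0 || b1 + 1 + n_flank > nbins) next
      if (!is.null(exclude_bouts) && nrow(exclude_bouts) > 0 &&
          any(st < exclude_bouts$end_s & st + dur > exclude_bouts$start_s))
        next
      placed <- TRUE; break
    }
    if (!placed)
      stop("could not place a null window; session too short for the pool")
    traces[i, ] <- .warp_window(act, bin_size_s, st, st + dur, pad_s,
                                target_len_bins)
  }
  structure(list(mean = colMeans(traces),
                 p2.5 = apply(traces, 2, stats::quantile, 0.025),
                 p97.5 = apply(traces, 2, stats::quantile, 0.975),
                 n = n, target_len_bins = target_len_bins,
                 n_flank_bins = n_flank),
            class = "bootstrap_null")
}

#' Fraction of warped bins where a trace escapes the null band
#'
#' Convenience test of ensemble grooming significance: an observed
#' bout-averaged warped trace is compared bin-wise against the bootstrap
#' band; an ensemble is called significant when a contiguous run of at
#' least \code{min_run} bins lies outside \code{[p2.5, p97.5]}.
#'
#' @param trace observed bout-averaged warped trace.
#' @param null \code{bootstrap_null}.
#' @param min_run minimum contiguous out-of-band run (default 2 bins).
#' @return list with \code{inside_fraction}, \code{significant},
#'   \code{outside} (logical per bin).
#' @export
band_significance <- function(trace, null, min_run = 2) {
  stopifnot(length(trace) == length(null$mean))
  outside <- trace < null$p2.5 | trace > null$p97.5
  r <- rle(outside)
  sig <- any(r$values & r$lengths >= min_run)
  list(inside_fraction = mean(!outside), significant = sig,
       outside = outside)
}

#' Peak time of bout-averaged warped ensemble activity
#'
#' Averages a \code{warped_activity} over bouts, min-max normalizes each
#' row to \code{[0, 1]}, and reports the argmax bin on the normalized time
#' axis (pre-flank < 0, core in \code{[0, 1]}, post-flank > 1). Ties take
#' the earliest bin.
#'
#' @param w \code{warped_activity}.
#' @return data.frame with \code{row}, \code{peak_bin},
#'   \code{peak_norm_time}.
#' @export
ensemble_peak_times <- function(w) {
  avg <- apply(w$traces, c(1, 3), mean)
  if (is.null(dim(avg))) avg <- matrix(avg, nrow = 1)
  avg <- minmax_rows(avg)
  pk <- apply(avg, 1, which.max)      # which.max takes the earliest tie
  data.frame(row = seq_len(nrow(avg)), peak_bin = pk,
             peak_norm_time = w$norm_time[pk])
}

#' Fraction of active units per ensemble per bin
#'
#' Fraction of member units whose raw spike count in the bin reaches
#' \code{threshold} (default: at least one spike per 1.5 s bin).
#'
#' @param gm \code{grooming_matrix} (raw counts are used).
#' @param a \code{ensemble_assignment}.
#' @param threshold minimum count for "active" (default 1).
#' @return matrix: ensembles x bins, values in \code{[0, 1]}.
#' @export
fraction_active_units <- function(gm, a, threshold = 1) {
  cl <- a$cluster[match(rownames(gm$counts), names(a$cluster))]
  ks <- sort(unique(stats::na.omit(cl)))
  out <- t(vapply(ks, function(k) {
    colMeans(gm$counts[which(cl == k), , drop = FALSE] >= threshold)
  }, numeric(ncol(gm$counts))))
  rownames(out) <- paste0("ensemble_", ks)
  out
}

#' Cross-session cluster summary
#'
#' Per-session cluster count, size statistics, percent clustered units and
#' cluster composition, plus ordinary least-squares fits of cluster count
#' and mean cluster size against unit count.
#'
#' @param assignments list of \code{ensemble_assignment}, one per session.
#' @param labels_list optional list of per-unit type labels ("SPN"/"FSI"),
#'   named by unit id, for composition counts.
#' @return list with \code{per_session} (data.frame) and \code{fits}
#'   (slope, R-squared and two-sided slope p-value for cluster count and
#'   mean size vs unit count).
#' @export
cluster_summary <- function(assignments, labels_list = NULL) {
  stopifnot(length(assignments) >= 2)
  rows <- lapply(seq_along(assignments), function(i) {
    a <- assignments[[i]]
    sz <- ensemble_sizes(a)
    comp <- c(spn_only = NA_integer_, fsi_only = NA_integer_,
              mixed = NA_integer_)
    if (!is.null(labels_list)) {
      lab <- labels_list[[i]]
      ks <- sort(unique(stats::na.omit(a$cluster)))
      kinds <- vapply(ks, function(k) {
        u <- names(a$cluster)[which(a$cluster == k)]
        types <- unique(lab[u])
        if (setequal(types, "SPN")) "spn_only"
        else if (setequal(types, "FSI")) "fsi_only" else "mixed"
      }, character(1))
      comp <- c(spn_only = sum(kinds == "spn_only"),
                fsi_only = sum(kinds == "fsi_only"),
                mixed = sum(kinds == "mixed"))
    }
    data.frame(session = i, n_units = length(a$cluster),
               n_clusters = length(sz),
               mean_size = if (length(sz)) mean(sz) else NA_real_,
               median_size = if (length(sz)) stats::median(sz) else NA_real_,
               pct_clustered = 100 * mean(!is.na(a$cluster)),
               spn_only = comp["spn_only"], fsi_only = comp["fsi_only"],
               mixed = comp["mixed"], row.names = NULL)
  })
  per_session <- do.call(rbind, rows)
  fit_stats <- function(y) {
    if (stats::var(y) == 0)
      return(c(slope = 0, r_squared = 0, p_value = NA_real_))
    f <- stats::lm(y ~ per_session$n_units)
    s <- summary(f)
    c(slope = unname(stats::coef(f)[2]), r_squared = s$r.squared,
      p_value = s$coefficients[2, 4])
  }
  list(per_session = per_session,
       fits = list(clusters_vs_units = fit_stats(per_session$n_clusters),
                   mean_size_vs_units = fit_stats(per_session$mean_size)))
}
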