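#' @title Event-aligned single-unit responses
#' @description Event-triggered averages around grooming transitions,
#'   the 2-SD grooming-modulation flag, and PCA response typing.
#' @name event_response
NULL

#' Event-triggered average response
#'
#' Bins each unit's spikes in a window around every event and averages the
#' binned counts across events. With the default window \code{(-5, 5)} and
#' 250 ms bins there are exactly 40 bins and each event time falls on the
#' boundary between bins 19 and 20 (0-based). Events closer than
#' \code{edge_s} to the session edges are excluded rather than zero-padded.
#'
#' @param sd \code{spike_data}.
#' @param events numeric event times (s), e.g. bout starts or ends.
#' @param window length-2 window around each event (default \code{c(-5, 5)}).
#' @param bin_size_s bin width (default 0.25 s).
#' @param edge_s exclusion margin at session edges (default 5 s).
#' @return \code{response_profile}: list with \code{mean_response}
#'   (units x bins), \code{bin_centers_s}, \code{n_events_used},
#'   \code{unit_ids}, \code{bin_size_s}, \code{window}.
#' @export
event_triggered_average <- function(sd, events, window = c(-5, 5),
                                    bin_size_s = 0.25, edge_s = 5) {
  stopifnot(length(window) == 2, window[2] > window[1])
  events <- events[events + window[1] >= 0 - 1e-9 &
                     events + window[2] <= sd$duration_s + 1e-9 &
                     events >= edge_s & events <= sd$duration_s - edge_s]
  if (length(events) == 0) stop("no usable events within the session")
  nb <- round((window[2] - window[1]) / bin_size_s)
  acc <- matrix(0, length(sd$unit_ids), nb)
  for (ev in events) {
    ba <- bin_spikes(sd, bin_size_s, t0 = ev + window[1], t1 = ev + window[2])
    acc <- acc + ba$counts[, seq_len(nb), drop = FALSE]
  }
  m <- acc / length(events)
  rownames(m) <- as.character(sd$unit_ids)
  structure(list(mean_response = m,
                 bin_centers_s = window[1] + bin_size_s * (seq_len(nb) - 0.5),
                 n_events_used = length(events),
                 unit_ids = sd$unit_ids, bin_size_s = bin_size_s,
                 window = window),
            class = "response_profile")
}

#' @export
print.response_profile <- function(x, ...) {
  cat(sprintf("<response_profile: %d units x %d bins, %d events>\n",
              nrow(x$mean_response), ncol(x$mean_response), x$n_events_used))
  invisible(x)
}

#' Flag grooming-modulated units (2-SD rule)
#'
#' Works on 500 ms bins of bout-averaged activity. For start-aligned
#' analysis the baseline is the grooming-free period \code{[-5, -2)} s
#' before bout start and the test window is \code{[-1, +1)} s around the
#' start; for end-aligned analysis the baseline is \code{[+2, +5)} s after
#' bout end and the test window \code{[-1, +1)} around the end. A unit is
#' flagged when the mean bout-averaged activity in the test window exceeds
#' the baseline mean by more than 2 sample standard deviations of the 6
#' bout-averaged baseline bins. This rule selects illustrative strongly
#' modulated units; it is not a filter for downstream stages. If the
#' baseline is all zero (sd = 0) the unit is flagged iff the test mean is
#' positive.
#'
#' @param sd \code{spike_data} (may be a single-unit subset).
#' @param bouts isolated \code{grooming_bouts} (pass through
#'   \code{\link{merge_close_bouts}} and \code{\link{select_isolated_bouts}}
#'   first).
#' @param alignment \code{"start"} or \code{"end"}.
#' @param n_sd flag threshold in baseline standard deviations (default 2).
#' @return named logical vector, one element per unit.
#' @export
flag_grooming_modulated <- function(sd, bouts, alignment = c("start", "end"),
                                    n_sd = 2) {
  alignment <- match.arg(alignment)
  bouts <- as_grooming_bouts(bouts)
  if (nrow(bouts) == 0) stop("need at least one bout")
  events <- if (alignment == "start") bouts$start_s else bouts$end_s
  prof <- event_triggered_average(sd, events, window = c(-5, 5),
                                  bin_size_s = 0.5)
  # 20 bins of 0.5 s spanning [-5, 5); bin k covers [-5 + k/2, -4.5 + k/2)
  centers <- prof$bin_centers_s
  if (alignment == "start") {
    base_idx <- which(centers > -5 & centers < -2)   # [-5, -2): bins 1..6
  } else {
    base_idx <- which(centers > 2 & centers < 5)     # [+2, +5): bins 15..20
  }
  test_idx <- which(centers > -1 & centers < 1)      # [-1, +1): 4 bins
  res <- apply(prof$mean_response, 1, function(r) {
    mu <- mean(r[base_idx]); sdev <- stats::sd(r[base_idx])
    tm <- mean(r[test_idx])
    if (sdev == 0) tm > mu else tm > mu + n_sd * sdev
  })
  stats::setNames(as.logical(res), rownames(prof$mean_response))
}

#' PCA response typing of event-triggered profiles
#'
#' Each unit's event-triggered average (a row of 40 bins for the +/- 5 s
#' window at 250 ms) is z-scored across time, then PCA is run with units as
#' observations and time bins as variables. The first two components are
#' time courses; each unit's weights (scores) on them determine its group:
#' units whose absolute weight is larger for the first component than the
#' second form the "PC1" group, the rest "PC2", with the sign of the
#' winning weight recorded. Component signs are unidentifiable, so each
#' component is oriented so that its largest-magnitude time bin is
#' positive, making group counts reproducible across runs. Typing is
#' intended to be applied separately per cell type and alignment.
#'
#' @param profiles \code{response_profile}.
#' @return \code{pca_typing}: list with \code{components} (2 x bins),
#'   \code{explained_variance_fraction}, \code{weights} (units x 2),
#'   \code{group} ("PC1"/"PC2"), \code{sign} ("+"/"-"), \code{unit_ids},
#'   \code{dropped} (zero-variance units).
#' @export
pca_response_types <- function(profiles) {
  m <- profiles$mean_response
  if (nrow(m) < 3) stop("need at least 3 units for response typing")
  rsd <- apply(m, 1, stats::sd)
  dropped <- rownames(m)[rsd == 0]
  if (length(dropped))
    warning(sprintf("dropping %d constant-response unit(s)", length(dropped)))
  m <- m[rsd > 0, , drop = FALSE]
  z <- t(scale(t(m)))                      # z-score each unit across time
  p <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  comp <- t(p$rotation[, 1:2])             # 2 x time
  w <- p$x[, 1:2, drop = FALSE]            # units x 2
  # orient: largest-|value| time bin of each component is positive
  for (j in 1:2) {
    flip <- sign(comp[j, which.max(abs(comp[j, ]))])
    comp[j, ] <- comp[j, ] * flip
    w[, j] <- w[, j] * flip
  }
  grp <- ifelse(abs(w[, 1]) >= abs(w[, 2]), "PC1", "PC2")
  sgn <- ifelse(ifelse(grp == "PC1", w[, 1], w[, 2]) >= 0, "+", "-")
  ev <- p$sdev^2 / sum(p$sdev^2)
  structure(list(components = comp,
                 explained_variance_fraction = ev[1:2],
                 weights = w, group = grp, sign = sgn,
                 unit_ids = rownames(m), dropped = dropped),
            class = "pca_typing")
}

#' @export
print.pca_typing <- function(x, ...) {
  cat(sprintf("<pca_typing: %d units; PC1 %d (%.1f%% var), PC2 %d (%.1f%% var)>\n",
              length(x$group), sum(x$group == "PC1"),
              100 * x$explained_variance_fraction[1],
              sum(x$group == "PC2"),
              100 * x$explained_variance_fraction[2]))
  invisible(x)
}
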