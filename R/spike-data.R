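#' Spike data container
#'
#' Per-unit spike timestamps for one session, with unit metadata.
#'
#' @param time_s numeric spike times in seconds, in \code{[0, duration_s]}.
#' @param unit_id unit identifier per spike (integer or character).
#' @param duration_s session duration in seconds.
#' @param units optional unit metadata data.frame with a \code{unit_id}
#'   column (labels, positions, waveform features).
#' @return object of class \code{spike_data}.
#' @export
spike_data <- function(time_s, unit_id, duration_s, units = NULL) {
  stopifnot(length(time_s) == length(unit_id), duration_s > 0)
  if (length(time_s) && (min(time_s) < 0 || max(time_s) > duration_s))
    stop("spike times must lie within [0, duration_s]")
  o <- order(unit_id, time_s)
  d <- data.frame(time_s = as.numeric(time_s)[o], unit_id = unit_id[o])
  ids <- if (!is.null(units)) units$unit_id else sort(unique(unit_id))
  if (!all(d$unit_id %in% ids))
    stop("spikes reference unit_ids absent from the unit table")
  structure(list(spikes = d, unit_ids = ids, duration_s = duration_s,
                 units = units),
            class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf("<spike_data: %d spikes, %d units, %.0f s>\n",
              nrow(x$spikes), length(x$unit_ids), x$duration_s))
  invisible(x)
}

#' Spike times of one unit
#' @param sd \code{spike_data}.
#' @param unit unit id.
#' @return sorted numeric vector of spike times.
#' @export
unit_spike_times <- function(sd, unit) {
  sd$spikes$time_s[sd$spikes$unit_id == unit]
}

#' Restrict a spike_data object to a subset of units
#' @param sd \code{spike_data}.
#' @param ids unit ids to keep.
#' @return \code{spike_data}.
#' @export
subset_units <- function(sd, ids) {
  keep <- sd$spikes$unit_id %in% ids
  units <- sd$units
  if (!is.null(units)) units <- units[units$unit_id %in% ids, , drop = FALSE]
  out <- spike_data(sd$spikes$time_s[keep], sd$spikes$unit_id[keep],
                    sd$duration_s, units = units)
  out$unit_ids <- ids
  out
}

#' Bin spike counts into a units x bins matrix
#'
#' Half-open bins \code{[t0 + k*bin, t0 + (k+1)*bin)} tiled from \code{t0};
#' a trailing partial bin is kept so every spike in \code{[t0, t1)} is
#' counted exactly once (total count conservation). A spike exactly on a bin
#' edge falls into the right-hand bin.
#'
#' @param sd \code{spike_data}.
#' @param bin_size_s bin width in seconds.
#' @param t0,t1 window (defaults: whole session).
#' @return \code{binned_activity}: list with \code{counts} (units x bins
#'   integer matrix), \code{unit_ids}, \code{bin_size_s},
#'   \code{bin_start_times_s}, and a \code{normalization} tag
#'   (\code{"raw_counts"}).
#' @export
bin_spikes <- function(sd, bin_size_s, t0 = 0, t1 = sd$duration_s) {
  stopifnot(t1 > t0, bin_size_s > 0)
  nb <- ceiling((t1 - t0) / bin_size_s - 1e-9)
  nu <- length(sd$unit_ids)
  sel <- sd$spikes$time_s >= t0 & sd$spikes$time_s < t1
  ti <- floor((sd$spikes$time_s[sel] - t0) / bin_size_s)
  ti[ti >= nb] <- nb - 1           # numeric guard at the right edge
  ui <- match(sd$spikes$unit_id[sel], sd$unit_ids)
  counts <- matrix(tabulate(ui + nu * ti, nbins = nu * nb), nrow = nu)
  rownames(counts) <- as.character(sd$unit_ids)
  structure(list(counts = counts, unit_ids = sd$unit_ids,
                 bin_size_s = bin_size_s,
                 bin_start_times_s = t0 + bin_size_s * (seq_len(nb) - 1),
                 normalization = "raw_counts"),
            class = "binned_activity")
}

#' @export
print.binned_activity <- function(x, ...) {
  cat(sprintf("<binned_activity: %d units x %d bins @ %g s [%s]>\n",
              nrow(x$counts), ncol(x$counts), x$bin_size_s, x$normalization))
  invisible(x)
}

# Gaussian smoothing along rows of a matrix. sd and truncation are in bins;
# the kernel is renormalized where it overhangs the edges (normalized
# convolution), so a constant row stays constant.
gauss_smooth_rows <- function(m, sd_bins, trunc_sd = 4) {
  if (sd_bins <= 0 || ncol(m) < 2) return(m)
  h <- max(1L, ceiling(trunc_sd * sd_bins))
  k <- stats::dnorm(seq(-h, h), sd = sd_bins)
  nb <- ncol(m)
  out <- matrix(0, nrow(m), nb, dimnames = dimnames(m))
  # pad with zeros, convolve, then renormalize by the kernel mass in-range
  pad <- cbind(matrix(0, nrow(m), h), m, matrix(0, nrow(m), h))
  mass <- as.numeric(stats::filter(c(rep(0, h), rep(1, nb), rep(0, h)),
                                   k, sides = 2))[(h + 1):(h + nb)]
  for (i in seq_len(nrow(m))) {
    sm <- as.numeric(stats::filter(pad[i, ], k, sides = 2))[(h + 1):(h + nb)]
    out[i, ] <- sm / mass
  }
  out
}

# Per-row min-max normalization to [0, 1]; constant rows map to all zeros
# (0/0 guard for silent units).
minmax_rows <- function(m) {
  rng <- apply(m, 1, range)
  lo <- rng[1, ]; span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  sweep(sweep(m, 1, lo, "-"), 1, span, "/")
}
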