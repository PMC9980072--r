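#' @title Putative cell-type classification
#' @description Classifies sorted striatal units into putative spiny
#'   projection neurons (SPN), fast-spiking interneurons (FSI), or 'other'
#'   from two waveform features (peak width, peak-to-valley interval) and
#'   the mean firing rate over the whole session.
#' @name unit_classification
NULL

#' Extract waveform features from a mean waveform
#'
#' \code{peak_width_us} is the full width at half maximum of the dominant
#' deflection (the sample with the largest absolute amplitude), with linear
#' interpolation at the half-maximum crossings. \code{peak_valley_us} is the
#' time from the dominant extremum to the next opposite-sign extremum.
#'
#' @param mean_waveform numeric amplitude series (arbitrary units).
#' @param sampling_rate_hz waveform sampling rate.
#' @return named numeric vector \code{c(peak_width_us, peak_valley_us)}.
#' @export
extract_waveform_features <- function(mean_waveform, sampling_rate_hz) {
  w <- as.numeric(mean_waveform)
  if (length(w) < 3) stop("waveform must have at least 3 samples")
  if (all(diff(w) >= 0) || all(diff(w) <= 0))
    stop("waveform is monotone: no extremum to measure")
  dt_us <- 1e6 / sampling_rate_hz

  i0 <- which.max(abs(w))
  sgn <- sign(w[i0])
  v <- w * sgn                       # dominant deflection now a positive peak
  half <- v[i0] / 2

  # FWHM with linear interpolation at the half-max crossings
  left <- i0
  while (left > 1 && v[left - 1] > half) left <- left - 1
  if (left == 1 || v[left - 1] > half) {
    tl <- left
  } else {
    tl <- (left - 1) + (half - v[left - 1]) / (v[left] - v[left - 1])
  }
  right <- i0
  n <- length(v)
  while (right < n && v[right + 1] > half) right <- right + 1
  if (right == n || v[right + 1] > half) {
    tr <- right
  } else {
    tr <- right + (v[right] - half) / (v[right] - v[right + 1])
  }
  peak_width_us <- (tr - tl) * dt_us

  # next opposite-sign extremum after the dominant one; monophasic
  # waveforms have no valley, reported as NA
  after <- v[i0:n]
  j <- which.min(after)              # most negative (= opposite sign) sample
  if (after[j] >= 0 || j == 1) {
    before <- v[1:i0]                # fall back to a lobe before the peak
    j2 <- which.min(before)
    peak_valley_us <- if (before[j2] >= 0) NA_real_ else (i0 - j2) * dt_us
  } else {
    peak_valley_us <- (j - 1) * dt_us
  }
  c(peak_width_us = peak_width_us, peak_valley_us = peak_valley_us)
}

#' Classify units into putative SPN / FSI / other
#'
#' The printed rule, with exact boundary semantics:
#' SPN iff \code{peak_width_us > 150} and \code{peak_valley_us > 500} and
#' \code{mean_rate_hz <= 10}; FSI iff \code{peak_width_us <= 150} and
#' \code{peak_valley_us <= 500} and \code{mean_rate_hz >= 0.1}; anything
#' else is \code{other}. The three regions partition feature space, so every
#' unit receives exactly one label. 'other' units are conventionally
#' excluded from all downstream analyses.
#'
#' @param peak_width_us waveform peak full width at half maximum (microsec).
#' @param peak_valley_us peak-to-valley interval (microseconds).
#' @param mean_rate_hz mean firing rate over the entire session (Hz),
#'   i.e. total spikes / session duration.
#' @return character vector of labels in \code{c("SPN", "FSI", "other")}.
#' @export
#' @examples
#' classify_unit(200, 600, 5)    # "SPN"
#' classify_unit(120, 400, 15)   # "FSI"
#' classify_unit(200, 600, 12)   # "other"
classify_unit <- function(peak_width_us, peak_valley_us, mean_rate_hz) {
  stopifnot(is.finite(peak_width_us), is.finite(peak_valley_us),
            is.finite(mean_rate_hz))
  spn <- peak_width_us > 150 & peak_valley_us > 500 & mean_rate_hz <= 10
  fsi <- peak_width_us <= 150 & peak_valley_us <= 500 & mean_rate_hz >= 0.1
  ifelse(spn, "SPN", ifelse(fsi, "FSI", "other"))
}

#' Classify every unit in a waveform feature table
#'
#' @param units data.frame with columns \code{peak_width_us},
#'   \code{peak_valley_us}, \code{mean_rate_hz} (one row per unit).
#' @return the table with a \code{label} column added.
#' @export
classify_units <- function(units) {
  need <- c("peak_width_us", "peak_valley_us", "mean_rate_hz")
  if (!all(need %in% names(units)))
    stop("units table needs columns: ", paste(need, collapse = ", "))
  units$label <- classify_unit(units$peak_width_us, units$peak_valley_us,
                               units$mean_rate_hz)
  units
}
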