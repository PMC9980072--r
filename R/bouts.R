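#' Grooming bout intervals
#'
#' Constructs a validated set of grooming bouts: an ordered list of
#' half-open intervals \code{[start_s, end_s)} in seconds. Bouts must be
#' sorted by start time, non-overlapping, and strictly positive in length.
#'
#' @param start_s numeric vector of bout start times (seconds).
#' @param end_s numeric vector of bout end times (seconds), same length.
#' @return A data.frame of class \code{grooming_bouts} with columns
#'   \code{start_s} and \code{end_s}.
#' @export
#' @examples
#' grooming_bouts(c(10, 100), c(22.5, 130))
grooming_bouts <- function(start_s = numeric(0), end_s = numeric(0)) {
  if (length(start_s) != length(end_s))
    stop("start_s and end_s must have the same length")
  b <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s))
  if (nrow(b) > 0) {
    b <- b[order(b$start_s), , drop = FALSE]
    rownames(b) <- NULL
    if (any(b$end_s <= b$start_s))
      stop("every bout must satisfy end_s > start_s")
    if (nrow(b) > 1 && any(b$start_s[-1] < b$end_s[-nrow(b)]))
      stop("bouts must be non-overlapping")
  }
  class(b) <- c("grooming_bouts", "data.frame")
  b
}

#' @export
print.grooming_bouts <- function(x, ...) {
  cat(sprintf("<grooming_bouts: %d bout(s), %.1f s total>\n",
              nrow(x), sum(x$end_s - x$start_s)))
  if (nrow(x) > 0) print(as.data.frame(x), ...)
  invisible(x)
}

is_grooming_bouts <- function(x) inherits(x, "grooming_bouts")

as_grooming_bouts <- function(x) {
  if (is_grooming_bouts(x)) return(x)
  grooming_bouts(x$start_s, x$end_s)
}

#' Bout durations and total grooming time
#' @param b \code{grooming_bouts}.
#' @return \code{bout_durations}: numeric vector of durations (s);
#'   \code{bout_total_time}: total time covered (s).
#' @export
bout_durations <- function(b) b$end_s - b$start_s

#' @rdname bout_durations
#' @export
bout_total_time <- function(b) sum(bout_durations(b))

# Union of possibly-overlapping intervals given as a 2-col matrix/data.frame;
# returns grooming_bouts. Touching intervals (gap 0) are fused.
interval_union <- function(start_s, end_s) {
  if (length(start_s) == 0) return(grooming_bouts())
  o <- order(start_s)
  s <- start_s[o]; e <- end_s[o]
  us <- s[1]; ue <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= ue[length(ue)]) {
      ue[length(ue)] <- max(ue[length(ue)], e[i])
    } else {
      us <- c(us, s[i]); ue <- c(ue, e[i])
    }
  }
  grooming_bouts(us, ue)
}

# total time in the intersection of two disjoint-interval sets
interval_intersection_time <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  tot <- 0
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a$start_s[i], b$start_s)
    hi <- pmin(a$end_s[i], b$end_s)
    tot <- tot + sum(pmax(0, hi - lo))
  }
  tot
}

#' Merge grooming bouts separated by short gaps
#'
#' Bouts whose inter-bout gap is shorter than \code{max_gap_s} are fused into
#' a single bout. Used to consolidate annotations before transition-aligned
#' analyses, where two bouts separated by under 3 seconds are treated as one
#' continuous bout. The operation is idempotent. A gap exactly equal to
#' \code{max_gap_s} is not merged (strict inequality).
#'
#' @param b \code{grooming_bouts}.
#' @param max_gap_s gaps strictly shorter than this (seconds) are closed.
#' @return \code{grooming_bouts}.
#' @export
merge_close_bouts <- function(b, max_gap_s = 3.0) {
  b <- as_grooming_bouts(b)
  if (nrow(b) < 2) return(b)
  s <- b$start_s[1]; e <- b$end_s[1]
  out_s <- c(); out_e <- c()
  for (i in 2:nrow(b)) {
    if (b$start_s[i] - e < max_gap_s) {
      e <- b$end_s[i]
    } else {
      out_s <- c(out_s, s); out_e <- c(out_e, e)
      s <- b$start_s[i]; e <- b$end_s[i]
    }
  }
  grooming_bouts(c(out_s, s), c(out_e, e))
}

#' Interval Jaccard index between two bout annotations
#'
#' Intersection-over-union of total time: time covered by both annotations
#' divided by time covered by either. Used to quantify agreement between
#' bout annotations (e.g. detector output vs. reference). Returns 1 when
#' both annotations are empty (degenerate convention; a message is emitted).
#'
#' @param a,b \code{grooming_bouts}.
#' @param total_duration_s session duration; intervals must lie within
#'   \code{[0, total_duration_s]}.
#' @return Jaccard index in \code{[0, 1]}.
#' @export
jaccard_agreement <- function(a, b, total_duration_s = NULL) {
  a <- as_grooming_bouts(a); b <- as_grooming_bouts(b)
  if (!is.null(total_duration_s)) {
    if ((nrow(a) && (min(a$start_s) < 0 || max(a$end_s) > total_duration_s)) ||
        (nrow(b) && (min(b$start_s) < 0 || max(b$end_s) > total_duration_s)))
      stop("intervals must lie within [0, total_duration_s]")
  }
  if (nrow(a) == 0 && nrow(b) == 0) {
    message("jaccard_agreement: both annotations empty; returning 1")
    return(1.0)
  }
  inter <- interval_intersection_time(a, b)
  uni <- bout_total_time(a) + bout_total_time(b) - inter
  inter / uni
}

#' Keep only well-isolated grooming bouts
#'
#' Drops bouts that start within \code{min_gap_s} of the end of the previous
#' bout, so that the +/- 5 s analysis flanks of retained bouts are free of
#' neighbouring grooming. Bouts are expected to have been consolidated with
#' \code{\link{merge_close_bouts}} first. The first bout is kept only if it
#' starts at least \code{edge_s} into the session so a pre-flank exists.
#'
#' @param b \code{grooming_bouts} (already merged at 3 s).
#' @param min_gap_s minimum gap from the previous bout's end (default 10 s).
#' @param edge_s required clearance from the session start (default 5 s).
#' @return \code{grooming_bouts}.
#' @export
select_isolated_bouts <- function(b, min_gap_s = 10, edge_s = 5) {
  b <- as_grooming_bouts(b)
  if (nrow(b) == 0) return(b)
  keep <- logical(nrow(b))
  keep[1] <- b$start_s[1] >= edge_s
  if (nrow(b) > 1) {
    gaps <- b$start_s[-1] - b$end_s[-nrow(b)]
    keep[-1] <- gaps >= min_gap_s
  }
  grooming_bouts(b$start_s[keep], b$end_s[keep])
}

#' Read / write bout interval CSV files
#'
#' Two-column CSV with header \code{start_s,end_s}.
#'
#' @param path file path.
#' @return \code{read_bouts_csv}: \code{grooming_bouts}.
#' @export
read_bouts_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("start_s", "end_s") %in% names(d)))
    stop("bout CSV must have columns start_s, end_s")
  grooming_bouts(d$start_s, d$end_s)
}

#' @rdname read_bouts_csv
#' @param b \code{grooming_bouts} to write.
#' @export
write_bouts_csv <- function(b, path) {
  utils::write.csv(as.data.frame(as_grooming_bouts(b))[, c("start_s", "end_s")],
                   path, row.names = FALSE)
  invisible(path)
}
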