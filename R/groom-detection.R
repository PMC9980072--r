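#' @title Grooming detection from 3D pose
#' @description Postural-heuristic grooming detection: per-frame predicates
#'   on rearing and paws-near-head geometry, followed by temporal merging of
#'   flagged frames and a minimum-duration filter.
#' @name groom_detection
NULL

#' The 15 tracked keypoints
#' @export
POSE_KEYPOINTS <- c(
  "snout", "eye_L", "eye_R", "ear_L", "ear_R",
  "shoulder_L", "shoulder_R", "elbow_L", "elbow_R",
  "wrist_L", "wrist_R", "paw_L", "paw_R", "hind_L", "hind_R"
)

#' Construct a 3D pose track
#'
#' @param coords numeric array \code{n_frames x n_keypoints x 3} (x, y, z),
#'   with keypoint names as the second dimnames.
#' @param frame_rate_hz acquisition frame rate (default 125 fps).
#' @param frames optional frame indices (0-based, strictly increasing).
#' @param confidence optional \code{n_frames x n_keypoints} matrix of
#'   per-keypoint tracking confidence in \code{[0, 1]}.
#' @return object of class \code{pose3d_track}.
#' @export
pose3d_track <- function(coords, frame_rate_hz = 125, frames = NULL,
                         confidence = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3, frame_rate_hz > 0)
  if (is.null(dimnames(coords)[[2]]))
    stop("coords must carry keypoint names on the second dimension")
  n <- dim(coords)[1]
  if (is.null(frames)) frames <- seq_len(n) - 1L
  if (length(frames) != n || (n > 1 && any(diff(frames) <= 0)))
    stop("frames must be strictly increasing and match coords")
  if (!is.null(confidence))
    stopifnot(nrow(confidence) == n, ncol(confidence) == dim(coords)[2])
  structure(list(coords = coords, frame_rate_hz = frame_rate_hz,
                 frames = as.integer(frames), confidence = confidence),
            class = "pose3d_track")
}

#' @export
print.pose3d_track <- function(x, ...) {
  cat(sprintf("<pose3d_track: %d frames @ %g fps, %d keypoints>\n",
              dim(x$coords)[1], x$frame_rate_hz, dim(x$coords)[2]))
  invisible(x)
}

#' Heuristic thresholds for grooming detection
#'
#' Threshold container for the per-frame grooming predicates. Distances and
#' heights are in arena units (the generator's arena uses millimetres);
#' defaults are calibrated to the synthetic arena geometry and are
#' arena-specific — real recordings need their own calibration. A frame is
#' flagged as grooming when the mouse is rearing (snout high, eyes-to-hind
#' midline compressed) AND its paws are near its head (paw midpoint close to
#' the snout and to the eye midpoint, paw midpoint elevated), optionally AND
#' moving slowly. Low-confidence keypoints fail predicates conservatively.
#'
#' @param min_snout_height rearing: snout z must exceed this.
#' @param max_eyes_hind_dist rearing: eyes-midpoint to hind-midpoint
#'   distance must be below this.
#' @param max_paws_snout_dist paw-midpoint to snout distance ceiling.
#' @param max_paws_eyes_dist paw-midpoint to eyes-midpoint distance ceiling.
#' @param min_paws_height paw-midpoint z floor.
#' @param max_speed optional body-speed ceiling (units/s); \code{NULL}
#'   disables the speed predicate.
#' @param merge_window_s flagged runs separated by less than this are merged
#'   (default 1.2 s).
#' @param min_bout_s merged bouts shorter than this are discarded
#'   (default 2 s).
#' @param min_confidence keypoints below this confidence are treated as
#'   missing (default 0.6).
#' @return list of class \code{heuristic_thresholds}.
#' @export
heuristic_thresholds <- function(min_snout_height = 20,
                                 max_eyes_hind_dist = 50,
                                 max_paws_snout_dist = 15,
                                 max_paws_eyes_dist = 18,
                                 min_paws_height = 10,
                                 max_speed = NULL,
                                 merge_window_s = 1.2,
                                 min_bout_s = 2.0,
                                 min_confidence = 0.6) {
  stopifnot(merge_window_s > 0, min_bout_s >= 0)
  structure(list(min_snout_height = min_snout_height,
                 max_eyes_hind_dist = max_eyes_hind_dist,
                 max_paws_snout_dist = max_paws_snout_dist,
                 max_paws_eyes_dist = max_paws_eyes_dist,
                 min_paws_height = min_paws_height,
                 max_speed = max_speed,
                 merge_window_s = merge_window_s,
                 min_bout_s = min_bout_s,
                 min_confidence = min_confidence),
            class = "heuristic_thresholds")
}

.kp <- function(track, name) {
  kps <- dimnames(track$coords)[[2]]
  if (!name %in% kps) stop(sprintf("required keypoint '%s' missing", name))
  m <- track$coords[, name, , drop = FALSE]
  dim(m) <- dim(m)[c(1, 3)]
  m
}

.kp_ok <- function(track, name, min_confidence) {
  if (is.null(track$confidence)) return(rep(TRUE, dim(track$coords)[1]))
  j <- match(name, dimnames(track$coords)[[2]])
  track$confidence[, j] >= min_confidence
}

.row_dist <- function(a, b) sqrt(rowSums((a - b)^2))

#' Compute per-frame postural features
#'
#' Midpoints are coordinate-wise means of the two named keypoints; distances
#' are 3D Euclidean. Body speed is the frame-to-frame displacement of the
#' eye midpoint times the frame rate, smoothed with a centred moving
#' average. Frames with a low-confidence contributing keypoint get \code{NA}
#' features, which downstream predicates treat as non-grooming.
#'
#' @param track \code{pose3d_track}.
#' @param speed_smooth_s centred moving-average window for body speed
#'   (default 0.2 s).
#' @param min_confidence confidence cutoff below which a keypoint is missing.
#' @return data.frame with one row per frame: \code{snout_height},
#'   \code{eyes_mid_to_hind_mid}, \code{paws_mid_to_snout},
#'   \code{paws_mid_to_eyes_mid}, \code{paws_mid_height}, \code{body_speed}.
#' @export
compute_postural_features <- function(track, speed_smooth_s = 0.2,
                                      min_confidence = 0.6) {
  stopifnot(inherits(track, "pose3d_track"))
  need <- c("snout", "paw_L", "paw_R", "eye_L", "eye_R", "hind_L", "hind_R")
  snout <- .kp(track, "snout")
  paws_mid <- (.kp(track, "paw_L") + .kp(track, "paw_R")) / 2
  eyes_mid <- (.kp(track, "eye_L") + .kp(track, "eye_R")) / 2
  hind_mid <- (.kp(track, "hind_L") + .kp(track, "hind_R")) / 2

  ok <- Reduce(`&`, lapply(need, .kp_ok, track = track,
                           min_confidence = min_confidence))

  n <- dim(track$coords)[1]
  feat <- data.frame(
    snout_height = snout[, 3],
    eyes_mid_to_hind_mid = .row_dist(eyes_mid, hind_mid),
    paws_mid_to_snout = .row_dist(paws_mid, snout),
    paws_mid_to_eyes_mid = .row_dist(paws_mid, eyes_mid),
    paws_mid_height = paws_mid[, 3]
  )

  # speed of the eye midpoint; centred moving-average smoothing
  if (n >= 2) {
    step <- .row_dist(eyes_mid[-1, , drop = FALSE],
                      eyes_mid[-n, , drop = FALSE]) * track$frame_rate_hz
    sp <- c(step[1], step)        # per-frame, first frame copies the next
    w <- max(1L, round(speed_smooth_s * track$frame_rate_hz))
    if (w %% 2 == 0) w <- w + 1L
    if (w > 1 && n >= w) {
      k <- rep(1 / w, w)
      sm <- stats::filter(sp, k, sides = 2)
      sp <- ifelse(is.na(sm), sp, as.numeric(sm))  # edges keep raw value
    }
    feat$body_speed <- sp
  } else {
    feat$body_speed <- rep(0, n)
  }
  feat[!ok, ] <- NA
  feat
}

#' Detect grooming bouts from postural features
#'
#' Applies the per-frame grooming predicate (conjunction of rearing,
#' paws-near-head, and optional slow-movement conditions; \code{NA} features
#' fail), merges flagged runs whose gaps are shorter than
#' \code{merge_window_s}, and discards bouts shorter than \code{min_bout_s}.
#' Frame \code{f} occupies \code{[f/rate, (f+1)/rate)} seconds.
#'
#' @param feat postural features from \code{\link{compute_postural_features}}.
#' @param thr \code{\link{heuristic_thresholds}}.
#' @param frame_rate_hz frame rate used to convert frames to seconds.
#' @param frames optional frame indices matching \code{feat} rows.
#' @return \code{grooming_bouts}.
#' @export
detect_grooming <- function(feat, thr = heuristic_thresholds(),
                            frame_rate_hz = 125, frames = NULL) {
  stopifnot(all(vapply(thr[c("min_snout_height", "max_eyes_hind_dist",
                             "max_paws_snout_dist", "max_paws_eyes_dist",
                             "min_paws_height")], is.finite, TRUE)))
  n <- nrow(feat)
  if (is.null(frames)) frames <- seq_len(n) - 1L
  if (n == 0) return(grooming_bouts())
  flag <- feat$snout_height > thr$min_snout_height &
    feat$eyes_mid_to_hind_mid < thr$max_eyes_hind_dist &
    feat$paws_mid_to_snout < thr$max_paws_snout_dist &
    feat$paws_mid_to_eyes_mid < thr$max_paws_eyes_dist &
    feat$paws_mid_height > thr$min_paws_height
  if (!is.null(thr$max_speed))
    flag <- flag & feat$body_speed < thr$max_speed
  flag[is.na(flag)] <- FALSE
  flags_to_bouts(flag, frame_rate_hz, frames = frames,
                 merge_window_s = thr$merge_window_s,
                 min_bout_s = thr$min_bout_s)
}

#' Convert per-frame flags to bout intervals
#'
#' Exposed separately so the merge/duration rules can be tested on arbitrary
#' flag patterns. Runs of \code{TRUE} frames become intervals; gaps strictly
#' shorter than \code{merge_window_s} are merged; intervals shorter than
#' \code{min_bout_s} are dropped.
#'
#' @param flag logical vector, one element per frame.
#' @param frame_rate_hz frames per second.
#' @param frames frame indices (0-based).
#' @param merge_window_s,min_bout_s see \code{\link{heuristic_thresholds}}.
#' @return \code{grooming_bouts}.
#' @export
flags_to_bouts <- function(flag, frame_rate_hz, frames = NULL,
                           merge_window_s = 1.2, min_bout_s = 2.0) {
  n <- length(flag)
  if (is.null(frames)) frames <- seq_len(n) - 1L
  if (n == 0 || !any(flag)) return(grooming_bouts())
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  # frame f covers [f/rate, (f+1)/rate)
  s <- frames[starts[on]] / frame_rate_hz
  e <- (frames[ends[on]] + 1) / frame_rate_hz
  b <- grooming_bouts(s, e)
  b <- merge_close_bouts(b, max_gap_s = merge_window_s)
  keep <- bout_durations(b) >= min_bout_s
  grooming_bouts(b$start_s[keep], b$end_s[keep])
}

#' Read / write pose CSV
#'
#' Long format: columns \code{frame, keypoint, x, y, z} (optionally
#' \code{confidence}). Wide format: \code{frame} plus
#' \code{<keypoint>_x/_y/_z} columns.
#'
#' @param path file path.
#' @param frame_rate_hz frame rate to attach to the track.
#' @return \code{pose3d_track}.
#' @export
read_pose_csv <- function(path, frame_rate_hz = 125) {
  d <- utils::read.csv(path)
  if (all(c("frame", "keypoint", "x", "y", "z") %in% names(d))) {
    kps <- unique(d$keypoint)
    frames <- sort(unique(d$frame))
    co <- array(NA_real_, c(length(frames), length(kps), 3),
                dimnames = list(NULL, kps, c("x", "y", "z")))
    fi <- match(d$frame, frames); ki <- match(d$keypoint, kps)
    co[cbind(fi, ki, 1L)] <- d$x
    co[cbind(fi, ki, 2L)] <- d$y
    co[cbind(fi, ki, 3L)] <- d$z
    conf <- NULL
    if ("confidence" %in% names(d)) {
      conf <- matrix(1, length(frames), length(kps))
      conf[cbind(fi, ki)] <- d$confidence
    }
    return(pose3d_track(co, frame_rate_hz, frames = frames, confidence = conf))
  }
  if (!"frame" %in% names(d)) stop("pose CSV must contain a 'frame' column")
  kps <- unique(sub("_(x|y|z)$", "", setdiff(names(d), "frame")))
  co <- array(NA_real_, c(nrow(d), length(kps), 3),
              dimnames = list(NULL, kps, c("x", "y", "z")))
  for (i in seq_along(kps)) for (j in 1:3)
    co[, i, j] <- d[[paste0(kps[i], "_", c("x", "y", "z")[j])]]
  pose3d_track(co, frame_rate_hz, frames = d$frame)
}

#' @rdname read_pose_csv
#' @param track \code{pose3d_track} to write (long format).
#' @export
write_pose_csv <- function(track, path) {
  kps <- dimnames(track$coords)[[2]]
  n <- dim(track$coords)[1]
  d <- data.frame(
    frame = rep(track$frames, times = length(kps)),
    keypoint = rep(kps, each = n),
    x = as.vector(track$coords[, , 1]),
    y = as.vector(track$coords[, , 2]),
    z = as.vector(track$coords[, , 3])
  )
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
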