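#' @title Ensemble detection
#' @description Builds the grooming-restricted activity matrix, estimates
#'   the number of co-active ensembles with a shuffle-eigenvalue test, and
#'   detects ensembles with meta-k-means consensus clustering.
#' @name ensemble_detection
NULL

#' Build the grooming-restricted activity matrix
#'
#' Restricts the session to grooming bouts padded by +/- 5 s (overlapping
#' padded bouts are merged into one segment so no bin straddles two
#' segments), bins spike counts at 1.5 s (0.667 Hz) tiling each segment
#' from its start (a trailing sliver shorter than one bin is dropped so
#' every bin has equal exposure), concatenates the segments, min-max normalizes each unit over the concatenated matrix, and
#' Gaussian-smooths (sd = 3 s = 2 bins, truncated at 4 sd, renormalized
#' kernel) within each segment independently. Raw counts are retained
#' alongside the processed matrix. Ensemble identification is restricted to
#' sessions with enough simultaneously recorded units (default 30).
#'
#' @param sd \code{spike_data} (SPN + FSI units only).
#' @param bouts \code{grooming_bouts}.
#' @param bin_size_s bin width (default 1.5 s).
#' @param pad_s flank added before/after each bout (default 5 s).
#' @param smooth_sd_s Gaussian smoothing sd in seconds (default 3).
#' @param min_units minimum simultaneously recorded units (default 30).
#' @return \code{grooming_matrix}: list with \code{norm} (smoothed
#'   normalized units x bins), \code{counts} (raw), \code{segment}
#'   (per-bin segment index), \code{bin_start_times_s}, \code{bin_size_s},
#'   \code{unit_ids}, \code{segments} (\code{grooming_bouts} of padded
#'   segments).
#' @export
build_grooming_matrix <- function(sd, bouts, bin_size_s = 1.5, pad_s = 5,
                                  smooth_sd_s = 3, min_units = 30) {
  bouts <- as_grooming_bouts(bouts)
  if (length(sd$unit_ids) < min_units)
    stop(sprintf("ensemble identification requires at least %d units; got %d",
                 min_units, length(sd$unit_ids)))
  if (nrow(bouts) == 0) stop("need at least one grooming bout")
  seg <- interval_union(pmax(0, bouts$start_s - pad_s),
                        pmin(sd$duration_s, bouts$end_s + pad_s))
  counts <- NULL; segid <- integer(0); starts <- numeric(0)
  for (i in seq_len(nrow(seg))) {
    len <- seg$end_s[i] - seg$start_s[i]
    # equal-exposure bins only: a trailing sliver would either carry a
    # shared artificial dip (raw) or explode into an outlier (rescaled),
    # planting common structure across all units
    nb_full <- floor(len / bin_size_s + 1e-9)
    if (nb_full < 1) next
    t1 <- seg$start_s[i] + nb_full * bin_size_s
    ba <- bin_spikes(sd, bin_size_s, t0 = seg$start_s[i], t1 = t1)
    counts <- cbind(counts, ba$counts)
    segid <- c(segid, rep(i, nb_full))
    starts <- c(starts, ba$bin_start_times_s)
  }
  if (is.null(counts)) stop("no segment long enough for a single bin")
  norm <- minmax_rows(counts)
  sm <- matrix(0, nrow(norm), ncol(norm), dimnames = dimnames(norm))
  for (i in unique(segid)) {
    idx <- which(segid == i)
    sm[, idx] <- gauss_smooth_rows(norm[, idx, drop = FALSE],
                                   sd_bins = smooth_sd_s / bin_size_s)
  }
  structure(list(norm = sm, counts = counts, segment = segid,
                 bin_start_times_s = starts, bin_size_s = bin_size_s,
                 unit_ids = sd$unit_ids, segments = seg),
            class = "grooming_matrix")
}

#' @export
print.grooming_matrix <- function(x, ...) {
  cat(sprintf("<grooming_matrix: %d units x %d bins (%d segments) @ %g s>\n",
              nrow(x$norm), ncol(x$norm), length(unique(x$segment)),
              x$bin_size_s))
  invisible(x)
}

#' Whole-session activity matrix with grooming-matrix processing
#'
#' Applies the same binning / min-max normalization / Gaussian smoothing as
#' \code{\link{build_grooming_matrix}} to the entire session (one segment),
#' so grooming-restricted and whole-session statistics differ only in the
#' time mask.
#'
#' @inheritParams build_grooming_matrix
#' @return \code{grooming_matrix} covering the full session.
#' @export
build_session_matrix <- function(sd, bin_size_s = 1.5, smooth_sd_s = 3) {
  nb_full <- floor(sd$duration_s / bin_size_s + 1e-9)
  ba <- bin_spikes(sd, bin_size_s, t0 = 0, t1 = nb_full * bin_size_s)
  norm <- minmax_rows(ba$counts)
  sm <- gauss_smooth_rows(norm, sd_bins = smooth_sd_s / bin_size_s)
  structure(list(norm = sm, counts = ba$counts,
                 segment = rep(1L, ncol(sm)),
                 bin_start_times_s = ba$bin_start_times_s,
                 bin_size_s = bin_size_s, unit_ids = sd$unit_ids,
                 segments = grooming_bouts(0, sd$duration_s)),
            class = "grooming_matrix")
}

#' Estimate the number of ensembles (shuffle-eigenvalue test)
#'
#' Z-scores each unit's binned grooming activity (raw counts), computes the
#' eigenvalues of the resulting unit-by-unit covariance matrix (the
#' correlation matrix), and compares them against a null distribution of
#' the maximal eigenvalue obtained by independently permuting each unit's
#' time bins \code{n_shuffles} times. The estimate is the number of real
#' eigenvalues above the null's 99th percentile. Zero-variance units are
#' dropped with a warning before z-scoring.
#'
#' @param gm \code{grooming_matrix}.
#' @param n_shuffles number of row-permutation shuffles (default 5000).
#' @param percentile null percentile (default 0.99).
#' @param seed optional integer seed for the shuffles.
#' @return \code{ensemble_count_estimate}: list with \code{n_significant},
#'   \code{eigenvalues} (sorted decreasing), \code{null_threshold},
#'   \code{null_max_eigenvalues}, \code{n_shuffles}.
#' @export
estimate_ensemble_count <- function(gm, n_shuffles = 5000, percentile = 0.99,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- gm$counts
  nb <- ncol(x)
  if (nrow(x) < 2 || nb < 3) stop("need >= 2 units and >= 3 bins")
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    warning(sprintf("dropping %d zero-variance unit(s)", sum(v == 0)))
    x <- x[v > 0, , drop = FALSE]
  }
  z <- t(scale(t(x)))                     # rows z-scored
  cm <- stats::cov(t(z))                  # = correlation matrix (up to df)
  ev <- sort(eigen(cm, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  nu <- nrow(z)
  null_max <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    zs <- z
    for (i in seq_len(nu)) zs[i, ] <- z[i, sample.int(nb)]
    cms <- stats::cov(t(zs))
    null_max[s] <- max(eigen(cms, symmetric = TRUE, only.values = TRUE)$values)
  }
  thr <- stats::quantile(null_max, percentile, names = FALSE)
  structure(list(n_significant = sum(ev > thr), eigenvalues = ev,
                 null_threshold = thr, null_max_eigenvalues = null_max,
                 n_shuffles = n_shuffles, percentile = percentile),
            class = "ensemble_count_estimate")
}

#' @export
print.ensemble_count_estimate <- function(x, ...) {
  cat(sprintf(
    "<ensemble_count_estimate: %d significant eigenvalue(s); null p%g = %.3f>\n",
    x$n_significant, 100 * x$percentile, x$null_threshold))
  invisible(x)
}

# Greedy k-means++ initialization (sklearn-style): each new center is chosen
# among 2 + floor(log(k)) candidates sampled proportional to squared
# distance, keeping the candidate that minimizes the total potential.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  n_cand <- 2L + as.integer(floor(log(k)))
  centers <- matrix(NA_real_, k, ncol(x))
  first <- sample.int(n, 1)
  centers[1, ] <- x[first, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k)[-1]) {
    if (all(d2 == 0)) {
      cand <- sample.int(n, 1)
      centers[j, ] <- x[cand, ]
      next
    }
    cand <- sample.int(n, n_cand, replace = TRUE, prob = d2)
    best_pot <- Inf; best <- cand[1]; best_d2 <- d2
    for (c in cand) {
      dc <- rowSums(sweep(x, 2, x[c, ])^2)
      nd2 <- pmin(d2, dc)
      pot <- sum(nd2)
      if (pot < best_pot) { best_pot <- pot; best <- c; best_d2 <- nd2 }
    }
    centers[j, ] <- x[best, ]
    d2 <- best_d2
  }
  centers
}

# connected components of an undirected adjacency matrix (logical), BFS
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n); cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      nb <- which(adj[v, ] & comp == 0)
      queue <- c(queue, nb)
    }
  }
  comp
}

# mean silhouette over assigned units; labels > 0 assigned, 0 = unassigned.
# Returns NA when fewer than 2 clusters are present.
mean_silhouette <- function(d, labels) {
  idx <- which(labels > 0)
  labs <- labels[idx]
  if (length(unique(labs)) < 2) return(NA_real_)
  sil <- cluster::silhouette(labs, dmatrix = as.matrix(d)[idx, idx])
  mean(sil[, "sil_width"])
}

#' Meta-k-means consensus clustering of units into ensembles
#'
#' Runs many repeats of k-means (Lloyd, greedy k-means++ initialization,
#' one initialization per repeat) clustering units by their smoothed
#' normalized grooming activity vectors, with the initial \code{k} set to
#' the square root of the number of units. Unit pairs assigned to the same
#' cluster in more than \code{pair_threshold} of runs define edges of a
#' co-assignment graph whose connected components form intermediate
#' clusters; single-unit components are unassigned. Intermediate clusters
#' are then greedily merged: at each step the merge that maximizes the mean
#' silhouette score (Euclidean distance, assigned units only) is accepted
#' while the score does not decrease. Only clusters with at least 2 units
#' are reported.
#'
#' @param gm \code{grooming_matrix}.
#' @param n_runs number of k-means repeats (default 1000).
#' @param pair_threshold co-assignment frequency defining an edge
#'   (default 0.8, strict inequality).
#' @param k_init initial k; default \code{round(sqrt(n_units))}.
#' @param iter_max Lloyd iterations per run (default 300).
#' @param seed optional integer seed.
#' @return \code{ensemble_assignment}: list with \code{cluster} (named
#'   integer; \code{NA} = unassigned), \code{coassignment} (units x units
#'   frequency matrix), \code{k_init}, \code{n_runs}, \code{pair_threshold},
#'   \code{silhouette} (final mean silhouette, \code{NA} if < 2 clusters).
#' @export
meta_kmeans <- function(gm, n_runs = 1000, pair_threshold = 0.8,
                        k_init = NULL, iter_max = 300, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  # distance step operates on row-z-scored vectors: co-activity is temporal
  # pattern similarity, so each unit's overall activity level (which
  # min-max alone preserves) must not drive the Euclidean metric
  x <- gm$norm
  rs <- apply(x, 1, stats::sd)
  x <- (x - rowMeans(x)) / ifelse(rs > 0, rs, 1)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 units for meta-k-means")
  if (is.null(k_init)) k_init <- max(2L, as.integer(round(sqrt(n))))
  co <- matrix(0, n, n)
  for (r in seq_len(n_runs)) {
    centers <- kmeanspp_init(x, k_init)
    km <- tryCatch(
      stats::kmeans(x, centers = centers, iter.max = iter_max,
                    algorithm = "Lloyd"),
      error = function(e) NULL,
      warning = function(w) suppressWarnings(
        stats::kmeans(x, centers = centers, iter.max = iter_max,
                      algorithm = "Lloyd")))
    if (is.null(km)) { n_runs <- n_runs; next }
    lab <- km$cluster
    same <- outer(lab, lab, "==")
    co <- co + same
  }
  co <- co / n_runs
  diag(co) <- 1
  rownames(co) <- colnames(co) <- rownames(x)

  comp <- connected_components(co > pair_threshold)
  sizes <- table(comp)
  labels <- ifelse(sizes[as.character(comp)] >= 2, comp, 0L)
  labels <- as.integer(factor(labels, levels = c(0, setdiff(sort(unique(labels)), 0)))) - 1L

  # greedy silhouette-guided merging of intermediate clusters
  d <- stats::dist(x)
  cur <- mean_silhouette(d, labels)
  repeat {
    ids <- setdiff(sort(unique(labels)), 0L)
    if (length(ids) < 3 || is.na(cur)) break   # merging to 1 cluster leaves
    best <- NULL; best_score <- -Inf           # silhouette undefined
    for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
      trial <- labels
      trial[trial == ids[i]] <- ids[j]
      s <- mean_silhouette(d, trial)
      if (!is.na(s) && s > best_score) { best_score <- s; best <- c(ids[j], ids[i]) }
    }
    if (is.null(best) || best_score < cur) break
    labels[labels == best[2]] <- best[1]
    cur <- best_score
  }
  ids <- setdiff(sort(unique(labels)), 0L)
  relab <- rep(NA_integer_, n)
  for (k in seq_along(ids)) relab[labels == ids[k]] <- k
  names(relab) <- rownames(x)
  structure(list(cluster = relab, coassignment = co, k_init = k_init,
                 n_runs = n_runs, pair_threshold = pair_threshold,
                 silhouette = cur, unit_ids = gm$unit_ids),
            class = "ensemble_assignment")
}

#' @export
print.ensemble_assignment <- function(x, ...) {
  k <- length(unique(stats::na.omit(x$cluster)))
  cat(sprintf(
    "<ensemble_assignment: %d cluster(s), %d/%d units assigned (k_init %d, %d runs)>\n",
    k, sum(!is.na(x$cluster)), length(x$cluster), x$k_init, x$n_runs))
  invisible(x)
}

#' Sizes of detected ensembles
#' @param a \code{ensemble_assignment}.
#' @return integer vector of cluster sizes.
#' @export
ensemble_sizes <- function(a) {
  as.integer(table(stats::na.omit(a$cluster)))
}
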