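#' @title Low-dimensional grooming trajectories
#' @description Rank-3 non-negative matrix factorization of concatenated
#'   grooming-bout activity (NNDSVD-a initialization, Frobenius loss,
#'   multiplicative updates), plus helpers that assemble its inputs from
#'   units, clustered units, unclustered units, or ensemble averages.
#' @name trajectories
NULL

# NNDSVD initialization (Boutsidis & Gallopoulos); variant "a" fills zeros
# with the matrix mean, which also makes the downstream multiplicative
# updates strictly positive and hence deterministic.
nndsvd_init <- function(A, k, variant = c("a", "zero")) {
  variant <- match.arg(variant)
  sv <- svd(A, nu = k, nv = k)
  W <- matrix(0, nrow(A), k)
  H <- matrix(0, k, ncol(A))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k > 1) for (j in 2:k) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    n_up <- sqrt(sum(up^2)); n_un <- sqrt(sum(un^2))
    n_vp <- sqrt(sum(vp^2)); n_vn <- sqrt(sum(vn^2))
    if (n_up * n_vp >= n_un * n_vn) {
      sig <- n_up * n_vp
      if (sig > 0) { wu <- up / n_up; hv <- vp / n_vp } else { wu <- up; hv <- vp }
    } else {
      sig <- n_un * n_vn
      wu <- un / n_un; hv <- vn / n_vn
    }
    W[, j] <- sqrt(sv$d[j] * sig) * wu
    H[j, ] <- sqrt(sv$d[j] * sig) * hv
  }
  if (variant == "a") {
    mu <- mean(A)
    W[W == 0] <- mu
    H[H == 0] <- mu
  }
  list(W = W, H = H)
}

#' Rank-k non-negative matrix factorization of grooming activity
#'
#' Factorizes a non-negative rows-by-time matrix into \code{basis}
#' (rows x k loadings) and \code{scores} (k x time), initialized with
#' NNDSVD with zeros filled by the matrix mean, minimizing the Frobenius
#' reconstruction loss with multiplicative updates. The loss is
#' non-increasing over iterations; iteration stops when the relative loss
#' change drops below \code{tol} or after \code{max_iter} iterations.
#' Factors are ordered by the time of their peak score so that factor 1
#' tracks onset, later factors later epochs. The deterministic
#' initialization makes the solve reproducible without a seed.
#'
#' @param activity non-negative matrix, rows (units or ensembles) x
#'   concatenated bout time bins.
#' @param k number of components (default 3).
#' @param max_iter maximum multiplicative-update iterations (default 500).
#' @param tol relative loss-change convergence tolerance (default 1e-6).
#' @return \code{trajectory_factors}: list with \code{basis},
#'   \code{scores}, \code{loss} (per-iteration Frobenius norm),
#'   \code{reconstruction_error} (final Frobenius norm),
#'   \code{relative_error} (vs \code{norm(activity)}), \code{n_iter}.
#' @export
nmf_trajectories <- function(activity, k = 3, max_iter = 500, tol = 1e-6) {
  A <- as.matrix(activity)
  if (any(A < 0)) stop("activity must be non-negative")
  if (k > min(dim(A))) stop("k exceeds matrix dimensions")
  init <- nndsvd_init(A, k)
  W <- init$W; H <- init$H
  eps <- 1e-10
  loss <- numeric(0)
  fr <- function(W, H) sqrt(sum((A - W %*% H)^2))
  prev <- fr(W, H)
  loss <- prev
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, A)) / (crossprod(W) %*% H + eps)
    W <- W * (A %*% t(H)) / (W %*% tcrossprod(H) + eps)
    cur <- fr(W, H)
    loss <- c(loss, cur)
    if (prev > 0 && abs(prev - cur) / prev < tol) { prev <- cur; break }
    prev <- cur
  }
  # fix the W/H scale ambiguity: unit-norm columns of W
  nrm <- sqrt(colSums(W^2)); nrm[nrm == 0] <- 1
  W <- sweep(W, 2, nrm, "/"); H <- sweep(H, 1, nrm, "*")
  # order factors by time of peak score
  ord <- order(apply(H, 1, which.max))
  W <- W[, ord, drop = FALSE]; H <- H[ord, , drop = FALSE]
  structure(list(basis = W, scores = H, loss = loss,
                 reconstruction_error = prev,
                 relative_error = prev / sqrt(sum(A^2)),
                 n_iter = length(loss) - 1),
            class = "trajectory_factors")
}

#' @export
print.trajectory_factors <- function(x, ...) {
  cat(sprintf(
    "<trajectory_factors: %d rows x %d factors, rel. error %.3g (%d iter)>\n",
    nrow(x$basis), ncol(x$basis), x$relative_error, x$n_iter))
  invisible(x)
}

#' Assemble trajectory input matrices
#'
#' Builds the non-negative activity matrices used for trajectory NMF:
#' spikes are binned at \code{bin_size_s} (default 250 ms) over the
#' concatenation of grooming bouts padded by +/- 5 s, Gaussian-smoothed
#' (default sd 0.5 s) within padded-bout segments, and min-max normalized
#' per row. Returns the matrix for all units and its restriction to
#' clustered units, unclustered units, and per-ensemble means, all on the
#' same time base.
#'
#' @param sd \code{spike_data}.
#' @param bouts \code{grooming_bouts}.
#' @param a \code{ensemble_assignment}.
#' @param bin_size_s bin width (default 0.25 s).
#' @param smooth_sd_s Gaussian smoothing sd (default 0.5 s).
#' @param pad_s flank around each bout (default 5 s).
#' @return list with matrices \code{all_units}, \code{clustered_units},
#'   \code{unclustered_units}, \code{ensemble_means} (empty subsets are
#'   \code{NULL} with a warning), plus \code{segment} (bin -> segment map)
#'   and \code{bin_start_times_s}.
#' @export
split_trajectory_inputs <- function(sd, bouts, a, bin_size_s = 0.25,
                                    smooth_sd_s = 0.5, pad_s = 5) {
  gm <- build_grooming_matrix(sd, bouts, bin_size_s = bin_size_s,
                              pad_s = pad_s, smooth_sd_s = smooth_sd_s,
                              min_units = 1)
  m <- gm$norm
  cl <- a$cluster[match(rownames(m), names(a$cluster))]
  pick <- function(idx, what) {
    if (length(idx) == 0) {
      warning(sprintf("no %s units; subset skipped", what))
      return(NULL)
    }
    m[idx, , drop = FALSE]
  }
  clustered <- pick(which(!is.na(cl)), "clustered")
  unclustered <- pick(which(is.na(cl)), "unclustered")
  ks <- sort(unique(stats::na.omit(cl)))
  ens <- NULL
  if (length(ks)) {
    ens <- t(vapply(ks, function(k)
      colMeans(m[which(cl == k), , drop = FALSE]), numeric(ncol(m))))
    rownames(ens) <- paste0("ensemble_", ks)
  }
  list(all_units = m, clustered_units = clustered,
       unclustered_units = unclustered, ensemble_means = ens,
       segment = gm$segment, bin_start_times_s = gm$bin_start_times_s)
}
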