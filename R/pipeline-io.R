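#' @title Session I/O and pipeline orchestration
#' @description CSV bundle readers/writers, a KiloSort/phy-style directory
#'   reader, and \code{run_pipeline()}, which executes the full analysis
#'   (simulate/load -> detect -> classify -> responses -> ensembles ->
#'   characterize -> trajectories) with per-stage artifacts and a JSON run
#'   report. All times are seconds (floats), all intervals half-open,
#'   bin indexing 0-based.
#' @name pipeline_io
NULL

#' Write / read a session bundle as a CSV directory
#'
#' Layout: \code{spikes.csv} (time_s, unit_id), \code{units.csv},
#' \code{bouts.csv} (start_s, end_s), optional \code{pose.csv}, and
#' \code{session.yaml} (duration, frame rate, provenance).
#'
#' @param bundle \code{session_bundle} (or compatible list).
#' @param path directory to create.
#' @return the path, invisibly.
#' @export
write_session_csv <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$spikes$spikes, file.path(path, "spikes.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$units, file.path(path, "units.csv"),
                   row.names = FALSE)
  write_bouts_csv(bundle$bouts, file.path(path, "bouts.csv"))
  if (!is.null(bundle$pose))
    write_pose_csv(bundle$pose, file.path(path, "pose.csv"))
  meta <- list(duration_s = bundle$spikes$duration_s,
               frame_rate_hz = if (!is.null(bundle$pose))
                 bundle$pose$frame_rate_hz else NULL,
               seed = if (!is.null(bundle$config)) bundle$config$seed else NULL,
               tool = "groomensembles")
  yaml::write_yaml(meta, file.path(path, "session.yaml"))
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  meta <- yaml::read_yaml(file.path(path, "session.yaml"))
  sp <- utils::read.csv(file.path(path, "spikes.csv"))
  units <- utils::read.csv(file.path(path, "units.csv"))
  bouts <- read_bouts_csv(file.path(path, "bouts.csv"))
  pose <- NULL
  pose_path <- file.path(path, "pose.csv")
  if (file.exists(pose_path))
    pose <- read_pose_csv(pose_path,
                          frame_rate_hz = meta$frame_rate_hz %||% 125)
  sd <- spike_data(sp$time_s, sp$unit_id, meta$duration_s, units = units)
  structure(list(spikes = sd, units = units, bouts = bouts, pose = pose,
                 ground_truth = NULL, config = NULL),
            class = "session_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal NumPy .npy reader: version 1.x/2.x headers, C-order,
# little-endian signed/unsigned integers and floats, 0/1-d arrays. phy
# outputs (spike_times.npy, spike_clusters.npy) fit this profile.
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("not a .npy file: ", path)
  ver <- readBin(con, "raw", 2)
  hlen <- if (as.integer(ver[1]) >= 2)
    readBin(con, "integer", 1, size = 4, endian = "little")
  else readBin(con, "integer", 1, size = 2, signed = FALSE,
               endian = "little")
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  if (fortran) stop("Fortran-order .npy not supported")
  shape <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.integer(strsplit(gsub("\\s", "", shape), ",")[[1]])
  n <- if (length(dims) == 0 || is.na(dims[1])) 1L else prod(dims)
  typ <- substr(descr, 2, 2)
  size <- as.integer(substr(descr, 3, 3))
  endian <- if (substr(descr, 1, 1) == ">") "big" else "little"
  out <- switch(typ,
    "f" = readBin(con, "numeric", n, size = size, endian = endian),
    "i" = if (size == 8)
      bit64_to_double(readBin(con, "raw", n * 8), endian) else
      readBin(con, "integer", n, size = size, endian = endian),
    "u" = if (size == 8)
      bit64_to_double(readBin(con, "raw", n * 8), endian) else
      readBin(con, "integer", n, size = size, signed = FALSE,
              endian = endian),
    stop("unsupported .npy dtype: ", descr))
  out
}

# interpret raw bytes as 64-bit integers via double arithmetic (exact for
# values < 2^53, far beyond any spike-sample index here)
bit64_to_double <- function(r, endian) {
  m <- matrix(as.numeric(r), nrow = 8)
  w <- if (endian == "little") 256^(0:7) else 256^(7:0)
  as.numeric(w %*% m)
}

#' Read a KiloSort/phy-style sorted-output directory
#'
#' Consumes \code{spike_times.npy} (sample indices),
#' \code{spike_clusters.npy} (cluster id per spike) and
#' \code{cluster_group.tsv} (curated labels), keeping only units labeled
#' \code{good}.
#'
#' @param path directory.
#' @param sampling_rate_hz acquisition rate to convert sample indices to
#'   seconds (default 30000).
#' @param duration_s session duration; default: last spike time.
#' @return \code{spike_data} with curated units only.
#' @export
read_phy_dir <- function(path, sampling_rate_hz = 30000, duration_s = NULL) {
  st <- read_npy(file.path(path, "spike_times.npy")) / sampling_rate_hz
  cl <- read_npy(file.path(path, "spike_clusters.npy"))
  grp <- utils::read.delim(file.path(path, "cluster_group.tsv"))
  names(grp) <- tolower(names(grp))
  good <- grp$cluster_id[grp$group == "good"]
  keep <- cl %in% good
  if (is.null(duration_s)) duration_s <- max(st) + 1
  units <- data.frame(unit_id = sort(unique(cl[keep])))
  spike_data(st[keep], cl[keep], duration_s, units = units)
}

#' Run the full grooming-ensemble analysis pipeline
#'
#' Executes every stage in order on a synthetic or loaded session, writes
#' per-stage CSV artifacts into \code{out_dir}, and returns (and writes as
#' \code{report.json}) a run report with unit counts by class, bout
#' statistics, grooming-detection agreement, the ensemble-count estimate,
#' cluster statistics, correlation-contrast AUCs, ensemble peak times and
#' trajectory reconstruction errors. A single \code{seed} fans out to
#' per-stage child seeds so stages are independently reproducible; two
#' runs with the same inputs and seed produce byte-identical reports.
#' Sessions with fewer than \code{min_units} SPN+FSI units skip the
#' ensemble stages with a recorded reason.
#'
#' @param bundle \code{session_bundle} (from \code{\link{simulate_session}}
#'   or \code{\link{read_session_csv}}).
#' @param out_dir output directory.
#' @param seed master integer seed (default 1).
#' @param n_shuffles eigenvalue-test shuffles (default 1000).
#' @param n_kmeans_runs meta-k-means repeats (default 1000).
#' @param n_bootstrap bootstrap null windows (default 1000).
#' @param min_units minimum units for ensemble stages (default 30).
#' @param detect_pose run heuristic grooming detection when pose is
#'   present (default TRUE).
#' @return the report, invisibly.
#' @export
run_pipeline <- function(bundle, out_dir, seed = 1L,
                         n_shuffles = 1000, n_kmeans_runs = 1000,
                         n_bootstrap = 1000, min_units = 30,
                         detect_pose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = seed, n_units = length(bundle$spikes$unit_ids))

  # -- grooming bouts (detect from pose when available, else annotations)
  bouts <- as_grooming_bouts(bundle$bouts)
  report$bout_stats <- list(
    n_bouts = nrow(bouts),
    mean_bout_s = if (nrow(bouts)) mean(bout_durations(bouts)) else 0,
    groom_fraction = bout_total_time(bouts) / bundle$spikes$duration_s,
    mean_ibi_s = if (nrow(bouts) > 1)
      mean(bouts$start_s[-1] - bouts$end_s[-nrow(bouts)]) else NA)
  if (detect_pose && !is.null(bundle$pose)) {
    feat <- compute_postural_features(bundle$pose)
    det <- detect_grooming(feat, heuristic_thresholds(),
                           frame_rate_hz = bundle$pose$frame_rate_hz)
    write_bouts_csv(det, file.path(out_dir, "detected_bouts.csv"))
    report$detection <- list(
      n_detected = nrow(det),
      jaccard_vs_annotations = jaccard_agreement(det, bouts))
  }

  # -- unit classification
  units <- classify_units(bundle$units)
  utils::write.csv(units, file.path(out_dir, "units_classified.csv"),
                   row.names = FALSE)
  report$unit_counts <- as.list(table(units$label))
  keep <- units$unit_id[units$label %in% c("SPN", "FSI")]
  sd <- subset_units(bundle$spikes, keep)

  # -- transition-aligned responses
  merged <- merge_close_bouts(bouts, 3)
  iso <- select_isolated_bouts(merged, 10)
  report$n_isolated_bouts <- nrow(iso)
  if (nrow(iso) >= 1) {
    for (al in c("start", "end")) {
      ev <- if (al == "start") iso$start_s else iso$end_s
      prof <- tryCatch(event_triggered_average(sd, ev), error = function(e) NULL)
      if (is.null(prof)) next
      utils::write.csv(
        data.frame(unit_id = rownames(prof$mean_response),
                   prof$mean_response, check.names = FALSE),
        file.path(out_dir, sprintf("responses_%s.csv", al)),
        row.names = FALSE)
      flg <- tryCatch(flag_grooming_modulated(sd, iso, al),
                      error = function(e) NULL)
      typ <- tryCatch(pca_response_types(prof), error = function(e) NULL)
      report[[paste0("responses_", al)]] <- list(
        n_events = prof$n_events_used,
        n_flagged = if (!is.null(flg)) sum(flg) else NA,
        pc1_group = if (!is.null(typ)) sum(typ$group == "PC1") else NA,
        pc2_group = if (!is.null(typ)) sum(typ$group == "PC2") else NA,
        explained_variance =
          if (!is.null(typ)) typ$explained_variance_fraction else NA)
    }
  }

  # -- ensembles
  if (length(sd$unit_ids) < min_units) {
    report$ensembles <- list(
      skipped = TRUE,
      reason = sprintf("fewer than %d SPN+FSI units (%d)", min_units,
                       length(sd$unit_ids)))
  } else if (nrow(merged) == 0) {
    report$ensembles <- list(skipped = TRUE, reason = "no grooming bouts")
  } else {
    gm <- build_grooming_matrix(sd, merged, min_units = min_units)
    est <- estimate_ensemble_count(gm, n_shuffles = n_shuffles,
                                   seed = seed + 10L)
    asg <- meta_kmeans(gm, n_runs = n_kmeans_runs, seed = seed + 20L)
    utils::write.csv(
      data.frame(unit_id = names(asg$cluster), cluster_id = asg$cluster),
      file.path(out_dir, "ensemble_assignment.csv"), row.names = FALSE)
    utils::write.csv(asg$coassignment,
                     file.path(out_dir, "coassignment.csv"))
    szs <- ensemble_sizes(asg)
    report$ensembles <- list(
      skipped = FALSE,
      n_significant_eigenvalues = est$n_significant,
      null_threshold = est$null_threshold,
      n_clusters = length(szs),
      cluster_sizes = szs,
      median_cluster_size = if (length(szs)) stats::median(szs) else NA,
      pct_clustered = 100 * mean(!is.na(asg$cluster)))

    # -- characterization
    if (length(szs) >= 1) {
      sm <- build_session_matrix(sd)
      cs_g <- pairwise_correlation_split(gm, asg)
      cs_w <- pairwise_correlation_split(sm, asg)
      report$correlation_contrast <- list(
        auc_grooming = distribution_auc(cs_g$within, cs_g$between),
        auc_whole_session = distribution_auc(cs_w$within, cs_w$between))
      if (all(c("x_um", "depth_um") %in% names(units))) {
        dsp <- pairwise_distance_split(units, asg)
        report$distance_contrast <- list(
          median_within_um = stats::median(dsp$within),
          median_between_um = stats::median(dsp$between))
      }

      cl <- asg$cluster
      ks <- sort(unique(stats::na.omit(cl)))
      ba <- bin_spikes(sd, 1.5)
      act <- minmax_rows(ba$counts)
      ens_act <- t(vapply(ks, function(k)
        colMeans(act[which(cl == k), , drop = FALSE]), numeric(ncol(act))))
      w <- timewarp_bout_activity(ens_act, merged, 1.5)
      pk <- ensemble_peak_times(w)
      utils::write.csv(pk, file.path(out_dir, "ensemble_peaks.csv"),
                       row.names = FALSE)
      sig <- logical(length(ks))
      for (j in seq_along(ks)) {
        bn <- bootstrap_null(ens_act[j, ], sd$duration_s,
                             bout_durations(merged), 1.5,
                             w$target_len_bins, n = n_bootstrap,
                             exclude_bouts = merged, seed = seed + 30L + j)
        obs <- apply(w$traces[j, , , drop = FALSE], 3, mean)
        sig[j] <- band_significance(obs, bn)$significant
      }
      report$ensemble_significance <- list(
        n_significant = sum(sig), n_tested = length(ks),
        peak_norm_times = pk$peak_norm_time)

      # -- trajectories
      tri <- split_trajectory_inputs(sd, merged, asg)
      report$trajectories <- list()
      for (mode in c("all_units", "ensemble_means")) {
        m <- tri[[mode]]
        if (is.null(m) || nrow(m) < 3) next
        tf <- nmf_trajectories(m, k = 3)
        utils::write.csv(tf$basis,
                         file.path(out_dir, sprintf("nmf_basis_%s.csv", mode)))
        report$trajectories[[mode]] <- list(
          relative_error = tf$relative_error, n_iter = tf$n_iter)
      }
    }
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(report)
}
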