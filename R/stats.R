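#' Summarise a contact geometry series
#'
#' Reports the statistics a trajectory study prints for each contact:
#' the primary-region occupancy (fraction of simulation time with a
#' geometrically correct halogen bond), mean +/- SD of distance and
#' sigma-hole angle over all frames, and the per-region fractions.
#' SDs are population SDs: the series is the full population of frames
#' being described, not a sample.
#'
#' @param object an `xb_series`.
#' @param ... unused.
#' @return list of class `xb_summary`.
#' @export
summary.xb_series <- function(object, ...) {
  if (nrow(object) == 0L) stop("empty geometry series")
  fr <- table(object$region) / nrow(object)
  out <- list(contact_label = attr(object, "contact_label"),
              n_frames = nrow(object),
              primary_occupancy = unname(fr["primary"]),
              mean_d = mean(object$distance_A),
              sd_d = .pop_sd(object$distance_A),
              mean_theta = mean(object$sigma_hole_deg),
              sd_theta = .pop_sd(object$sigma_hole_deg),
              region_fractions = as.numeric(fr))
  names(out$region_fractions) <- names(fr)
  class(out) <- "xb_summary"
  out
}

.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' @export
print.xb_summary <- function(x, ...) {
  cat("Halogen-bond contact summary",
      if (!is.null(x$contact_label)) paste0("(", x$contact_label, ")"), "\n")
  cat(sprintf("  frames: %d\n", x$n_frames))
  cat(sprintf("  primary XB occupancy: %.0f%% of simulation time\n",
              100 * x$primary_occupancy))
  cat(sprintf("  distance: %.1f ± %.1f Å\n", x$mean_d, x$sd_d))
  cat(sprintf("  σ-hole angle: %.1f ± %.1f°\n",
              x$mean_theta, x$sd_theta))
  cat("  region fractions:",
      paste(sprintf("%s %.2f", names(x$region_fractions),
                    x$region_fractions), collapse = ", "), "\n")
  invisible(x)
}

# interval index per time stamp: half-open [k*L, (k+1)*L) windows from
# the first time stamp, with anything past the last full window folded
# into the final interval, so a 60 ns series at 6 ns gives 10 intervals
.interval_index <- function(times, interval_ns) {
  t0 <- times[1]
  dur <- max(times) - t0
  nint <- max(1L, as.integer(ceiling((dur - 1e-9) / interval_ns)))
  idx <- pmin(floor((times - t0) / interval_ns) + 1L, nint)
  list(idx = idx, n = nint)
}

#' Per-interval medians of distance and angle
#'
#' Reduces a dense geometry series to one median point per time
#' interval (default 6 ns), the compact view used to track whether a
#' halogen bond drifts between the primary and secondary regions.
#'
#' @param series an `xb_series`.
#' @param interval_ns interval length in ns (default 6).
#' @return data.frame of class `xb_interval_medians` with columns
#'   `interval`, `t_start_ns`, `t_end_ns`, `n`, `median_d`,
#'   `median_theta`; empty intervals carry `NA` medians.
#' @export
interval_medians <- function(series, interval_ns = 6) {
  iv <- .interval_index(series$time_ns, interval_ns)
  out <- data.frame(interval = seq_len(iv$n))
  out$t_start_ns <- series$time_ns[1] + (out$interval - 1) * interval_ns
  out$t_end_ns <- out$t_start_ns + interval_ns
  out$n <- as.integer(tabulate(iv$idx, iv$n))
  out$median_d <- NA_real_
  out$median_theta <- NA_real_
  for (k in seq_len(iv$n)) {
    sel <- iv$idx == k
    if (any(sel)) {
      out$median_d[k] <- stats::median(series$distance_A[sel])
      out$median_theta[k] <- stats::median(series$sigma_hole_deg[sel])
    }
  }
  class(out) <- c("xb_interval_medians", "data.frame")
  out
}

#' Per-interval boxplot statistics
#'
#' Five-number summaries (whisker low, Q1, median, Q3, whisker high)
#' for distance and angle in each interval.  Quartiles use linear
#' interpolation ([stats::quantile] type 7); whiskers extend to the
#' most extreme observation within 1.5 IQR of the quartiles.
#'
#' @inheritParams interval_medians
#' @return data.frame with one row per interval and variable
#'   (`distance_A` / `sigma_hole_deg`).
#' @export
boxplot_stats <- function(series, interval_ns = 6) {
  iv <- .interval_index(series$time_ns, interval_ns)
  rows <- list()
  for (k in seq_len(iv$n)) for (var in c("distance_A", "sigma_hole_deg")) {
    x <- series[[var]][iv$idx == k]
    if (!length(x)) {
      five <- rep(NA_real_, 5)
    } else {
      q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
      iqr <- q[3] - q[1]
      lo <- min(x[x >= q[1] - 1.5 * iqr])
      hi <- max(x[x <= q[3] + 1.5 * iqr])
      five <- c(lo, q, hi)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      interval = k, variable = var, n = length(x),
      whisker_low = five[1], q1 = five[2], median = five[3],
      q3 = five[4], whisker_high = five[5], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# atom row indices used to superpose frames: C-alphas of receptor
# residues within `radius` of any ligand atom in the reference frame
.pocket_fit_indices <- function(traj, reference = 1L, radius = 6) {
  a <- traj$atoms
  lig <- which(a$is_ligand)
  ca <- which(!a$is_ligand & a$name == "CA")
  if (!length(lig) || !length(ca)) return(ca)
  ref <- matrix(traj$xyz[reference, ], ncol = 3, byrow = TRUE)
  keep <- vapply(ca, function(i) {
    min(sqrt(colSums((t(ref[lig, , drop = FALSE]) - ref[i, ])^2))) <= radius
  }, logical(1))
  if (!any(keep)) ca else ca[keep]
}

# superpose every frame onto the reference using the atom rows in
# `fit_idx` (least-squares fit via bio3d), returning the fitted xyz
.superpose <- function(traj, fit_idx, reference = 1L) {
  fixed.inds <- as.vector(rbind(3 * fit_idx - 2, 3 * fit_idx - 1, 3 * fit_idx))
  bio3d::fit.xyz(fixed = traj$xyz[reference, ], mobile = traj$xyz,
                 fixed.inds = fixed.inds, mobile.inds = fixed.inds)
}

#' Ligand RMSD after binding-pocket superposition
#'
#' Each frame is least-squares superposed onto the reference frame
#' using a receptor selection (by default the C-alpha atoms of pocket
#' residues within 6 A of the ligand in the reference frame); the RMSD
#' of the ligand heavy atoms is then measured without re-fitting the
#' ligand, so it reports genuine binding-mode drift, not internal
#' flexibility alone.
#'
#' @param traj an [xb_trajectory].
#' @param reference reference frame index (default 1).
#' @param superpose_on optional integer vector of atom serials to fit
#'   on; default is the pocket C-alpha selection.
#' @return numeric vector of per-frame RMSD values in A.
#' @export
ligand_rmsd <- function(traj, reference = 1L, superpose_on = NULL) {
  fit_idx <- if (is.null(superpose_on)) {
    .pocket_fit_indices(traj, reference)
  } else {
    match(superpose_on, traj$atoms$serial)
  }
  if (!length(fit_idx) || anyNA(fit_idx))
    stop("empty or invalid superposition selection")
  lig <- which(traj$atoms$is_ligand & traj$atoms$element != "H")
  if (!length(lig)) stop("no ligand heavy atoms")
  fitted <- .superpose(traj, fit_idx, reference)
  lig.inds <- as.vector(rbind(3 * lig - 2, 3 * lig - 1, 3 * lig))
  ref <- fitted[reference, lig.inds]
  apply(fitted[, lig.inds, drop = FALSE], 1, function(fr)
    sqrt(mean(colSums(matrix((fr - ref)^2, nrow = 3)))))
}

#' Hierarchical clustering of trajectory frames
#'
#' Frames are superposed on the binding pocket, the pairwise ligand
#' heavy-atom RMSD matrix is computed, and complete trajectories are
#' grouped by average-linkage agglomerative clustering.  The
#' representative frame is taken from the most populated cluster as
#' the member with the smallest summed RMSD to the rest of its
#' cluster; all ties break deterministically towards the lower frame
#' index.
#'
#' @param traj an [xb_trajectory].
#' @param k number of clusters (default 10).
#' @param reference frame used for pocket superposition (default 1).
#' @return list of class `xb_clusters`: `assignment` (integer per
#'   frame), `sizes`, `representative` (frame index), `k`.
#' @export
cluster_frames <- function(traj, k = 10, reference = 1L) {
  n <- n_frames(traj)
  if (n < k) stop("frame count (", n, ") is smaller than k (", k, ")")
  lig <- which(traj$atoms$is_ligand & traj$atoms$element != "H")
  if (!length(lig)) stop("no ligand heavy atoms")
  fit_idx <- .pocket_fit_indices(traj, reference)
  fitted <- if (length(fit_idx)) .superpose(traj, fit_idx, reference)
            else traj$xyz
  lig.inds <- as.vector(rbind(3 * lig - 2, 3 * lig - 1, 3 * lig))
  # pairwise RMSD = euclidean distance of flattened coords / sqrt(m)
  dmat <- stats::dist(fitted[, lig.inds, drop = FALSE]) / sqrt(length(lig))
  hc <- stats::hclust(dmat, method = "average")
  assignment <- stats::cutree(hc, k = k)
  sizes <- tabulate(assignment, k)
  big <- which(sizes == max(sizes))[1]
  members <- which(assignment == big)
  dm <- as.matrix(dmat)
  sums <- rowSums(dm[members, members, drop = FALSE])
  representative <- members[which.min(sums)]
  structure(list(assignment = assignment, sizes = sizes,
                 representative = representative, k = k),
            class = "xb_clusters")
}

#' @export
print.xb_clusters <- function(x, ...) {
  cat("xb_clusters: k =", x$k, "\n")
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat("  representative frame:", x$representative,
      "(cluster", x$assignment[x$representative], ")\n")
  invisible(x)
}

#' Pick the replicate with the most stable halogen-bond geometry
#'
#' Of several replicate simulations of the same system, selects the
#' one with the lowest variation of XB distance and angle, scored as
#' the sum of the two coefficients of variation (population SD /
#' mean); ties break towards the lower index.
#'
#' @param series_list list of `xb_series`, one per replicate.
#' @return integer index into `series_list`.
#' @export
select_replicate <- function(series_list) {
  if (!length(series_list)) stop("no replicates supplied")
  score <- vapply(series_list, function(s) {
    .pop_sd(s$distance_A) / mean(s$distance_A) +
      .pop_sd(s$sigma_hole_deg) / mean(s$sigma_hole_deg)
  }, numeric(1))
  which.min(score)
}
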