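#' Region thresholds for the distance-angle plane
#'
#' A geometrically correct (primary) halogen bond has an X...A distance
#' below `d_cut` and a C-X...A sigma-hole angle above `theta_cut`;
#' satisfying exactly one of the two conditions gives a weak
#' (secondary) halogen bond.  Defaults are the conventional 4.0 A and
#' 140 degrees.
#'
#' @param d_cut distance threshold in A (> 0).
#' @param theta_cut angle threshold in degrees, in (0, 180).
#' @return list of class `xb_thresholds`.
#' @export
region_thresholds <- function(d_cut = 4.0, theta_cut = 140.0) {
  stopifnot(d_cut > 0, theta_cut > 0, theta_cut < 180)
  structure(list(d_cut = d_cut, theta_cut = theta_cut),
            class = "xb_thresholds")
}

#' Halogen-acceptor distance per frame
#'
#' @param traj an [xb_trajectory].
#' @param contact an [xb_contact].
#' @param frames frame indices (default all).
#' @return numeric vector of X...A distances in A.
#' @export
xb_distance <- function(traj, contact, frames = seq_len(n_frames(traj))) {
  xi <- match(contact$halogen_serial, traj$atoms$serial)
  ai <- match(contact$acceptor_serial, traj$atoms$serial)
  if (is.na(xi) || is.na(ai)) stop("contact atoms absent from trajectory")
  dx <- traj$xyz[frames, 3 * xi - 2] - traj$xyz[frames, 3 * ai - 2]
  dy <- traj$xyz[frames, 3 * xi - 1] - traj$xyz[frames, 3 * ai - 1]
  dz <- traj$xyz[frames, 3 * xi]     - traj$xyz[frames, 3 * ai]
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Sigma-hole angle per frame
#'
#' The C-X...A angle with its vertex at the halogen: 180 degrees is the
#' ideal collinear sigma-hole geometry in which the acceptor sits on
#' the extension of the C-X bond, over the region of depleted electron
#' density.
#'
#' @inheritParams xb_distance
#' @return numeric vector of angles in degrees, in [0, 180].
#' @export
sigma_hole_angle <- function(traj, contact, frames = seq_len(n_frames(traj))) {
  ci <- match(contact$carbon_serial, traj$atoms$serial)
  xi <- match(contact$halogen_serial, traj$atoms$serial)
  ai <- match(contact$acceptor_serial, traj$atoms$serial)
  if (anyNA(c(ci, xi, ai))) stop("contact atoms absent from trajectory")
  v1x <- traj$xyz[frames, 3 * ci - 2] - traj$xyz[frames, 3 * xi - 2]
  v1y <- traj$xyz[frames, 3 * ci - 1] - traj$xyz[frames, 3 * xi - 1]
  v1z <- traj$xyz[frames, 3 * ci]     - traj$xyz[frames, 3 * xi]
  v2x <- traj$xyz[frames, 3 * ai - 2] - traj$xyz[frames, 3 * xi - 2]
  v2y <- traj$xyz[frames, 3 * ai - 1] - traj$xyz[frames, 3 * xi - 1]
  v2z <- traj$xyz[frames, 3 * ai]     - traj$xyz[frames, 3 * xi]
  n1 <- sqrt(v1x^2 + v1y^2 + v1z^2)
  n2 <- sqrt(v2x^2 + v2y^2 + v2z^2)
  if (any(n1 == 0) || any(n2 == 0))
    stop("degenerate geometry: zero-length C-X or X...A vector")
  cosang <- (v1x * v2x + v1y * v2y + v1z * v2z) / (n1 * n2)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

.regions <- c("primary", "secondary_short", "secondary_long", "none")

#' Classify points of the distance-angle plane
#'
#' The plane is partitioned into four regions: `primary`
#' (d < d_cut and theta > theta_cut, a geometrically correct halogen
#' bond), `secondary_short` (short but bent), `secondary_long` (linear
#' but long; both secondary regions are weak halogen bonds), and
#' `none`.  Values exactly at a threshold fall in the less favourable
#' region, matching the strict inequalities of the definition.
#'
#' @param d distance(s) in A.
#' @param theta sigma-hole angle(s) in degrees.
#' @param thresholds an [region_thresholds] object.
#' @return factor with levels primary, secondary_short, secondary_long,
#'   none.
#' @export
classify_region <- function(d, theta, thresholds = region_thresholds()) {
  stopifnot(all(d > 0), all(theta >= 0), all(theta <= 180))
  short <- d < thresholds$d_cut
  lin <- theta > thresholds$theta_cut
  out <- ifelse(short & lin, "primary",
         ifelse(short, "secondary_short",
         ifelse(lin, "secondary_long", "none")))
  factor(out, levels = .regions)
}

#' Per-frame geometry series for one contact
#'
#' @param traj an [xb_trajectory].
#' @param contact an [xb_contact].
#' @param thresholds an [region_thresholds] object.
#' @return data.frame of class `xb_series` with columns `time_ns`,
#'   `distance_A`, `sigma_hole_deg`, `region`; the contact label and
#'   thresholds are kept as attributes.
#' @export
contact_series <- function(traj, contact, thresholds = region_thresholds()) {
  d <- xb_distance(traj, contact)
  th <- sigma_hole_angle(traj, contact)
  out <- data.frame(time_ns = traj$times, distance_A = d,
                    sigma_hole_deg = th,
                    region = classify_region(d, th, thresholds))
  attr(out, "contact_label") <- contact$label
  attr(out, "thresholds") <- thresholds
  class(out) <- c("xb_series", "data.frame")
  out
}

#' Write a geometry series as CSV
#' @param series an `xb_series`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Distance-angle plane plot with region shading
#'
#' The multivariate view of one contact: every frame as a point in the
#' distance-angle plane, the primary region shaded green, the two
#' secondary regions yellow, optionally overlaid with interval medians.
#'
#' @param x an `xb_series`.
#' @param medians optional result of [interval_medians] to overlay.
#' @param ... passed to [graphics::plot].
#' @return invisibly, `x`.
#' @export
plot.xb_series <- function(x, medians = NULL, ...) {
  thr <- attr(x, "thresholds")
  if (is.null(thr)) thr <- region_thresholds()
  xlim <- range(x$distance_A, thr$d_cut)
  ylim <- range(x$sigma_hole_deg, thr$theta_cut)
  graphics::plot(NA, xlim = xlim, ylim = ylim,
                 xlab = "XB distance X···A [Å]",
                 ylab = "σ-hole angle C–X···A [°]",
                 main = attr(x, "contact_label"), ...)
  usr <- graphics::par("usr")
  graphics::rect(usr[1], thr$theta_cut, thr$d_cut, usr[4],
                 col = grDevices::adjustcolor("darkgreen", 0.15), border = NA)
  graphics::rect(usr[1], usr[3], thr$d_cut, thr$theta_cut,
                 col = grDevices::adjustcolor("gold", 0.15), border = NA)
  graphics::rect(thr$d_cut, thr$theta_cut, usr[2], usr[4],
                 col = grDevices::adjustcolor("gold", 0.15), border = NA)
  graphics::points(x$distance_A, x$sigma_hole_deg, pch = 16, cex = 0.4,
                   col = grDevices::adjustcolor("grey25", 0.5))
  if (!is.null(medians))
    graphics::points(medians$median_d, medians$median_theta, pch = 21,
                     bg = "red", cex = 1.2)
  graphics::abline(v = thr$d_cut, h = thr$theta_cut, lty = 2)
  invisible(x)
}
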