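#' Run configuration for a full analysis
#'
#' @param structure path to the topology / structure PDB.
#' @param series optional path to a coordinate-series file appended to
#'   the topology (multi-model PDB, DCD or CSV).
#' @param ligand optional ligand residue-name selector.
#' @param acceptors character vector of residue selectors
#'   (`chain:resseq` or generic labels).
#' @param numbering_map optional path to a generic-numbering TSV.
#' @param d_cut,theta_cut region thresholds (4.0 A, 140 deg).
#' @param interval_ns interval length for medians/boxplots (6 ns).
#' @param cluster_k number of frame clusters (10).
#' @param detect_cutoff,min_fraction automatic contact detection
#'   parameters (5.5 A, 0.10).
#' @param out_dir output directory.
#' @param plots write PNG distance-angle plots (default FALSE).
#' @return list of class `xb_config`.
#' @export
xb_config <- function(structure, series = NULL, ligand = NULL,
                      acceptors, numbering_map = NULL,
                      d_cut = 4.0, theta_cut = 140.0, interval_ns = 6,
                      cluster_k = 10, detect_cutoff = 5.5,
                      min_fraction = 0.10, out_dir = ".", plots = FALSE) {
  for (p in c(structure, series, numbering_map))
    if (!is.null(p) && !file.exists(p)) stop("input path not found: ", p)
  structure(list(structure = structure, series = series, ligand = ligand,
                 acceptors = acceptors, numbering_map = numbering_map,
                 thresholds = region_thresholds(d_cut, theta_cut),
                 interval_ns = interval_ns, cluster_k = cluster_k,
                 detect_cutoff = detect_cutoff, min_fraction = min_fraction,
                 out_dir = out_dir, plots = plots),
            class = "xb_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [xb_config]; `overrides` (named list)
#' take precedence over file values.
#'
#' @param path YAML file.
#' @param overrides named list of values overriding the file.
#' @return list of class `xb_config`.
#' @export
read_xb_config <- function(path, overrides = list()) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs needs the 'yaml' package")
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(xb_config, vals)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the halogen-bond trajectory analysis end to end
#'
#' Reads the structure (and optional coordinate series), perceives
#' donors and acceptors, detects contacts, and writes per-contact
#' geometry CSVs, a JSON summary (occupancy %, mean +/- SD),
#' interval-median and boxplot CSVs, the ligand-RMSD series, frame
#' cluster assignments and the representative-frame PDB, plus optional
#' distance-angle PNG plots.  Outputs are deterministic for a given
#' config, so a rerun reproduces files byte-identically.
#'
#' @param config an [xb_config] (or path to a YAML config).
#' @return named list of output paths, invisibly; the summaries are
#'   returned in the `"summaries"` element.
#' @export
run_xb_analysis <- function(config) {
  if (is.character(config)) config <- read_xb_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  traj <- .stage("read_structure",
                 read_structure(config$structure, ligand = config$ligand))
  if (!is.null(config$series))
    traj <- .stage("read_series",
                   read_coordinate_series(traj, config$series))
  nmap <- if (!is.null(config$numbering_map))
    .stage("numbering_map", read_numbering_map(config$numbering_map))
  donors <- .stage("find_donors", find_donors(traj, ligand = config$ligand))
  acceptors <- .stage("find_acceptors",
                      find_acceptors(traj, config$acceptors, map = nmap))
  contacts <- .stage("auto_contacts",
                     auto_contacts(traj, donors, acceptors,
                                   config$detect_cutoff,
                                   config$min_fraction))
  out <- list()
  summaries <- list()
  slug <- function(x) gsub("[^A-Za-z0-9]+", "_", x)
  for (ct in contacts) {
    ser <- .stage(paste0("series ", ct$label),
                  contact_series(traj, ct, config$thresholds))
    tag <- slug(ct$label)
    f <- file.path(config$out_dir, paste0("series_", tag, ".csv"))
    write_series_csv(ser, f)
    out[[paste0("series_", tag)]] <- f
    med <- interval_medians(ser, config$interval_ns)
    f <- file.path(config$out_dir, paste0("medians_", tag, ".csv"))
    utils::write.csv(as.data.frame(med), f, row.names = FALSE, quote = FALSE)
    out[[paste0("medians_", tag)]] <- f
    box <- boxplot_stats(ser, config$interval_ns)
    f <- file.path(config$out_dir, paste0("boxplot_", tag, ".csv"))
    utils::write.csv(box, f, row.names = FALSE, quote = FALSE)
    out[[paste0("boxplot_", tag)]] <- f
    if (isTRUE(config$plots)) {
      f <- file.path(config$out_dir, paste0("plane_", tag, ".png"))
      grDevices::png(f, width = 900, height = 700, res = 120)
      plot(ser, medians = med)
      grDevices::dev.off()
      out[[paste0("plane_", tag)]] <- f
    }
    s <- summary(ser)
    summaries[[ct$label]] <- list(
      contact = ct$label, n_frames = s$n_frames,
      primary_occupancy_pct = 100 * s$primary_occupancy,
      mean_distance_A = s$mean_d, sd_distance_A = s$sd_d,
      mean_sigma_hole_deg = s$mean_theta, sd_sigma_hole_deg = s$sd_theta,
      region_fractions = as.list(s$region_fractions))
  }
  f <- file.path(config$out_dir, "contact_summaries.json")
  jsonlite::write_json(summaries, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  out$summary_json <- f

  if (n_frames(traj) >= 2) {
    rms <- .stage("ligand_rmsd", ligand_rmsd(traj))
    f <- file.path(config$out_dir, "ligand_rmsd.csv")
    utils::write.csv(data.frame(time_ns = traj$times, rmsd_A = rms), f,
                     row.names = FALSE, quote = FALSE)
    out$rmsd <- f
  }
  if (n_frames(traj) >= config$cluster_k) {
    cl <- .stage("cluster_frames", cluster_frames(traj, config$cluster_k))
    f <- file.path(config$out_dir, "clusters.csv")
    utils::write.csv(data.frame(frame = seq_len(n_frames(traj)),
                                time_ns = traj$times,
                                cluster = cl$assignment), f,
                     row.names = FALSE, quote = FALSE)
    out$clusters <- f
    rep_traj <- traj
    rep_traj$xyz <- traj$xyz[cl$representative, , drop = FALSE]
    rep_traj$times <- traj$times[cl$representative]
    f <- file.path(config$out_dir, "representative_frame.pdb")
    write_structure(rep_traj, f)
    out$representative <- f
  }
  out$summaries <- summaries
  invisible(out)
}

#' Build and report XSAR sets from an activity table
#'
#' Finds matched halogenated/parent pairs, computes Xeffect values and
#' chemotype classes, and writes the result as JSON.
#'
#' @param table_path activity CSV (`id,smiles,activity_nM`).
#' @param out_dir output directory.
#' @param chemotypes compute PI-AR distances and classes per parent
#'   (default TRUE; needs 3D embedding and is the slow part).
#' @param seed conformer-subsample seed.
#' @return the report list, invisibly; JSON written to
#'   `<out_dir>/xsar_report.json`.
#' @export
run_xsar_report <- function(table_path, out_dir = ".", chemotypes = TRUE,
                            seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- .stage("read_activity_table", read_activity_table(table_path))
  sets <- .stage("find_xsar_sets", find_xsar_sets(records))
  report <- lapply(sets, function(s) {
    entry <- list(parent = s$parent$id,
                  parent_activity_nM = s$parent$activity_nM,
                  derivatives = lapply(seq_len(nrow(s$derivatives)),
                    function(i) as.list(s$derivatives[i, ])))
    if (chemotypes) {
      d <- tryCatch(pi_ar_distance(s$parent$smiles, seed = seed),
                    error = function(e) NA_real_)
      entry$pi_ar_distance_A <- d
      entry$chemotype <- if (is.na(d)) NA_character_ else
        classify_chemotype(d)
    }
    entry
  })
  f <- file.path(out_dir, "xsar_report.json")
  jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}
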