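# --- OpenBabel plumbing -----------------------------------------------------
# SMILES handling, 3D embedding and canonicalisation go through the
# obabel CLI; graph/ring work on the resulting SDF uses ChemmineR.

.obabel <- function(args, stdin_lines = NULL) {
  out <- suppressWarnings(system2("obabel", args, stdout = TRUE,
                                  stderr = FALSE,
                                  input = stdin_lines))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("obabel failed (status ", status, "): obabel ",
         paste(args, collapse = " "))
  out
}

.require_obabel <- function() {
  if (Sys.which("obabel") == "")
    stop("the XSAR module needs the OpenBabel 'obabel' executable on the PATH")
}

#' Canonical SMILES
#'
#' @param smiles a SMILES string.
#' @return canonical SMILES (OpenBabel canonical form), or `NA` when
#'   the input does not parse.
#' @export
canonical_smiles <- function(smiles) {
  .require_obabel()
  vapply(smiles, function(s) {
    out <- tryCatch(.obabel(c(paste0("-:", shQuote(s)), "-ocan")),
                    error = function(e) character(0))
    out <- out[nzchar(trimws(out))]
    if (!length(out)) return(NA_character_)
    sub("[\t ].*$", "", trimws(out[1]))
  }, character(1), USE.NAMES = FALSE)
}

# SMILES -> ChemmineR SDF (connection table only, no 3D)
.smiles_to_sdf <- function(smiles) {
  f <- tempfile(fileext = ".sdf")
  on.exit(unlink(f))
  tryCatch(.obabel(c(paste0("-:", shQuote(smiles)), "-O", f)),
           error = function(e) NULL)
  if (!file.exists(f) || file.size(f) == 0) return(NULL)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(f))
  if (!length(sdfs)) return(NULL)
  sdfs[[1]]
}

# element symbols, adjacency list and aromatic-atom flags of an SDF
.mol_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- gsub("_.*", "", rownames(ab))
  nb <- lapply(seq_len(nrow(ab)), function(i) {
    b <- bb[bb[, 1] == i | bb[, 2] == i, , drop = FALSE]
    setdiff(unique(c(b[, 1], b[, 2])), i)
  })
  rg <- ChemmineR::rings(sdf, upper = 7, type = "all", arom = TRUE)
  arom_names <- unique(unlist(rg$RINGS[rg$AROMATIC]))
  ring_names <- unique(unlist(rg$RINGS))
  list(ab = ab, bb = bb, elem = elem, nb = nb,
       aromatic = rownames(ab) %in% arom_names,
       in_ring = rownames(ab) %in% ring_names,
       arom_rings = lapply(rg$RINGS[rg$AROMATIC],
                           function(r) match(r, rownames(ab))))
}

# indices of halogen atoms singly bonded to an aromatic carbon
.aryl_halogen_idx <- function(g, halogens) {
  idx <- which(g$elem %in% halogens)
  idx[vapply(idx, function(i) {
    length(g$nb[[i]]) == 1L && g$elem[g$nb[[i]]] == "C" &&
      g$aromatic[g$nb[[i]]]
  }, logical(1))]
}

# remove atoms by index from an SDF, reindexing bonds
.drop_atoms <- function(sdf, drop) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  keep <- setdiff(seq_len(nrow(ab)), drop)
  map <- match(seq_len(nrow(ab)), keep)
  bb2 <- bb[!(bb[, 1] %in% drop | bb[, 2] %in% drop), , drop = FALSE]
  bb2[, 1] <- map[bb2[, 1]]
  bb2[, 2] <- map[bb2[, 2]]
  out <- sdf
  out@atomblock <- ab[keep, , drop = FALSE]
  out@bondblock <- bb2
  hb <- ChemmineR::header(sdf)
  hb["Counts_Line"] <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                               length(keep), nrow(bb2))
  out@header <- hb
  out
}

.sdf_to_cansmi <- function(sdf) {
  f <- tempfile(fileext = ".sdf")
  on.exit(unlink(f))
  ChemmineR::write.SDF(sdf, f)
  out <- .obabel(c(f, "-ocan"))
  out <- out[nzchar(trimws(out))]
  if (!length(out)) return(NA_character_)
  sub("[\t ].*$", "", trimws(out[1]))
}

# --- activity table and matched pairs ---------------------------------------

#' Read a ligand activity table
#'
#' @param path CSV with columns `id`, `smiles`, `activity_nM` (potency
#'   on a lower-is-better scale, e.g. Ki or IC50 in nM).
#' @return data.frame with those columns.
#' @export
read_activity_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  names(df)[names(df) == "activity_nm"] <- "activity_nM"
  if (!all(c("id", "smiles", "activity_nM") %in% names(df)))
    stop("activity table needs columns id, smiles, activity_nM")
  if (any(df$activity_nM <= 0)) stop("activities must be positive")
  df[, c("id", "smiles", "activity_nM")]
}

#' Xeffect: potency fold-change on halogenation
#'
#' The activity ratio parent / halogenated derivative on a
#' lower-is-better potency scale (nM Ki or IC50): values above 1 mean
#' halogenation increased potency by that fold, values in (0, 1) a
#' potency loss.  Inputs in pKi or other log units must be converted
#' by the caller first.
#'
#' @param parent_activity,derivative_activity positive activities (nM).
#' @return numeric Xeffect value(s).
#' @export
xeffect <- function(parent_activity, derivative_activity) {
  if (any(parent_activity <= 0) || any(derivative_activity <= 0))
    stop("activities must be positive")
  parent_activity / derivative_activity
}

#' Find XSAR sets: matched halogenated/parent ligand pairs
#'
#' Every record carrying at least one aryl-bound halogen is reduced to
#' its unsubstituted skeleton by replacing those halogens with
#' hydrogen; skeletons are matched against the non-halogenated records
#' by canonical-SMILES equality.  Each parent with at least one
#' matching derivative yields one XSAR set with per-derivative
#' substitution descriptors and Xeffect values.  Fluorine does not
#' form halogen bonds and is excluded from the default halogen set;
#' aliphatic halogens are never matched.
#'
#' @param records data.frame as from [read_activity_table].
#' @param halogens halogen elements considered (default Cl, Br, I).
#' @return list of `xsar_set` objects.
#' @export
find_xsar_sets <- function(records, halogens = c("Cl", "Br", "I")) {
  .require_obabel()
  stopifnot(nrow(records) >= 2)
  info <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    sdf <- .smiles_to_sdf(records$smiles[i])
    if (is.null(sdf)) {
      warning("skipping record ", records$id[i], ": unparseable SMILES '",
              records$smiles[i], "'")
      next
    }
    g <- .mol_graph(sdf)
    hal <- .aryl_halogen_idx(g, halogens)
    can <- .sdf_to_cansmi(sdf)
    skel <- if (length(hal)) .sdf_to_cansmi(.drop_atoms(sdf, hal)) else can
    tab <- table(g$elem[hal])
    info[[i]] <- list(can = can, skeleton = skel,
                      n_hal = length(hal),
                      descriptor = if (length(hal))
                        paste(sprintf("%s x%d", names(tab), as.integer(tab)),
                              collapse = ", ") else "")
  }
  ok <- !vapply(info, is.null, logical(1))
  parents <- which(ok)[vapply(info[ok], function(x) x$n_hal == 0, logical(1))]
  derivs <- setdiff(which(ok), parents)
  sets <- list()
  for (p in parents) {
    hit <- derivs[vapply(info[derivs], function(x)
      identical(x$skeleton, info[[p]]$can), logical(1))]
    if (!length(hit)) next
    dtab <- records[hit, , drop = FALSE]
    dtab$substitution <- vapply(info[hit], function(x) x$descriptor,
                                character(1))
    dtab$n_halogens <- vapply(info[hit], function(x) x$n_hal, integer(1))
    dtab$xeffect <- xeffect(records$activity_nM[p], dtab$activity_nM)
    rownames(dtab) <- NULL
    sets[[length(sets) + 1L]] <- structure(
      list(parent = records[p, , drop = FALSE], derivatives = dtab),
      class = "xsar_set")
  }
  sets
}

#' @export
print.xsar_set <- function(x, ...) {
  cat("XSAR set: parent", x$parent$id,
      sprintf("(%.4g nM)\n", x$parent$activity_nM))
  for (i in seq_len(nrow(x$derivatives)))
    cat(sprintf("  %s [%s] %.4g nM, Xeffect %.3g\n",
                x$derivatives$id[i], x$derivatives$substitution[i],
                x$derivatives$activity_nM[i], x$derivatives$xeffect[i]))
  invisible(x)
}

# --- chemotype classification ----------------------------------------------

# basic-centre (PI) atom index: aliphatic amine nitrogen, ring amine
# preferred, excluding aryl-conjugated and amide nitrogens
.pi_atom <- function(g) {
  is_amide <- function(i) any(vapply(g$nb[[i]], function(j) {
    if (g$elem[j] != "C") return(FALSE)
    dbl <- g$bb[(g$bb[, 1] == j | g$bb[, 2] == j) & g$bb[, 3] == 2, 1:2,
                drop = FALSE]
    any(g$elem[setdiff(as.vector(dbl), j)] == "O")
  }, logical(1)))
  cand <- which(g$elem == "N" & !g$aromatic)
  cand <- cand[!vapply(cand, function(i) any(g$aromatic[g$nb[[i]]]),
                       logical(1))]
  cand <- cand[!vapply(cand, is_amide, logical(1))]
  if (!length(cand)) return(NA_integer_)
  ring <- cand[g$in_ring[cand]]
  if (length(ring)) ring[1] else cand[1]
}

# AR ring atom indices: the aromatic ring bearing the most halogens
# (the halogenated or candidate-halogenation ring); first ring on ties
.ar_ring <- function(g) {
  if (!length(g$arom_rings)) return(NULL)
  nhal <- vapply(g$arom_rings, function(r)
    sum(vapply(r, function(i)
      sum(g$elem[g$nb[[i]]] %in% c("Cl", "Br", "I")), numeric(1))),
    numeric(1))
  g$arom_rings[[which.max(nhal)]]
}

#' PI-AR pharmacophore distance over a conformer ensemble
#'
#' Distance between the basic centre (PI: the most basic aliphatic
#' amine nitrogen, ring amines preferred, aryl-conjugated and amide
#' nitrogens excluded) and the aromatic-ring centroid (AR: the
#' halogenated, or candidate halogenation, ring).  The molecule is
#' embedded in 3D and its rotamers enumerated systematically (OpenBabel
#' gen3d + Confab); the reported value is the median over the ensemble.
#' This distance separates aminergic chemotypes into a long class
#' (arylpiperazines, ~5.6 A) and a short class (benzylpiperidines /
#' benzylmorpholines, ~3.9 A).
#'
#' @param smiles SMILES of the molecule.
#' @param n_conformers ensemble size cap (default 20); when the
#'   systematic search yields more, a seeded random subset is used.
#' @param seed RNG seed for the subsample (default 1).
#' @param rmsd_cutoff Confab diversity cutoff in A (default 0.3).
#' @return median PI-AR distance in A.
#' @export
pi_ar_distance <- function(smiles, n_conformers = 20, seed = 1,
                           rmsd_cutoff = 0.3) {
  .require_obabel()
  f3d <- tempfile(fileext = ".sdf")
  fcf <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(f3d, fcf)))
  .obabel(c(paste0("-:", shQuote(smiles)), "-O", f3d, "--gen3d"))
  if (!file.exists(f3d) || file.size(f3d) == 0)
    stop("could not embed 3D coordinates for SMILES '", smiles, "'")
  .obabel(c(f3d, "-O", fcf, "--confab", "--rcutoff",
            format(rmsd_cutoff), "--ecutoff", "50"))
  confs <- suppressWarnings(ChemmineR::read.SDFset(fcf))
  if (!length(confs)) confs <- suppressWarnings(ChemmineR::read.SDFset(f3d))
  g <- .mol_graph(confs[[1]])
  pi_idx <- .pi_atom(g)
  ring <- .ar_ring(g)
  if (is.na(pi_idx))
    stop("no basic aliphatic amine nitrogen found in '", smiles, "'")
  if (is.null(ring))
    stop("no aromatic ring found in '", smiles, "'")
  ks <- seq_along(ChemmineR::cid(confs))
  if (length(ks) > n_conformers) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    ks <- sort(sample(ks, n_conformers))
  }
  ds <- vapply(ks, function(k) {
    xyz <- ChemmineR::atomblock(confs[[k]])[, 1:3, drop = FALSE]
    cen <- colMeans(xyz[ring, , drop = FALSE])
    sqrt(sum((xyz[pi_idx, ] - cen)^2))
  }, numeric(1))
  stats::median(ds)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Classify a chemotype by PI-AR distance
#'
#' Splits at 4.75 A, the midpoint between the two class archetypes
#' (5.6 A arylpiperazine-like, 3.9 A benzylpiperidine-like); the
#' boundary itself is assigned to the long class.
#'
#' @param distance PI-AR distance in A (> 0).
#' @return `"long"` or `"short"` (vectorised).
#' @export
classify_chemotype <- function(distance) {
  stopifnot(all(distance > 0))
  ifelse(distance >= 4.75, "long", "short")
}
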