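#' Find halogen-bond donors in a ligand
#'
#' A donor is a covalently bound Cl, Br or I together with its carbon;
#' fluorine is excluded because its sigma-hole is too weak to form
#' halogen bonds.  The covalent carbon is inferred from the first frame
#' as the nearest carbon within a 1.6-2.2 A bond window (PDB CONECT
#' records are unreliable).
#'
#' @param traj an [xb_trajectory].
#' @param ligand optional residue-name selector; default uses the
#'   trajectory's `is_ligand` flags.
#' @return data.frame of class `xb_donors` with one row per donor:
#'   `halogen_serial`, `carbon_serial`, `element`, `tag`.
#' @export
find_donors <- function(traj, ligand = NULL) {
  a <- traj$atoms
  lig <- if (is.null(ligand)) a$is_ligand else a$resname %in% ligand
  if (!any(lig)) stop("no ligand atoms present")
  hal_idx <- which(lig & a$element %in% c("Cl", "Br", "I"))
  out <- lapply(hal_idx, function(i) {
    x <- .coords(traj, i, 1)
    cand <- which(lig & a$element == "C")
    if (!length(cand))
      stop("halogen ", a$serial[i], " (", a$name[i],
           ") has no ligand carbon available")
    d <- sqrt(colSums((matrix(traj$xyz[1, as.vector(rbind(
      3 * cand - 2, 3 * cand - 1, 3 * cand))], nrow = 3) - x)^2))
    j <- cand[which.min(d)]
    if (min(d) < 1.6 || min(d) > 2.2)
      stop("halogen ", a$serial[i], " (", a$name[i],
           ") has no carbon within the 1.6-2.2 A bond window (nearest ",
           round(min(d), 2), " A)")
    data.frame(halogen_serial = a$serial[i], carbon_serial = a$serial[j],
               element = a$element[i],
               tag = a$name[i], stringsAsFactors = FALSE)
  })
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(halogen_serial = integer(0), carbon_serial = integer(0),
               element = character(0), tag = character(0))
  structure(out, class = c("xb_donors", "data.frame"))
}

# side-chain O/N acceptor atoms by residue type
.side_chain_acceptors <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = character(0),
  HIS = c("ND1", "NE2"), ASN = c("OD1", "ND2"), GLN = c("OE1", "NE2"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"), TRP = "NE1", MET = character(0))

#' Find halogen-bond acceptors in selected residues
#'
#' For each selected residue the backbone carbonyl oxygen is reported
#' as an acceptor of class `"c"` and any side-chain oxygen or nitrogen
#' (Ser OG, Thr OG1, His ND1/NE2, ...) as class `"s"`, following the
#' backbone/side-chain acceptor dichotomy used to label contacts such
#' as "V5x40 (c)" or "H6x55 (s)".  Water and ions are never acceptors.
#'
#' @param traj an [xb_trajectory].
#' @param residues character vector of selectors, each `"chain:resseq"`
#'   (e.g. `"A:193"`) or a generic label (e.g. `"5x40"`) resolved
#'   through `map`.
#' @param map optional [numbering_map] used to resolve generic labels
#'   and to attach generic names to reported acceptors.
#' @return data.frame of class `xb_acceptors`: `serial`, `name`,
#'   `chain`, `resno`, `resname`, `class` ("c" or "s"), `label`.
#' @export
find_acceptors <- function(traj, residues, map = NULL) {
  a <- traj$atoms
  rows <- lapply(residues, function(sel) {
    loc <- .resolve_selector(sel, map)
    hit <- which(!a$is_ligand & a$chain == loc$chain & a$resno == loc$resno)
    if (!length(hit))
      stop("residue ", sel, " not found in structure")
    resname <- a$resname[hit[1]]
    if (toupper(resname) %in% .solvent_ions)
      stop("residue ", sel, " (", resname, ") is solvent/ion, not an acceptor")
    gen <- if (!is.null(map)) generic_label(map, loc$chain, loc$resno)
           else NA_character_
    base <- if (!is.na(gen)) gen else paste0(loc$chain, ":", loc$resno)
    res <- data.frame(serial = integer(0), name = character(0),
                      chain = character(0), resno = integer(0),
                      resname = character(0), class = character(0),
                      label = character(0), stringsAsFactors = FALSE)
    bb <- hit[a$name[hit] == "O"]
    if (length(bb))
      res <- rbind(res, data.frame(
        serial = a$serial[bb[1]], name = "O", chain = loc$chain,
        resno = loc$resno, resname = resname, class = "c",
        label = paste0(base, "(c)"), stringsAsFactors = FALSE))
    sc_names <- .side_chain_acceptors[[toupper(resname)]]
    for (nm in sc_names) {
      sc <- hit[a$name[hit] == nm]
      if (length(sc))
        res <- rbind(res, data.frame(
          serial = a$serial[sc[1]], name = nm, chain = loc$chain,
          resno = loc$resno, resname = resname, class = "s",
          label = paste0(base, "(s:", nm, ")"), stringsAsFactors = FALSE))
    }
    if (nrow(res) == 0L)
      stop("residue ", sel, " (", resname,
           ") has no backbone O or side-chain O/N acceptor atom")
    res
  })
  structure(do.call(rbind, rows), class = c("xb_acceptors", "data.frame"))
}

.resolve_selector <- function(sel, map) {
  if (grepl("^[0-9]+x[0-9]+$", sel)) {
    if (is.null(map))
      stop("generic label ", sel, " given but no numbering map supplied")
    hit <- which(map$label == sel)
    if (!length(hit)) stop("generic label ", sel, " not in numbering map")
    list(chain = map$chain[hit[1]], resno = map$residue_seq[hit[1]])
  } else if (grepl("^[^:]*:[0-9]+$", sel)) {
    parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
    list(chain = parts[1], resno = as.integer(parts[2]))
  } else {
    stop("unrecognised residue selector: ", sel,
         " (use chain:resseq or a generic label like 5x40)")
  }
}

#' Build a donor-acceptor contact
#'
#' @param donor one row of an `xb_donors` table.
#' @param acceptor one row of an `xb_acceptors` table.
#' @return list of class `xb_contact` with `halogen_serial`,
#'   `carbon_serial`, `acceptor_serial`, `acceptor_class`, `label`.
#' @export
xb_contact <- function(donor, acceptor) {
  if (donor$halogen_serial[1] == acceptor$serial[1])
    stop("donor halogen and acceptor are the same atom")
  structure(list(halogen_serial = donor$halogen_serial[1],
                 carbon_serial = donor$carbon_serial[1],
                 acceptor_serial = acceptor$serial[1],
                 acceptor_class = acceptor$class[1],
                 label = paste0(donor$tag[1], " -> ", acceptor$label[1])),
            class = "xb_contact")
}

#' @export
print.xb_contact <- function(x, ...) {
  cat("xb_contact:", x$label, "\n")
  invisible(x)
}

#' Automatic contact detection across a trajectory
#'
#' Pairs every donor with every acceptor and keeps those whose
#' halogen-acceptor distance falls below `detect_cutoff` in at least a
#' fraction `min_fraction` of frames.
#'
#' @param traj an [xb_trajectory].
#' @param donors an `xb_donors` table.
#' @param acceptors an `xb_acceptors` table.
#' @param detect_cutoff distance cutoff in A (default 5.5).
#' @param min_fraction minimum fraction of frames within the cutoff
#'   (default 0.10).
#' @return list of [xb_contact] objects (possibly empty).
#' @export
auto_contacts <- function(traj, donors, acceptors,
                          detect_cutoff = 5.5, min_fraction = 0.10) {
  out <- list()
  for (i in seq_len(nrow(donors))) for (j in seq_len(nrow(acceptors))) {
    ct <- xb_contact(donors[i, ], acceptors[j, ])
    d <- xb_distance(traj, ct)
    if (mean(d <= detect_cutoff) >= min_fraction) out[[length(out) + 1L]] <- ct
  }
  out
}
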