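#' Protein-ligand trajectory container
#'
#' An `xb_trajectory` bundles a topology (one row of atom metadata per
#' atom) with an ordered set of coordinate frames.  Coordinates are in
#' Angstrom, times in nanoseconds.  The frame matrix follows the bio3d
#' convention: one row per frame, columns `x1, y1, z1, x2, ...`.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resno`, `chain`, `b`, `is_ligand`.
#' @param xyz numeric matrix, `n_frames x (3 * n_atoms)`.
#' @param times numeric vector of frame times in ns, nondecreasing.
#' @param label character tag for reports.
#' @return An object of class `xb_trajectory`.
#' @export
xb_trajectory <- function(atoms, xyz, times = NULL, label = "") {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (nrow(xyz) < 1L) stop("a trajectory needs at least one frame")
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("coordinate columns (", ncol(xyz), ") do not match 3 x atom count (",
         3L * nrow(atoms), ")")
  if (anyDuplicated(atoms$serial))
    stop("atom serial numbers must be unique")
  if (is.null(times)) times <- seq_len(nrow(xyz)) - 1
  if (length(times) != nrow(xyz))
    stop("times length must equal frame count")
  if (is.unsorted(times)) stop("frame times must be nondecreasing")
  structure(list(atoms = atoms, xyz = xyz, times = as.numeric(times),
                 label = label),
            class = "xb_trajectory")
}

#' @export
print.xb_trajectory <- function(x, ...) {
  cat("xb_trajectory", if (nzchar(x$label)) paste0("'", x$label, "'"), "\n")
  cat("  atoms:  ", n_atoms(x), " (", sum(x$atoms$is_ligand), " ligand)\n",
      sep = "")
  cat("  frames: ", n_frames(x), ", time ", format(min(x$times)), " - ",
      format(max(x$times)), " ns\n", sep = "")
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj an `xb_trajectory`.
#' @return integer count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' @rdname n_frames
#' @export
n_atoms <- function(traj) nrow(traj$atoms)

# residue names never treated as small-molecule ligands
.solvent_ions <- c("HOH", "WAT", "DOD", "H2O", "SOL", "TIP", "TIP3", "TIP4",
                   "NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "CU", "BR",
                   "IOD", "SO4", "PO4", "GOL", "EDO", "ACT")

#' Read a PDB structure or multi-model trajectory
#'
#' Parses PDB text (file path or character vector of lines) into an
#' [xb_trajectory]: one frame per MODEL record (a single frame when the
#' file has none).  HETATM records other than water and common
#' ions/cryoprotectants are flagged as ligand atoms; B-factors, chain
#' identifiers and 1-based PDB residue numbering are preserved.  Only
#' alternate location 'A' or blank is kept.
#'
#' @param input path to a PDB file, or a character vector of PDB lines.
#' @param ligand optional residue-name character vector overriding the
#'   default HETATM-based ligand detection.
#' @param dt_ns frame spacing used to assign times (default 1 ns).
#' @param label trajectory label; defaults to the file name.
#' @return An [xb_trajectory].
#' @export
read_structure <- function(input, ligand = NULL, dt_ns = 1, label = NULL) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    path <- input
    if (is.null(label)) label <- basename(path)
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(input, path)
    if (is.null(label)) label <- ""
  }
  .check_pdb_lines(readLines(path, warn = FALSE))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  xyz <- pdb$xyz[, as.vector(rbind(3 * which(keep) - 2,
                                   3 * which(keep) - 1,
                                   3 * which(keep))), drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms found in PDB input")
  elem <- at$elesy
  blank <- is.na(elem) | elem == ""
  elem[blank] <- .element_from_name(at$elety[blank])
  elem <- paste0(toupper(substr(elem, 1, 1)),
                 tolower(substr(elem, 2, 2)))
  if (is.null(ligand)) {
    is_lig <- at$type == "HETATM" & !(toupper(at$resid) %in% .solvent_ions)
  } else {
    is_lig <- at$resid %in% ligand
  }
  atoms <- data.frame(serial = at$eleno, name = trimws(at$elety),
                      element = elem, resname = at$resid,
                      resno = at$resno, chain = at$chain,
                      b = at$b, is_ligand = is_lig,
                      stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- ""
  xb_trajectory(atoms, xyz, times = dt_ns * (seq_len(nrow(xyz)) - 1),
                label = label)
}

# bio3d is permissive; reject ATOM/HETATM lines with unreadable
# coordinate fields up front, naming the offending line
.check_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in PDB input")
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM/HETATM record at line ", i, ": too short")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop("malformed ATOM/HETATM record at line ", i,
           ": unreadable coordinates")
  }
  invisible(TRUE)
}

.element_from_name <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  out <- ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA"),
                two, substr(gsub("[^A-Z]", "", nm), 1, 1))
  out
}

#' Append coordinate frames from a series file
#'
#' Reads a coordinate series (multi-model PDB, DCD, or a long-format
#' CSV with columns `frame,time_ns,serial,x,y,z`) and appends its
#' frames, in file order, to a topology.
#'
#' @param topology an [xb_trajectory] supplying atom metadata (its own
#'   frames are discarded).
#' @param path series file path.
#' @param format one of `"pdb"`, `"dcd"`, `"csv"`; default guessed from
#'   the file extension.
#' @param times optional frame times (ns); inferred when the format
#'   carries none.
#' @param dt_ns frame spacing used when `times` is absent.
#' @return An [xb_trajectory] with the new frames.
#' @export
read_coordinate_series <- function(topology, path,
                                   format = c("auto", "pdb", "dcd", "csv"),
                                   times = NULL, dt_ns = 1) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     dcd = "dcd", csv = "csv", "pdb")
  na <- n_atoms(topology)
  if (format == "pdb") {
    tr <- read_structure(path, dt_ns = dt_ns)
    xyz <- tr$xyz
    if (is.null(times)) times <- tr$times
  } else if (format == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  } else {
    df <- utils::read.csv(path)
    need <- c("frame", "time_ns", "serial", "x", "y", "z")
    if (!all(need %in% names(df)))
      stop("csv series needs columns ", paste(need, collapse = ", "))
    frames <- sort(unique(df$frame))
    ord <- match(df$serial, topology$atoms$serial)
    if (anyNA(ord)) stop("csv series has serials absent from topology")
    xyz <- matrix(NA_real_, length(frames), 3L * na)
    tms <- numeric(length(frames))
    for (k in seq_along(frames)) {
      sub <- df[df$frame == frames[k], , drop = FALSE]
      idx <- match(topology$atoms$serial, sub$serial)
      if (anyNA(idx)) stop("frame ", frames[k], " is missing atoms")
      xyz[k, ] <- as.vector(t(as.matrix(sub[idx, c("x", "y", "z")])))
      tms[k] <- sub$time_ns[1]
    }
    if (is.null(times)) times <- tms
  }
  if (ncol(xyz) != 3L * na)
    stop("series atom count (", ncol(xyz) / 3, ") does not match topology (",
         na, ")")
  if (is.null(times)) times <- dt_ns * (seq_len(nrow(xyz)) - 1)
  xb_trajectory(topology$atoms, xyz, times = times, label = topology$label)
}

#' Write a trajectory as (multi-model) PDB
#'
#' @param traj an [xb_trajectory].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(traj, path) {
  a <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  multi <- n_frames(traj) > 1L
  for (k in seq_len(n_frames(traj))) {
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- matrix(traj$xyz[k, ], ncol = 3, byrow = TRUE)
    # atom-name field (cols 13-16): names of atoms with 1-letter
    # element symbols start in column 14
    nm <- ifelse(nchar(a$name) >= 4L | nchar(a$element) == 2L,
                 formatC(a$name, width = -4),
                 formatC(paste0(" ", a$name), width = -4))
    writeLines(sprintf(
      "%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ifelse(a$is_ligand, "HETATM",
             ifelse(a$resname %in% .aa3, "ATOM", "HETATM")),
      a$serial, nm, a$resname, a$chain, a$resno,
      xyz[, 1], xyz[, 2], xyz[, 3], 1.00,
      ifelse(is.na(a$b), 0, a$b), toupper(a$element)), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

#' Look up crystallographic B-factors by atom serial
#'
#' Temperature factors of atoms involved in a halogen bond gauge how
#' well-ordered the contact is in the crystal.
#'
#' @param traj an [xb_trajectory] read from a crystal structure.
#' @param serials integer atom serial numbers.
#' @return numeric vector of B-factors (A^2), in input order.
#' @export
bfactors_of <- function(traj, serials) {
  idx <- match(serials, traj$atoms$serial)
  if (anyNA(idx))
    stop("unknown atom serial(s): ",
         paste(serials[is.na(idx)], collapse = ", "))
  traj$atoms$b[idx]
}

#' Read a generic residue-numbering map
#'
#' GPCRdb-style generic labels (e.g. "5x40" for a residue ten positions
#' before the most conserved position of helix 5) are transferable
#' across receptors; the map is a user-supplied TSV with header
#' `chain residue_seq label`.
#'
#' @param path TSV file path.
#' @return A data.frame of class `xb_numbering_map`.
#' @export
read_numbering_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("chain", "residue_seq", "label") %in% names(df)))
    stop("numbering map needs columns chain, residue_seq, label")
  numbering_map(df$chain, df$residue_seq, df$label)
}

#' Construct a generic numbering map in code
#' @param chain,residue_seq,label parallel vectors.
#' @return A data.frame of class `xb_numbering_map`.
#' @export
numbering_map <- function(chain, residue_seq, label) {
  ok <- grepl("^[0-9]+x[0-9]+$", label)
  if (!all(ok))
    stop("generic labels must match <helix>x<position>, offending: ",
         paste(unique(label[!ok]), collapse = ", "))
  structure(data.frame(chain = as.character(chain),
                       residue_seq = as.integer(residue_seq),
                       label = as.character(label),
                       stringsAsFactors = FALSE),
            class = c("xb_numbering_map", "data.frame"))
}

#' Generic label of a residue, or NA when unmapped
#' @param map an `xb_numbering_map`.
#' @param chain chain identifier.
#' @param residue_seq PDB residue number.
#' @return the label string, or `NA_character_`.
#' @export
generic_label <- function(map, chain, residue_seq) {
  hit <- map$chain == chain & map$residue_seq == residue_seq
  if (!any(hit)) return(NA_character_)
  map$label[which(hit)[1]]
}

# xyz coordinates of one atom (by row index) in one frame
.coords <- function(traj, atom_idx, frame) {
  traj$xyz[frame, c(3 * atom_idx - 2, 3 * atom_idx - 1, 3 * atom_idx)]
}
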