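# Fixture builders and independent oracles shared across the suite.

# one ATOM/HETATM line with wwPDB v3.3 column layout
pdb_line <- function(record = "ATOM", serial, name, resname, chain, resno,
                     x, y, z, b = 20, element = substr(name, 1, 1)) {
  nm <- if (nchar(name) >= 4 || nchar(element) == 2) {
    formatC(name, width = -4)
  } else {
    formatC(paste0(" ", name), width = -4)
  }
  sprintf("%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, resname, chain, resno, x, y, z, 1.00, b,
          toupper(element))
}

# a valine residue (N, CA, C, O) placed by offset
val_lines <- function(serial0, chain = "A", resno = 193, off = c(0, 0, 0),
                      b = 20) {
  c(pdb_line("ATOM", serial0 + 0, "N", "VAL", chain, resno,
             7.5 + off[1], 2.0 + off[2], 1.0 + off[3], b),
    pdb_line("ATOM", serial0 + 1, "CA", "VAL", chain, resno,
             6.8 + off[1], 1.2 + off[2], 0.2 + off[3], b),
    pdb_line("ATOM", serial0 + 2, "C", "VAL", chain, resno,
             5.6 + off[1], 0.6 + off[2], 1.0 + off[3], b),
    pdb_line("ATOM", serial0 + 3, "O", "VAL", chain, resno,
             4.6 + off[1], 1.2 + off[2], 1.2 + off[3], b))
}

# minimal single-frame complex: chloro-ligand + one valine, acceptor O
# placed so that the contact geometry equals (d, theta) exactly
site_pdb_lines <- function(d = 3.7, theta = 163.2, halogen = "CL1",
                           element = "Cl", b_hal = 25) {
  th <- theta * pi / 180
  o <- c(1.74, 0, 0) + d * c(cos(th) * -1, sin(th), 0)
  c(pdb_line("HETATM", 1, "C1", "LIG", "A", 900, 0, 0, 0, 30, "C"),
    pdb_line("HETATM", 2, halogen, "LIG", "A", 900, 1.74, 0, 0, b_hal,
             element),
    pdb_line("HETATM", 3, "C2", "LIG", "A", 900, -0.75, 1.3, 0, 30, "C"),
    pdb_line("ATOM", 4, "N", "VAL", "A", 193, o[1] + 1.2, o[2] + 2.5,
             o[3] + 1.0, 15, "N"),
    pdb_line("ATOM", 5, "CA", "VAL", "A", 193, o[1] + 1.0, o[2] + 1.4,
             o[3] + 0.3, 15, "C"),
    pdb_line("ATOM", 6, "C", "VAL", "A", 193, o[1] + 0.4, o[2] + 0.9,
             o[3] + 1.1, 15, "C"),
    pdb_line("ATOM", 7, "O", "VAL", "A", 193, o[1], o[2], o[3], 12, "O"),
    "END")
}

# independent brute-force angle at vertex b, in degrees
oracle_angle <- function(a, b, c) {
  v1 <- a - b
  v2 <- c - b
  acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
}

# independent Kabsch superposition of mobile onto fixed (n x 3)
oracle_kabsch <- function(fixed, mobile) {
  cf <- colMeans(fixed)
  cm <- colMeans(mobile)
  H <- t(sweep(mobile, 2, cm)) %*% sweep(fixed, 2, cf)
  sv <- svd(H)
  dsign <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)
  sweep(sweep(mobile, 2, cm) %*% t(R), 2, cf, "+")
}

oracle_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# sort-based quantile with linear interpolation (type-7 definition,
# written from the h = (n-1)p + 1 formula, not via stats::quantile)
oracle_quantile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# random 3D rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# apply a rigid transform to every frame of a trajectory
transform_traj <- function(traj, R, shift) {
  for (k in seq_len(n_frames(traj))) {
    m <- matrix(traj$xyz[k, ], ncol = 3, byrow = TRUE)
    traj$xyz[k, ] <- as.vector(t(m %*% t(R) + matrix(shift, nrow(m), 3,
                                                     byrow = TRUE)))
  }
  traj
}

# minimal CHARMM-format DCD writer (test fixture generator only)
write_dcd_fixture <- function(xyz, path) {
  n_fr <- nrow(xyz)
  natom <- ncol(xyz) / 3L
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(payload, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
    payload()
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- n_fr
  icntrl[2] <- 1L
  icntrl[3] <- 1L
  icntrl[4] <- n_fr
  icntrl[20] <- 24L
  rec(function() {
    writeChar("CORD", con, 4, eos = NULL)
    writeBin(icntrl, con, size = 4, endian = "little")
  }, 84)
  rec(function() {
    writeBin(1L, con, size = 4, endian = "little")
    writeChar(formatC("synthetic test trajectory", width = -80), con, 80,
              eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(natom), con, size = 4,
                          endian = "little"), 4)
  for (k in seq_len(n_fr)) for (dim in 1:3) {
    v <- xyz[k, seq(dim, by = 3, length.out = natom)]
    rec(function() writeBin(as.numeric(v), con, size = 4,
                            endian = "little"), 4 * natom)
  }
  invisible(path)
}

# spec for occupancy-recovery runs: tight primary-state geometry so the
# planted state and the region label coincide essentially surely
occupancy_spec <- function(p, n = 2000, seed = 1) {
  xb_spec(n_frames = n, dt_ns = 0.03,
          states = data.frame(weight = c(p, 1 - p),
                              d_mean = c(3.5, 6.5), d_sd = c(0.15, 0.5),
                              theta_mean = c(165, 100),
                              theta_sd = c(5, 10)),
          seed = seed)
}
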