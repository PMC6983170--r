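#' Specification of a synthetic two-state halogen-bond trajectory
#'
#' Describes the statistical model the generator draws from: a
#' halogen bond that switches between a bound state with primary-XB
#' geometry and a broken state, each state emitting (distance, angle)
#' pairs from truncated Gaussians.  Defaults emulate the behaviour a
#' stable GPCR-ligand halogen bond shows over a 60 ns simulation
#' sampled every 0.06 ns: a bound state at 3.8 +/- 0.4 A and
#' 163.7 +/- 8.2 deg holding ~60% of the time, against a broken state
#' at 6.5 +/- 0.7 A and 110 +/- 20 deg.
#'
#' @param n_frames number of frames (default 1000).
#' @param dt_ns frame spacing in ns (default 0.06).
#' @param states data.frame with columns `weight`, `d_mean`, `d_sd`,
#'   `theta_mean`, `theta_sd`; weights must sum to 1.
#' @param stay_prob optional scalar in [0, 1]: when given (two states
#'   only), states follow a symmetric 2-state Markov chain with this
#'   self-transition probability instead of independent draws.
#' @param seed RNG seed.
#' @return list of class `xb_spec`.
#' @export
xb_spec <- function(n_frames = 1000, dt_ns = 0.06,
                    states = data.frame(
                      weight = c(0.6, 0.4),
                      d_mean = c(3.8, 6.5), d_sd = c(0.4, 0.7),
                      theta_mean = c(163.7, 110), theta_sd = c(8.2, 20)),
                    stay_prob = NULL, seed = 1) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (abs(sum(states$weight) - 1) > 1e-8)
    stop("state weights must sum to 1")
  if (any(states$d_sd < 0) || any(states$theta_sd < 0))
    stop("state SDs must be nonnegative")
  if (!is.null(stay_prob)) {
    if (stay_prob < 0 || stay_prob > 1)
      stop("stay_prob must be in [0, 1]")
    if (nrow(states) != 2)
      stop("the Markov-chain mode needs exactly two states")
  }
  structure(list(n_frames = as.integer(n_frames), dt_ns = dt_ns,
                 states = states, stay_prob = stay_prob, seed = seed),
            class = "xb_spec")
}

# redraw-on-out-of-range truncated normal
.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lo | out >= hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lo | out[bad] >= hi]
  }
  out
}

#' Simulate a ground-truthed halogen-bond trajectory
#'
#' Builds a minimal complex — a four-atom chloro-ligand (C-Cl donor
#' plus two extra carbons), a valine-like acceptor residue whose
#' backbone O is the acceptor, and three pocket C-alpha atoms for
#' superposition — and realises each frame's drawn (d, theta) exactly
#' by placing the acceptor oxygen on a cone of half-angle
#' (180 deg - theta) about the fixed C-Cl axis at distance d, with a
#' uniform random azimuth.  Because the geometry is exact by
#' construction, downstream statistics are tested free of coordinate
#' noise.  Distances are truncated to > 2.5 A and angles to [0, 180].
#'
#' @param spec an [xb_spec].
#' @return list with elements `trajectory` (an [xb_trajectory]) and
#'   `truth` (data.frame `frame`, `time_ns`, `state`, `d`, `theta`,
#'   `region` under default thresholds).
#' @export
simulate_xb_trajectory <- function(spec) {
  stopifnot(inherits(spec, "xb_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n <- spec$n_frames
  ns <- nrow(spec$states)
  if (is.null(spec$stay_prob)) {
    state <- sample.int(ns, n, replace = TRUE, prob = spec$states$weight)
  } else {
    state <- integer(n)
    state[1] <- sample.int(2L, 1L, prob = spec$states$weight)
    flips <- stats::runif(n - 1) >= spec$stay_prob
    for (i in seq_len(n - 1))
      state[i + 1] <- if (flips[i]) 3L - state[i] else state[i]
  }
  d <- theta <- numeric(n)
  for (s in seq_len(ns)) {
    sel <- state == s
    if (!any(sel)) next
    st <- spec$states[s, ]
    d[sel] <- if (st$d_sd == 0) rep(st$d_mean, sum(sel)) else
      .rtrunc_norm(sum(sel), st$d_mean, st$d_sd, 2.5, Inf)
    theta[sel] <- if (st$theta_sd == 0) rep(st$theta_mean, sum(sel)) else
      .rtrunc_norm(sum(sel), st$theta_mean, st$theta_sd, 0, 180)
  }
  azimuth <- stats::runif(n, 0, 2 * pi)

  # fixed scaffold: ligand donor along +x, non-collinear pocket CAs
  # around it so least-squares superposition is well determined
  atoms <- data.frame(
    serial = 1:11,
    name = c("C1", "CL1", "C2", "C3", "N", "CA", "C", "O",
             "CA", "CA", "CA"),
    element = c("C", "Cl", "C", "C", "N", "C", "C", "O", "C", "C", "C"),
    resname = c(rep("LIG", 4), rep("VAL", 4), "GLY", "GLY", "GLY"),
    resno = c(rep(900L, 4), rep(193L, 4), 101L, 102L, 103L),
    chain = "A",
    b = NA_real_,
    is_ligand = c(rep(TRUE, 4), rep(FALSE, 7)),
    stringsAsFactors = FALSE)
  base <- rbind(c(0, 0, 0),        # C1 donor carbon
                c(1.74, 0, 0),     # CL1 halogen
                c(-0.75, 1.3, 0),  # C2
                c(-0.75, -1.3, 0), # C3
                c(7.5, 2.0, 1.0),  # VAL N
                c(6.8, 1.2, 0.2),  # VAL CA
                c(5.6, 0.6, 1.0),  # VAL C
                c(0, 0, 0),        # VAL O (placed per frame)
                c(4.0, -3.0, 2.0), # pocket GLY CAs
                c(0.5, 4.5, -2.0),
                c(-3.5, 2.0, 3.0))
  xc <- base[2, ]
  axis <- c(-1, 0, 0)              # unit vector Cl -> C
  perp1 <- c(0, 1, 0)
  perp2 <- c(0, 0, 1)
  xyz <- matrix(rep(as.vector(t(base)), each = n), nrow = n)
  th <- theta * pi / 180
  u <- cbind(cos(th)) %*% rbind(axis) +
    (sin(th) * cos(azimuth)) %*% rbind(perp1) +
    (sin(th) * sin(azimuth)) %*% rbind(perp2)
  opos <- matrix(xc, n, 3, byrow = TRUE) + d * u
  xyz[, 22:24] <- opos
  traj <- xb_trajectory(atoms, xyz, times = spec$dt_ns * (seq_len(n) - 1),
                        label = "synthetic-xb")
  truth <- data.frame(frame = seq_len(n), time_ns = traj$times,
                      state = state, d = d, theta = theta,
                      region = classify_region(d, theta))
  list(trajectory = traj, truth = truth)
}

#' Write a synthetic fixture to disk
#'
#' Emits a multi-model PDB of the simulated trajectory plus the
#' per-frame ground-truth CSV (`frame,state,d,theta,region`).
#'
#' @param spec an [xb_spec].
#' @param prefix output path prefix; writes `<prefix>.pdb` and
#'   `<prefix>_truth.csv`.
#' @return character vector of the two paths, invisibly.
#' @export
write_xb_fixture <- function(spec, prefix) {
  sim <- simulate_xb_trajectory(spec)
  pdb <- paste0(prefix, ".pdb")
  csv <- paste0(prefix, "_truth.csv")
  write_structure(sim$trajectory, pdb)
  utils::write.csv(sim$truth, csv, row.names = FALSE, quote = FALSE)
  invisible(c(pdb, csv))
}

# SMILES templates: parent scaffolds of the two aminergic chemotype
# classes with aryl positions open to chlorination
.xsar_templates <- list(
  arylpiperazine = list(
    parent = "c1ccccc1N1CCNCC1",
    derivs = c(`2-Cl` = "Clc1ccccc1N1CCNCC1",
               `2,3-diCl` = "Clc1cccc(c1Cl)N1CCNCC1")),
  benzylpiperidine = list(
    parent = "C1CCN(CC1)Cc1ccccc1",
    derivs = c(`3-Cl` = "C1CCN(CC1)Cc1cccc(Cl)c1",
               `4-Cl` = "C1CCN(CC1)Cc1ccc(Cl)cc1")))

#' Generate a toy XSAR activity table with planted Xeffects
#'
#' Emits parent scaffolds (arylpiperazine- and benzylpiperidine-like)
#' plus chlorinated variants whose activities are
#' `parent_activity / fold` for planted fold values, so the matched-
#' pair search and Xeffect computation can be validated exactly.
#'
#' @param n_parents number of parent scaffolds, 1 or 2 (default 2).
#' @param folds named or plain numeric vector of planted fold-changes,
#'   recycled across derivatives (default `c(122, 55, 27, 1.3)`).
#' @param parent_activity_nM parent activities (recycled; default 100).
#' @param seed seed used to jitter parent activities when
#'   `jitter = TRUE`.
#' @param jitter draw parent activities log-uniformly in
#'   [50, 500) nM instead of fixing them (default FALSE).
#' @return data.frame `id`, `smiles`, `activity_nM` with the planted
#'   folds attached as attribute `"truth"`.
#' @export
make_toy_xsar <- function(n_parents = 2, folds = c(122, 55, 27, 1.3),
                          parent_activity_nM = 100, seed = 1,
                          jitter = FALSE) {
  stopifnot(n_parents >= 1, n_parents <= length(.xsar_templates))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- list()
  truth <- list()
  fi <- 0L
  pact <- rep_len(parent_activity_nM, n_parents)
  if (jitter) pact <- exp(stats::runif(n_parents, log(50), log(500)))
  for (p in seq_len(n_parents)) {
    tmpl <- .xsar_templates[[p]]
    pid <- paste0("parent_", names(.xsar_templates)[p])
    rows[[length(rows) + 1L]] <- data.frame(
      id = pid, smiles = tmpl$parent, activity_nM = pact[p],
      stringsAsFactors = FALSE)
    for (dv in seq_along(tmpl$derivs)) {
      fi <- fi + 1L
      fold <- folds[(fi - 1L) %% length(folds) + 1L]
      did <- paste0(names(.xsar_templates)[p], "_",
                    names(tmpl$derivs)[dv])
      rows[[length(rows) + 1L]] <- data.frame(
        id = did, smiles = unname(tmpl$derivs[dv]),
        activity_nM = pact[p] / fold, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        parent = pid, derivative = did, fold = fold,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- do.call(rbind, truth)
  out
}
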