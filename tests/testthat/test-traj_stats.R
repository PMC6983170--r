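# build an xb_series directly from numbers
mk_series <- function(d, theta, times = seq_along(d) - 1,
                      thresholds = region_thresholds()) {
  out <- data.frame(time_ns = times, distance_A = d, sigma_hole_deg = theta,
                    region = classify_region(d, theta, thresholds))
  attr(out, "thresholds") <- thresholds
  class(out) <- c("xb_series", "data.frame")
  out
}

test_that("contact summaries report occupancy, mean +/- SD and fractions", {
  s <- mk_series(rep(3.5, 10), rep(165, 10))
  sm <- summary(s)
  expect_equal(sm$primary_occupancy, 1.0)
  expect_equal(sm$mean_d, 3.5)
  expect_equal(sm$sd_d, 0)
  expect_equal(sum(sm$region_fractions), 1)

  # population (not sample) SD
  x <- c(3, 4, 5, 6)
  sm2 <- summary(mk_series(x, rep(150, 4)))
  expect_equal(sm2$sd_d, sqrt(mean((x - mean(x))^2)))
  expect_gt(stats::sd(x), sm2$sd_d)

  expect_error(summary(mk_series(numeric(0), numeric(0))), "empty")
})

test_that("planted two-state occupancy is recovered within binomial bounds", {
  sim <- simulate_xb_trajectory(occupancy_spec(p = 0.6, n = 1000, seed = 4))
  ct <- xb_contact(find_donors(sim$trajectory),
                   find_acceptors(sim$trajectory, "A:193"))
  sm <- summary(contact_series(sim$trajectory, ct))
  # 99% binomial interval around 0.6 at n = 1000
  half <- stats::qnorm(0.995) * sqrt(0.6 * 0.4 / 1000)
  expect_lt(abs(sm$primary_occupancy - 0.6), half + 0.01)
  # and fractions always sum to one
  expect_equal(sum(sm$region_fractions), 1)
})

test_that("interval medians follow the half-open 6 ns convention", {
  s <- mk_series(rep(3.5, 100), rep(160, 100),
                 times = seq(0, 59.4, length.out = 100))
  m <- interval_medians(s, 6)
  expect_equal(nrow(m), 10L)
  expect_true(all(m$median_d == 3.5))
  expect_true(all(m$median_theta == 160))

  # a 60 ns end point folds into the last interval, still 10 intervals
  s2 <- mk_series(rep(3.5, 101), rep(160, 101),
                  times = seq(0, 60, length.out = 101))
  expect_equal(nrow(interval_medians(s2, 6)), 10L)

  # odd-count interval medians are the middle value
  s3 <- mk_series(c(3, 4, 5), c(150, 160, 170), times = c(0, 1, 2))
  m3 <- interval_medians(s3, 6)
  expect_equal(m3$median_d, 4)
  expect_equal(m3$median_theta, 160)

  # an empty interval is reported as missing, not an error
  s4 <- mk_series(c(3, 3, 5), c(150, 150, 170), times = c(0, 1, 14))
  m4 <- interval_medians(s4, 6)
  expect_equal(nrow(m4), 3L)
  expect_true(is.na(m4$median_d[2]))
  expect_equal(m4$median_d[3], 5)
})

test_that("interval medians agree with independent per-interval medians", {
  set.seed(21)
  d <- stats::runif(500, 2.5, 8)
  th <- stats::runif(500, 60, 180)
  times <- sort(stats::runif(500, 0, 60))
  s <- mk_series(d, th, times = times)
  m <- interval_medians(s, 6)
  nint <- nrow(m)
  idx <- pmin(floor((times - times[1]) / 6) + 1, nint)
  for (k in seq_len(nint)) {
    sel <- idx == k
    if (any(sel)) {
      expect_equal(m$median_d[k], stats::median(d[sel]))
      expect_equal(m$median_theta[k], stats::median(th[sel]))
    }
  }
})

test_that("boxplot statistics match the sort-based quantile oracle", {
  s <- mk_series(rep(4, 5), rep(120, 5), times = 0:4)
  b <- boxplot_stats(s, 6)
  drow <- b[b$variable == "distance_A", ]
  expect_true(all(unlist(drow[c("whisker_low", "q1", "median", "q3",
                                "whisker_high")]) == 4))

  s2 <- mk_series(1:5, rep(120, 5), times = 0:4)
  d2 <- boxplot_stats(s2, 6)
  d2 <- d2[d2$variable == "distance_A", ]
  expect_equal(d2$q1, 2)
  expect_equal(d2$median, 3)
  expect_equal(d2$q3, 4)

  set.seed(13)
  for (i in 1:100) {
    x <- stats::rnorm(sample(5:60, 1))
    s3 <- mk_series(abs(x) + 1, rep(120, length(x)),
                    times = seq_along(x) - 1)
    b3 <- boxplot_stats(s3, 1000)
    b3 <- b3[b3$variable == "distance_A", ]
    expect_equal(b3$q1, oracle_quantile(abs(x) + 1, 0.25),
                 tolerance = 1e-8)
    expect_equal(b3$median, oracle_quantile(abs(x) + 1, 0.5),
                 tolerance = 1e-8)
    expect_equal(b3$q3, oracle_quantile(abs(x) + 1, 0.75),
                 tolerance = 1e-8)
  }
})

test_that("ligand RMSD is zero for identical frames and exact for shifts", {
  sim <- simulate_xb_trajectory(xb_spec(
    n_frames = 5, seed = 1,
    states = data.frame(weight = 1, d_mean = 3.8, d_sd = 0,
                        theta_mean = 163, theta_sd = 0)))
  tr <- sim$trajectory
  tr$xyz <- tr$xyz[rep(1, 5), ]   # identical frames
  expect_equal(ligand_rmsd(tr), rep(0, 5), tolerance = 1e-9)

  # rigid 2 A ligand translation with receptor fixed
  tr2 <- tr
  lig <- which(tr2$atoms$is_ligand)
  cols <- as.vector(rbind(3 * lig - 2, 3 * lig - 1, 3 * lig))
  xcols <- cols[seq(1, length(cols), by = 3)]
  tr2$xyz[2, xcols] <- tr2$xyz[2, xcols] + 2
  r <- ligand_rmsd(tr2)
  expect_equal(r[1], 0, tolerance = 1e-9)
  expect_equal(r[2], 2, tolerance = 1e-6)

  expect_error(ligand_rmsd(tr, superpose_on = 12345), "selection")
})

test_that("ligand RMSD agrees with an independent Kabsch oracle", {
  set.seed(31)
  sim <- simulate_xb_trajectory(xb_spec(n_frames = 12, seed = 31))
  tr <- sim$trajectory
  # perturb every atom, then rigidly transform whole frames
  tr$xyz <- tr$xyz + stats::rnorm(length(tr$xyz), sd = 0.3)
  for (k in 2:n_frames(tr)) {
    m <- matrix(tr$xyz[k, ], ncol = 3, byrow = TRUE)
    R <- random_rotation()
    tr$xyz[k, ] <- as.vector(t(m %*% t(R) +
      matrix(stats::rnorm(3, sd = 5), nrow(m), 3, byrow = TRUE)))
  }
  ca <- which(!tr$atoms$is_ligand & tr$atoms$name == "CA")
  lig <- which(tr$atoms$is_ligand)
  got <- ligand_rmsd(tr, superpose_on = tr$atoms$serial[ca])
  ref_full <- matrix(tr$xyz[1, ], ncol = 3, byrow = TRUE)
  for (k in seq_len(n_frames(tr))) {
    mob <- matrix(tr$xyz[k, ], ncol = 3, byrow = TRUE)
    # oracle: Kabsch on the CA selection, applied to all atoms
    cf <- colMeans(ref_full[ca, , drop = FALSE])
    cm <- colMeans(mob[ca, , drop = FALSE])
    H <- t(sweep(mob[ca, , drop = FALSE], 2, cm)) %*%
      sweep(ref_full[ca, , drop = FALSE], 2, cf)
    sv <- svd(H)
    R <- sv$v %*% diag(c(1, 1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
    fitted <- sweep(sweep(mob, 2, cm) %*% t(R), 2, cf, "+")
    expect_equal(got[k], oracle_rmsd(fitted[lig, , drop = FALSE],
                                     ref_full[lig, , drop = FALSE]),
                 tolerance = 1e-6)
  }
})

test_that("ligand RMSD is invariant to rigid transforms of whole frames", {
  sim <- simulate_xb_trajectory(xb_spec(n_frames = 10, seed = 17))
  base <- ligand_rmsd(sim$trajectory)
  set.seed(18)
  tr2 <- transform_traj(sim$trajectory, random_rotation(),
                        stats::rnorm(3, sd = 8))
  expect_equal(ligand_rmsd(tr2), base, tolerance = 1e-6)
  expect_true(all(base >= 0))
})

test_that("frame clustering recovers planted conformations and sums sizes", {
  # two well-separated ligand conformations, 60 + 40 frames
  sim <- simulate_xb_trajectory(xb_spec(n_frames = 100, seed = 23))
  tr <- sim$trajectory
  lig <- which(tr$atoms$is_ligand)
  cols <- as.vector(rbind(3 * lig - 2, 3 * lig - 1, 3 * lig))
  planted <- rep(1:2, c(60, 40))
  set.seed(23)
  for (k in seq_len(100)) {
    shift <- if (planted[k] == 1) 0 else 6
    tr$xyz[k, cols] <- sim$trajectory$xyz[1, cols] + shift +
      stats::rnorm(length(cols), sd = 0.05)
  }
  cl <- cluster_frames(tr, k = 2)
  expect_equal(sum(cl$sizes), 100L)
  # exact recovery up to label permutation
  expect_equal(length(unique(cl$assignment[planted == 1])), 1L)
  expect_equal(length(unique(cl$assignment[planted == 2])), 1L)
  expect_equal(sort(cl$sizes), c(40L, 60L))
  # representative lies in the largest cluster
  expect_equal(cl$sizes[cl$assignment[cl$representative]], 60L)

  sim2 <- simulate_xb_trajectory(xb_spec(n_frames = 50, seed = 29))
  cl10 <- cluster_frames(sim2$trajectory, k = 10)
  expect_equal(sum(cl10$sizes), 50L)
  expect_equal(sort(unique(cl10$assignment)), 1:10)

  expect_error(cluster_frames(sim2$trajectory, k = 60), "smaller than k")
})

test_that("degenerate all-identical frames split deterministically", {
  sim <- simulate_xb_trajectory(xb_spec(
    n_frames = 10, seed = 3,
    states = data.frame(weight = 1, d_mean = 3.8, d_sd = 0,
                        theta_mean = 163, theta_sd = 0)))
  tr <- sim$trajectory
  tr$xyz <- tr$xyz[rep(1, 10), ]
  c1 <- cluster_frames(tr, k = 10)
  c2 <- cluster_frames(tr, k = 10)
  expect_identical(c1$assignment, c2$assignment)
  expect_equal(sum(c1$sizes), 10L)
})

test_that("replicate selection minimises the summed coefficient of variation", {
  sA <- mk_series(rep(3.5, 50), rep(160, 50))
  set.seed(41)
  sB <- mk_series(3.5 + stats::rnorm(50, sd = 0.5),
                  pmin(179, 160 + stats::rnorm(50, sd = 10)))
  expect_equal(select_replicate(list(sA, sB)), 1L)
  expect_equal(select_replicate(list(sB, sA)), 2L)
  expect_equal(select_replicate(list(sB)), 1L)
  expect_error(select_replicate(list()), "no replicates")

  # planted variances: verified against direct CV computation
  set.seed(43)
  reps <- lapply(c(0.6, 0.2, 0.4), function(sd) {
    mk_series(4 + stats::rnorm(200, sd = sd),
              pmin(179, pmax(1, 150 + stats::rnorm(200, sd = 8 * sd))))
  })
  cv <- vapply(reps, function(s) {
    psd <- function(x) sqrt(mean((x - mean(x))^2))
    psd(s$distance_A) / mean(s$distance_A) +
      psd(s$sigma_hole_deg) / mean(s$sigma_hole_deg)
  }, numeric(1))
  expect_equal(select_replicate(reps), which.min(cv))
})
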