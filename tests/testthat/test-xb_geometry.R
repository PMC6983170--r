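# direct trajectory with arbitrary atom positions for one contact
geom_traj <- function(cpos, xpos, apos) {
  atoms <- data.frame(serial = 1:3, name = c("C1", "CL1", "O"),
                      element = c("C", "Cl", "O"),
                      resname = c("LIG", "LIG", "VAL"),
                      resno = c(900L, 900L, 193L), chain = "A",
                      b = NA_real_, is_ligand = c(TRUE, TRUE, FALSE),
                      stringsAsFactors = FALSE)
  xb_trajectory(atoms, matrix(c(cpos, xpos, apos), nrow = 1))
}
geom_contact <- list(halogen_serial = 2L, carbon_serial = 1L,
                     acceptor_serial = 3L, acceptor_class = "c",
                     label = "CL1 -> V193(c)")

test_that("halogen-acceptor distance is plain Euclidean distance", {
  tr <- geom_traj(c(-1, 0, 0), c(0, 0, 0), c(3, 4, 0))
  expect_equal(xb_distance(tr, geom_contact), 5)
  tr0 <- geom_traj(c(-1, 0, 0), c(0, 0, 0), c(0, 0, 0))
  expect_equal(xb_distance(tr0, geom_contact), 0)
})

test_that("sigma-hole angle has its vertex at the halogen", {
  lin <- geom_traj(c(-1, 0, 0), c(0, 0, 0), c(2, 0, 0))
  expect_equal(sigma_hole_angle(lin, geom_contact), 180)
  orth <- geom_traj(c(-1, 0, 0), c(0, 0, 0), c(0, 2, 0))
  expect_equal(sigma_hole_angle(orth, geom_contact), 90)
  degen <- geom_traj(c(0, 0, 0), c(0, 0, 0), c(2, 0, 0))
  expect_error(sigma_hole_angle(degen, geom_contact), "degenerate")
})

test_that("sigma-hole angle matches a brute-force vector oracle", {
  set.seed(42)
  for (i in 1:100) {
    cpos <- stats::rnorm(3)
    xpos <- cpos + stats::rnorm(3)
    apos <- xpos + stats::rnorm(3, sd = 2)
    tr <- geom_traj(cpos, xpos, apos)
    expect_equal(sigma_hole_angle(tr, geom_contact),
                 oracle_angle(cpos, xpos, apos), tolerance = 1e-8)
  }
  # the worked vector example: C(0,0,0), X(1.7,0,0), A(4.5,1,0)
  tr <- geom_traj(c(0, 0, 0), c(1.7, 0, 0), c(4.5, 1, 0))
  expect_equal(sigma_hole_angle(tr, geom_contact),
               oracle_angle(c(0, 0, 0), c(1.7, 0, 0), c(4.5, 1, 0)),
               tolerance = 1e-10)
})

test_that("sigma-hole angle is invariant under rigid transforms", {
  set.seed(7)
  for (i in 1:20) {
    cpos <- stats::rnorm(3)
    xpos <- cpos + stats::rnorm(3)
    apos <- xpos + stats::rnorm(3, sd = 2)
    tr <- geom_traj(cpos, xpos, apos)
    ref <- sigma_hole_angle(tr, geom_contact)
    R <- random_rotation()
    shift <- stats::rnorm(3, sd = 10)
    tr2 <- transform_traj(tr, R, shift)
    expect_equal(sigma_hole_angle(tr2, geom_contact), ref,
                 tolerance = 1e-8)
  }
})

test_that("printed geometries classify into their stated regions", {
  expect_equal(as.character(classify_region(3.7, 163.2)), "primary")
  expect_equal(as.character(classify_region(3.3, 102.9)),
               "secondary_short")
  expect_equal(as.character(classify_region(4.5, 120)), "none")
  expect_equal(as.character(classify_region(4.5, 150)), "secondary_long")
  # boundary values go to the less favourable region
  expect_equal(as.character(classify_region(4.0, 165)), "secondary_long")
  expect_equal(as.character(classify_region(3.5, 140)), "secondary_short")
  expect_equal(as.character(classify_region(4.0, 140)), "none")
})

test_that("the four regions partition the distance-angle plane", {
  set.seed(11)
  d <- stats::runif(10000, 0.1, 10)
  th <- stats::runif(10000, 0, 180)
  r <- classify_region(d, th)
  expect_false(anyNA(r))
  expect_equal(length(r), 10000L)
  # each point lands in exactly one region and all four occur
  expect_setequal(as.character(unique(r)),
                  c("primary", "secondary_short", "secondary_long", "none"))
  # monotonicity: at short distance, raising theta never leaves primary
  dfix <- 3.2
  ths <- sort(stats::runif(200, 0, 180))
  rr <- as.character(classify_region(rep(dfix, 200), ths))
  first_primary <- match("primary", rr)
  if (!is.na(first_primary))
    expect_true(all(rr[first_primary:200] == "primary"))
})

test_that("contact series carries one classified record per frame", {
  one <- simulate_xb_trajectory(xb_spec(
    n_frames = 1, seed = 1,
    states = data.frame(weight = 1, d_mean = 3.8, d_sd = 0,
                        theta_mean = 163, theta_sd = 0)))
  ct <- xb_contact(find_donors(one$trajectory),
                   find_acceptors(one$trajectory, "A:193"))
  s1 <- contact_series(one$trajectory, ct)
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$distance_A, 3.8, tolerance = 1e-6)
  expect_equal(s1$sigma_hole_deg, 163, tolerance = 1e-6)
  expect_equal(as.character(s1$region), "primary")

  sim <- simulate_xb_trajectory(xb_spec(n_frames = 400, seed = 8))
  ct <- xb_contact(find_donors(sim$trajectory),
                   find_acceptors(sim$trajectory, "A:193"))
  ser <- contact_series(sim$trajectory, ct)
  expect_equal(nrow(ser), 400L)
  # region labels agree with the generator's per-frame ground truth
  expect_equal(as.character(ser$region), as.character(sim$truth$region))
  expect_equal(ser$distance_A, sim$truth$d, tolerance = 1e-9)
  expect_equal(ser$sigma_hole_deg, sim$truth$theta, tolerance = 1e-9)
})

test_that("series CSV export round-trips numerically", {
  sim <- simulate_xb_trajectory(xb_spec(n_frames = 20, seed = 2))
  ct <- xb_contact(find_donors(sim$trajectory),
                   find_acceptors(sim$trajectory, "A:193"))
  ser <- contact_series(sim$trajectory, ct)
  f <- tempfile(fileext = ".csv")
  write_series_csv(ser, f)
  back <- utils::read.csv(f)
  expect_equal(names(back),
               c("time_ns", "distance_A", "sigma_hole_deg", "region"))
  expect_equal(back$distance_A, ser$distance_A, tolerance = 1e-12)
})
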