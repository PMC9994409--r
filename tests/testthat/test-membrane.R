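box30 <- box_spec(30)

test_that("wrapping maps coordinates into the box", {
  expect_equal(wrap_position(c(31.5, -0.5), box30), c(1.5, 29.5))
  expect_equal(wrap_position(c(15, 15), box30), c(15, 15))
  expect_equal(wrap_position(c(60, 90), box30), c(0, 0))
  expect_error(wrap_position(c(NaN, 1), box30), "non-finite")
})

test_that("minimal image matches the brute-force 9-image oracle", {
  expect_equal(minimal_image(c(1, 1), c(1, 1), box30), c(0, 0))
  d <- minimal_image(c(0.1, 0), c(29.9, 0), box30)
  expect_equal(d, c(-0.2, 0))
  expect_equal(torus_distance(c(0.1, 0), c(29.9, 0), box30), 0.2)
  set.seed(4)
  for (k in 1:1000) {
    p <- runif(2, 0, 30)
    q <- runif(2, 0, 30)
    expect_equal(minimal_image(p, q, box30), brute_minimal_image(p, q, 30))
  }
})

test_that("torus distance is a metric on sampled triples", {
  set.seed(5)
  for (k in 1:200) {
    a <- runif(2, 0, 30); b <- runif(2, 0, 30); cc <- runif(2, 0, 30)
    dab <- torus_distance(a, b, box30)
    expect_equal(dab, torus_distance(b, a, box30))
    expect_lte(dab, torus_distance(a, cc, box30) +
                    torus_distance(cc, b, box30) + 1e-12)
  }
  expect_equal(torus_distance(c(3, 4), c(3, 4), box30), 0)
})

test_that("local diffusivity honours the closed-disc convention", {
  dom <- domain_set(data.frame(cx = 15, cy = 15, r = 5), box30)
  mp <- motion_params(d_out = 1, d_in = 0.1)
  expect_equal(local_diffusivity(c(15, 15), dom, mp, box30), 0.1)
  expect_equal(local_diffusivity(c(1, 1), dom, mp, box30), 1)
  # exactly on the boundary counts as inside
  expect_equal(local_diffusivity(c(20, 15), dom, mp, box30), 0.1)
  # wrap-around membership
  dom_edge <- domain_set(data.frame(cx = 1, cy = 15, r = 3), box30)
  expect_equal(local_diffusivity(c(29, 15), dom_edge, mp, box30), 0.1)
})

test_that("domain sets validate overlap and report occupied fraction", {
  d1 <- domain_set(data.frame(cx = 15, cy = 15, r = sqrt(0.35 / pi) * 30),
                   box30)
  expect_equal(d1$occupied_fraction, 0.35, tolerance = 1e-9)
  expect_error(
    domain_set(data.frame(cx = c(10, 12), cy = c(15, 15), r = c(2, 2)),
               box30),
    "overlap")
  d0 <- domain_set(NULL, box30)
  expect_equal(d0$occupied_fraction, 0)
})

test_that("proposed step lengths follow the configured law", {
  # frozen agent
  set.seed(1)
  expect_equal(propose_step(c(5, 5), 0, box30), c(5, 5))
  # half-normal moments at D = 1: E[r] = sqrt(2/pi), E[r^2] = 1
  set.seed(2)
  p0 <- c(15, 15)
  r <- replicate(1e5, torus_distance(p0, propose_step(p0, 1, box30), box30))
  expect_equal(mean(r), sqrt(2 / pi), tolerance = 0.01)
  expect_equal(mean(r^2), 1, tolerance = 0.02)
  # rayleigh mean at D = 1: sqrt(pi/2)
  set.seed(3)
  mp <- motion_params(step_length_law = "rayleigh")
  r2 <- replicate(2e4, torus_distance(
    p0, propose_step(p0, 1, box30, motion = mp), box30))
  expect_equal(mean(r2), sqrt(pi / 2), tolerance = 0.02)
  # dimer step scale reduced by 2^(1/4)
  set.seed(6)
  rd <- replicate(2e4, torus_distance(
    p0, propose_step(p0, 1, box30, species = "dimer"), box30))
  expect_equal(mean(rd), sqrt(2 / pi) / 2^0.25, tolerance = 0.02)
})

test_that("overlap test allows tangency and matches the grid query", {
  ag <- data.frame(x = 10, y = 10, radius = 1)
  expect_false(overlaps(c(12, 10), 1, ag, box30))  # tangent
  expect_true(overlaps(c(11.9, 10), 1, ag, box30))
  expect_false(overlaps(c(1, 1), 1,
                        data.frame(x = numeric(), y = numeric(),
                                   radius = numeric()), box30))
  # grid-backed engine query agrees with the all-pairs reference on
  # random configurations
  set.seed(7)
  for (k in 1:500) {
    n <- sample(1:60, 1)
    ag <- data.frame(x = runif(n, 0, 30), y = runif(n, 0, 30),
                     radius = runif(n, 0.2, 0.9))
    cand <- runif(2, 0, 30)
    rad <- runif(1, 0.2, 0.9)
    expect_identical(
      raftsim:::cpp_overlaps(cand, rad, as.matrix(ag), 30),
      overlaps(cand, rad, ag, box30))
  }
})

test_that("uniform placement produces feasible non-overlapping packings", {
  expect_equal(nrow(place_uniform(0, 0.5, box30)), 0)
  set.seed(8)
  ag <- place_uniform(47, 0.57, box30)
  expect_equal(nrow(ag), 47)
  assert_no_overlaps(ag, 30)
  d <- as.matrix(dist(ag[, c("x", "y")]))
  diag(d) <- Inf
  # torus distance >= euclidean wrap check via oracle already; plain
  # euclidean pairs must exceed the diameter unless they wrap
  expect_true(all(d[d < 15] >= 1.14 - 1e-9))
  # impossible packing errors out with the achieved count
  expect_error(place_uniform(20, 10, box30, max_attempts = 200),
               "packing infeasible")
})

test_that("free diffusion MSD is linear with slope D", {
  cfg <- sim_config(domain_fraction = 0, n_receptor_monomers = 1,
                    k_b = 0, k_d = 0, n_steps = 1e5, window = 100, thin = 100)
  sim <- run_sim(cfg, seed = 9, snapshot_every = 1)
  u <- sim$snapshots[order(sim$snapshots$step), c("ux", "uy")]
  # time-averaged MSD at short lags from the unwrapped trajectory
  lags <- c(1, 5, 10, 20)
  msd <- vapply(lags, function(l) {
    du <- u[-seq_len(l), ] - u[seq_len(nrow(u) - l), ]
    mean(du$ux^2 + du$uy^2)
  }, numeric(1))
  fit <- stats::lm(msd ~ 0 + lags)
  expect_equal(unname(coef(fit)), 1, tolerance = 0.05)  # slope = D = 1
})

test_that("equal diffusivities leave domain occupancy at the area fraction", {
  cfg <- sim_config(d_out = 1, d_in = 1, k_b = 0, k_d = 0,
                    n_receptor_monomers = 5, n_steps = 2e5, window = 1.5e5)
  sim <- run_sim(cfg, seed = 10)
  frac <- window_mean(sim)[["fraction_inside"]]
  expect_equal(frac, 0.35, tolerance = 0.06)  # within 2 percentage points
})
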