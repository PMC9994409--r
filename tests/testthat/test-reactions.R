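box30 <- box_spec(30)
rmono <- 0.57

mk_agents <- function(xs, ys, species = "monomer", radius = rmono) {
  data.frame(id = seq_along(xs), species = species, radius = radius,
             x = xs, y = ys, stringsAsFactors = FALSE)
}

test_that("capture candidates use the edge-to-edge gap threshold", {
  # tangent pair: gap 0 -> candidate
  ag <- mk_agents(c(10, 10 + 2 * rmono), c(10, 10))
  expect_identical(capture_candidates(1, ag, box = box30), 2L)
  # gap = 0.25 diameter -> not a candidate
  ag2 <- mk_agents(c(10, 10 + 2 * rmono * 1.25), c(10, 10))
  expect_identical(capture_candidates(1, ag2, box = box30), integer())
  # three monomers at gaps {0.05, 0.08, 0.2} diameters: two candidates,
  # nearest first
  d <- 2 * rmono
  ag3 <- mk_agents(c(10, 10 + d * 1.05, 10 - d * 1.08, 10 + d * 1.2),
                   c(10, 10, 10, 10))
  set.seed(1)
  expect_identical(capture_candidates(1, ag3, box = box30), c(2L, 3L))
  # dimers are never candidates
  ag4 <- mk_agents(c(10, 10 + d), c(10, 10))
  ag4$species[2] <- "dimer"
  expect_identical(capture_candidates(1, ag4, box = box30), integer())
  expect_error(capture_candidates(2, ag4, box = box30), "monomer")
})

test_that("dimerisation replaces a tangent pair by an area-conserving dimer", {
  ag <- mk_agents(c(10, 10 + 2 * rmono), c(10, 10))
  # zero rate: nothing ever happens
  set.seed(2)
  for (k in 1:20) {
    out <- attempt_dimerise(1, ag, reaction_params(k_b = 0), box30)
    expect_identical(out$event, "none")
    expect_identical(out$agents, ag)
  }
  # certain event: dimer at the midpoint, radius sqrt(2) R, area conserved
  set.seed(3)
  out <- attempt_dimerise(1, ag, reaction_params(k_b = 1), box30)
  expect_identical(out$event, "dimerise")
  d <- out$agents
  expect_equal(nrow(d), 1)
  expect_identical(d$species, "dimer")
  expect_equal(c(d$x, d$y), c(10 + rmono, 10))
  expect_equal(d$radius, sqrt(2) * rmono)
  expect_equal(pi * d$radius^2, 2 * pi * rmono^2, tolerance = 1e-12)
  # blocked midpoint: event abandoned, monomers persist
  blocker <- mk_agents(10 + rmono, 10 + 2 * rmono * 0.9)
  blocker$id <- 99L
  set.seed(4)
  out2 <- attempt_dimerise(1, rbind(ag, blocker), reaction_params(k_b = 1),
                           box30)
  expect_identical(out2$event, "abandoned")
  expect_equal(sum(out2$agents$species == "monomer"), 3)
})

test_that("dimerisation success rate matches the binomial oracle", {
  # 1e4 independent single-candidate trials at k_b = 0.05
  ag <- mk_agents(c(10, 10 + 2 * rmono), c(10, 10))
  pars <- reaction_params(k_b = 0.05)
  set.seed(5)
  hits <- 0L
  n <- 1e4
  for (k in seq_len(n)) {
    if (attempt_dimerise(1, ag, pars, box30)$event == "dimerise")
      hits <- hits + 1L
  }
  sigma <- sqrt(n * 0.05 * 0.95)
  expect_lt(abs(hits - n * 0.05), 3 * sigma)
})

test_that("dissociation places tangent monomers and conserves molecules", {
  dimer <- data.frame(id = 1L, species = "dimer", radius = sqrt(2) * rmono,
                      x = 15, y = 15, stringsAsFactors = FALSE)
  # zero rate
  set.seed(6)
  for (k in 1:20)
    expect_identical(attempt_dissociate(1, dimer, reaction_params(k_d = 0),
                                        box30)$event, "none")
  # certain event: two tangent monomers symmetric about the old centre
  set.seed(7)
  out <- attempt_dissociate(1, dimer, reaction_params(k_d = 1), box30)
  expect_identical(out$event, "dissociate")
  m <- out$agents
  expect_equal(nrow(m), 2)
  expect_true(all(m$species == "monomer"))
  expect_equal(m$radius, rep(rmono, 2))
  expect_equal(torus_distance(c(m$x[1], m$y[1]), c(m$x[2], m$y[2]), box30),
               2 * rmono, tolerance = 1e-12)
  expect_equal(c(mean(m$x), mean(m$y)), c(15, 15))
  # total receptor disc area conserved to machine precision
  expect_equal(sum(pi * m$radius^2), pi * dimer$radius^2, tolerance = 1e-12)
})

test_that("dimer lifetimes are geometric with mean 1/k_d", {
  # 4000 isolated dimers, k_b = 0: each dissociation event step is a
  # lifetime draw; geometric mean = 1/k_d = 100
  set.seed(8)
  L <- 300
  ag <- place_uniform(4000, sqrt(2) * rmono, box_spec(L), species = "dimer")
  ag$species <- "dimer"
  cfg <- sim_config(box_length = L, domain_fraction = 0, k_b = 0, k_d = 0.01,
                    d_out = 1, d_in = 1, n_steps = 2000, window = 100,
                    n_receptor_monomers = 0)
  st <- structure(list(agents = ag, domains = domain_set(NULL, box_spec(L)),
                       box = box_spec(L)), class = "sim_state")
  res <- raftsim:::run_engine(st, cfg, 2000, record_events = TRUE)
  ev <- as.data.frame(res$events)
  lifetimes <- ev$step[ev$type == 2]
  # censoring at 2000 steps is negligible (0.99^2000 ~ 2e-9)
  expect_gt(length(lifetimes), 3800)
  expect_equal(mean(lifetimes), 100, tolerance = 0.05)
})

test_that("conversion events never create overlaps and conserve counts", {
  cfg <- quick_config(n_steps = 3000, d_in = 0.1, thin = 1)
  sim <- run_sim(cfg, seed = 9, snapshot_every = 250)
  # molecule conservation at every recorded step
  mol <- sim$series$n_monomers + 2 * sim$series$n_dimers
  expect_true(all(mol == mol[1]))
  # no overlap in any snapshot (all-pairs oracle)
  for (s in unique(sim$snapshots$step)) {
    snap <- sim$snapshots[sim$snapshots$step == s, ]
    assert_no_overlaps(snap, cfg$box_length)
    expect_true(all(snap$radius > 0))
  }
  # receptor area conserved: monomers pi r^2 + dimers pi (sqrt2 r)^2
  area <- vapply(split(sim$snapshots, sim$snapshots$step), function(sn) {
    sum(pi * sn$radius[sn$species != "inert"]^2)
  }, numeric(1))
  expect_equal(max(area) - min(area), 0, tolerance = 1e-9)
})

test_that("equilibrium dimer fraction responds to k_b and k_d as expected", {
  # sparse well-mixed box; raising k_b raises the dimer fraction,
  # raising k_d lowers it
  base <- quick_config(domain_fraction = 0, n_steps = 30000, window = 10000)
  lo_b <- base; lo_b$k_b <- 0.01
  lo_b <- raftsim:::validate_sim_config(unclass(lo_b))
  hi_d <- base; hi_d$k_d <- 0.05
  hi_d <- raftsim:::validate_sim_config(unclass(hi_d))
  f <- function(cfg, seed) {
    r <- run_replicates(cfg, seed = seed, replicates = 2)
    r$mean[r$observable == "fraction_dimeric"]
  }
  f_base <- f(base, 11)
  expect_gt(f_base, f(lo_b, 12))
  expect_gt(f_base, f(hi_d, 13))
})
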