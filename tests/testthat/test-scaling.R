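test_that("sphere geometry reproduces platelet radius and area", {
  g <- sphere_geometry(7.4e-18)
  expect_equal(g$radius, 1.2e-6, tolerance = 0.05)
  expect_equal(g$area, 1.8e-11, tolerance = 0.05)
  # identity case: unit sphere
  u <- sphere_geometry(4 * pi / 3)
  expect_equal(u$radius, 1)
  expect_equal(u$area, 4 * pi)
  # mouse platelet, checked by closed-form hand computation:
  # R = (3*4.7e-18/(4*pi))^(1/3) = 1.0391e-6, A = 4*pi*R^2 = 1.3567e-11
  m <- sphere_geometry(4.7e-18)
  expect_equal(m$area, 1.3567e-11, tolerance = 1e-3)
  expect_error(sphere_geometry(0), "positive")
  expect_error(sphere_geometry(-1), "positive")
})

test_that("raft layout yields the canonical box count", {
  A <- sphere_geometry(7.4e-18)$area
  rl <- raft_layout(A, 0.35, 200e-9)
  expect_equal(rl$raft_total_area, 6.4e-12, tolerance = 0.02)
  expect_equal(rl$boxes_per_platelet_rounded, 205)
  # vanishing fraction
  expect_lt(raft_layout(A, 1e-12, 200e-9)$raft_total_area, 1e-20)
  # symmetry: area of 4 rafts at fraction 1 gives exactly 4 boxes
  r4 <- raft_layout(4 * pi * (100e-9)^2, 1, 200e-9)
  expect_equal(r4$boxes_per_platelet, 4, tolerance = 1e-12)
  expect_error(raft_layout(A, 0.35, 0), "positive")
  expect_error(raft_layout(A, 0, 200e-9), "\\(0, 1\\]")
})

test_that("box dimensions follow from area division", {
  A <- sphere_geometry(7.4e-18)$area
  b <- box_dimensions(A, 205)
  expect_equal(b$box_area, 9.0e-14, tolerance = 0.02)
  expect_equal(b$box_length, 3.0e-7, tolerance = 0.01)
  expect_equal(box_dimensions(1, 1)$box_length, 1)
  expect_equal(box_dimensions(100, 4)$box_length, 5)
  expect_error(box_dimensions(1, 0.5), "at least 1")
})

test_that("receptor count per box rounds to nearest integer", {
  expect_identical(receptors_per_box(9600, 205), 47)
  expect_identical(receptors_per_box(0, 205), 0)
  # 7800/205 = 38.05 -> 38
  expect_identical(receptors_per_box(7800, 205), 38)
  expect_error(receptors_per_box(-1, 205), "non-negative")
})

test_that("scaled receptor diameter is the crystal/box ratio", {
  expect_equal(scaled_diameter(114e-10, 3.0e-7), 0.038, tolerance = 0.01)
  expect_equal(scaled_diameter(1, 100), 0.01)
  expect_equal(scaled_diameter(45e-10, 3.0e-7), 0.015, tolerance = 1e-6)
  expect_error(scaled_diameter(1, 1), "smaller")
})

test_that("expected step and timestep match the printed arithmetic", {
  st <- expected_step_and_timestep(3.0e-7, 30, 0.091e-12)
  expect_equal(st$expected_step, 12.5e-9, tolerance = 0.01)
  expect_equal(st$timestep, 0.43e-3, tolerance = 0.01)
  # scaling law: doubling the box doubles the step, quadruples the timestep
  st2 <- expected_step_and_timestep(6.0e-7, 30, 0.091e-12)
  expect_equal(st2$expected_step / st$expected_step, 2)
  expect_equal(st2$timestep / st$timestep, 4)
  # unit normalisation
  stu <- expected_step_and_timestep(30, 30, (pi / 2) / 4)
  expect_equal(stu$expected_step, sqrt(pi / 2))
  expect_equal(stu$timestep, 1)
  expect_error(expected_step_and_timestep(3e-7, 30, 0), "positive")
})

test_that("surface density converts to molecules per square micrometre", {
  expect_equal(surface_density(9600, 1.8e-11), 533, tolerance = 0.01)
  expect_equal(surface_density(7800, sphere_geometry(4.7e-18)$area), 575,
               tolerance = 0.01)
  expect_equal(surface_density(0, 1.8e-11), 0)
  expect_error(surface_density(10, 0), "positive")
})

test_that("full scaling chain reproduces the derived parameter table", {
  sp <- scale_parameters(real_world_params())
  two_sf <- function(x) signif(x, 2)
  expect_equal(two_sf(sp$platelet_area), 1.8e-11)
  expect_equal(two_sf(sp$boxes_per_platelet_rounded), 200)  # 205 at 2 s.f.
  expect_equal(sp$boxes_per_platelet_rounded, 205)
  expect_equal(two_sf(sp$box_length), 3.0e-7)
  expect_identical(sp$receptors_per_box, 47)
  expect_equal(two_sf(sp$scaled_receptor_diameter), 0.038)
  expect_equal(two_sf(sp$expected_step), 1.3e-8)  # 12.5 nm -> 1.3e-8 at 2 s.f.
  expect_equal(sp$expected_step, 12.5e-9, tolerance = 0.01)
  expect_equal(two_sf(sp$timestep), 4.3e-4)
  # mouse preset
  spm <- scale_parameters(real_world_params(preset = "mouse"))
  expect_equal(spm$surface_density, 575, tolerance = 0.01)
})

test_that("scaling chain invariants hold", {
  sp <- scale_parameters(real_world_params())
  # round trip: boxes * box_area = platelet area (unrounded chain)
  expect_equal(sp$boxes_per_platelet * sp$box_area, sp$platelet_area,
               tolerance = 1e-6)
  # receptors per box non-increasing in box count
  counts <- vapply(c(100, 150, 205, 300, 500),
                   function(b) receptors_per_box(9600, b), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # rounding policy: rounded vs unrounded intermediates change results < 3%
  unr <- box_dimensions(sp$platelet_area, sp$boxes_per_platelet)
  rnd <- box_dimensions(1.8e-11, 205)
  expect_lt(abs(rnd$box_length - unr$box_length) / unr$box_length, 0.03)
  expect_lt(abs(receptors_per_box(9600, 205) -
                receptors_per_box(9600, sp$boxes_per_platelet)), 1)
})

test_that("real-world parameter validation rejects bad inputs", {
  expect_error(real_world_params(platelet_volume = -1), "positive")
  expect_error(real_world_params(raft_fraction = 0), "\\(0, 1\\]")
  expect_error(real_world_params(raft_fraction = 1.2), "\\(0, 1\\]")
  df <- as.data.frame(scale_parameters(real_world_params()))
  expect_true(all(c("parameter", "value", "unit") %in% names(df)))
  expect_equal(nrow(df), 19)
})
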