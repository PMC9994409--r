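#' Real-world platelet and receptor constants
#'
#' Bundles the physical constants from which every simulation-scale
#' parameter is derived: platelet volume, GPVI copy number, the
#' single-particle-tracking diffusivity of GPVI, the projected crystal
#' dimension of the receptor, and the lipid-raft geometry (diameter and
#' fraction of the membrane occupied).
#'
#' @param platelet_volume Platelet volume in m^3.
#' @param gpvi_copies GPVI copies per platelet.
#' @param gpvi_diffusivity Lateral diffusivity of GPVI in m^2/s.
#' @param gpvi_crystal_length Longest crystal dimension of GPVI in m
#'   (the projected disc diameter on the membrane).
#' @param raft_diameter Lipid-raft diameter in m.
#' @param raft_fraction Fraction of the membrane area occupied by rafts,
#'   in (0, 1].
#' @param scaled_box_units Side length of the simulation box in
#'   simulation units (the box maps to one raft-containing membrane tile).
#' @param preset Optional species preset: `"human"` (7.4 fl platelet,
#'   9600 copies) or `"mouse"` (4.7 fl, 7800 copies). Explicit arguments
#'   override preset values.
#' @return An object of class `real_world_params`.
#' @examples
#' real_world_params()               # human defaults
#' real_world_params(preset = "mouse")
#' @export
real_world_params <- function(platelet_volume = NULL,
                              gpvi_copies = NULL,
                              gpvi_diffusivity = 0.091e-12,
                              gpvi_crystal_length = 114e-10,
                              raft_diameter = 200e-9,
                              raft_fraction = 0.35,
                              scaled_box_units = 30,
                              preset = c("human", "mouse")) {
  preset <- match.arg(preset)
  base <- switch(preset,
    human = list(platelet_volume = 7.4e-18, gpvi_copies = 9600),
    mouse = list(platelet_volume = 4.7e-18, gpvi_copies = 7800))
  if (is.null(platelet_volume)) platelet_volume <- base$platelet_volume
  if (is.null(gpvi_copies)) gpvi_copies <- base$gpvi_copies

  p <- list(platelet_volume = platelet_volume,
            gpvi_copies = gpvi_copies,
            gpvi_diffusivity = gpvi_diffusivity,
            gpvi_crystal_length = gpvi_crystal_length,
            raft_diameter = raft_diameter,
            raft_fraction = raft_fraction,
            scaled_box_units = scaled_box_units,
            preset = preset)
  for (f in c("platelet_volume", "gpvi_diffusivity", "gpvi_crystal_length",
              "raft_diameter", "scaled_box_units")) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) ||
        p[[f]] <= 0)
      stop(sprintf("'%s' must be a single positive number", f), call. = FALSE)
  }
  if (!is.numeric(gpvi_copies) || gpvi_copies < 0)
    stop("'gpvi_copies' must be a non-negative count", call. = FALSE)
  if (!is.numeric(raft_fraction) || raft_fraction <= 0 || raft_fraction > 1)
    stop("'raft_fraction' must lie in (0, 1]", call. = FALSE)
  class(p) <- "real_world_params"
  p
}

#' Sphere radius and surface area from volume
#'
#' Platelets are treated as perfect spheres, so a volume determines the
#' membrane surface area available to receptors.
#'
#' @param volume Sphere volume (m^3).
#' @return List with `radius` (m) and `area` (m^2).
#' @examples
#' sphere_geometry(7.4e-18)  # human platelet: R ~ 1.2e-6 m, A ~ 1.8e-11 m^2
#' @export
sphere_geometry <- function(volume) {
  if (!is.numeric(volume) || length(volume) != 1 || !is.finite(volume) ||
      volume <= 0)
    stop("'volume' must be a single positive number", call. = FALSE)
  radius <- (3 * volume / (4 * pi))^(1 / 3)
  list(radius = radius, area = 4 * pi * radius^2)
}

#' Total raft area and raft (simulation box) count per platelet
#'
#' The membrane is tiled into boxes containing one confined domain each,
#' so the number of boxes per platelet equals total raft area divided by
#' the area of a single circular raft.
#'
#' @param area Platelet surface area (m^2).
#' @param raft_fraction Fraction of the membrane occupied by rafts.
#' @param raft_diameter Raft diameter (m).
#' @return List with `raft_total_area` (m^2), `boxes_per_platelet`
#'   (unrounded) and `boxes_per_platelet_rounded`.
#' @export
raft_layout <- function(area, raft_fraction, raft_diameter) {
  if (raft_fraction <= 0 || raft_fraction > 1)
    stop("'raft_fraction' must lie in (0, 1]", call. = FALSE)
  if (raft_diameter <= 0)
    stop("'raft_diameter' must be positive", call. = FALSE)
  raft_total_area <- raft_fraction * area
  boxes <- raft_total_area / (pi * (raft_diameter / 2)^2)
  list(raft_total_area = raft_total_area,
       boxes_per_platelet = boxes,
       boxes_per_platelet_rounded = round_half_up(boxes))
}

#' Simulation box area and side length
#'
#' @param area Platelet surface area (m^2).
#' @param boxes_per_platelet Number of raft-containing tiles.
#' @return List with `box_area` (m^2) and `box_length` (m).
#' @export
box_dimensions <- function(area, boxes_per_platelet) {
  if (boxes_per_platelet < 1)
    stop("'boxes_per_platelet' must be at least 1", call. = FALSE)
  box_area <- area / boxes_per_platelet
  list(box_area = box_area, box_length = sqrt(box_area))
}

#' Receptor copies per simulation box
#'
#' Rounds half away from zero to the nearest integer (the convention that
#' yields the canonical 47 receptors per box from 9600 copies and 205
#' boxes).
#'
#' @param copies Receptor copies per platelet.
#' @param boxes Boxes per platelet.
#' @return Integer count.
#' @export
receptors_per_box <- function(copies, boxes) {
  if (copies < 0) stop("'copies' must be non-negative", call. = FALSE)
  if (boxes < 1) stop("'boxes' must be at least 1", call. = FALSE)
  round_half_up(copies / boxes)
}

# round half away from zero (round() rounds half to even)
round_half_up <- function(x) trunc(x + sign(x) * 0.5)

#' Receptor diameter as a fraction of the box length
#'
#' @param crystal_length Longest crystal dimension (m).
#' @param box_length Simulation box side (m).
#' @return Dimensionless fraction in (0, 1).
#' @export
scaled_diameter <- function(crystal_length, box_length) {
  if (crystal_length <= 0 || box_length <= 0)
    stop("lengths must be positive", call. = FALSE)
  if (crystal_length >= box_length)
    stop("'crystal_length' must be smaller than 'box_length'", call. = FALSE)
  crystal_length / box_length
}

#' Expected per-tick step and the physical duration of a tick
#'
#' One simulation length unit is `box_length / scaled_box_units`. With
#' unit diffusivity the per-tick step length is half-normal with unit
#' scale, whose radial expectation is (pi/2)^(1/2); the expected physical
#' step is therefore (pi/2)^(1/2) * (box_length / scaled_box_units). The
#' tick duration follows from the two-dimensional mean-square-displacement
#' relation MSD = 4 D t applied to that expected step.
#'
#' @param box_length Simulation box side (m).
#' @param scaled_box_units Box side in simulation units.
#' @param diffusivity Receptor diffusivity (m^2/s).
#' @return List with `expected_step` (m) and `timestep` (s).
#' @export
expected_step_and_timestep <- function(box_length, scaled_box_units,
                                       diffusivity) {
  if (box_length <= 0 || scaled_box_units <= 0)
    stop("lengths must be positive", call. = FALSE)
  if (diffusivity <= 0)
    stop("'diffusivity' must be positive", call. = FALSE)
  expected_step <- sqrt(pi / 2) * (box_length / scaled_box_units)
  list(expected_step = expected_step,
       timestep = expected_step^2 / (4 * diffusivity))
}

#' Receptor surface density
#'
#' @param copies Receptor copies per platelet.
#' @param area Platelet surface area (m^2).
#' @return Molecules per square micrometre.
#' @export
surface_density <- function(copies, area) {
  if (area <= 0) stop("'area' must be positive", call. = FALSE)
  (copies / area) * 1e-12  # m^-2 -> um^-2
}

#' Derive all simulation-scale parameters from real-world constants
#'
#' Runs the full scaling chain: sphere geometry, raft layout, box
#' dimensions, receptors per box, scaled receptor diameter, expected
#' per-tick step, tick duration and surface density. All intermediates
#' are carried unrounded; rounding happens only for display and for the
#' integer receptor count.
#'
#' @param params A [real_world_params()] object.
#' @return An object of class `scaled_params` (also a list).
#' @examples
#' scale_parameters(real_world_params())
#' @export
scale_parameters <- function(params = real_world_params()) {
  stopifnot(inherits(params, "real_world_params"))
  geo <- sphere_geometry(params$platelet_volume)
  rl <- raft_layout(geo$area, params$raft_fraction, params$raft_diameter)
  bx <- box_dimensions(geo$area, rl$boxes_per_platelet)
  st <- expected_step_and_timestep(bx$box_length, params$scaled_box_units,
                                   params$gpvi_diffusivity)
  out <- list(
    real_world = params,
    platelet_radius = geo$radius,
    platelet_area = geo$area,
    raft_total_area = rl$raft_total_area,
    boxes_per_platelet = rl$boxes_per_platelet,
    boxes_per_platelet_rounded = rl$boxes_per_platelet_rounded,
    box_area = bx$box_area,
    box_length = bx$box_length,
    receptors_per_box = receptors_per_box(params$gpvi_copies,
                                          rl$boxes_per_platelet),
    scaled_receptor_diameter = scaled_diameter(params$gpvi_crystal_length,
                                               bx$box_length),
    expected_step = st$expected_step,
    timestep = st$timestep,
    surface_density = surface_density(params$gpvi_copies, geo$area))
  stopifnot(out$scaled_receptor_diameter > 0,
            out$scaled_receptor_diameter < 1)
  class(out) <- "scaled_params"
  out
}

#' @export
print.scaled_params <- function(x, ...) {
  rw <- x$real_world
  fmt <- function(v, unit) sprintf("%-38s %-12.4g %s", "", v, unit)
  cat("Real-world to simulation-unit scaling\n")
  cat(sprintf("  %-36s %s\n", "preset", rw$preset))
  rows <- as.data.frame(x)
  for (k in seq_len(nrow(rows)))
    cat(sprintf("  %-36s %-12.4g %s\n", rows$parameter[k], rows$value[k],
                rows$unit[k]))
  invisible(x)
}

#' Tabulate a scaled parameter set
#'
#' @param x A `scaled_params` object.
#' @param row.names,optional,... Ignored (data.frame method signature).
#' @return A data.frame with columns `parameter`, `value`, `unit`.
#' @export
as.data.frame.scaled_params <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  rw <- x$real_world
  data.frame(
    parameter = c("platelet_volume", "gpvi_copies", "gpvi_diffusivity",
                  "gpvi_crystal_length", "raft_diameter", "raft_fraction",
                  "scaled_box_units", "platelet_radius", "platelet_area",
                  "raft_total_area", "boxes_per_platelet",
                  "boxes_per_platelet_rounded", "box_area", "box_length",
                  "receptors_per_box", "scaled_receptor_diameter",
                  "expected_step", "timestep", "surface_density"),
    value = c(rw$platelet_volume, rw$gpvi_copies, rw$gpvi_diffusivity,
              rw$gpvi_crystal_length, rw$raft_diameter, rw$raft_fraction,
              rw$scaled_box_units, x$platelet_radius, x$platelet_area,
              x$raft_total_area, x$boxes_per_platelet,
              x$boxes_per_platelet_rounded, x$box_area, x$box_length,
              x$receptors_per_box, x$scaled_receptor_diameter,
              x$expected_step, x$timestep, x$surface_density),
    unit = c("m^3", "copies", "m^2/s", "m", "m", "", "sim units", "m", "m^2",
             "m^2", "", "", "m^2", "m", "copies", "fraction of box", "m", "s",
             "molecules/um^2"),
    stringsAsFactors = FALSE)
}
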