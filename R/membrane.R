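#' Periodic simulation box
#'
#' The membrane patch is a square box with periodic boundary conditions
#' (a flat torus), so agents leaving one side re-enter on the opposite
#' side and distances use the minimal image.
#'
#' @param length Side length in simulation units.
#' @return Object of class `box_spec`.
#' @export
box_spec <- function(length = 30) {
  if (!is.numeric(length) || length(length) != 1 || !is.finite(length) ||
      length <= 0)
    stop("'length' must be a single positive number", call. = FALSE)
  structure(list(length = length, periodic = TRUE), class = "box_spec")
}

#' Wrap coordinates into the periodic box
#'
#' @param p Numeric vector `c(x, y)` or a two-column matrix of positions.
#' @param box A [box_spec()].
#' @return Coordinates mapped into `[0, length)` componentwise.
#' @export
wrap_position <- function(p, box) {
  L <- box$length
  if (any(!is.finite(p)))
    stop("non-finite coordinates cannot be wrapped", call. = FALSE)
  w <- p - L * floor(p / L)
  w[w >= L] <- 0  # guard against floating round-up at the seam
  w
}

#' Minimal-image displacement between two points on the torus
#'
#' Returns the shortest displacement `q - p` over all periodic images;
#' each component lies in `[-L/2, L/2]`.
#'
#' @param p,q Numeric `c(x, y)` positions (wrapped).
#' @param box A [box_spec()].
#' @return Numeric `c(dx, dy)`.
#' @export
minimal_image <- function(p, q, box) {
  L <- box$length
  d <- q - p
  d - L * round(d / L)
}

#' Minimal-image distance
#' @inheritParams minimal_image
#' @return Euclidean torus distance between `p` and `q`.
#' @export
torus_distance <- function(p, q, box) {
  sqrt(sum(minimal_image(p, q, box)^2))
}

#' Confined-domain set
#'
#' Circular regions of reduced diffusivity, the model's proxy for lipid
#' rafts. Circles are static for the whole run and pairwise
#' non-overlapping under the minimal image.
#'
#' @param circles data.frame with columns `cx`, `cy`, `r` (box units); may
#'   have zero rows for a domain-free membrane.
#' @param box A [box_spec()].
#' @return Object of class `domain_set` with an `occupied_fraction` field.
#' @export
domain_set <- function(circles, box = box_spec()) {
  if (is.null(circles)) circles <- data.frame(cx = numeric(), cy = numeric(),
                                              r = numeric())
  stopifnot(all(c("cx", "cy", "r") %in% names(circles)))
  if (nrow(circles) > 0) {
    if (any(circles$r <= 0)) stop("domain radii must be positive", call. = FALSE)
    if (nrow(circles) > 1) {
      for (i in seq_len(nrow(circles) - 1)) {
        for (j in seq(i + 1, nrow(circles))) {
          d <- torus_distance(c(circles$cx[i], circles$cy[i]),
                              c(circles$cx[j], circles$cy[j]), box)
          if (d < circles$r[i] + circles$r[j])
            stop("domain circles overlap", call. = FALSE)
        }
      }
    }
  }
  structure(list(circles = circles,
                 occupied_fraction = sum(pi * circles$r^2) / box$length^2),
            class = "domain_set")
}

#' Is a point inside any confined domain?
#'
#' Membership is decided by the agent centre against the closed disc,
#' under the minimal image.
#'
#' @param p Numeric `c(x, y)`.
#' @param domains A [domain_set()].
#' @param box A [box_spec()].
#' @return Logical.
#' @export
in_domain <- function(p, domains, box = box_spec()) {
  cir <- domains$circles
  if (nrow(cir) == 0) return(FALSE)
  for (k in seq_len(nrow(cir))) {
    if (torus_distance(p, c(cir$cx[k], cir$cy[k]), box) <= cir$r[k])
      return(TRUE)
  }
  FALSE
}

#' Motion parameters
#'
#' @param d_out Diffusivity outside confined domains (box units^2/tick).
#' @param d_in Diffusivity inside confined domains.
#' @param inert_speed_factor Multiplier on the step scale of inert
#'   crowder proteins (default 0.5: crowders move at half receptor speed).
#' @param step_length_law `"half_normal"` (step length = sqrt(D) |N(0,1)|,
#'   the default) or `"rayleigh"` (Rayleigh with scale sqrt(D), whose mean
#'   sqrt(pi/2) matches the expected-step arithmetic of the scaling
#'   calculator).
#' @return Object of class `motion_params`.
#' @export
motion_params <- function(d_out = 1, d_in = 1, inert_speed_factor = 0.5,
                          step_length_law = c("half_normal", "rayleigh")) {
  step_length_law <- match.arg(step_length_law)
  if (d_out < 0 || d_in < 0)
    stop("diffusivities must be non-negative", call. = FALSE)
  if (inert_speed_factor <= 0)
    stop("'inert_speed_factor' must be positive", call. = FALSE)
  structure(list(d_out = d_out, d_in = d_in,
                 inert_speed_factor = inert_speed_factor,
                 step_length_law = step_length_law),
            class = "motion_params")
}

#' Local diffusivity at a position
#'
#' `d_in` if the agent centre lies inside any confined domain (closed
#' disc), else `d_out`. The inert speed factor is applied to the step
#' scale at proposal time, not here.
#'
#' @param p Numeric `c(x, y)` (wrapped).
#' @param domains A [domain_set()].
#' @param motion A [motion_params()].
#' @param box A [box_spec()].
#' @return Diffusivity in box units^2 per tick.
#' @export
local_diffusivity <- function(p, domains, motion, box = box_spec()) {
  if (in_domain(p, domains, box)) motion$d_in else motion$d_out
}

#' Propose a Brownian step
#'
#' Direction is uniform on `[0, 2*pi)`; length is `sqrt(D) |N(0,1)|`
#' (half-normal law) or Rayleigh with scale `sqrt(D)`. Dimers step with
#' scale divided by 2^(1/4) relative to a monomer at the same
#' diffusivity, the Stokes-Einstein consequence of doubling the disc
#' area. Consumes R's RNG.
#'
#' @param p Numeric `c(x, y)` current position.
#' @param diffusivity Local diffusivity (box units^2/tick).
#' @param box A [box_spec()].
#' @param species `"monomer"`, `"dimer"` or `"inert"`.
#' @param motion A [motion_params()] (for the step law and inert factor).
#' @return Wrapped candidate position `c(x, y)`.
#' @export
propose_step <- function(p, diffusivity, box = box_spec(),
                         species = "monomer", motion = motion_params()) {
  scale <- sqrt(diffusivity)
  if (species == "inert") scale <- scale * motion$inert_speed_factor
  if (species == "dimer") scale <- scale / 2^0.25
  if (scale == 0) return(p)
  r <- if (motion$step_length_law == "half_normal") {
    scale * abs(stats::rnorm(1))
  } else {
    scale * sqrt(-2 * log(stats::runif(1)))
  }
  theta <- 2 * pi * stats::runif(1)
  wrap_position(p + r * c(cos(theta), sin(theta)), box)
}

#' All-pairs overlap test (reference implementation)
#'
#' TRUE iff the candidate disc overlaps any agent: minimal-image centre
#' distance strictly less than the sum of radii. Tangency is not an
#' overlap, so dissociation can place tangent monomers. This is the
#' reference all-pairs rule; the compiled engine uses a spatial grid that
#' must agree with it.
#'
#' @param candidate Numeric `c(x, y)` (wrapped).
#' @param radius Candidate disc radius.
#' @param agents data.frame with columns `x`, `y`, `radius` (others
#'   ignored); may have zero rows.
#' @param box A [box_spec()].
#' @return Logical.
#' @export
overlaps <- function(candidate, radius, agents, box = box_spec()) {
  if (is.null(agents) || nrow(agents) == 0) return(FALSE)
  L <- box$length
  dx <- agents$x - candidate[1]; dx <- dx - L * round(dx / L)
  dy <- agents$y - candidate[2]; dy <- dy - L * round(dy / L)
  any(dx^2 + dy^2 < (radius + agents$radius)^2)
}

#' Place non-overlapping discs uniformly at random
#'
#' Rejection sampling: candidate centres are uniform over the box and
#' rejected if the disc would overlap an already placed or pre-existing
#' agent. Consumes R's RNG.
#'
#' @param n Number of discs to place.
#' @param radius Disc radius (single value or vector of length `n`).
#' @param box A [box_spec()].
#' @param species Species label for the new agents.
#' @param existing data.frame of already placed agents (or NULL).
#' @param domains Unused; placement is uniform regardless of domains
#'   (kept for interface symmetry).
#' @param max_attempts Attempts per disc before giving up.
#' @return data.frame with columns `id`, `species`, `radius`, `x`, `y`,
#'   the new agents appended after `existing`.
#' @export
place_uniform <- function(n, radius, box = box_spec(), species = "monomer",
                          existing = NULL, domains = NULL,
                          max_attempts = 1e5) {
  stopifnot(n >= 0)
  radius <- rep_len(radius, max(n, 1))
  agents <- if (is.null(existing)) {
    data.frame(id = integer(), species = character(), radius = numeric(),
               x = numeric(), y = numeric(), stringsAsFactors = FALSE)
  } else existing
  if (n == 0) return(agents)
  next_id <- if (nrow(agents) > 0) max(agents$id) + 1L else 1L
  L <- box$length
  for (k in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      cand <- stats::runif(2, 0, L)
      if (!overlaps(cand, radius[k], agents, box)) {
        agents <- rbind(agents, data.frame(
          id = next_id, species = species, radius = radius[k],
          x = cand[1], y = cand[2], stringsAsFactors = FALSE))
        next_id <- next_id + 1L
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf(
        "packing infeasible: placed %d of %d discs of radius %.3g",
        k - 1L, n, radius[k]), call. = FALSE)
  }
  rownames(agents) <- NULL
  agents
}
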