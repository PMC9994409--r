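#' Reaction parameters for monomer-dimer interconversion
#'
#' Dimerisation and dissociation are per-tick Bernoulli events: a monomer
#' with at least one capture candidate dimerises with probability `k_b`
#' per tick; a dimer dissociates with probability `k_d` per tick. Two
#' monomers are capture candidates when their edge-to-edge gap is at most
#' `capture_threshold_fraction` of the monomer diameter.
#'
#' @param k_b Binding probability per molecule per tick, in `[0, 1]`.
#' @param k_d Dissociation probability per tick, in `[0, 1]`.
#' @param capture_threshold_fraction Capture gap as a fraction of the
#'   monomer diameter (default 0.1).
#' @return Object of class `reaction_params`.
#' @export
reaction_params <- function(k_b = 0.05, k_d = 0.01,
                            capture_threshold_fraction = 0.1) {
  if (!is.numeric(k_b) || k_b < 0 || k_b > 1)
    stop("'k_b' must be a probability in [0, 1]", call. = FALSE)
  if (!is.numeric(k_d) || k_d < 0 || k_d > 1)
    stop("'k_d' must be a probability in [0, 1]", call. = FALSE)
  if (capture_threshold_fraction <= 0)
    stop("'capture_threshold_fraction' must be positive", call. = FALSE)
  structure(list(k_b = k_b, k_d = k_d,
                 capture_threshold_fraction = capture_threshold_fraction),
            class = "reaction_params")
}

#' Capture candidates for a focal monomer
#'
#' All other monomers whose edge-to-edge gap (minimal-image centre
#' distance minus two monomer radii) is at most the capture threshold,
#' ordered by ascending gap with ties broken uniformly at random.
#'
#' @param focal_id `id` of the focal monomer in `agents`.
#' @param agents Agent data.frame (`id`, `species`, `radius`, `x`, `y`).
#' @param params A [reaction_params()].
#' @param box A [box_spec()].
#' @return Integer vector of candidate `id`s, nearest first.
#' @export
capture_candidates <- function(focal_id, agents, params = reaction_params(),
                               box = box_spec()) {
  f <- agents[agents$id == focal_id, ]
  if (nrow(f) != 1 || f$species != "monomer")
    stop("focal agent must be a single monomer", call. = FALSE)
  others <- agents[agents$id != focal_id & agents$species == "monomer", ]
  if (nrow(others) == 0) return(integer())
  L <- box$length
  dx <- others$x - f$x; dx <- dx - L * round(dx / L)
  dy <- others$y - f$y; dy <- dy - L * round(dy / L)
  gap <- sqrt(dx^2 + dy^2) - 2 * f$radius
  keep <- gap <= params$capture_threshold_fraction * 2 * f$radius
  ids <- others$id[keep]
  gap <- gap[keep]
  if (length(ids) == 0) return(integer())
  # random tie-break before the stable sort
  o <- sample.int(length(ids))
  ids <- ids[o]; gap <- gap[o]
  ids[order(gap)]
}

#' Attempt to dimerise a focal monomer
#'
#' Draws `u ~ U[0, 1]`; when `u < k_b` and a capture candidate exists,
#' the focal monomer and its nearest candidate are replaced by one dimer
#' of radius `sqrt(2)` times the monomer radius (total disc area is
#' conserved), centred at the minimal-image midpoint. If that dimer would
#' overlap any other agent the event is abandoned and both monomers
#' persist. Consumes R's RNG.
#'
#' @param focal_id `id` of the focal monomer.
#' @param agents Agent data.frame.
#' @param params A [reaction_params()].
#' @param box A [box_spec()].
#' @return List with `agents` (updated data.frame) and `event` (one of
#'   `"dimerise"`, `"abandoned"`, `"none"`).
#' @export
attempt_dimerise <- function(focal_id, agents, params = reaction_params(),
                             box = box_spec()) {
  cand <- capture_candidates(focal_id, agents, params, box)
  u <- stats::runif(1)
  if (u >= params$k_b || length(cand) == 0)
    return(list(agents = agents, event = "none"))
  f <- agents[agents$id == focal_id, ]
  g <- agents[agents$id == cand[1], ]
  mid <- wrap_position(
    c(f$x, f$y) + 0.5 * minimal_image(c(f$x, f$y), c(g$x, g$y), box), box)
  rd <- sqrt(2) * f$radius
  rest <- agents[!(agents$id %in% c(focal_id, cand[1])), ]
  if (overlaps(mid, rd, rest, box))
    return(list(agents = agents, event = "abandoned"))
  dimer <- data.frame(id = max(agents$id) + 1L, species = "dimer",
                      radius = rd, x = mid[1], y = mid[2],
                      stringsAsFactors = FALSE)
  out <- rbind(rest, dimer)
  rownames(out) <- NULL
  list(agents = out, event = "dimerise")
}

#' Attempt to dissociate a dimer
#'
#' Draws `u ~ U[0, 1]`; when `u < k_d` the dimer is replaced by two
#' tangent monomers centred at the dimer centre plus/minus the monomer
#' radius along a uniformly random axis. If either monomer would overlap
#' another agent a fresh axis is drawn, up to `max_retries` times; on
#' total failure the dimer persists (the event is deferred). Consumes
#' R's RNG.
#'
#' @param dimer_id `id` of the dimer.
#' @param agents Agent data.frame.
#' @param params A [reaction_params()].
#' @param box A [box_spec()].
#' @param max_retries Axis draws before deferring the event.
#' @return List with `agents` and `event` (one of `"dissociate"`,
#'   `"deferred"`, `"none"`).
#' @export
attempt_dissociate <- function(dimer_id, agents, params = reaction_params(),
                               box = box_spec(), max_retries = 20) {
  d <- agents[agents$id == dimer_id, ]
  if (nrow(d) != 1 || d$species != "dimer")
    stop("agent must be a single dimer", call. = FALSE)
  u <- stats::runif(1)
  if (u >= params$k_d) return(list(agents = agents, event = "none"))
  rm_ <- d$radius / sqrt(2)
  rest <- agents[agents$id != dimer_id, ]
  for (t in seq_len(max_retries)) {
    phi <- 2 * pi * stats::runif(1)
    ax <- rm_ * c(cos(phi), sin(phi))
    p1 <- wrap_position(c(d$x, d$y) + ax, box)
    p2 <- wrap_position(c(d$x, d$y) - ax, box)
    # the two children are tangent by construction; test others only
    if (!overlaps(p1, rm_, rest, box) && !overlaps(p2, rm_, rest, box)) {
      nid <- max(agents$id)
      kids <- data.frame(id = nid + 1:2, species = "monomer", radius = rm_,
                         x = c(p1[1], p2[1]), y = c(p1[2], p2[2]),
                         stringsAsFactors = FALSE)
      out <- rbind(rest, kids)
      rownames(out) <- NULL
      return(list(agents = out, event = "dissociate"))
    }
  }
  list(agents = agents, event = "deferred")
}
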