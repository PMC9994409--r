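#' Complete, seedable specification of one simulation run
#'
#' Defaults reproduce the standard setup: 47 receptor monomers (diameter
#' 3.8% of a 30-unit periodic box) starting uniformly distributed with no
#' dimers, one central confined domain occupying 35% of the box, binding
#' probability `k_b = 0.05` per molecule per tick, dissociation
#' probability `k_d = 0.01` per tick, 200,000 ticks with observables
#' averaged over the last 50,000, and 3 replicates.
#'
#' @param box_length Box side in simulation units.
#' @param domain_fraction Fraction of the box area occupied by confined
#'   domains, in `[0, 1)`; 0 means no domains.
#' @param n_domains Number of equal-area domain circles (a single circle
#'   sits at the box centre; several are placed uniformly without
#'   overlap).
#' @param d_out,d_in Diffusivity outside/inside domains (units^2/tick).
#' @param inert_speed_factor Step-scale multiplier for inert crowders.
#' @param step_length_law `"half_normal"` or `"rayleigh"`.
#' @param k_b,k_d Dimerisation / dissociation probabilities per tick.
#' @param capture_threshold_fraction Capture gap as a fraction of the
#'   monomer diameter.
#' @param n_receptor_monomers Receptor monomers at start (no dimers).
#' @param n_inert Inert crowder discs.
#' @param receptor_radius Monomer radius (default 3.8% of the box length,
#'   halved).
#' @param inert_radius Crowder radius (default: diameter 5% of the box).
#' @param n_steps Ticks to run.
#' @param window Averaging window (final `window` ticks).
#' @param thin Record observables every `thin` ticks.
#' @param replicates Replicate runs for [run_replicates()].
#' @param seed Master seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(box_length = 30,
                       domain_fraction = 0.35,
                       n_domains = 1,
                       d_out = 1, d_in = 1,
                       inert_speed_factor = 0.5,
                       step_length_law = c("half_normal", "rayleigh"),
                       k_b = 0.05, k_d = 0.01,
                       capture_threshold_fraction = 0.1,
                       n_receptor_monomers = 47,
                       n_inert = 0,
                       receptor_radius = 0.038 * box_length / 2,
                       inert_radius = 0.05 * box_length / 2,
                       n_steps = 200000,
                       window = 50000,
                       thin = 10,
                       replicates = 3,
                       seed = 1) {
  step_length_law <- match.arg(step_length_law)
  cfg <- list(box_length = box_length, domain_fraction = domain_fraction,
              n_domains = n_domains, d_out = d_out, d_in = d_in,
              inert_speed_factor = inert_speed_factor,
              step_length_law = step_length_law,
              k_b = k_b, k_d = k_d,
              capture_threshold_fraction = capture_threshold_fraction,
              n_receptor_monomers = n_receptor_monomers, n_inert = n_inert,
              receptor_radius = receptor_radius, inert_radius = inert_radius,
              n_steps = n_steps, window = window, thin = thin,
              replicates = replicates, seed = seed)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
  chk(is.numeric(cfg$box_length) && cfg$box_length > 0,
      "'box_length' must be positive")
  chk(cfg$domain_fraction >= 0 && cfg$domain_fraction < 1,
      "'domain_fraction' must lie in [0, 1)")
  chk(cfg$n_domains >= 0 && cfg$n_domains == round(cfg$n_domains),
      "'n_domains' must be a non-negative integer")
  chk(cfg$d_out >= 0, "'d_out' must be non-negative")
  chk(cfg$d_in >= 0, "'d_in' must be non-negative")
  chk(cfg$inert_speed_factor > 0, "'inert_speed_factor' must be positive")
  chk(cfg$step_length_law %in% c("half_normal", "rayleigh"),
      "'step_length_law' must be 'half_normal' or 'rayleigh'")
  chk(cfg$k_b >= 0 && cfg$k_b <= 1, "'k_b' must be a probability in [0, 1]")
  chk(cfg$k_d >= 0 && cfg$k_d <= 1, "'k_d' must be a probability in [0, 1]")
  chk(cfg$capture_threshold_fraction > 0,
      "'capture_threshold_fraction' must be positive")
  chk(cfg$n_receptor_monomers >= 0, "'n_receptor_monomers' must be >= 0")
  chk(cfg$n_inert >= 0, "'n_inert' must be >= 0")
  chk(cfg$receptor_radius > 0, "'receptor_radius' must be positive")
  chk(cfg$inert_radius > 0, "'inert_radius' must be positive")
  chk(cfg$n_steps >= 0, "'n_steps' must be >= 0")
  chk(cfg$window >= 1 && cfg$window <= max(cfg$n_steps, 1),
      "'window' must be at least 1 and no larger than 'n_steps'")
  chk(cfg$thin >= 1, "'thin' must be >= 1")
  chk(cfg$replicates >= 1, "'replicates' must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  box %g x %g (periodic), %d domain(s) covering %.1f%%\n",
              x$box_length, x$box_length, x$n_domains,
              100 * x$domain_fraction))
  cat(sprintf("  receptors: %d monomers, radius %.3g; inert: %d, radius %.3g\n",
              x$n_receptor_monomers, x$receptor_radius, x$n_inert,
              x$inert_radius))
  cat(sprintf("  D_out %g, D_in %g (%s steps); k_b %g, k_d %g\n",
              x$d_out, x$d_in, x$step_length_law, x$k_b, x$k_d))
  cat(sprintf("  %d steps, window %d, thin %d, %d replicate(s), seed %d\n",
              x$n_steps, x$window, x$thin, x$replicates, x$seed))
  invisible(x)
}

#' Build the initial state for a run
#'
#' Lays out the confined domains, then places inert discs and receptor
#' monomers by uniform rejection sampling (zero dimers initially).
#' Consumes R's RNG; call `set.seed()` first for a reproducible state.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_state`: list with `agents`, `domains`,
#'   `box`.
#' @export
init_state <- function(config) {
  box <- box_spec(config$box_length)
  domains <- if (config$domain_fraction > 0 && config$n_domains > 0) {
    split_domains(config$domain_fraction, config$n_domains, box)
  } else {
    domain_set(NULL, box)
  }
  agents <- place_uniform(config$n_inert, config$inert_radius, box,
                          species = "inert")
  agents <- place_uniform(config$n_receptor_monomers, config$receptor_radius,
                          box, species = "monomer", existing = agents)
  structure(list(agents = agents, domains = domains, box = box),
            class = "sim_state")
}

species_code <- function(species)
  match(species, c("monomer", "dimer", "inert")) - 1L

species_label <- function(code) c("monomer", "dimer", "inert")[code + 1L]

# low-level bridge into the compiled tick loop
run_engine <- function(state, config, n_steps, snapshot_every = 0,
                       record_events = FALSE) {
  ag <- state$agents
  cir <- state$domains$circles
  cpp_run(as.matrix(ag[, c("x", "y", "radius")]),
          species_code(ag$species),
          if (nrow(cir) > 0) as.matrix(cir[, c("cx", "cy", "r")])
          else matrix(numeric(), 0, 3),
          config$box_length, config$d_out, config$d_in,
          config$inert_speed_factor,
          if (config$step_length_law == "half_normal") 0L else 1L,
          config$k_b, config$k_d, config$capture_threshold_fraction,
          config$receptor_radius,
          as.integer(n_steps), as.integer(config$thin),
          as.integer(snapshot_every), record_events)
}

engine_agents_df <- function(m) {
  data.frame(id = as.integer(m[, "id"]),
             species = species_label(as.integer(m[, "species"])),
             radius = m[, "radius"], x = m[, "x"], y = m[, "y"],
             ux = m[, "ux"], uy = m[, "uy"],
             stringsAsFactors = FALSE)
}

#' Advance a state by a fixed number of ticks
#'
#' One tick visits every agent once in a fresh uniform random order; each
#' agent proposes a Brownian step (rejected on overlap), then a monomer
#' may dimerise with its nearest capture candidate and a dimer may
#' dissociate. Agents created mid-tick act from the next tick. Consumes
#' R's RNG.
#'
#' @param state A `sim_state`.
#' @param config A [sim_config()].
#' @param n_steps Ticks to advance (default 1).
#' @return Updated `sim_state`.
#' @export
sim_tick <- function(state, config, n_steps = 1) {
  res <- run_engine(state, config, n_steps)
  state$agents <- engine_agents_df(res$agents)[, c("id", "species", "radius",
                                                   "x", "y")]
  state
}

#' Run one simulation
#'
#' Builds the initial state from `config` under `seed`, runs the compiled
#' tick loop for `config$n_steps` ticks and records the observable time
#' series (monomer and dimer counts, dimeric fraction of molecules,
#' fraction of molecules inside confined domains).
#'
#' @param config A [sim_config()].
#' @param seed Seed for this run (defaults to `config$seed`).
#' @param snapshot_every Record full agent snapshots every so many ticks
#'   (0 = never; snapshots grow quickly, use for diagnostics only).
#' @param record_events Keep a per-event log (dimerise / dissociate /
#'   deferred / abandoned).
#' @return Object of class `raft_sim`: list with `series` (data.frame),
#'   `agents` (final state), `counts`, `config`, `seed`, and optionally
#'   `snapshots` / `events`.
#' @examples
#' cfg <- sim_config(n_steps = 500, window = 200, n_receptor_monomers = 10)
#' sim <- run_sim(cfg, seed = 1)
#' window_mean(sim)
#' @export
run_sim <- function(config, seed = config$seed, snapshot_every = 0,
                    record_events = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  set.seed(seed)
  state <- init_state(config)
  res <- run_engine(state, config, config$n_steps,
                    snapshot_every = snapshot_every,
                    record_events = record_events)
  series <- as.data.frame(res$series)
  out <- list(series = series,
              agents = engine_agents_df(res$agents),
              counts = res$counts,
              domains = state$domains,
              config = config,
              seed = seed,
              runtime = proc.time()[["elapsed"]] - t0)
  if (snapshot_every > 0) {
    sn <- as.data.frame(res$snapshots)
    sn$species <- species_label(as.integer(sn$species))
    out$snapshots <- sn
  }
  if (record_events && nrow(res$events) > 0) {
    ev <- as.data.frame(res$events)
    ev$event <- c("dimerise", "dissociate", "deferred",
                  "abandoned")[ev$type]
    out$events <- ev
  }
  class(out) <- "raft_sim"
  out
}

#' @export
print.raft_sim <- function(x, ...) {
  cat(sprintf("raft_sim: %d ticks, seed %d (%.2f s)\n",
              max(x$series$step), x$seed, x$runtime))
  wm <- window_mean(x)
  cat(sprintf("  equilibrium window (last %d ticks): %.1f%% dimeric, %.1f%% inside domains\n",
              x$config$window, 100 * wm[["fraction_dimeric"]],
              100 * wm[["fraction_inside"]]))
  cat(sprintf("  events: %d dimerisations, %d dissociations (%d deferred, %d abandoned)\n",
              x$counts[["dimerise"]], x$counts[["dissociate"]],
              x$counts[["dissociation_deferred"]],
              x$counts[["dimerisation_abandoned"]]))
  invisible(x)
}

#' @export
summary.raft_sim <- function(object, ...) {
  print(object)
  invisible(window_mean(object))
}

#' Plot observable time series of a run
#'
#' @param x A `raft_sim`.
#' @param which Observables to draw.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.raft_sim <- function(x, which = c("fraction_dimeric", "fraction_inside"),
                          ...) {
  s <- x$series
  op <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  for (w in which) {
    graphics::plot(s$step, s[[w]], type = "l", xlab = "tick", ylab = w,
                   ylim = c(0, 1), ...)
    graphics::abline(v = max(s$step) - x$config$window, lty = 2, col = "grey")
  }
  invisible(x)
}

#' Equilibrium window means
#'
#' Arithmetic mean of each recorded observable over the final `window`
#' ticks of a run (on the thinned records).
#'
#' @param x A `raft_sim` or its `series` data.frame.
#' @param window Averaging window in ticks (defaults to the run config).
#' @return Named numeric vector over the recorded observables.
#' @export
window_mean <- function(x, window = NULL) {
  series <- if (inherits(x, "raft_sim")) x$series else x
  if (is.null(window))
    window <- if (inherits(x, "raft_sim")) x$config$window else
      stop("'window' required when passing a bare series", call. = FALSE)
  span <- max(series$step)
  if (window > span && span > 0)
    stop("'window' exceeds the recorded span", call. = FALSE)
  keep <- series$step > span - window
  cols <- setdiff(names(series), "step")
  vapply(cols, function(cl) mean(series[[cl]][keep]), numeric(1))
}

#' Replicate runs and equilibrium summary statistics
#'
#' Runs `replicates` independent simulations with seeds `seed`,
#' `seed + 1`, ... and summarises the replicate window-means (mean and
#' sample SD per observable).
#'
#' @param config A [sim_config()].
#' @param seed Master seed (defaults to `config$seed`).
#' @param replicates Number of replicates (defaults to `config$replicates`).
#' @return Object of class `raft_replicates`: data.frame with columns
#'   `observable`, `mean`, `sd`, `n_replicates`, plus a `values` attribute
#'   holding the per-replicate window-means.
#' @export
run_replicates <- function(config, seed = config$seed,
                           replicates = config$replicates) {
  stopifnot(replicates >= 1)
  wms <- lapply(seq_len(replicates) - 1L,
                function(k) window_mean(run_sim(config, seed = seed + k)))
  vals <- do.call(rbind, wms)
  out <- data.frame(observable = colnames(vals),
                    mean = colMeans(vals),
                    sd = if (replicates > 1) apply(vals, 2, stats::sd)
                         else NA_real_,
                    n_replicates = replicates,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "values") <- vals
  attr(out, "seed") <- seed
  class(out) <- c("raft_replicates", "data.frame")
  out
}

#' @export
print.raft_replicates <- function(x, ...) {
  cat(sprintf("Equilibrium summary over %d replicate(s), master seed %d\n",
              x$n_replicates[1], attr(x, "seed")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
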