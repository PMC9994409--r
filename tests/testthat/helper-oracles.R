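# Independent oracles shared across the suite.

# all-pairs no-overlap check on an agent table; tangency within floating
# tolerance is allowed (dissociation places exactly tangent children)
assert_no_overlaps <- function(agents, box_length, tol = 1e-9) {
  n <- nrow(agents)
  if (n < 2) return(invisible(TRUE))
  L <- box_length
  for (i in seq_len(n - 1)) {
    dx <- agents$x[(i + 1):n] - agents$x[i]
    dx <- dx - L * round(dx / L)
    dy <- agents$y[(i + 1):n] - agents$y[i]
    dy <- dy - L * round(dy / L)
    d <- sqrt(dx^2 + dy^2)
    lim <- agents$radius[i] + agents$radius[(i + 1):n]
    if (any(d < lim - tol)) {
      stop(sprintf("overlap: agent %d, min clearance %.3g", i,
                   min(d - lim)))
    }
  }
  invisible(TRUE)
}

# brute-force minimal image over the 9 periodic image shifts
brute_minimal_image <- function(p, q, L) {
  best <- NULL
  bestd <- Inf
  for (sx in c(-L, 0, L)) {
    for (sy in c(-L, 0, L)) {
      d <- (q + c(sx, sy)) - p
      nd <- sum(d^2)
      if (nd < bestd) {
        bestd <- nd
        best <- d
      }
    }
  }
  best
}

# small fast config for property tests; window defaults to a quarter of
# the run when not supplied
quick_config <- function(...) {
  args <- list(...)
  defaults <- list(n_steps = 2000, thin = 5)
  merged <- utils::modifyList(defaults, args)
  if (is.null(merged$window))
    merged$window <- max(1, merged$n_steps %/% 4)
  do.call(sim_config, merged)
}
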