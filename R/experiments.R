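#' Lay out equal-area confined domains
#'
#' Splits a total occupied area fraction into `n_parts` equal circles,
#' each of radius `sqrt(total_area_fraction / (n_parts * pi)) * L`. A
#' single circle sits at the box centre; several circles are placed
#' uniformly at random without pairwise overlap (consumes R's RNG).
#' Membership tests are minimal-image aware, so a single large circle
#' (radius above half the box) remains usable for high area fractions.
#'
#' @param total_area_fraction Total fraction of the box area occupied.
#' @param n_parts Number of equal circles.
#' @param box A [box_spec()].
#' @param max_attempts Placement attempts per circle.
#' @return A [domain_set()].
#' @export
split_domains <- function(total_area_fraction, n_parts, box = box_spec(),
                          max_attempts = 1e5) {
  stopifnot(n_parts >= 1, total_area_fraction > 0)
  L <- box$length
  r <- sqrt(total_area_fraction / (n_parts * pi)) * L
  if (n_parts == 1) {
    return(domain_set(data.frame(cx = L / 2, cy = L / 2, r = r), box))
  }
  centres <- matrix(NA_real_, 0, 2)
  for (k in seq_len(n_parts)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      cand <- stats::runif(2, 0, L)
      clear <- TRUE
      if (nrow(centres) > 0) {
        for (j in seq_len(nrow(centres))) {
          if (torus_distance(cand, centres[j, ], box) < 2 * r) {
            clear <- FALSE
            break
          }
        }
      }
      if (clear) {
        centres <- rbind(centres, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop(sprintf("packing infeasible: placed %d of %d domain circles",
                   k - 1L, n_parts), call. = FALSE)
  }
  domain_set(data.frame(cx = centres[, 1], cy = centres[, 2], r = r), box)
}

#' Preset experiment sweeps
#'
#' The ten study designs, one per row of the parameter table: each is a
#' base configuration plus one or two swept parameters.
#'
#' 1. receptor localisation vs diffusivity contrast (no reactions),
#'    `D_in` = 2^0 .. 2^-10 at 35% confined area;
#' 2. dimerisation vs diffusivity contrast (same sweep, reactions on);
#' 3. dimerisation vs confined area (0-80%) crossed with `D_in`
#'    (2^0 .. 2^-5);
#' 4. domain merging: 0.5 .. 8 fold merging of 8 reference domains at
#'    fixed 35% total area, `D_in` = 0.1;
#' 5. inert crowding: 0 .. 200 crowders, no confined domain;
#' 6. crowder disintegration: one disc of diameter half the box split
#'    into 1 .. 256 equal-area discs;
#' 7. global diffusivity 2^-5 .. 2^5, no confined domain;
#' 8. confined-area estimation sweep: 15-22% area at `D_in` = 0.1
#'    crossed with `k_b` in {0, 0.01, 0.005, 0.0025, 0.00125, 0.000625},
#'    `k_d = k_b / 5`;
#' 9. receptor density 25-200% of the default 47 copies per box;
#' 10. `k_b` x `k_d` grid at 60-140% of the default rates.
#'
#' @param row_id Preset number, 1-10.
#' @return Object of class `sweep_spec`: list with `preset_id`, `base`
#'   (a [sim_config()]), and `points` (data.frame of per-point config
#'   overrides; columns starting with `.` are descriptive labels).
#' @examples
#' preset(2)$points
#' @export
preset <- function(row_id) {
  if (!row_id %in% 1:10) stop("unknown preset row", call. = FALSE)
  base <- sim_config()
  L <- base$box_length
  spec <- switch(as.character(row_id),
    "1" = list(base = sim_config(k_b = 0, k_d = 0),
               points = data.frame(d_in = 2^-(0:10), .ratio = 2^(0:10))),
    "2" = list(base = sim_config(),
               points = data.frame(d_in = 2^-(0:10), .ratio = 2^(0:10))),
    "3" = list(base = sim_config(),
               points = {
                 g <- expand.grid(domain_fraction = seq(0, 0.80, 0.05),
                                  d_in = 2^-(0:5))
                 g$.ratio <- 1 / g$d_in
                 g
               }),
    "4" = list(base = sim_config(d_in = 0.1),
               points = {
                 folds <- seq(0.5, 8, 0.5)
                 data.frame(n_domains = round_half_up(8 / folds),
                            .fold = folds)
               }),
    "5" = list(base = sim_config(domain_fraction = 0),
               points = data.frame(n_inert = seq(0, 200, 25))),
    "6" = list(base = sim_config(domain_fraction = 0),
               points = {
                 n <- 2^(0:8)
                 data.frame(n_inert = n, inert_radius = (L / 4) / sqrt(n),
                            .splits = n)
               }),
    "7" = list(base = sim_config(domain_fraction = 0),
               points = data.frame(d_out = 2^(-5:5), d_in = 2^(-5:5),
                                   .D = 2^(-5:5))),
    "8" = list(base = sim_config(d_in = 0.1),
               points = {
                 g <- expand.grid(
                   domain_fraction = seq(0.15, 0.22, 0.01),
                   k_b = c(0, 0.01, 0.005, 0.0025, 0.00125, 0.000625))
                 g$k_d <- g$k_b / 5
                 g
               }),
    "9" = list(base = sim_config(d_in = 0.1),
               points = {
                 pct <- seq(25, 200, 25)
                 data.frame(n_receptor_monomers = round_half_up(47 * pct / 100),
                            .density_pct = pct)
               }),
    "10" = list(base = sim_config(d_in = 0.1),
                points = expand.grid(k_b = 0.05 * seq(0.6, 1.4, 0.1),
                                     k_d = 0.01 * seq(0.6, 1.4, 0.1))))
  structure(list(preset_id = row_id, base = spec$base, points = spec$points),
            class = "sweep_spec")
}

#' @export
print.sweep_spec <- function(x, ...) {
  vary <- setdiff(names(x$points), grep("^\\.", names(x$points), value = TRUE))
  cat(sprintf("sweep_spec: preset %d, %d points varying {%s}\n",
              x$preset_id, nrow(x$points), paste(vary, collapse = ", ")))
  invisible(x)
}

#' Run a parameter sweep
#'
#' Runs [run_replicates()] at every sweep point and returns a tidy table
#' (one row per point and observable). Runtime fields (`n_steps`,
#' `window`, `thin`, `replicates`) may be overridden without touching the
#' swept science parameters. Seeds are derived deterministically: point
#' `i`, replicate `k` uses `seed + (i - 1) * replicates + (k - 1)`.
#'
#' @param spec A [preset()] result, or any `sweep_spec`-shaped list.
#' @param seed Master seed.
#' @param n_steps,window,thin,replicates Optional runtime overrides.
#' @return Object of class `sweep_result` (a data.frame): the point's
#'   override/label columns plus `observable`, `mean`, `sd`,
#'   `n_replicates`.
#' @export
run_sweep <- function(spec, seed = 1, n_steps = NULL, window = NULL,
                      thin = NULL, replicates = NULL) {
  stopifnot(inherits(spec, "sweep_spec") || is.list(spec))
  base <- spec$base
  if (!is.null(n_steps)) {
    base$n_steps <- n_steps
    # keep the averaging window inside a shortened run unless given
    if (is.null(window) && base$window > n_steps)
      window <- max(1, n_steps %/% 4)
  }
  if (!is.null(window)) base$window <- window
  if (!is.null(thin)) base$thin <- thin
  if (!is.null(replicates)) base$replicates <- replicates
  base <- validate_sim_config(unclass(base))
  pts <- spec$points
  ovr_cols <- grep("^\\.", names(pts), value = TRUE, invert = TRUE)
  rows <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    cfg <- unclass(base)
    for (cl in ovr_cols) cfg[[cl]] <- pts[[cl]][i]
    cfg <- validate_sim_config(cfg)
    rep_seed <- seed + (i - 1L) * base$replicates
    rr <- run_replicates(cfg, seed = rep_seed)
    tag <- pts[i, , drop = FALSE]
    rownames(tag) <- NULL
    rows[[i]] <- cbind(tag[rep(1, nrow(rr)), , drop = FALSE],
                       as.data.frame(rr), row.names = NULL)
  }
  out <- do.call(rbind, rows)
  attr(out, "preset_id") <- spec$preset_id
  attr(out, "seed") <- seed
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Pearson correlation coefficient
#'
#' @param xs,ys Equal-length numeric vectors (length at least 3) with
#'   non-zero variance.
#' @return Sample Pearson correlation.
#' @export
pearson <- function(xs, ys) {
  if (length(xs) != length(ys) || length(xs) < 3)
    stop("'xs' and 'ys' must have equal length >= 3", call. = FALSE)
  if (stats::var(xs) == 0 || stats::var(ys) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  stats::cor(xs, ys)
}

#' Confined-domain area at which half the receptors sit inside
#'
#' Fits an ordinary least-squares line to fraction-inside versus
#' confined-area percentage over the swept range (the estimation design,
#' preset 8) and solves for the area where the fitted fraction equals
#' `target_fraction`. If the fitted slope is non-positive or the solution
#' falls outside the swept range extended by 25%, an extrapolation
#' warning is attached to the result.
#'
#' @param sweep A [run_sweep()] result containing a `domain_fraction`
#'   column and `fraction_inside` rows, at a single `k_b` value (filter
#'   with `k_b` first if several were swept).
#' @param target_fraction Fraction of receptors inside (default 0.5).
#' @param k_b Optional filter when the sweep crossed several binding
#'   rates.
#' @return The estimated confined area in percent of the membrane, with
#'   attributes `fit` (intercept/slope) and possibly `warning`.
#' @export
estimate_area_at_half_inside <- function(sweep, target_fraction = 0.5,
                                         k_b = NULL) {
  df <- as.data.frame(sweep)
  if (!is.null(k_b)) df <- df[abs(df$k_b - k_b) < 1e-12, ]
  if (!is.null(df$k_b) && length(unique(df$k_b)) > 1)
    stop("sweep contains several k_b values; pass 'k_b' to select one",
         call. = FALSE)
  df <- df[df$observable == "fraction_inside", ]
  if (nrow(df) < 3)
    stop("need at least 3 sweep points with fraction_inside", call. = FALSE)
  x <- 100 * df$domain_fraction
  fit <- stats::lm(df$mean ~ x)
  a <- stats::coef(fit)[[1]]
  b <- stats::coef(fit)[[2]]
  est <- (target_fraction - a) / b
  warn <- NULL
  rng <- range(x)
  pad <- 0.25 * diff(rng)
  if (b <= 0) {
    warn <- "fitted slope is non-positive"
  } else if (est < rng[1] - pad || est > rng[2] + pad) {
    warn <- sprintf("estimate %.1f%% lies outside the swept range %g-%g%%",
                    est, rng[1], rng[2])
  }
  structure(est, fit = c(intercept = a, slope = b), warning = warn)
}

#' Equilibrium dimeric fraction over a k_b x k_d grid
#'
#' Scales the base binding and dissociation rates by every pair of
#' `scale_levels` (the ligand-binding proxy experiment) and returns the
#' matrix of equilibrium dimeric fractions, `k_b` levels in rows and
#' `k_d` levels in columns.
#'
#' @param base A [sim_config()] providing the centre-cell rates.
#' @param scale_levels Multipliers applied to both rates (default
#'   0.6 .. 1.4 in steps of 0.1, i.e. -40% .. +40%).
#' @param seed Master seed.
#' @param n_steps,window,replicates Optional runtime overrides.
#' @return Matrix of mean equilibrium dimeric fractions with a
#'   `sweep` attribute carrying the tidy per-cell results.
#' @export
kbkd_grid <- function(base = sim_config(d_in = 0.1),
                      scale_levels = seq(0.6, 1.4, 0.1), seed = 1,
                      n_steps = NULL, window = NULL, replicates = NULL) {
  if (any(scale_levels <= 0) || any(scale_levels >= 2))
    stop("'scale_levels' must lie in (0, 2)", call. = FALSE)
  pts <- expand.grid(k_b = base$k_b * scale_levels,
                     k_d = base$k_d * scale_levels)
  spec <- structure(list(preset_id = 10L, base = base, points = pts),
                    class = "sweep_spec")
  sw <- run_sweep(spec, seed = seed, n_steps = n_steps, window = window,
                  replicates = replicates)
  dd <- sw[sw$observable == "fraction_dimeric", ]
  m <- matrix(NA_real_, length(scale_levels), length(scale_levels),
              dimnames = list(k_b = sprintf("%g", base$k_b * scale_levels),
                              k_d = sprintf("%g", base$k_d * scale_levels)))
  for (r in seq_len(nrow(dd))) {
    i <- match(dd$k_b[r], base$k_b * scale_levels)
    j <- match(dd$k_d[r], base$k_d * scale_levels)
    m[i, j] <- dd$mean[r]
  }
  attr(m, "sweep") <- sw
  m
}

#' Plot a sweep result
#'
#' Mean with replicate-SD error bars against the first swept column; for
#' two-parameter sweeps one line per level of the second parameter.
#'
#' @param x A `sweep_result`.
#' @param observable Which observable to draw.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sweep_result <- function(x, observable = "fraction_dimeric", ...) {
  df <- as.data.frame(x)[as.data.frame(x)$observable == observable, ]
  labcols <- grep("^\\.", names(df), value = TRUE)
  xcol <- if (length(labcols) > 0) labcols[1] else
    setdiff(names(df), c("observable", "mean", "sd", "n_replicates"))[1]
  xv <- df[[xcol]]
  graphics::plot(xv, df$mean, ylim = c(0, 1), xlab = sub("^\\.", "", xcol),
                 ylab = observable, pch = 19, ...)
  ok <- !is.na(df$sd)
  if (any(ok))
    graphics::arrows(xv[ok], df$mean[ok] - df$sd[ok], xv[ok],
                     df$mean[ok] + df$sd[ok], angle = 90, code = 3,
                     length = 0.03)
  invisible(x)
}
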