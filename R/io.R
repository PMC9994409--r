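#' Load a simulation configuration from file
#'
#' Reads YAML (`.yaml`/`.yml`) or JSON (`.json`) whose keys mirror
#' [sim_config()] argument names. Missing keys take the standard-setup
#' defaults; unknown keys are rejected; values are validated (so e.g. a
#' binding probability above 1 or a window longer than the run fail with
#' a message naming the field). An empty file yields the full default
#' configuration.
#'
#' @param path Path to the configuration file.
#' @return A [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config file must hold a key-value mapping",
                           call. = FALSE)
  allowed <- names(formals(sim_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, vals)
}

#' Write a simulation configuration to file
#'
#' @param config A [sim_config()].
#' @param path Destination; format chosen by extension (YAML default,
#'   JSON for `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  vals <- unclass(config)
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path, precision = 17)
  }
  invisible(path)
}

#' Snapshot table with domain membership
#'
#' @param sim A [run_sim()] result produced with `snapshot_every > 0`.
#' @return data.frame with columns `step`, `agent_id`, `species`, `x`,
#'   `y`, `radius`, `inside_domain` (0/1); coordinates in box units,
#'   origin at the lower-left corner, y up.
#' @export
snapshot_export <- function(sim) {
  stopifnot(inherits(sim, "raft_sim"))
  if (is.null(sim$snapshots))
    stop("run_sim() was called without snapshot_every", call. = FALSE)
  sn <- sim$snapshots
  box <- box_spec(sim$config$box_length)
  inside <- vapply(seq_len(nrow(sn)), function(k)
    in_domain(c(sn$x[k], sn$y[k]), sim$domains, box), logical(1))
  data.frame(step = as.integer(sn$step), agent_id = as.integer(sn$id),
             species = sn$species, x = sn$x, y = sn$y, radius = sn$radius,
             inside_domain = as.integer(inside), stringsAsFactors = FALSE)
}

#' Write run, replicate or sweep results to a directory
#'
#' Writes CSV outputs plus a JSON manifest (config echo, seeds, package
#' version, wall time, file checksums) sufficient to re-run and
#' bit-reproduce the outputs.
#'
#' @param x A `raft_sim`, `raft_replicates` or `sweep_result`.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of written files (invisibly).
#' @export
write_results <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  manifest <- list(package = "raftsim",
                   version = as.character(utils::packageVersion("raftsim")),
                   written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (inherits(x, "raft_sim")) {
    f <- file.path(out_dir, "timeseries.csv")
    utils::write.csv(x$series, f, row.names = FALSE)
    files["timeseries"] <- f
    wm <- window_mean(x)
    f <- file.path(out_dir, "summary.csv")
    utils::write.csv(data.frame(observable = names(wm), mean = unname(wm)),
                     f, row.names = FALSE)
    files["summary"] <- f
    f <- file.path(out_dir, "config.yaml")
    save_config(x$config, f)
    files["config"] <- f
    if (!is.null(x$snapshots)) {
      f <- file.path(out_dir, "snapshots.csv")
      utils::write.csv(snapshot_export(x), f, row.names = FALSE)
      files["snapshots"] <- f
    }
    if (!is.null(x$events)) {
      f <- file.path(out_dir, "events.csv")
      utils::write.csv(x$events, f, row.names = FALSE)
      files["events"] <- f
    }
    manifest$seed <- x$seed
    manifest$config <- unclass(x$config)
    manifest$runtime_s <- x$runtime
  } else if (inherits(x, "raft_replicates")) {
    f <- file.path(out_dir, "summary.csv")
    utils::write.csv(as.data.frame(x), f, row.names = FALSE)
    files["summary"] <- f
    f <- file.path(out_dir, "replicate_values.csv")
    utils::write.csv(as.data.frame(attr(x, "values")), f, row.names = FALSE)
    files["replicates"] <- f
    manifest$seed <- attr(x, "seed")
    manifest$replicate_seeds <- attr(x, "seed") + seq_len(x$n_replicates[1]) - 1L
  } else if (inherits(x, "sweep_result")) {
    f <- file.path(out_dir, "sweep.csv")
    utils::write.csv(as.data.frame(x), f, row.names = FALSE)
    files["sweep"] <- f
    manifest$seed <- attr(x, "seed")
    manifest$preset_id <- attr(x, "preset_id")
  } else {
    stop("unsupported result object", call. = FALSE)
  }
  manifest$files <- lapply(files, function(f)
    list(path = basename(f), md5 = unname(tools::md5sum(f))))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files["manifest"] <- mf
  invisible(files)
}

#' Deterministic test fixtures
#'
#' Named initial configurations used across the test suite:
#' `"tangent_pair"` (two tangent monomers at the box centre, no domain),
#' `"default_47"` (the standard 47-monomer start with one 35% central
#' domain), `"crowded_200"` (200 inert crowders plus 47 monomers, no
#' domain), and `"two_domains"` (two equal domains totalling 35%).
#'
#' @param name Fixture name.
#' @param seed Seed for the random layouts.
#' @return A `sim_state` with a `config` attribute.
#' @export
make_fixture <- function(name = c("tangent_pair", "default_47",
                                  "crowded_200", "two_domains"),
                         seed = 1) {
  name <- match.arg(name)
  set.seed(seed)
  if (name == "tangent_pair") {
    cfg <- sim_config(domain_fraction = 0, n_receptor_monomers = 2)
    r <- cfg$receptor_radius
    L <- cfg$box_length
    st <- structure(list(
      agents = data.frame(id = 1:2, species = "monomer", radius = r,
                          x = c(L / 2 - r, L / 2 + r), y = L / 2,
                          stringsAsFactors = FALSE),
      domains = domain_set(NULL, box_spec(L)),
      box = box_spec(L)), class = "sim_state")
  } else {
    cfg <- switch(name,
      default_47 = sim_config(),
      crowded_200 = sim_config(domain_fraction = 0, n_inert = 200),
      two_domains = sim_config(n_domains = 2))
    st <- init_state(cfg)
  }
  attr(st, "config") <- cfg
  st
}
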