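#' Default run configuration
#'
#' Nested defaults for a simulation run: the standard network sizes
#' (Nx=15, Ny=12, Nz=1, P=8, alpha=5), drift parameters, learning
#' parameters (Adam, lr=0.001), the experiment selector, a seed, and an
#' output directory.
#'
#' @return nested list of class \code{run_config}.
#' @export
default_run_config <- function() {
  structure(list(
    network = list(Nx = 15L, Ny = 12L, Nz = 1L, P = 8L, alpha = 5),
    drift = list(sigma = 0.05, Umax = Inf, n_steps = 50000L,
                 record_every = 100L),
    learn = list(lr = 0.001, max_steps = 20000L, tol = NULL,
                 optimizer = "adam", alloc_sd = 0.1),
    experiment = list(protocol = "drift-demo"),
    seed = 1L,
    output_dir = "driftlab-out"
  ), class = "run_config")
}

.merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults))
      stop(sprintf("unknown configuration key: '%s'", here))
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop(sprintf("configuration key '%s' must be a mapping", here))
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]],
                                       c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration file, validates every key against the
#' documented schema (unknown keys are rejected with a message naming the
#' offending key), and fills unset values with the defaults of
#' \code{\link{default_run_config}}. An empty file yields the full default
#' configuration.
#'
#' @param path path to a YAML file.
#' @return a validated \code{run_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("configuration file not found: %s", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("configuration must be a YAML mapping")
  cfg <- .merge_config(default_run_config(), user)
  for (f in c("Nx", "Ny", "Nz", "P")) cfg$network[[f]] <- as.integer(cfg$network[[f]])
  cfg$drift$Umax <- as.numeric(cfg$drift$Umax)
  cfg$seed <- as.integer(cfg$seed)
  # validate by constructing the typed configs
  do.call(network_config, cfg$network)
  drift_config(sigma = cfg$drift$sigma, Umax = cfg$drift$Umax,
               n_steps = cfg$drift$n_steps,
               record_every = cfg$drift$record_every)
  learn_config(lr = cfg$learn$lr, max_steps = cfg$learn$max_steps,
               tol = cfg$learn$tol, optimizer = cfg$learn$optimizer,
               alloc_sd = cfg$learn$alloc_sd)
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#'
#' @param cfg a \code{run_config}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
dump_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- unclass(cfg)
  out$learn$tol <- if (is.null(out$learn$tol)) NULL else out$learn$tol
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Persist a drift trajectory and reports with a checksummed manifest
#'
#' Writes the trajectory time series (engagement fractions, per-neuron row
#' norms, readout error) to CSV, the eta snapshots to a long-format CSV,
#' any reports to JSON, and finally a JSON manifest recording the resolved
#' configuration, seed, package version, wall-clock metadata and an MD5
#' checksum for every written file.
#'
#' @param traj a \code{drift_trajectory} (or \code{NULL}).
#' @param reports named list of report objects serializable to JSON (or
#'   \code{NULL}).
#' @param output_dir directory to write into (created if needed).
#' @param run_config the resolved configuration to embed (optional).
#' @param seed the seed the run consumed.
#' @return invisible character vector of the written file paths.
#' @export
persist_run <- function(traj = NULL, reports = NULL, output_dir,
                        run_config = NULL, seed = NA_integer_) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  wr <- function(df, name) {
    p <- file.path(output_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
  }
  if (!is.null(traj)) {
    fr <- data.frame(time = traj$times, traj$fractions,
                     readout_error = traj$readout_error,
                     zhat_drift = traj$zhat_drift)
    wr(fr, "timeseries.csv")
    rn <- data.frame(time = traj$times, traj$row_norms)
    names(rn) <- c("time", paste0("neuron_", seq_len(ncol(traj$row_norms))))
    wr(rn, "row_norms.csv")
    d <- dim(traj$etas)
    snaps <- data.frame(
      time = rep(traj$times, each = d[1] * d[2]),
      neuron = rep(rep(seq_len(d[1]), d[2]), length(traj$times)),
      column = rep(rep(seq_len(d[2]), each = d[1]), length(traj$times)),
      eta = as.vector(traj$etas))
    wr(snaps, "eta_snapshots.csv")
  }
  if (!is.null(reports)) {
    for (nm in names(reports)) {
      p <- file.path(output_dir, paste0(nm, ".json"))
      jsonlite::write_json(reports[[nm]], p, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
      written <- c(written, p)
    }
  }
  manifest <- list(
    schema_version = "1",
    package_version = as.character(utils::packageVersion("driftlab")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = if (is.null(run_config)) NULL else unclass(run_config),
    files = lapply(written, function(p)
      list(name = basename(p), md5 = unname(tools::md5sum(p)))))
  mp <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(c(written, mp))
}

#' Verify the checksums of a persisted run
#'
#' Recomputes the MD5 checksum of every file listed in a run's manifest and
#' compares with the recorded values.
#'
#' @param output_dir directory containing \code{manifest.json}.
#' @return \code{TRUE} if all checksums match; otherwise stops, naming the
#'   first tampered or missing file.
#' @export
verify_manifest <- function(output_dir) {
  mp <- file.path(output_dir, "manifest.json")
  if (!file.exists(mp)) stop("manifest.json not found")
  man <- jsonlite::read_json(mp)
  for (f in man$files) {
    p <- file.path(output_dir, f$name)
    if (!file.exists(p)) stop(sprintf("missing file: %s", f$name))
    if (!identical(unname(tools::md5sum(p)), f$md5))
      stop(sprintf("checksum mismatch for file: %s", f$name))
  }
  TRUE
}
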