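config_defaults <- function() {
  list(
    theta = 2 * pi, alpha = 2 * pi, r = 0.01,
    arena = 7.5, density = 70, n_steps = 14400L,
    step_duration = 15 / 1440, speed = 40,
    stationary_prob = 0, max_turn = 0,
    angles = "radians", seed = NULL, out_dir = "."
  )
}

#' Load a run configuration
#'
#' Reads a YAML configuration mirroring [sim_config()] plus `seed`,
#' `angles` (`"radians"`, the default, or `"degrees"`) and `out_dir`.
#' Missing keys take the package defaults (the upper-bound validation
#' scenario: 7.5 km arena, 70 animals/km^2, 14400 steps of 15 min,
#' 40 km/day, 10 m detection radius, omnidirectional sensor and signal);
#' unknown keys are rejected. Angles given in degrees are converted to
#' radians on load.
#'
#' @param path Path to a YAML file. An empty file yields the defaults.
#' @return A named list of class `grem_config`, with a stable content
#'   hash in attribute `"hash"`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  defaults <- config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, raw)
  if (!cfg$angles %in% c("radians", "degrees")) {
    stop("`angles` must be \"radians\" or \"degrees\"", call. = FALSE)
  }
  if (cfg$angles == "degrees") {
    cfg$theta <- cfg$theta * pi / 180
    cfg$alpha <- cfg$alpha * pi / 180
    cfg$max_turn <- cfg$max_turn * pi / 180
    cfg$angles <- "radians"
  }
  bad <- character()
  if (cfg$theta <= 0 || cfg$theta > 2 * pi) bad <- c(bad, "theta")
  if (cfg$alpha < 0 || cfg$alpha > 2 * pi) bad <- c(bad, "alpha")
  if (cfg$r <= 0) bad <- c(bad, "r")
  if (cfg$arena <= 0) bad <- c(bad, "arena")
  if (cfg$density < 0) bad <- c(bad, "density")
  if (cfg$n_steps < 1) bad <- c(bad, "n_steps")
  if (cfg$step_duration <= 0) bad <- c(bad, "step_duration")
  if (cfg$speed <= 0) bad <- c(bad, "speed")
  if (cfg$stationary_prob < 0 || cfg$stationary_prob >= 1) {
    bad <- c(bad, "stationary_prob")
  }
  if (cfg$max_turn < 0 || cfg$max_turn > pi) bad <- c(bad, "max_turn")
  if (length(bad)) {
    stop("invalid config value(s) for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "grem_config",
            hash = rlang::hash(cfg[order(names(cfg))]))
}

#' Write experiment outputs with reproducibility metadata
#'
#' Writes each table as an RFC-4180 CSV (UTF-8, `.` decimal separator,
#' header row, deterministic column order) together with a
#' `metadata.yaml` sidecar recording the seed, the configuration and its
#' hash, so every output is reproducible from the sidecar alone.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param config Optional configuration list recorded in the sidecar.
#' @param seed Optional integer seed recorded in the sidecar.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(tables, out_dir, config = NULL, seed = NULL) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(as.data.frame(tables[[nm]]), p, row.names = FALSE,
                     fileEncoding = "UTF-8")
    paths <- c(paths, p)
  }
  meta <- list(
    files = basename(paths),
    seed = seed,
    config = if (is.null(config)) NULL else unclass(config),
    config_hash = if (is.null(config)) NULL else
      rlang::hash(unclass(config)[order(names(config))])
  )
  mp <- file.path(out_dir, "metadata.yaml")
  yaml::write_yaml(meta, mp, precision = 15)
  invisible(c(paths, mp))
}
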