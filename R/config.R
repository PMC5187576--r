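#' Full default configuration
#'
#' The complete parameter set of the package in one nested list: network
#' architecture and learning rate, plant physical constants, PD gains,
#' error-scaling coefficients, mossy-fiber gains, and the experimental
#' protocol (sampling period 10 ms, amplitude pi, default frequencies,
#' 100 cycles, 5 replicate seeds).  Every run is driven from such a list,
#' so a saved configuration fully reconstructs an experiment.
#'
#' @param ... named overrides replacing top-level sections or, as nested
#'   lists, individual fields (unknown names are an error).
#' @return a nested configuration list of class \code{"flocculus_config"}.
#' @export
#' @examples
#' cfg <- flocculus_config()
#' cfg$network$n_gc         # 755
#' cfg2 <- flocculus_config(network = list(gamma = 0.004))
#' cfg2$network$gamma
flocculus_config <- function(...) {
  defaults <- list(
    network = list(
      n_gc = 755L, n_go = 5L, n_ba = 15L, n_pc = 1L,
      sigma = 8, mu = 0.5, gamma = 0.008,
      convergence = list(mf_gc = 4L, go_gc = 3L, pf_go = 150L,
                         pf_ba = 50L)),
    plant = list(
      motor = list(J = 5e-5, B = 2e-4, Kt = 0.01, dt_inner = 1e-3,
                   i_max = Inf),
      robot = list(m_b = 0.8, m_w = 0.05, r = 0.025, l = 0.1,
                   I_b = 0.8 * 0.1^2 / 3, I_w = 0.05 * 0.025^2 / 2,
                   g = 9.81, Kt = 0.1, polarity = -1, tip_over = pi / 4,
                   dt_inner = 1e-3, i_max = Inf)),
    gains = list(
      motor = list(kp = 0.8, kd = 0.01),
      robot = list(kp = 5, kd = 0.5, kp_w = 0.2, kd_w = 0.05)),
    coefficients = list(a1 = 0.5, a2 = 0.02, b1 = 5, b2 = 0.5, c1 = -0.4),
    mossy_gains = list(
      motor = c(0.1, 0.19, 0.5, 0.07, 1),
      robot = c(0.03, 0.04, 1, 0.5, 0.1, 0.2, 0.5)),
    experiment = list(
      ts = 0.01, amplitude = pi,
      frequency = list(motor = 0.5, robot = 0.2),
      cycles = 100L, n_seeds = 5L,
      output_gain = list(motor = 0.3, robot = 0.02),
      me_polarity = -1, weight_floor = 1e-6, cf_clip = NULL))
  cfg <- merge_config(defaults, list(...), path = "")
  class(cfg) <- c("flocculus_config", "list")
  cfg
}

# recursive merge of user values into defaults; unknown keys rejected with
# their field path
merge_config <- function(defaults, user, path) {
  if (length(user) == 0L) return(defaults)
  nm <- names(user)
  if (is.null(nm) || any(nm == ""))
    stop("configuration entries must be named (at '", path, "')")
  for (k in nm) {
    here <- if (nzchar(path)) paste0(path, "$", k) else k
    if (!k %in% names(defaults))
      stop("unknown configuration key: '", here, "'")
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]]))
        stop("configuration key '", here, "' must be a named list")
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], here)
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  # the network section must build for both plants
  for (plant in c("motor", "robot"))
    do.call(network_config, c(list(plant = plant), cfg$network))
  do.call(motor_params, cfg$plant$motor)
  do.call(robot_params, cfg$plant$robot)
  do.call(pd_gains, c(list(plant = "motor"), cfg$gains$motor))
  do.call(pd_gains, c(list(plant = "robot"), cfg$gains$robot))
  do.call(error_coefficients, cfg$coefficients)
  mossy_fiber_spec("motor", gains = cfg$mossy_gains$motor)
  mossy_fiber_spec("robot", gains = cfg$mossy_gains$robot)
  with(cfg$experiment, stopifnot(ts > 0, amplitude > 0,
                                 frequency$motor > 0, frequency$robot > 0,
                                 cycles >= 1, n_seeds >= 1))
  invisible(cfg)
}

#' Load and validate a configuration file
#'
#' Reads a YAML configuration, fills every unset field with the package
#' defaults, rejects unknown keys (reporting the field path) and
#' validates the result; an empty file yields the full defaults.
#'
#' @param path YAML file path.
#' @return a validated \code{"flocculus_config"} list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.null(user$mossy_gains))
    user$mossy_gains <- lapply(user$mossy_gains, as.numeric)
  cfg <- do.call(flocculus_config, user)
  validate_config(cfg)
  cfg
}

#' Save a configuration to YAML
#'
#' @param config a configuration list.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(config, path) {
  cfg <- unclass(config)
  # full double precision so physical constants survive the round trip
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' Export a trial to portable text files
#'
#' Writes the per-step time series and the PF-PC weight snapshots as CSV
#' and a JSON manifest describing the run (protocol parameters, seed,
#' Purkinje guard scale, file list), so a result directory is fully
#' reconstructible.
#'
#' @param trial a \code{"cnn_trial"}.
#' @param dir output directory (created if needed).
#' @return the manifest as a list, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  series_file <- file.path(dir, "series.csv")
  utils::write.csv(trial$series, series_file, row.names = FALSE)
  files <- "series.csv"
  if (!is.null(trial$w_snapshots)) {
    w_file <- file.path(dir, "weights.csv")
    utils::write.csv(trial$w_snapshots, w_file, row.names = FALSE)
    corr_file <- file.path(dir, "correlations.csv")
    utils::write.csv(trial$correlations, corr_file, row.names = FALSE)
    files <- c(files, "weights.csv", "correlations.csv")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("flocculus")),
    timestamp = format(Sys.time(), tz = "UTC"),
    plant = trial$plant, cf_mode = trial$cf_mode,
    frequency = trial$frequency, amplitude = trial$amplitude,
    cycles = trial$cycles, ts = trial$ts, seed = trial$seed,
    guard_scale = trial$guard_scale, failed = trial$failed,
    files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
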