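#' Run the multi-seed, multi-CF closed-loop protocol
#'
#' Repeats [cnn_control()] for each climbing-fiber mode over a battery of
#' random weight initializations (five by default), and runs the PD-only
#' baseline once (the baseline loop has no randomness, so one run
#' represents it for every seed).  Aggregates per-cycle RSE curves per
#' mode: per-seed curves plus their mean.
#'
#' @param plant \code{"motor"} or \code{"robot"}.
#' @param cf_modes character vector of CF modes to compare.
#' @param frequency stimulus frequency, Hz (plant default when NULL).
#' @param amplitude stimulus amplitude, rad.
#' @param cycles stimulus cycles per trial.
#' @param seeds integer vector of replicate seeds; when NULL,
#'   \code{n_seeds} seeds are expanded from \code{seed} via
#'   [default_seeds()].
#' @param n_seeds number of replicates when \code{seeds} is NULL.
#' @param seed master seed used when \code{seeds} is NULL.
#' @param config full configuration list.
#' @param keep_trials logical; keep the individual \code{"cnn_trial"}
#'   objects (default TRUE).
#' @return an object of class \code{"cnn_battery"}: list with
#'   \code{rse} (per mode, a cycles x seeds matrix), \code{rse_mean}
#'   (per mode), \code{baseline} (the PD-only trial), \code{baseline_rse},
#'   \code{trials} (per mode, list of trials), \code{seeds}, and the
#'   protocol parameters.
#' @export
cnn_battery <- function(plant = c("motor", "robot"),
                        cf_modes = c("SE", "ME", "SE+ME"),
                        frequency = NULL, amplitude = pi, cycles = 100L,
                        seeds = NULL, n_seeds = 5L, seed = 1L,
                        config = flocculus_config(),
                        keep_trials = TRUE) {
  plant <- match.arg(plant)
  if (is.null(seeds)) seeds <- default_seeds(seed, n_seeds)
  seeds <- as.integer(seeds)

  baseline <- cnn_control(plant, "none", frequency = frequency,
                          amplitude = amplitude, cycles = cycles,
                          seed = seeds[1L], config = config, cnn = FALSE)
  trials <- list(); rse <- list(); rse_mean <- list()
  for (mode in cf_modes) {
    tl <- lapply(seeds, function(s)
      cnn_control(plant, mode, frequency = frequency,
                  amplitude = amplitude, cycles = cycles, seed = s,
                  config = config))
    m <- vapply(tl, function(tr) {
      r <- rep(NA_real_, cycles)
      r[seq_along(tr$rse)] <- tr$rse
      r
    }, numeric(cycles))
    rse[[mode]] <- m
    rse_mean[[mode]] <- rowMeans(m)
    if (keep_trials) trials[[mode]] <- tl
  }
  structure(list(plant = plant, cf_modes = cf_modes,
                 frequency = baseline$frequency, amplitude = amplitude,
                 cycles = as.integer(cycles), seeds = seeds,
                 rse = rse, rse_mean = rse_mean,
                 baseline = baseline, baseline_rse = baseline$rse,
                 trials = if (keep_trials) trials else NULL),
            class = "cnn_battery")
}

#' @export
print.cnn_battery <- function(x, ...) {
  cat(sprintf("Cerebellar control battery: %s plant at %g Hz, %d cycles, %d seeds\n",
              x$plant, x$frequency, x$cycles, length(x$seeds)))
  late <- seq.int(max(1L, x$cycles - 9L), x$cycles)
  base <- mean(x$baseline_rse[late])
  cat(sprintf("  PD-only late RSE: %.4f rad\n", base))
  for (mode in x$cf_modes) {
    m <- mean(x$rse_mean[[mode]][late], na.rm = TRUE)
    cat(sprintf("  CF = %-6s late RSE: %.4f rad (%+.1f%% vs PD)\n",
                mode, m, 100 * (m - base) / base))
  }
  invisible(x)
}

#' @export
summary.cnn_battery <- function(object, late = 10L, ...) {
  late_idx <- seq.int(max(1L, object$cycles - late + 1L), object$cycles)
  base <- mean(object$baseline_rse[late_idx])
  rows <- lapply(object$cf_modes, function(mode) {
    per_seed <- colMeans(object$rse[[mode]][late_idx, , drop = FALSE],
                         na.rm = TRUE)
    data.frame(cf_mode = mode,
               rse_late_mean = mean(per_seed),
               rse_late_min = min(per_seed),
               rse_late_max = max(per_seed),
               improvement_pct = 100 * (base - mean(per_seed)) / base)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline_rse_late") <- base
  out
}

#' Plot the mean RSE curves of a battery against the PD baseline
#'
#' @param x a \code{"cnn_battery"}.
#' @param ... passed to \code{matplot}.
#' @export
plot.cnn_battery <- function(x, ...) {
  m <- do.call(cbind, x$rse_mean)
  matplot(m, type = "l", lty = 1, xlab = "cycle",
          ylab = "mean RSE of phi (rad)",
          main = sprintf("%s plant, %g Hz", x$plant, x$frequency), ...)
  lines(x$baseline_rse, col = "grey", lwd = 2)
  legend("topright", legend = c(colnames(m), "PD only"),
         col = c(seq_len(ncol(m)), "grey"), lty = 1, bty = "n")
  invisible(x)
}
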