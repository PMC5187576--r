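#' Run one closed-loop cerebellar control experiment
#'
#' The central fitting function of the package.  It wires the cerebellar
#' network, the PD controller and a simulated plant into the 10-ms control
#' loop and runs a sinusoidal tracking protocol for a number of stimulus
#' cycles, adapting the PF-PC weights every sample with the chosen
#' climbing-fiber teaching signal.  Per control sample, in order: read the
#' plant state, form the desired-minus-actual errors, compute the PD
#' command, the sensory-error and motor-error signals and the composed CF,
#' encode the mossy fibers (including the efference copy of the previous
#' command), evaluate the network, combine PD and Purkinje outputs into
#' the plant command, advance the plant, and apply the plasticity rule.
#'
#' The learned quantity is the plastic PF-PC weight vector; [coef()]
#' returns it, [residuals()] the per-step tracking error, and [plot()]
#' the per-cycle RMS error curve.
#'
#' @param plant \code{"motor"} (DC motor shaft) or \code{"robot"}
#'   (two-wheeled balancing robot).
#' @param cf climbing-fiber mode: \code{"SE"}, \code{"ME"},
#'   \code{"SE+ME"} or \code{"none"} (CF = 0, no learning).
#' @param frequency stimulus frequency, Hz; defaults to 0.5 for the motor
#'   and 0.2 for the robot.
#' @param amplitude stimulus amplitude, rad (default pi).
#' @param cycles number of stimulus cycles (default 100).
#' @param seed integer master seed; expanded deterministically into the
#'   connectivity and weight draws.
#' @param config full configuration list from [flocculus_config()] or
#'   [load_config()].
#' @param cnn logical; \code{FALSE} runs the PD-only baseline (Purkinje
#'   contribution disconnected, no learning, otherwise the identical
#'   loop).
#' @param record_pf logical; store the full parallel-fiber rate history
#'   (time x granule cells).  Memory-guarded; only sensible for short
#'   runs.  Correlation profiles do not need it: they are accumulated in
#'   streaming form regardless.
#' @return an object of class \code{"cnn_trial"}.  Key elements:
#'   \code{series} (per-step data frame: t, phi_des, phi, theta, phi_e,
#'   cf, y_pc, pd, command), \code{rse} (per-cycle RMS of the wheel/shaft
#'   angle error), \code{rse_theta} (robot only), \code{w_pf_pc_initial},
#'   \code{w_pf_pc_final}, \code{w_snapshots} (granule cells x cycles+1),
#'   \code{correlations} (per-GC Pearson r of the PF rate against CF,
#'   phi_e and phi_des), \code{calibration} (the five logged
#'   operating-point scalars; \code{guard_scale} is its basket-output
#'   element), \code{failed}, \code{failure_time}.
#' @seealso [cnn_battery()] for the multi-seed protocol with PD baseline.
#' @export
#' @examples
#' tr <- cnn_control("motor", "SE", cycles = 5, seed = 1)
#' round(tr$rse, 4)
cnn_control <- function(plant = c("motor", "robot"),
                        cf = c("SE", "ME", "SE+ME", "none"),
                        frequency = NULL, amplitude = pi, cycles = 100L,
                        seed = 1L, config = flocculus_config(),
                        cnn = TRUE, record_pf = FALSE) {
  plant <- match.arg(plant)
  cf <- match.arg(cf)
  if (is.null(frequency))
    frequency <- config$experiment$frequency[[plant]]
  stopifnot(frequency > 0, amplitude > 0, cycles >= 1)
  ts <- config$experiment$ts
  og <- config$experiment$output_gain
  if (is.list(og)) og <- og[[plant]]
  output_gain <- if (cnn) og else 0
  cf_clip <- config$experiment$cf_clip   # NULL = raw CF (default)

  n_steps <- as.integer(floor(cycles / (frequency * ts) + 1e-9))
  tvec <- (seq_len(n_steps) - 1) * ts
  des <- desired_trajectory(amplitude, frequency, tvec)
  cycle_idx <- pmin(as.integer(floor(tvec * frequency + 1e-9)) + 1L,
                    as.integer(cycles))

  ## plant
  pp <- if (plant == "motor") do.call(motor_params, config$plant$motor)
        else do.call(robot_params, config$plant$robot)
  mats <- if (plant == "motor") motor_matrices(pp) else robot_matrices(pp)
  disc <- plant_discretize(mats$A, mats$B, pp$dt_inner, ts)
  Fm <- disc$F; Gv <- disc$G
  x <- numeric(nrow(Fm))

  ## controller
  gains <- do.call(pd_gains, c(list(plant = plant), config$gains[[plant]]))
  co <- do.call(error_coefficients, config$coefficients)
  ## orientation of the motor-error pathway: the catalogued coefficient
  ## c1 is negative, a sign the original hardware absorbs in its wiring;
  ## in this loop's explicit conventions (errors = desired - actual,
  ## command = PD - y_pc) a corrective ME teaching signal must carry the
  ## sign of the needed command correction, so the loop applies
  ## me_polarity * c1 (default me_polarity = -1, i.e. +0.4 per A).
  me_c1 <- config$experiment$me_polarity * co$c1
  robot <- plant == "robot"
  kp <- gains$kp; kd <- gains$kd
  kpw <- if (robot) gains$kp_w else 0
  kdw <- if (robot) gains$kd_w else 0

  ## network
  guard_scale <- NA_real_
  calibration <- NULL
  net_cfg <- NULL
  if (cnn) {
    net_cfg <- do.call(network_config,
                       c(list(plant = plant), config$network))
    ss <- derive_seeds(seed, 2L)
    masks <- build_connectivity(net_cfg, ss[1L])
    weights <- initialize_weights(net_cfg, masks, ss[2L])
    sg <- net_cfg$sigma; mu <- net_cfg$mu
    gamma <- net_cfg$gamma
    mf <- mossy_fiber_spec(plant, gains = config$mossy_gains[[plant]])
    gvec <- mf$gain
    MW <- list(mf_gc = masks$m_mf_gc * weights$w_mf_gc,
               go_gc = masks$m_go_gc * weights$w_go_gc,
               mf_go = masks$m_mf_go * weights$w_mf_go,
               pf_go = masks$m_pf_go * weights$w_pf_go,
               pf_ba = masks$m_pf_ba * weights$w_pf_ba,
               ba_pc = weights$w_ba_pc)
    ## operating-point calibration over one PD-only warmup cycle
    n_cal <- min(n_steps, as.integer(round(1 / (frequency * ts))))
    raw_cal <- pd_only_signals(plant, Fm, Gv, gains,
                               lapply(des, function(v) v[seq_len(n_cal)]),
                               n_cal, pp$i_max)
    Y_cal <- sigmoid_rate(sweep(raw_cal, 2L, gvec, `*`), sg, mu)
    cal <- calibrate_network(Y_cal, MW, weights$w_pf_pc, sg, mu,
                             net_cfg$n_go)
    MW <- cal$MW
    calibration <- cal$scales
    guard_scale <- cal$scales[["ba_pc"]]
    MW_mf_gc <- MW$mf_gc; MW_go_gc <- MW$go_gc
    MW_mf_go <- MW$mf_go; MW_pf_go <- MW$pf_go; MW_pf_ba <- MW$pf_ba
    w_ba_pc <- drop(MW$ba_pc)
    w_pf_pc <- weights$w_pf_pc
    w_pf_pc_initial <- w_pf_pc
    n_gc <- net_cfg$n_gc
    y_go_prev <- rep(0.5, net_cfg$n_go)
    learn <- cf != "none"
    eps <- config$experiment$weight_floor
    ## weight snapshots: initial + one per cycle
    snaps <- matrix(NA_real_, n_gc, cycles + 1L)
    snaps[, 1L] <- w_pf_pc
    ## streaming correlation sums
    sy <- numeric(n_gc); syy <- numeric(n_gc)
    syr_cf <- numeric(n_gc); syr_pe <- numeric(n_gc)
    syr_pd <- numeric(n_gc)
    s_cf <- s_cf2 <- s_pe <- s_pe2 <- s_pd <- s_pd2 <- 0
    if (record_pf) {
      if (as.double(n_steps) * n_gc > 2e7)
        stop("record_pf = TRUE would store ", n_steps, " x ", n_gc,
             " rates; shorten the run")
      pf_history <- matrix(NA_real_, n_steps, n_gc)
    }
  }

  ## per-step records
  phi_r <- numeric(n_steps); theta_r <- numeric(n_steps)
  cf_r <- numeric(n_steps); ypc_r <- numeric(n_steps)
  pd_r <- numeric(n_steps); cmd_r <- numeric(n_steps)

  command_prev <- 0
  failed <- FALSE; failure_time <- NA_real_
  last_cycle <- 1L
  k_done <- 0L

  for (k in seq_len(n_steps)) {
    phi <- x[1L]; phid <- x[2L]
    pe <- des$phi_des[k] - phi
    pde <- des$phi_dot_des[k] - phid
    if (robot) {
      te <- -x[3L]; tde <- -x[4L]
      pd <- kp * te + kd * tde + kpw * pe + kdw * pde
      se <- co$a1 * pe + co$a2 * pde + co$b1 * te + co$b2 * tde
    } else {
      pd <- kp * pe + kd * pde
      se <- co$a1 * pe + co$a2 * pde
    }
    me <- me_c1 * pd
    cfv <- if (cf == "SE") se else if (cf == "ME") me
           else if (cf == "SE+ME") se + me else 0
    if (!is.null(cf_clip)) cfv <- max(min(cfv, cf_clip), -cf_clip)

    if (cnn) {
      raw <- if (robot)
        c(des$phi_des[k], des$phi_dot_des[k], te, tde, pe, pde,
          command_prev)
      else
        c(des$phi_des[k], des$phi_dot_des[k], pe, pde, command_prev)
      y_mf <- 1 / (1 + exp(-sg * (gvec * raw - mu)))
      x_gc <- drop(y_mf %*% MW_mf_gc) + drop(y_go_prev %*% MW_go_gc)
      y_pf <- 1 / (1 + exp(-sg * (x_gc - mu)))
      x_go <- drop(y_mf %*% MW_mf_go) + drop(y_pf %*% MW_pf_go)
      y_go_prev <- 1 / (1 + exp(-sg * (x_go - mu)))
      x_ba <- drop(y_pf %*% MW_pf_ba)
      y_ba <- 1 / (1 + exp(-sg * (x_ba - mu)))
      x_pc <- sum(y_pf * w_pf_pc) + sum(y_ba * w_ba_pc)
      if (!is.finite(x_pc)) stop("non-finite Purkinje drive at t = ",
                                 tvec[k])
      y_pc <- 1 / (1 + exp(-sg * (x_pc - mu))) - 0.5
    } else y_pc <- 0

    cmd <- pd - output_gain * y_pc
    cmd <- apply_saturation(cmd, pp$i_max)

    phi_r[k] <- phi
    if (robot) theta_r[k] <- x[3L]
    cf_r[k] <- cfv; ypc_r[k] <- y_pc; pd_r[k] <- pd; cmd_r[k] <- cmd

    x <- drop(Fm %*% x) + Gv * cmd
    if (!all(is.finite(x))) stop("non-finite plant state at t = ", tvec[k])

    if (cnn) {
      if (learn)
        w_pf_pc <- pmin(pmax(w_pf_pc - (gamma * cfv) * (y_pf - 0.5), eps), 1)
      sy <- sy + y_pf; syy <- syy + y_pf * y_pf
      syr_cf <- syr_cf + y_pf * cfv
      syr_pe <- syr_pe + y_pf * pe
      syr_pd <- syr_pd + y_pf * des$phi_des[k]
      s_cf <- s_cf + cfv; s_cf2 <- s_cf2 + cfv^2
      s_pe <- s_pe + pe; s_pe2 <- s_pe2 + pe^2
      s_pd <- s_pd + des$phi_des[k]; s_pd2 <- s_pd2 + des$phi_des[k]^2
      if (record_pf) pf_history[k, ] <- y_pf
      if (cycle_idx[k] != last_cycle) {
        snaps[, last_cycle + 1L] <- w_pf_pc
        last_cycle <- cycle_idx[k]
      }
    }
    command_prev <- cmd
    k_done <- k

    if (robot && abs(x[3L]) >= pp$tip_over) {
      failed <- TRUE
      failure_time <- tvec[k] + ts
      break
    }
  }

  keep <- seq_len(k_done)
  phi_e <- des$phi_des[keep] - phi_r[keep]
  cycles_done <- cycle_idx[k_done]
  complete <- if (failed) cycle_idx[keep] < cycles_done else cycle_idx[keep] <= cycles_done
  rse <- rse_series(phi_e[complete], cycle_idx[keep][complete])
  rse_theta <- if (robot)
    rse_series(theta_r[keep][complete], cycle_idx[keep][complete]) else NULL

  out <- list(call = match.call(),
              plant = plant, cf_mode = cf, frequency = frequency,
              amplitude = amplitude, cycles = as.integer(cycles),
              ts = ts, seed = seed, cnn = cnn,
              output_gain = output_gain,
              guard_scale = guard_scale,
              calibration = calibration,
              network = net_cfg,
              series = data.frame(
                t = tvec[keep], phi_des = des$phi_des[keep],
                phi = phi_r[keep],
                theta = if (robot) theta_r[keep] else NA_real_,
                phi_e = phi_e, cf = cf_r[keep], y_pc = ypc_r[keep],
                pd = pd_r[keep], command = cmd_r[keep],
                cycle = cycle_idx[keep]),
              rse = rse, rse_theta = rse_theta,
              failed = failed, failure_time = failure_time)
  if (cnn) {
    n <- length(keep)
    if (cf == "none") snaps[, seq.int(2L, cycles + 1L)] <- w_pf_pc
    else snaps[, cycles_done + 1L] <- w_pf_pc
    out$w_pf_pc_initial <- w_pf_pc_initial
    out$w_pf_pc_final <- w_pf_pc
    out$w_snapshots <- snaps
    out$correlations <- data.frame(
      gc = seq_len(n_gc),
      r_cf = correlation_from_sums(n, sy, syy, syr_cf, s_cf, s_cf2),
      r_phi_e = correlation_from_sums(n, sy, syy, syr_pe, s_pe, s_pe2),
      r_phi_des = correlation_from_sums(n, sy, syy, syr_pd, s_pd, s_pd2))
    if (record_pf) out$pf_history <- pf_history[keep, , drop = FALSE]
  }
  class(out) <- "cnn_trial"
  out
}

#' @export
print.cnn_trial <- function(x, ...) {
  cat(sprintf("Cerebellar control trial: %s plant, CF = %s%s\n",
              x$plant, x$cf_mode, if (!x$cnn) " (PD-only baseline)" else ""))
  cat(sprintf("  stimulus: %.3g rad at %g Hz, %d cycles (ts = %g s)\n",
              x$amplitude, x$frequency, x$cycles, x$ts))
  if (x$failed)
    cat(sprintf("  FAILED: tip-over at t = %.2f s\n", x$failure_time))
  n <- length(x$rse)
  if (n >= 1)
    cat(sprintf("  RSE(phi): first cycle %.4f rad, last cycle %.4f rad\n",
                x$rse[1], x$rse[n]))
  invisible(x)
}

#' @export
summary.cnn_trial <- function(object, late = 10L, ...) {
  n <- length(object$rse)
  late_idx <- seq.int(max(1L, n - late + 1L), n)
  s <- list(plant = object$plant, cf_mode = object$cf_mode,
            cnn = object$cnn, frequency = object$frequency,
            cycles_run = n, failed = object$failed,
            rse_first = unname(object$rse[1]),
            rse_late_mean = mean(object$rse[late_idx]),
            guard_scale = object$guard_scale)
  if (object$cnn) {
    wc <- ltd_ltp_fractions(object$w_pf_pc_initial, object$w_pf_pc_final)
    s$depressed_fraction <- wc$depressed_fraction
    s$potentiated_fraction <- wc$potentiated_fraction
  }
  class(s) <- "summary.cnn_trial"
  s
}

#' @export
print.summary.cnn_trial <- function(x, ...) {
  cat(sprintf("%s plant, CF = %s%s: %d cycles%s\n", x$plant, x$cf_mode,
              if (!x$cnn) " (PD-only)" else "", x$cycles_run,
              if (x$failed) " (tipped over)" else ""))
  cat(sprintf("  RSE(phi): cycle 1 = %.4f rad, late mean = %.4f rad\n",
              x$rse_first, x$rse_late_mean))
  if (!is.null(x$depressed_fraction))
    cat(sprintf("  PF-PC weights: %.1f%% depressed, %.1f%% potentiated (guard scale %.3g)\n",
                100 * x$depressed_fraction, 100 * x$potentiated_fraction,
                x$guard_scale))
  invisible(x)
}

#' @export
coef.cnn_trial <- function(object, ...) {
  if (!object$cnn) stop("PD-only baseline has no learned weights")
  object$w_pf_pc_final
}

#' @export
residuals.cnn_trial <- function(object, ...) object$series$phi_e

#' @export
fitted.cnn_trial <- function(object, ...) object$series$phi

#' Plot a cerebellar control trial
#'
#' @param x a \code{"cnn_trial"}.
#' @param which one of \code{"rse"} (per-cycle RMS error), \code{"tracking"}
#'   (desired vs yielded angle, final cycle), \code{"weights"} (PF-PC
#'   weight trajectories), \code{"rotated"} (the -45-degree rotated XY
#'   view of the final cycle).
#' @param ... passed to the underlying base plotting call.
#' @export
plot.cnn_trial <- function(x, which = c("rse", "tracking", "weights",
                                        "rotated"), ...) {
  which <- match.arg(which)
  s <- x$series
  if (which == "rse") {
    plot(seq_along(x$rse), x$rse, type = "l", xlab = "cycle",
         ylab = "RSE of phi (rad)",
         main = sprintf("%s / CF = %s", x$plant, x$cf_mode), ...)
  } else if (which == "tracking") {
    last <- s$cycle == max(s$cycle)
    plot(s$t[last], s$phi_des[last], type = "l", lty = 2,
         xlab = "t (s)", ylab = "angle (rad)", ...)
    lines(s$t[last], s$phi[last])
    legend("topright", legend = c("desired", "yielded"), lty = c(2, 1),
           bty = "n")
  } else if (which == "weights") {
    if (!x$cnn) stop("PD-only baseline has no weights")
    matplot(t(x$w_snapshots[seq(1, nrow(x$w_snapshots), by = 25), ]),
            type = "l", lty = 1, xlab = "cycle", ylab = "w (PF-PC)", ...)
  } else {
    last <- s$cycle == max(s$cycle)
    rot <- rotate_trajectory(s$phi_des[last], s$phi[last])
    plot(rot$x, rot$y, type = "l", xlab = "x' (rad)", ylab = "y' (rad)",
         ...)
    abline(h = 0, lty = 2)
  }
  invisible(x)
}
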