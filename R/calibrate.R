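# Operating-point calibration of the fixed (non-plastic) weights.
#
# A freshly sampled weight set puts every downstream population far
# outside the dynamic range of the shared sigmoid: a Golgi cell summing
# 150 parallel fibers saturates, which in turn shuts granule cells down,
# and the Purkinje drive (755 excitatory inputs against 15 inhibitory
# ones) is two orders of magnitude above the activation midpoint.  Both
# failure modes (Purkinje over-inhibition; a runaway granule-Golgi loop)
# need taming before learning can operate, and the cure here is one
# logged scalar per projection, applied once after initialization:
#
#   * MF->GC excitation scaled so its mean drive is 2*mu and GO->GC
#     inhibition so its mean drive is -mu: granule drives then straddle
#     the activation midpoint with wide cell-to-cell diversity, and in
#     particular a subpopulation of strongly driven cells stays active at
#     every stimulus phase, which keeps the climbing-fiber-gated rule
#     corrective (the population term sum(y*(y-0.5)) that couples a CF
#     excursion to the Purkinje drive never changes sign),
#   * the Golgi input (MF->GO with PF->GO, one scalar) scaled to mean mu,
#   * the basket pathway (PF->BA input scale and BA->PC output scale)
#     set so that the inhibition exactly centres the mean Purkinje drive
#     at mu while cancelling as much of the common-mode parallel-fiber
#     drive fluctuation as possible: for each candidate input scale the
#     output scale is fixed by the mean constraint, and the input scale
#     minimizing the residual drive variance is kept (the plastic PF->PC
#     vector is never rescaled).
#
# Statistics are taken over a one-cycle PD-only warmup pass of the actual
# closed-loop signals, so the calibration reflects the real operating
# point; because each scalar shifts the operating point of the
# populations downstream, the measure-and-rescale step is iterated to a
# fixed point.  The plastic weights and the learning rule are untouched.

# raw mossy-fiber signal matrix (n_steps x n_channels) along the PD-only
# trajectory, efference copy = previous PD command
pd_only_signals <- function(plant, Fm, Gv, gains, des, n_steps, i_max) {
  robot <- plant == "robot"
  x <- numeric(nrow(Fm))
  raw <- matrix(0, n_steps, if (robot) 7L else 5L)
  command_prev <- 0
  for (k in seq_len(n_steps)) {
    pe <- des$phi_des[k] - x[1L]
    pde <- des$phi_dot_des[k] - x[2L]
    if (robot) {
      te <- -x[3L]; tde <- -x[4L]
      pd <- gains$kp * te + gains$kd * tde + gains$kp_w * pe +
        gains$kd_w * pde
      raw[k, ] <- c(des$phi_des[k], des$phi_dot_des[k], te, tde, pe, pde,
                    command_prev)
    } else {
      pd <- gains$kp * pe + gains$kd * pde
      raw[k, ] <- c(des$phi_des[k], des$phi_dot_des[k], pe, pde,
                    command_prev)
    }
    pd <- apply_saturation(pd, i_max)
    x <- drop(Fm %*% x) + Gv * pd
    command_prev <- pd
  }
  raw
}

# per-projection drive statistics over a sequential network pass: the
# per-sample granule excitation and inhibition matrices (for the sparse
# coding fit), mean drives for the mean-matched projections, the
# per-sample Purkinje excitatory drive, and the basket drive vectors
calibration_pass <- function(Y_mf, MW, w_pf_pc, sg, mu, n_go, n_ba) {
  n <- nrow(Y_mf)
  n_gc <- ncol(MW$mf_gc)
  y_go_prev <- rep(0.5, n_go)
  acc <- c(go = 0, ba = 0)
  pc_pf <- numeric(n)
  d_ba_all <- matrix(0, n, n_ba)
  E <- matrix(0, n, n_gc); I <- matrix(0, n, n_gc)
  for (k in seq_len(n)) {
    y_mf <- Y_mf[k, ]
    e_gc <- drop(y_mf %*% MW$mf_gc)
    i_gc <- drop(y_go_prev %*% MW$go_gc)
    y_pf <- 1 / (1 + exp(-sg * (e_gc + i_gc - mu)))
    d_go <- drop(y_mf %*% MW$mf_go) + drop(y_pf %*% MW$pf_go)
    y_go_prev <- 1 / (1 + exp(-sg * (d_go - mu)))
    d_ba <- drop(y_pf %*% MW$pf_ba)
    acc <- acc + c(mean(d_go), mean(d_ba))
    E[k, ] <- e_gc; I[k, ] <- i_gc
    d_ba_all[k, ] <- d_ba
    pc_pf[k] <- sum(y_pf * w_pf_pc)
  }
  list(means = acc / n, E = E, I = I, pc_pf = pc_pf, d_ba = d_ba_all)
}

# returns rescaled masked-weight matrices plus the applied scalars
calibrate_network <- function(Y_mf, MW, w_pf_pc, sg, mu, n_go,
                              iterations = 4L) {
  n_ba <- ncol(MW$pf_ba)
  scales <- c(mf_gc = 1, go_gc = 1, go_in = 1, pf_ba = 1, ba_pc = 1)
  p <- NULL
  for (it in seq_len(iterations)) {
    p <- calibration_pass(Y_mf, MW, w_pf_pc, sg, mu, n_go, n_ba)
    s <- c(mf_gc = 2 * mu / mean(p$E),
           go_gc = -mu / mean(p$I),
           go_in = mu / p$means[["go"]],
           pf_ba = mu / p$means[["ba"]])
    if (any(!is.finite(s)) || any(s <= 0))
      stop("network calibration failed: degenerate operating point")
    MW$mf_gc <- MW$mf_gc * s[["mf_gc"]]
    MW$go_gc <- MW$go_gc * s[["go_gc"]]
    MW$mf_go <- MW$mf_go * s[["go_in"]]
    MW$pf_go <- MW$pf_go * s[["go_in"]]
    MW$pf_ba <- MW$pf_ba * s[["pf_ba"]]
    scales[1:4] <- scales[1:4] * s
    if (it < iterations) next
    ## final pass statistics are used for the basket fit below
    p <- calibration_pass(Y_mf, MW, w_pf_pc, sg, mu, n_go, n_ba)
  }
  ## basket pathway: pick the input scale (operating point of the basket
  ## sigmoid) whose mean-centring output scale best cancels the
  ## parallel-fiber drive fluctuation
  w_ba <- drop(MW$ba_pc)
  mean_pf <- mean(p$pc_pf)
  candidates <- 2^seq(-4, 4, by = 0.25)
  best <- NULL
  for (m_in in candidates) {
    y_ba <- 1 / (1 + exp(-sg * (m_in * p$d_ba - mu)))
    pc_ba <- drop(y_ba %*% w_ba)
    mb <- mean(pc_ba)
    if (!is.finite(mb) || mb >= 0) next
    s_out <- (mu - mean_pf) / mb
    if (!is.finite(s_out) || s_out <= 0) next
    res <- stats::sd(p$pc_pf + s_out * pc_ba)
    if (is.null(best) || res < best$res)
      best <- list(m_in = m_in, s_out = s_out, res = res)
  }
  if (is.null(best))
    stop("network calibration failed: basket pathway cannot centre the Purkinje drive")
  MW$pf_ba <- MW$pf_ba * best$m_in
  MW$ba_pc <- MW$ba_pc * best$s_out
  scales[["pf_ba"]] <- scales[["pf_ba"]] * best$m_in
  scales[["ba_pc"]] <- best$s_out
  list(MW = MW, scales = scales)
}
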