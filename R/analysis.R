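#' Per-cycle root-mean-square error
#'
#' Splits a per-step error record into stimulus cycles and returns the RMS
#' error of each cycle, the performance metric of the closed-loop
#' experiments.
#'
#' @param errors numeric vector of per-step errors (rad).
#' @param cycle integer vector, same length, assigning each sample to its
#'   stimulus cycle (cycles are the \code{[k/f, (k+1)/f)} windows of the
#'   desired signal).
#' @return numeric vector, one RMS value per cycle, named by cycle.
#' @export
#' @examples
#' rse_series(rep(0.2, 10), rep(1:2, each = 5))  # 0.2 in both cycles
rse_series <- function(errors, cycle) {
  if (length(errors) != length(cycle))
    stop("errors and cycle index must have the same length")
  cyc <- unique(cycle)
  if (anyNA(errors)) stop("errors contain NA")
  out <- vapply(split(errors, factor(cycle, levels = sort(cyc))),
                function(e) {
                  if (!length(e)) stop("empty cycle")
                  sqrt(mean(e^2))
                }, numeric(1))
  out
}

#' Summarize plastic weight changes (LTD/LTP fractions)
#'
#' Compares the final and initial PF-PC weight vectors and classifies each
#' synapse as depressed (final < initial), potentiated (final > initial)
#' or unchanged, with an equality tolerance; also returns the sort order
#' of granule cells from most depressed to most potentiated, the ordering
#' used by the correlation profiles.
#'
#' @param w_initial,w_final numeric vectors of equal length.
#' @param tol equality tolerance (default 1e-12).
#' @return an object of class \code{"weight_change_summary"}: list with
#'   \code{delta}, \code{depressed_fraction}, \code{potentiated_fraction},
#'   \code{unchanged_fraction}, and \code{order} (indices sorted by
#'   ascending delta).
#' @export
ltd_ltp_fractions <- function(w_initial, w_final, tol = 1e-12) {
  if (length(w_initial) != length(w_final))
    stop("weight vectors must have equal length")
  delta <- w_final - w_initial
  n <- length(delta)
  dep <- sum(delta < -tol)
  pot <- sum(delta > tol)
  structure(list(delta = delta,
                 depressed_fraction = dep / n,
                 potentiated_fraction = pot / n,
                 unchanged_fraction = (n - dep - pot) / n,
                 order = order(delta)),
            class = "weight_change_summary")
}

#' @export
print.weight_change_summary <- function(x, ...) {
  cat(sprintf(
    "PF-PC weight changes: %.1f%% depressed, %.1f%% potentiated, %.1f%% unchanged (n = %d)\n",
    100 * x$depressed_fraction, 100 * x$potentiated_fraction,
    100 * x$unchanged_fraction, length(x$delta)))
  invisible(x)
}

#' Granule-cell correlation profile against a reference signal
#'
#' Pearson correlation of every granule cell's parallel-fiber rate series
#' with a reference signal (climbing fiber, an error component, or a
#' desired-motion channel), ordered from the most depressed to the most
#' potentiated cell, with a centered moving-average smoothed copy
#' (window truncated symmetrically at the edges).
#'
#' @param y_pf_history matrix of rates, time in rows, granule cells in
#'   columns.
#' @param reference numeric reference series, length \code{nrow}.
#' @param order integer permutation of granule-cell indices (typically the
#'   \code{order} element of [ltd_ltp_fractions()]); default keeps the
#'   native order.
#' @param window moving-average window (default 13).
#' @return an object of class \code{"correlation_profile"}: data frame
#'   with columns \code{gc} (original index), \code{r}, \code{r_smooth}.
#' @export
gc_correlation <- function(y_pf_history, reference, order = NULL,
                           window = 13L) {
  if (nrow(y_pf_history) != length(reference))
    stop("reference length must match the number of time samples")
  if (stats::sd(reference) == 0)
    stop("reference signal is constant; correlation undefined")
  r <- suppressWarnings(
    as.vector(stats::cor(y_pf_history, reference)))
  if (anyNA(r)) {
    bad <- which(is.na(r))
    stop("constant granule-cell rate series: correlation undefined for ",
         length(bad), " cell(s), first at index ", bad[1L])
  }
  if (is.null(order)) order <- seq_along(r)
  out <- data.frame(gc = order, r = r[order],
                    r_smooth = moving_average(r[order], window))
  class(out) <- c("correlation_profile", "data.frame")
  out
}

# Pearson profile from streaming sums (n, sum y, sum y^2, sum y*ref per
# cell, plus scalar sum ref, sum ref^2); used by cnn_control so full rate
# histories need not be stored
correlation_from_sums <- function(n, sy, syy, syr, sr, srr) {
  num <- n * syr - sy * sr
  den <- sqrt(pmax(n * syy - sy^2, 0)) * sqrt(max(n * srr - sr^2, 0))
  ifelse(den > 0, num / den, NA_real_)
}

#' Rotated XY view of a tracking trajectory
#'
#' Places the desired motion on the X-axis and the yielded motion on the
#' Y-axis, rotated -45 degrees, so perfect tracking maps onto the
#' horizontal line y = 0: \code{x = (phi_des + phi)/sqrt(2)},
#' \code{y = (phi - phi_des)/sqrt(2)}.
#'
#' @param phi_des,phi equal-length numeric series (rad).
#' @return data frame with columns \code{x} and \code{y}.
#' @export
rotate_trajectory <- function(phi_des, phi) {
  if (length(phi_des) != length(phi))
    stop("phi_des and phi must have the same length")
  data.frame(x = (phi_des + phi) / sqrt(2),
             y = (phi - phi_des) / sqrt(2))
}
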