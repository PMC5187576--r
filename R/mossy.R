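#' Mossy-fiber channel specification
#'
#' The ordered input channels of the model with their pre-cerebellar
#' scaling gains, chosen to normalize each physical signal before the
#' sigmoidal encoding.  Motor (5 channels): desired shaft position and
#' velocity, shaft position and velocity errors, efference copy.  Robot
#' (7 channels): desired wheel position and velocity, body tilt position
#' and velocity errors, wheel position and velocity errors, efference
#' copy.  The efference copy carries the previous control sample's total
#' plant command.
#'
#' @param plant \code{"motor"} or \code{"robot"}.
#' @param gains optional numeric vector overriding the default scaling
#'   gains (same length and order as the default channels).
#' @return an object of class \code{"mossy_fiber_spec"}: a data frame with
#'   columns \code{channel}, \code{source}, \code{gain}.
#' @export
#' @examples
#' mossy_fiber_spec("robot")   # 7 channels
mossy_fiber_spec <- function(plant = c("motor", "robot"), gains = NULL) {
  plant <- match.arg(plant)
  spec <- if (plant == "motor") {
    data.frame(
      channel = c("des_pos", "des_vel", "pos_error", "vel_error",
                  "efference"),
      source = c("phi_des", "phi_dot_des", "phi_e", "phi_dot_e",
                 "command_prev"),
      gain = c(0.1, 0.19, 0.5, 0.07, 1),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      channel = c("des_pos", "des_vel", "tilt_error", "tilt_vel_error",
                  "pos_error", "vel_error", "efference"),
      source = c("phi_des", "phi_dot_des", "theta_e", "theta_dot_e",
                 "phi_e", "phi_dot_e", "command_prev"),
      gain = c(0.03, 0.04, 1, 0.5, 0.1, 0.2, 0.5),
      stringsAsFactors = FALSE)
  }
  if (!is.null(gains)) {
    if (length(gains) != nrow(spec))
      stop("expected ", nrow(spec), " gains for the ", plant, " plant")
    spec$gain <- gains
  }
  attr(spec, "plant") <- plant
  class(spec) <- c("mossy_fiber_spec", "data.frame")
  spec
}

#' Encode raw signals into mossy-fiber rates
#'
#' Each channel's raw physical value is scaled by its pre-cerebellar gain
#' and passed through the sigmoidal activation, yielding rates in (0, 1).
#'
#' @param raw_signals numeric vector, one raw value per channel, in the
#'   channel order of \code{spec}.
#' @param spec a [mossy_fiber_spec()] object.
#' @param sigma,mu activation constants (defaults as in the network).
#' @return mossy-fiber rate vector.
#' @export
encode_mossy_fibers <- function(raw_signals, spec, sigma = 8, mu = 0.5) {
  if (length(raw_signals) != nrow(spec))
    stop("expected ", nrow(spec), " raw signals, got ",
         length(raw_signals))
  sigmoid_rate(spec$gain * raw_signals, sigma, mu)
}
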