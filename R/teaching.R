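#' PD controller gains (the non-cerebellar pathway)
#'
#' Default proportional/derivative gains: motor position loop kp = 0.8,
#' kd = 0.01; robot body loop kp = 5, kd = 0.5 plus wheel loop kp_w = 0.2,
#' kd_w = 0.05 (a parallel configuration of two controllers).
#'
#' @param plant \code{"motor"} or \code{"robot"}.
#' @param kp,kd position-loop gains (body loop for the robot).
#' @param kp_w,kd_w wheel-loop gains (robot only).
#' @return an object of class \code{"pd_gains"}.
#' @export
pd_gains <- function(plant = c("motor", "robot"), kp = NULL, kd = NULL,
                     kp_w = 0.2, kd_w = 0.05) {
  plant <- match.arg(plant)
  if (is.null(kp)) kp <- if (plant == "motor") 0.8 else 5
  if (is.null(kd)) kd <- if (plant == "motor") 0.01 else 0.5
  g <- if (plant == "motor") list(plant = plant, kp = kp, kd = kd)
       else list(plant = plant, kp = kp, kd = kd, kp_w = kp_w, kd_w = kd_w)
  if (any(unlist(g[-1]) < 0)) stop("PD gains must be non-negative")
  structure(g, class = "pd_gains")
}

#' Scaling coefficients of the error signals
#'
#' The constants weighting each error component so that all contribute
#' comparably to the composite teaching signals: a1 (wheel/shaft position
#' error, 1/rad), a2 (velocity error, s/rad), b1, b2 (body tilt position
#' and velocity errors, robot only) and c1 (PD output, 1/A; negative).
#'
#' @param a1,a2,b1,b2,c1 the coefficients.
#' @return an object of class \code{"error_coefficients"}.
#' @export
error_coefficients <- function(a1 = 0.5, a2 = 0.02, b1 = 5, b2 = 0.5,
                               c1 = -0.4) {
  structure(list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1),
            class = "error_coefficients")
}

#' PD motor command
#'
#' Motor: \code{kp * phi_e + kd * phi_dot_e}.  Robot: the sum of the body
#' controller \code{kp * theta_e + kd * theta_dot_e} and the wheel
#' controller \code{kp_w * phi_e + kd_w * phi_dot_e}.  Errors follow the
#' desired-minus-actual convention.  This value is both the non-cerebellar
#' contribution to the plant command and the input of [compute_me()].
#'
#' @param errors list with \code{phi_e}, \code{phi_dot_e} and, for the
#'   robot, \code{theta_e}, \code{theta_dot_e}.
#' @param gains a [pd_gains()] object.
#' @return command current, A.
#' @export
#' @examples
#' pd_command(list(phi_e = 0.1, phi_dot_e = 1), pd_gains("motor"))  # 0.09 A
pd_command <- function(errors, gains) {
  if (gains$plant == "motor") {
    gains$kp * errors$phi_e + gains$kd * errors$phi_dot_e
  } else {
    (gains$kp * errors$theta_e + gains$kd * errors$theta_dot_e) +
      (gains$kp_w * errors$phi_e + gains$kd_w * errors$phi_dot_e)
  }
}

#' Sensory-error teaching signal
#'
#' Kinematic-coordinate error: motor \code{a1 phi_e + a2 phi_dot_e};
#' robot adds the body-tilt terms \code{b1 theta_e + b2 theta_dot_e}.
#'
#' @param errors error list as in [pd_command()].
#' @param coeff an [error_coefficients()] object.
#' @param plant \code{"motor"} or \code{"robot"}.
#' @return the SE scalar.
#' @export
compute_se <- function(errors, coeff, plant = c("motor", "robot")) {
  plant <- match.arg(plant)
  se <- coeff$a1 * errors$phi_e + coeff$a2 * errors$phi_dot_e
  if (plant == "robot")
    se <- se + coeff$b1 * errors$theta_e + coeff$b2 * errors$theta_dot_e
  se
}

#' Motor-error teaching signal
#'
#' Motor-command-coordinate error, the scaled PD output \code{c1 * PD(t)}
#' of the feedback-error-learning scheme; identical for both plants.
#'
#' @param pd_output PD command, A.
#' @param coeff an [error_coefficients()] object.
#' @return the ME scalar.
#' @export
compute_me <- function(pd_output, coeff) coeff$c1 * pd_output

#' Compose the climbing-fiber teaching signal
#'
#' @param se,me sensory-error and motor-error values.
#' @param mode one of \code{"SE"}, \code{"ME"}, \code{"SE+ME"},
#'   \code{"none"} (\code{"none"} disables learning: CF = 0).
#' @return the CF scalar.
#' @export
compose_cf <- function(se, me, mode) {
  switch(mode,
         "SE" = se,
         "ME" = me,
         "SE+ME" = se + me,
         "none" = 0,
         stop("invalid climbing-fiber mode: ", mode))
}

#' Combine PD and Purkinje outputs into the plant command
#'
#' The vestibular-nucleus stage: the inhibitory Purkinje output is
#' subtracted from the PD command, \code{pd - output_gain * y_pc}.
#'
#' @param pd_output PD command, A.
#' @param y_pc Purkinje rate in (-0.5, 0.5).
#' @param output_gain scale of the Purkinje contribution (A per unit rate,
#'   default 1).
#' @return plant command current, A.
#' @export
combine_command <- function(pd_output, y_pc, output_gain = 1) {
  pd_output - output_gain * y_pc
}
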