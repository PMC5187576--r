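#' DC motor plant parameters
#'
#' Linear model of a small brushed DC motor driving a shaft:
#' \code{J * d2phi/dt2 = Kt * i - B * dphi/dt}.  The state is the shaft
#' angle phi (rad) and its angular velocity (rad/s); the input is the
#' armature current (A).
#'
#' @param J rotor plus shaft inertia, kg m^2.
#' @param B viscous friction, N m s.
#' @param Kt torque constant, N m / A.
#' @param dt_inner integration sub-step, s; must divide the control period.
#' @param i_max optional symmetric current saturation, A (default none).
#' @return an object of class \code{"motor_params"}.
#' @export
motor_params <- function(J = 5e-5, B = 2e-4, Kt = 0.01, dt_inner = 1e-3,
                         i_max = Inf) {
  stopifnot(J > 0, B > 0, Kt > 0, dt_inner > 0, i_max > 0)
  structure(list(J = J, B = B, Kt = Kt, dt_inner = dt_inner, i_max = i_max),
            class = "motor_params")
}

#' Two-wheeled balancing robot plant parameters
#'
#' Linearized wheeled-inverted-pendulum dynamics about the upright
#' position:
#' \deqn{(I_w + (m_w + m_b) r^2)\ddot\phi + m_b r l \ddot\theta = \tau}
#' \deqn{(I_b + m_b l^2)\ddot\theta + m_b r l \ddot\phi - m_b g l \theta = -\tau}
#' with wheel angle phi, body tilt theta, and motor torque
#' \code{tau = polarity * Kt * i}.  The drive polarity is -1 by default:
#' positive command current torques the wheels in the -phi direction, the
#' conventional wiring for a wheel-position PD loop on an inverted pendulum
#' (equivalently, the controller feeds back +state rather than +error).
#' With the shipped defaults the plant is open-loop unstable and the
#' default PD gains stabilize it.
#'
#' @param m_b body mass, kg.
#' @param m_w wheel mass, kg.
#' @param r wheel radius, m.
#' @param l axle to body centre-of-mass distance, m.
#' @param I_b body inertia about the axle, kg m^2.
#' @param I_w wheel inertia, kg m^2.
#' @param g gravity, m/s^2.
#' @param Kt torque constant, N m / A.
#' @param polarity sign of the current-to-torque map (+1 or -1).
#' @param tip_over body tilt magnitude (rad) at which the trial is marked
#'   failed.
#' @param dt_inner integration sub-step, s.
#' @param i_max optional symmetric current saturation, A (default none).
#' @return an object of class \code{"robot_params"}.
#' @export
robot_params <- function(m_b = 0.8, m_w = 0.05, r = 0.025, l = 0.1,
                         I_b = m_b * l^2 / 3, I_w = m_w * r^2 / 2,
                         g = 9.81, Kt = 0.1, polarity = -1,
                         tip_over = pi / 4, dt_inner = 1e-3, i_max = Inf) {
  stopifnot(m_b > 0, m_w > 0, r > 0, l > 0, I_b > 0, I_w > 0, g > 0,
            Kt > 0, abs(polarity) == 1, tip_over > 0, dt_inner > 0,
            i_max > 0)
  structure(list(m_b = m_b, m_w = m_w, r = r, l = l, I_b = I_b, I_w = I_w,
                 g = g, Kt = Kt, polarity = polarity, tip_over = tip_over,
                 dt_inner = dt_inner, i_max = i_max),
            class = "robot_params")
}

# continuous-time (A, B) of the motor: state (phi, phi_dot), input i
motor_matrices <- function(p) {
  list(A = rbind(c(0, 1), c(0, -p$B / p$J)),
       B = c(0, p$Kt / p$J))
}

# continuous-time (A, B) of the robot: state (phi, phi_dot, theta,
# theta_dot), input i.  Solves the coupled linearized equations for the
# accelerations.
robot_matrices <- function(p) {
  a <- p$I_w + (p$m_w + p$m_b) * p$r^2
  cc <- p$m_b * p$r * p$l
  b <- p$I_b + p$m_b * p$l^2
  k <- p$m_b * p$g * p$l
  det <- a * b - cc^2
  # phi''  = ((b + cc) tau - cc k theta) / det
  # theta'' = (a k theta - (a + cc) tau) / det
  A <- rbind(c(0, 1, 0, 0),
             c(0, 0, -cc * k / det, 0),
             c(0, 0, 0, 1),
             c(0, 0, a * k / det, 0))
  Bv <- p$polarity * p$Kt * c(0, (b + cc) / det, 0, -(a + cc) / det)
  list(A = A, B = Bv)
}

# Fixed-step RK4 discretization of a linear system x' = A x + B u under a
# zero-order-hold input.  For one RK4 step of size h the update is exactly
# the 4th-order Taylor polynomial F = sum (hA)^k / k!, G = h sum
# (hA)^k/(k+1)! B; composing n sub-steps gives the whole control period.
plant_discretize <- function(A, B, dt_inner, control_period) {
  n_sub <- control_period / dt_inner
  if (abs(n_sub - round(n_sub)) > 1e-9)
    stop("dt_inner must divide the control period")
  n_sub <- as.integer(round(n_sub))
  d <- nrow(A)
  hA <- dt_inner * A
  Fm <- diag(d); P <- diag(d)
  Gs <- diag(d)                      # sum (hA)^k/(k+1)!
  for (k in 1:4) {
    P <- P %*% hA / k
    Fm <- Fm + P
    if (k < 4) Gs <- Gs + P / (k + 1)
  }
  G <- dt_inner * (Gs %*% B)
  # compose n_sub sub-steps
  Ftot <- diag(d); Gtot <- matrix(0, d, 1)
  for (s in seq_len(n_sub)) {
    Gtot <- Fm %*% Gtot + G
    Ftot <- Fm %*% Ftot
  }
  list(F = Ftot, G = drop(Gtot))
}

apply_saturation <- function(i, i_max) {
  if (is.finite(i_max)) max(min(i, i_max), -i_max) else i
}

#' Advance the DC motor by one control period
#'
#' Integrates the linear motor dynamics under a zero-order-hold command
#' current using fixed-step 4th-order integration at \code{dt_inner}.
#'
#' @param state numeric vector \code{c(phi, phi_dot)} (rad, rad/s).
#' @param current command current, A.
#' @param params a [motor_params()] object.
#' @param control_period hold interval, s (default 0.01).
#' @return the new \code{c(phi, phi_dot)}.
#' @export
motor_step <- function(state, current, params, control_period = 0.01) {
  if (!all(is.finite(state)) || !is.finite(current))
    stop("non-finite motor state or command")
  current <- apply_saturation(current, params$i_max)
  m <- motor_matrices(params)
  d <- plant_discretize(m$A, m$B, params$dt_inner, control_period)
  drop(d$F %*% state) + d$G * current
}

#' Advance the balancing robot by one control period
#'
#' Same integrator contract as [motor_step()] for the linearized
#' wheeled-inverted-pendulum dynamics.  If the body tilt magnitude reaches
#' the tip-over limit the returned state carries attribute
#' \code{"tipped" = TRUE}.
#'
#' @param state numeric vector \code{c(phi, phi_dot, theta, theta_dot)}.
#' @param current command current, A.
#' @param params a [robot_params()] object.
#' @param control_period hold interval, s (default 0.01).
#' @return the new state vector, with attribute \code{"tipped"} when the
#'   tilt limit is exceeded.
#' @export
robot_step <- function(state, current, params, control_period = 0.01) {
  if (!all(is.finite(state)) || !is.finite(current))
    stop("non-finite robot state or command")
  if (abs(state[3]) >= params$tip_over)
    stop("robot already tipped over")
  current <- apply_saturation(current, params$i_max)
  m <- robot_matrices(params)
  d <- plant_discretize(m$A, m$B, params$dt_inner, control_period)
  out <- drop(d$F %*% state) + d$G * current
  if (abs(out[3]) >= params$tip_over) attr(out, "tipped") <- TRUE
  out
}
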