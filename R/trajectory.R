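#' Sinusoidal desired trajectory
#'
#' The tracking stimulus: \code{phi_des = A sin(2 pi f t)} with its
#' analytic velocity \code{A 2 pi f cos(2 pi f t)}.  With the default
#' amplitude pi and f = 0.4 Hz the peak desired velocity is 7.896 rad/s.
#'
#' @param amplitude A, rad.
#' @param frequency f, Hz.
#' @param t time(s), s (vectorized).
#' @return list with \code{phi_des} (rad) and \code{phi_dot_des} (rad/s).
#' @export
#' @examples
#' d <- desired_trajectory(pi, 0.4, seq(0, 2.5, by = 0.001))
#' max(d$phi_dot_des)   # ~7.896 rad/s
desired_trajectory <- function(amplitude, frequency, t) {
  w <- 2 * pi * frequency
  list(phi_des = amplitude * sin(w * t),
       phi_dot_des = amplitude * w * cos(w * t))
}
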