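## Discrete PI regulation of the electrode r.m.s. voltage:
##   V = Kp (T_target - T_tip) + Ki int (T_target - T_tip) dt
## Rectangle-rule integral at the controller update interval, output
## clamped at zero volts, and anti-windup: the integral accumulator is
## frozen while the output clamps.

#' Create a PI controller state
#'
#' @param target Control temperature at the electrode tip (degrees C).
#' @param Kp Proportional gain (V/K), default 1.15.
#' @param Ki Integral gain (V/K/s), default 0.06.
#' @return List of class `pi_controller` with the gains, the integral
#'   accumulator (K s), the current output voltage and the clamped flag.
#' @examples
#' ctrl <- pi_controller(90)
#' ctrl <- update_controller(ctrl, tip_T = 37, dt = 0.25)
#' ctrl$V  # 1.15 * 53 = 60.95 V on the first step
#' @export
pi_controller <- function(target, Kp = 1.15, Ki = 0.06) {
  stopifnot(is.numeric(target), length(target) == 1L, Kp >= 0, Ki >= 0)
  structure(list(target = target, Kp = Kp, Ki = Ki,
                 integral = 0, V = 0, clamped = FALSE, active = TRUE),
            class = "pi_controller")
}

#' One controller update
#'
#' Computes the new r.m.s. voltage from the current tip temperature. The
#' first call (zero accumulator) returns the pure proportional response;
#' the error is accumulated after the output is formed (rectangle rule),
#' and accumulation is suspended while the output clamps at zero so the
#' integrator cannot wind up.
#'
#' @param ctrl A [pi_controller()] state.
#' @param tip_T Measured tip temperature (degrees C).
#' @param dt Controller update interval (s), > 0.
#' @return Updated controller state; the applied voltage is in `$V`.
#' @export
update_controller <- function(ctrl, tip_T, dt) {
  if (dt <= 0) stop("dt must be positive")
  if (!ctrl$active) {
    ctrl$V <- 0
    return(ctrl)
  }
  e <- ctrl$target - tip_T
  V <- ctrl$Kp * e + ctrl$Ki * ctrl$integral
  if (V < 0) {
    ctrl$V <- 0
    ctrl$clamped <- TRUE
  } else {
    ctrl$V <- V
    ctrl$clamped <- FALSE
    ctrl$integral <- ctrl$integral + e * dt
  }
  ctrl
}

#' Switch the controller to the cooldown phase
#'
#' Forces zero output voltage for the remainder of the simulation (active
#' electrode turned off); the integrator is inert. Thermal diffusion and
#' damage integration continue downstream.
#'
#' @param ctrl A [pi_controller()] state.
#' @return Updated controller state with `V = 0`.
#' @export
cooldown_mode <- function(ctrl) {
  ctrl$active <- FALSE
  ctrl$V <- 0
  ctrl
}
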