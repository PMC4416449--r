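#' Reference trajectory specification
#'
#' A sinusoid or sum of sines for one controlled variable:
#' `pos(t) = sum_k amp[k] * sin(2 pi freq[k] t + phase[k])`. The cycle
#' period is the period of the fundamental (lowest-frequency) term.
#'
#' @param amp amplitudes (rad or m)
#' @param freq frequencies (Hz), same length as `amp`
#' @param phase phases (rad), recycled
#' @return an object of class `trajectory_spec` with a `period` field (s)
#' @export
trajectory <- function(amp, freq, phase = 0) {
  stopifnot(length(amp) == length(freq), all(freq > 0))
  phase <- rep_len(phase, length(amp))
  structure(list(amp = amp, freq = freq, phase = phase,
                 period = 1 / min(freq)),
            class = "trajectory_spec")
}

#' Evaluate a reference trajectory and its derivative
#'
#' @param spec a `trajectory_spec`
#' @param t time (s), vectorized, `t >= 0`
#' @return list(pos, vel) evaluated analytically
#' @export
reference <- function(spec, t) {
  stopifnot(all(t >= 0))
  pos <- 0; vel <- 0
  for (k in seq_along(spec$amp)) {
    w <- 2 * pi * spec$freq[k]
    pos <- pos + spec$amp[k] * sin(w * t + spec$phase[k])
    vel <- vel + spec$amp[k] * w * cos(w * t + spec$phase[k])
  }
  list(pos = pos, vel = vel)
}

#' Default reference trajectories of the three control tasks
#'
#' DC motor: `pi * sin(2 pi 0.5 t)` (shaft angle); robot: `pi * sin(2 pi
#' 0.25 t)` (wheel angle, body tilt reference 0); quadcopter: `2 * sin(2 pi
#' 0.2 t)` (horizontal position). `robot_sos` is the harder sum-of-sines
#' wheel motion `pi sin(2 pi 0.2 t) + sin(2 pi 0.7 t)` used for the
#' mid-trial task switch.
#'
#' @param plant one of "dc_motor", "robot", "quad", "robot_sos"
#' @return a `trajectory_spec`
#' @export
default_trajectory <- function(plant = c("dc_motor", "robot", "quad",
                                         "robot_sos")) {
  switch(match.arg(plant),
    dc_motor  = trajectory(pi, 0.5),
    robot     = trajectory(pi, 0.25),
    quad      = trajectory(2, 0.2),
    robot_sos = trajectory(c(pi, 1), c(0.2, 0.7))
  )
}

#' DC-motor plant parameters
#'
#' A brushed DC motor driven by an armature voltage command: electrical loop
#' `L di/dt = u - R i - ke w`, mechanical loop `J dw/dt = kt i - b w`.
#' The constants are chosen so the printed PD position gains (kp = 0.8,
#' kd = 0.01) track the 0.5 Hz, pi-amplitude shaft reference with a
#' cycle RSE of a few tenths of a radian before learning.
#'
#' @param J rotor inertia (kg m^2)
#' @param b viscous friction (N m s/rad)
#' @param kt torque constant (N m/A)
#' @param ke back-EMF constant (V s/rad)
#' @param R armature resistance (ohm)
#' @param L armature inductance (H)
#' @param u_max command saturation (absolute)
#' @return list of parameters with class `plant_params`
#' @export
dc_motor_params <- function(J = 0.002, b = 0.01, kt = 0.5, ke = 0.02,
                            R = 1, L = 0.005, u_max = 5) {
  structure(list(kind = "dc_motor", J = J, b = b, kt = kt, ke = ke,
                 R = R, L = L, u_max = u_max),
            class = "plant_params")
}

#' Two-wheel inverted-pendulum robot parameters
#'
#' Nonlinear wheeled inverted pendulum: wheel angle `phi` and body tilt
#' `theta`, a single motor applying torque between body and wheels. The
#' upright equilibrium is open-loop unstable. Constants are sized like a
#' small desktop balancing robot and chosen so the printed body/wheel PD
#' gains stabilize the 0.25 Hz single-sinusoid wheel task.
#'
#' @param m_b,m_w body and (total) wheel mass (kg)
#' @param l axle-to-body-COM distance (m)
#' @param r wheel radius (m)
#' @param I_b,I_w body and wheel moment of inertia (kg m^2)
#' @param b_f viscous friction at the axle (N m s/rad)
#' @param km motor torque per command unit (N m per unit)
#' @param u_max command saturation (absolute)
#' @param fall_threshold body tilt (rad) beyond which the trial counts as
#'   fallen
#' @return list of parameters with class `plant_params`
#' @export
robot_params <- function(m_b = 0.7, m_w = 0.1, l = 0.13, r = 0.03,
                         I_b = 0.004, I_w = 5e-5, b_f = 0.002, km = 0.05,
                         u_max = 1.5, fall_threshold = pi / 4) {
  structure(list(kind = "robot", m_b = m_b, m_w = m_w, l = l, r = r,
                 I_b = I_b, I_w = I_w, b_f = b_f, km = km, u_max = u_max,
                 fall_threshold = fall_threshold, g = 9.81),
            class = "plant_params")
}

#' Planar quadcopter pitch/horizontal subsystem parameters
#'
#' Only the pitch loop is cerebellar; yaw, roll and altitude are assumed
#' held at setpoint by ideal controllers, leaving the planar tilt-to-
#' translate subsystem: `I ddtheta = u - c_th dtheta`,
#' `m ddx = m g tan(theta) - c_x dx`.
#'
#' @param m mass (kg)
#' @param I pitch inertia (kg m^2)
#' @param c_x horizontal drag (N s/m)
#' @param c_th rotational damping (N m s/rad)
#' @param th_max pitch-reference clip (rad) of the outer position loop
#' @param u_max pitch torque command saturation (absolute)
#' @return list of parameters with class `plant_params`
#' @export
quad_params <- function(m = 1.2, I = 0.05, c_x = 0.4, c_th = 0.02,
                        th_max = 0.35, u_max = 3) {
  structure(list(kind = "quad", m = m, I = I, c_x = c_x, c_th = c_th,
                 th_max = th_max, u_max = u_max, g = 9.81),
            class = "plant_params")
}

#' Initial plant state
#'
#' All plants start at rest at the origin of their state space.
#'
#' @param params a `plant_params`
#' @return named numeric state vector
#' @export
plant_init_state <- function(params) {
  switch(params$kind,
    dc_motor = c(phi = 0, omega = 0, i = 0),
    robot    = c(phi = 0, dphi = 0, th = 0, dth = 0),
    quad     = c(x = 0, vx = 0, th = 0, dth = 0),
    stop("unknown plant kind: ", params$kind)
  )
}

# Time derivative of the plant state under a held command u.
plant_deriv <- function(params, s, u) {
  switch(params$kind,
    dc_motor = {
      c(s[["omega"]],
        (params$kt * s[["i"]] - params$b * s[["omega"]]) / params$J,
        (u - params$R * s[["i"]] - params$ke * s[["omega"]]) / params$L)
    },
    robot = {
      th <- s[["th"]]; dth <- s[["dth"]]; dphi <- s[["dphi"]]
      tau <- params$km * u
      m11 <- (params$m_w + params$m_b) * params$r^2 + params$I_w
      m12 <- params$m_b * params$r * params$l * cos(th)
      m22 <- params$m_b * params$l^2 + params$I_b
      fr <- params$b_f * (dphi - dth)
      r1 <- tau - fr + params$m_b * params$r * params$l * dth^2 * sin(th)
      r2 <- -tau + fr + params$m_b * params$g * params$l * sin(th)
      det <- m11 * m22 - m12 * m12
      c(dphi,
        (m22 * r1 - m12 * r2) / det,
        dth,
        (m11 * r2 - m12 * r1) / det)
    },
    quad = {
      th <- s[["th"]]
      thc <- max(-1.2, min(1.2, th))  # model valid near hover only
      c(s[["vx"]],
        params$g * tan(thc) - params$c_x / params$m * s[["vx"]],
        s[["dth"]],
        (u - params$c_th * s[["dth"]]) / params$I)
    }
  )
}

#' Integrate a plant over one control period
#'
#' Classical fixed-step RK4 with `n_sub` sub-steps under a zero-order-hold
#' command. Deterministic given (state, command, dt). A non-finite or
#' out-of-range state is reported through the `ok` flag (trial failure),
#' not an exception.
#'
#' @param params a `plant_params`
#' @param state named state vector
#' @param u actuator command (held over dt); saturated at `u_max`
#' @param dt control period (s)
#' @param n_sub RK4 sub-steps per control period
#' @return list(state, ok) where `ok = FALSE` flags divergence or (robot) a
#'   fall past the tilt threshold
#' @export
plant_step <- function(params, state, u, dt = 0.01, n_sub = 10L) {
  stopifnot(dt > 0, is.finite(u))
  u <- max(-params$u_max, min(params$u_max, u))
  h <- dt / n_sub
  s <- state
  for (k in seq_len(n_sub)) {
    k1 <- plant_deriv(params, s, u)
    k2 <- plant_deriv(params, s + h / 2 * k1, u)
    k3 <- plant_deriv(params, s + h / 2 * k2, u)
    k4 <- plant_deriv(params, s + h * k3, u)
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  names(s) <- names(state)
  ok <- all(is.finite(s))
  if (ok && params$kind == "robot" &&
      abs(s[["th"]]) > params$fall_threshold) ok <- FALSE
  list(state = s, ok = ok)
}

#' Default PD controller gains
#'
#' DC motor: shaft position PD (kp = 0.8, kd = 0.01). Robot: parallel body
#' PD (kp = -18.017, kd = -2.511) and wheel PD (kp = -0.553, kd = -0.197)
#' whose outputs add. Quadcopter: a cascade where a horizontal-position PD
#' sets the pitch reference (clipped at `th_max`) and a pitch PD sets the
#' torque command; these inner/outer gains are tuning choices of this
#' implementation.
#'
#' @param plant one of "dc_motor", "robot", "quad"
#' @return named list of gains
#' @export
pd_gains <- function(plant = c("dc_motor", "robot", "quad")) {
  switch(match.arg(plant),
    dc_motor = list(kp = 0.8, kd = 0.01),
    robot    = list(kp_body = -18.017, kd_body = -2.511,
                    kp_wheel = -0.553, kd_wheel = -0.197),
    quad     = list(kp_x = 0.5, kd_x = 0.9, kp_th = 4, kd_th = 0.8)
  )
}

# Pitch reference set by the quadcopter's outer horizontal-position loop.
quad_pitch_ref <- function(params, gains, state, ref) {
  e_x <- ref$pos - state[["x"]]
  e_v <- ref$vel - state[["vx"]]
  max(-params$th_max, min(params$th_max, gains$kp_x * e_x + gains$kd_x * e_v))
}

#' PD baseline command
#'
#' Computes the non-adaptive feedback command for a plant given the current
#' reference (of the tracked variable) and measured state.
#'
#' @param params a `plant_params`
#' @param gains gains as from [pd_gains()]
#' @param state named plant state vector
#' @param ref list(pos, vel) of the tracked variable at the current time
#' @return scalar command (unsaturated)
#' @export
pd_command <- function(params, gains, state, ref) {
  switch(params$kind,
    dc_motor = gains$kp * (ref$pos - state[["phi"]]) +
      gains$kd * (ref$vel - state[["omega"]]),
    robot = {
      gains$kp_body * (0 - state[["th"]]) +
        gains$kd_body * (0 - state[["dth"]]) +
        gains$kp_wheel * (ref$pos - state[["phi"]]) +
        gains$kd_wheel * (ref$vel - state[["dphi"]])
    },
    quad = {
      th_ref <- quad_pitch_ref(params, gains, state, ref)
      gains$kp_th * (th_ref - state[["th"]]) +
        gains$kd_th * (0 - state[["dth"]])
    }
  )
}
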