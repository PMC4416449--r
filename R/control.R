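#' Mossy-fiber channel specification for a plant
#'
#' Each plant exposes a fixed set of signals carried by the mossy fibers,
#' each with a printed scaling gain (units^-1): DC motor - reference shaft
#' position (0.1/rad) and velocity (0.19 per rad/s), shaft position error
#' (0.5/rad), shaft velocity error (0.07 per rad/s), efference copy (1/A);
#' robot - reference wheel position (0.03/rad) and velocity (0.04 per
#' rad/s), body tilt error (1/rad), tilt velocity error (0.5 per rad/s),
#' wheel position error (0.1/rad), wheel velocity error (0.2 per rad/s),
#' efference copy (0.5/A); quadcopter - reference horizontal position
#' (0.05/m), reference pitch (0.5/rad), horizontal position error (0.05/m),
#' pitch error (0.6/rad), horizontal velocity error (0.05 per m/s), pitch
#' velocity error (0.1 per rad/s), efference copy (0.3/A).
#'
#' Because rates must lie in [0, 1] while the signals are signed, every
#' signal feeds two rectified channels (positive and negative polarity) and
#' the MF population is partitioned near-evenly across the
#' (signal x polarity) channels by interleaving. Both hemispheres receive
#' the identical MF vector.
#'
#' @param plant one of "dc_motor", "robot", "quad"
#' @param n_mf number of mossy fibers per hemisphere
#' @return data.frame: fiber, signal (id), signal_name, gain, pol (+1/-1)
#' @export
mf_channels <- function(plant = c("dc_motor", "robot", "quad"),
                        n_mf = default_counts()[["MF"]]) {
  plant <- match.arg(plant)
  sig <- switch(plant,
    dc_motor = data.frame(
      signal_name = c("ref_shaft_pos", "ref_shaft_vel", "shaft_pos_error",
                      "shaft_vel_error", "efference_copy"),
      gain = c(0.1, 0.19, 0.5, 0.07, 1)),
    robot = data.frame(
      signal_name = c("ref_wheel_pos", "ref_wheel_vel", "tilt_pos_error",
                      "tilt_vel_error", "wheel_pos_error",
                      "wheel_vel_error", "efference_copy"),
      gain = c(0.03, 0.04, 1, 0.5, 0.1, 0.2, 0.5)),
    quad = data.frame(
      signal_name = c("ref_hor_pos", "ref_pitch_pos", "hor_pos_error",
                      "pitch_error", "hor_vel_error", "pitch_vel_error",
                      "efference_copy"),
      gain = c(0.05, 0.5, 0.05, 0.6, 0.05, 0.1, 0.3))
  )
  n_ch <- 2L * nrow(sig)
  fiber <- seq_len(n_mf)
  ch <- (fiber - 1L) %% n_ch + 1L          # interleaved near-even partition
  signal <- (ch - 1L) %/% 2L + 1L
  pol <- ifelse(ch %% 2L == 1L, 1, -1)
  data.frame(fiber = fiber, signal = signal,
             signal_name = sig$signal_name[signal],
             gain = sig$gain[signal], pol = pol)
}

#' Encode plant signals onto mossy-fiber rates
#'
#' `rate = clip(pol * gain * signal, 0, 1)` per fiber.
#'
#' @param signals numeric vector of the plant's signal values, in the order
#'   of the channel table's signal ids
#' @param channels channel table from [mf_channels()]
#' @return MF rate vector (one entry per fiber)
#' @export
encode_mf <- function(signals, channels) {
  n_sig <- max(channels$signal)
  if (length(signals) != n_sig) {
    stop("configuration error: expected ", n_sig, " signals (",
         paste(unique(channels$signal_name), collapse = ", "),
         "), got ", length(signals))
  }
  if (any(!is.finite(signals))) {
    stop("configuration error: non-finite signal value")
  }
  pmin(1, pmax(0, channels$pol * channels$gain * signals[channels$signal]))
}

#' Closed-loop control configuration
#'
#' Bundles the control period, cerebellar output gain, CF encoding gains and
#' plasticity constants for one plant. The cerebellar gain `g_cb` scales the
#' combined PC output (in [-1, 1]) to actuator units and is sized per plant
#' near the peak command the PD controller produces on the default task; the
#' CF gain `g_pref` maps the plant's typical peak error to a CF rate around
#' 0.5 above spontaneous.
#'
#' @param plant one of "dc_motor", "robot", "quad"
#' @param dt control period (s), default 0.01
#' @param n_sub RK4 sub-steps per control period
#' @param g_cb cerebellar output gain (actuator units)
#' @param g_pref,g_np CF encoding gains (per rad or per m of error)
#' @param plast plasticity parameters from [plasticity_params()]
#' @param noise_sd sd of additive Gaussian sensor noise (state units);
#'   0 disables (noiseless simulation mode, the default)
#' @param noise_seed seed for the sensor-noise stream
#' @return list of class `control_config`
#' @export
control_config <- function(plant = c("dc_motor", "robot", "quad"),
                           dt = 0.01, n_sub = 10L,
                           g_cb = NULL, g_pref = NULL, g_np = NULL,
                           plast = plasticity_params(),
                           noise_sd = 0, noise_seed = 1L) {
  plant <- match.arg(plant)
  defaults <- switch(plant,
    dc_motor = list(g_cb = 20, g_pref = 1.0),
    robot    = list(g_cb = 2.0, g_pref = 0.5),
    quad     = list(g_cb = 2.0, g_pref = 1.5))
  if (is.null(g_cb)) g_cb <- defaults$g_cb
  if (is.null(g_pref)) g_pref <- defaults$g_pref
  if (is.null(g_np)) g_np <- g_pref / 10
  stopifnot(dt > 0, n_sub >= 1, g_pref > 0, g_np > 0, noise_sd >= 0)
  structure(list(plant = plant, dt = dt, n_sub = as.integer(n_sub),
                 g_cb = g_cb, g_pref = g_pref, g_np = g_np, plast = plast,
                 noise_sd = noise_sd, noise_seed = as.integer(noise_seed)),
            class = "control_config")
}

# Signal vector, CF error and controlled variable for one plant at one step.
plant_signals <- function(params, gains, state, ref, u_prev) {
  switch(params$kind,
    dc_motor = list(
      signals = c(ref$pos, ref$vel, ref$pos - state[["phi"]],
                  ref$vel - state[["omega"]], u_prev),
      cf_error = ref$pos - state[["phi"]],
      controlled = state[["phi"]]),
    robot = list(
      signals = c(ref$pos, ref$vel, -state[["th"]], -state[["dth"]],
                  ref$pos - state[["phi"]], ref$vel - state[["dphi"]],
                  u_prev),
      cf_error = ref$pos - state[["phi"]],
      controlled = state[["phi"]]),
    quad = {
      th_ref <- quad_pitch_ref(params, gains, state, ref)
      list(signals = c(ref$pos, th_ref, ref$pos - state[["x"]],
                       th_ref - state[["th"]], ref$vel - state[["vx"]],
                       -state[["dth"]], u_prev),
           cf_error = ref$pos - state[["x"]],
           controlled = state[["x"]])
    }
  )
}

#' Advance the closed loop by one control step (reference implementation)
#'
#' Order within a step: read sensors, compute errors against the reference,
#' encode MF rates (the efference copy is the previous step's command),
#' advance both hemispheres, encode the CF pair from the designated error
#' signal, apply plasticity, form the command `u = u_pd + g_cb * output`,
#' and integrate the plant over `dt`. This pure-R path defines the
#' semantics; [run_trial()] uses a compiled equivalent by default.
#'
#' @param loop state bundle as produced by [init_loop()]
#' @param t current time (s)
#' @return the updated loop bundle, with fields `row` (the step's trace) and
#'   `ok`
#' @export
run_step <- function(loop, t) {
  cfg <- loop$config
  ref <- reference(loop$traj, t - loop$t_offset)
  ps <- plant_signals(loop$params, loop$gains, loop$state, ref, loop$u_prev)
  u_pd <- pd_command(loop$params, loop$gains, loop$state, ref)
  if (loop$pd_only) {
    out <- 0; cf <- list(cf_left = NA_real_, cf_right = NA_real_)
  } else {
    mf <- encode_mf(ps$signals, loop$channels)
    loop$sl <- step_hemisphere(loop$model$left, loop$sl, mf)
    loop$sr <- step_hemisphere(loop$model$right, loop$sr, mf)
    cf <- encode_cf(ps$cf_error, cfg$plast, cfg$g_pref, cfg$g_np)
    if (loop$plast_on) {
      loop$model$left$syn$pf_pc$w[1, ] <- update_pf_pc(
        loop$model$left$syn$pf_pc$w[1, ],
        loop$sl$y_gc[loop$model$left$syn$pf_pc$conn[1, ]],
        cf$cf_left, cfg$plast)
      loop$model$right$syn$pf_pc$w[1, ] <- update_pf_pc(
        loop$model$right$syn$pf_pc$w[1, ],
        loop$sr$y_gc[loop$model$right$syn$pf_pc$conn[1, ]],
        cf$cf_right, cfg$plast)
    }
    out <- combine_hemispheres(loop$sl$y_pc, loop$sr$y_pc)
  }
  u <- u_pd + cfg$g_cb * out
  u_sat <- max(-loop$params$u_max, min(loop$params$u_max, u))
  st <- plant_step(loop$params, loop$state, u_sat, cfg$dt, cfg$n_sub)
  loop$row <- data.frame(
    t = t, ref = ref$pos, y = ps$controlled, u_pd = u_pd,
    u_cb = cfg$g_cb * out, u = u_sat,
    cf_left = cf$cf_left, cf_right = cf$cf_right,
    y_pc_l = if (loop$pd_only) NA_real_ else loop$sl$y_pc,
    y_pc_r = if (loop$pd_only) NA_real_ else loop$sr$y_pc)
  loop$state <- st$state
  loop$ok <- st$ok
  loop$u_prev <- u_sat
  loop
}

#' Initialize a closed-loop state bundle
#'
#' @param model a `bicnn_model` (may be NULL when `pd_only`)
#' @param params a `plant_params`
#' @param config a `control_config`
#' @param traj a `trajectory_spec`
#' @param gains PD gains, default [pd_gains()] for the plant
#' @param pd_only disable the cerebellar pathway entirely
#' @param plast_on apply plasticity each step
#' @return a loop bundle consumed by [run_step()]
#' @export
init_loop <- function(model, params, config, traj,
                      gains = pd_gains(params$kind),
                      pd_only = FALSE, plast_on = TRUE) {
  list(model = model, params = params, config = config, traj = traj,
       gains = gains, channels = if (pd_only) NULL else
         mf_channels(params$kind, model$left$counts[["MF"]]),
       state = plant_init_state(params),
       sl = if (pd_only) NULL else hemisphere_state(model$left),
       sr = if (pd_only) NULL else hemisphere_state(model$right),
       u_prev = 0, t_offset = 0, pd_only = pd_only, plast_on = plast_on,
       ok = TRUE)
}

#' Run a closed-loop trial over repeated cycles
#'
#' Repeats the desired motion for `n_cycles` periods, optionally switching
#' to a second trajectory at a given cycle boundary (the switched
#' trajectory restarts at phase zero). Computes the cycle-wise root mean
#' square error of the controlled variable, flags falls/divergence, and can
#' record per-cycle PF-PC weight snapshots for both hemispheres.
#'
#' @inheritParams init_loop
#' @param n_cycles number of reference cycles (>= 1)
#' @param traj2,switch_cycle optional second trajectory entered after
#'   `switch_cycle` completed cycles
#' @param record_traces keep the full per-step trace table
#' @param record_weights keep per-cycle PF-PC weight snapshots
#' @param engine "cpp" (compiled, default) or "r" (reference)
#' @return an object of class `trial_record`: list(cycles, trace, fallen,
#'   fall_step, model, weights_left, weights_right, config echo)
#' @export
run_trial <- function(model, params, config, traj, n_cycles,
                      gains = pd_gains(params$kind),
                      traj2 = NULL, switch_cycle = NULL,
                      pd_only = FALSE, plast_on = TRUE,
                      record_traces = TRUE, record_weights = FALSE,
                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(n_cycles >= 1)
  if (!is.null(traj2) && is.null(switch_cycle)) {
    stop("switch_cycle required with traj2")
  }
  if (engine == "cpp") {
    return(run_trial_cpp(model, params, config, traj, n_cycles, gains,
                         traj2, switch_cycle, pd_only, plast_on,
                         record_traces, record_weights))
  }
  dt <- config$dt
  spc1 <- as.integer(round(traj$period / dt))
  n_sw <- if (is.null(switch_cycle)) n_cycles else switch_cycle
  spc2 <- if (is.null(traj2)) spc1 else as.integer(round(traj2$period / dt))
  cycle_len <- c(rep(spc1, n_sw), rep(spc2, n_cycles - n_sw))
  n_steps <- sum(cycle_len)
  cycle_of <- rep(seq_len(n_cycles), cycle_len)
  switch_step <- if (is.null(traj2)) NA_integer_ else n_sw * spc1
  loop <- init_loop(model, params, config, traj, gains, pd_only, plast_on)
  rows <- vector("list", if (record_traces) n_steps else 0L)
  sq <- numeric(n_cycles); cnt <- integer(n_cycles)
  wl <- if (record_weights) matrix(NA_real_, n_cycles,
                                   model$left$counts[["GC"]]) else NULL
  wr <- if (record_weights) matrix(NA_real_, n_cycles,
                                   model$right$counts[["GC"]]) else NULL
  fallen <- FALSE; fall_step <- NA_integer_
  for (k in seq_len(n_steps)) {
    if (!is.na(switch_step) && k == switch_step + 1L) {
      loop$traj <- traj2
      loop$t_offset <- switch_step * dt
    }
    t <- (k - 1L) * dt
    loop <- run_step(loop, t)
    cyc <- cycle_of[k]
    e <- loop$row$ref - loop$row$y
    sq[cyc] <- sq[cyc] + e * e
    cnt[cyc] <- cnt[cyc] + 1L
    if (record_traces) rows[[k]] <- loop$row
    if (record_weights && !pd_only &&
        (k == n_steps || cycle_of[k + 1L] != cyc)) {
      wl[cyc, loop$model$left$syn$pf_pc$conn[1, ]] <-
        loop$model$left$syn$pf_pc$w[1, ]
      wr[cyc, loop$model$right$syn$pf_pc$conn[1, ]] <-
        loop$model$right$syn$pf_pc$w[1, ]
    }
    if (!loop$ok) { fallen <- TRUE; fall_step <- k; break }
  }
  done <- if (fallen) cycle_of[fall_step] - 1L else n_cycles
  cycles <- data.frame(cycle = seq_len(n_cycles),
                       rse = ifelse(cnt > 0, sqrt(sq / pmax(cnt, 1L)),
                                    NA_real_),
                       complete = seq_len(n_cycles) <= done)
  cycles$rse[!cycles$complete] <- NA_real_
  structure(list(
    cycles = cycles,
    trace = if (record_traces) do.call(rbind, rows[!vapply(rows, is.null,
                                                           TRUE)]) else NULL,
    fallen = fallen, fall_step = fall_step,
    model = if (pd_only) NULL else loop$model,
    weights_left = wl, weights_right = wr,
    n_cycles = n_cycles, plant = params$kind), class = "trial_record")
}
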