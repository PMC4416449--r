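# Flatten a hemisphere into the target-major arrays consumed by the
# compiled trial driver. Connectivity is converted to 0-based indices.
# GC-originating projections are compressed to active-source edges only:
# a knocked-down GC's rate is exactly 0, so the dropped terms contribute
# exactly 0.0 to every drive sum and results are bit-identical.
pack_hemisphere <- function(net) {
  pk <- list()
  for (p in c("mf_go", "bc_go", "mf_gc", "go_gc", "pc_bc", "bc_pc",
              "pf_pc")) {
    g <- net$syn[[p]]
    pk[[p]] <- list(nt = nrow(g$conn), f = ncol(g$conn),
                    idx = as.integer(t(g$conn)) - 1L,
                    w = as.numeric(t(g$w)))
  }
  for (p in c("pf_go", "pf_bc")) {
    g <- net$syn[[p]]
    keep <- matrix(net$active[g$conn], nrow = nrow(g$conn))
    # row-major (per-target) filtered edge list
    tk <- t(keep); tc <- t(g$conn); tw <- t(g$w)
    sel <- as.vector(tk)
    pk[[paste0(p, "_csr")]] <- list(
      nt = nrow(g$conn),
      ptr = as.integer(c(0L, cumsum(rowSums(keep)))),
      idx = as.integer(tc[sel]) - 1L,
      w = as.numeric(tw[sel]))
  }
  pk$counts <- as.integer(net$counts[c("MF", "GO", "GC", "BC", "PC")])
  pk$comp <- net$comp_scale
  pk$sigma <- net$sigma
  pk$mu <- net$mu
  pk$act_idx <- which(net$active) - 1L
  pk$act_pos <- which(net$active[net$syn$pf_pc$conn[1, ]]) - 1L
  pk
}

plant_id <- function(kind) {
  switch(kind, dc_motor = 1L, robot = 2L, quad = 3L,
         stop("unknown plant kind: ", kind))
}

plant_par_vec <- function(params) {
  switch(params$kind,
    dc_motor = c(params$J, params$b, params$kt, params$ke, params$R,
                 params$L),
    robot = c(params$m_b, params$m_w, params$l, params$r, params$I_b,
              params$I_w, params$b_f, params$km, params$g),
    quad = c(params$m, params$I, params$c_x, params$c_th, params$th_max,
             params$g))
}

pd_vec <- function(kind, gains) {
  switch(kind,
    dc_motor = c(gains$kp, gains$kd),
    robot = c(gains$kp_body, gains$kd_body, gains$kp_wheel, gains$kd_wheel),
    quad = c(gains$kp_x, gains$kd_x, gains$kp_th, gains$kd_th))
}

# Compiled-engine implementation behind run_trial(engine = "cpp").
run_trial_cpp <- function(model, params, config, traj, n_cycles, gains,
                          traj2, switch_cycle, pd_only, plast_on,
                          record_traces, record_weights) {
  if (!pd_only && model$left$counts[["PC"]] != 1L) {
    stop("the compiled engine supports one PC per hemisphere; ",
         "use engine = 'r' for multi-PC configurations")
  }
  dt <- config$dt
  spc1 <- as.integer(round(traj$period / dt))
  n_sw <- if (is.null(switch_cycle)) n_cycles else as.integer(switch_cycle)
  spc2 <- if (is.null(traj2)) spc1 else as.integer(round(traj2$period / dt))
  cycle_len <- c(rep(spc1, n_sw), rep(spc2, n_cycles - n_sw))
  n_steps <- sum(cycle_len)
  cycle_of <- rep(seq_len(n_cycles), cycle_len)
  switch_step <- if (is.null(traj2)) 0L else n_sw * spc1

  channels <- mf_channels(params$kind,
                          if (pd_only) default_counts()[["MF"]]
                          else model$left$counts[["MF"]])
  gain_per_sig <- channels$gain[match(seq_len(max(channels$signal)),
                                      channels$signal)]
  mfspec <- list(sig = channels$signal - 1L, pol = channels$pol,
                 gain = gain_per_sig)
  cfspec <- list(g_pref = config$g_pref, g_np = config$g_np,
                 gamma_ltd = config$plast$gamma_ltd,
                 gamma_ltp = config$plast$gamma_ltp,
                 cf_spont = config$plast$cf_spont)
  ctrl <- list(dt = dt, n_sub = config$n_sub, g_cb = config$g_cb,
               n_steps = n_steps, n_cycles = as.integer(n_cycles),
               cycle_of = cycle_of, switch_step = switch_step,
               record_traces = record_traces,
               record_weights = record_weights,
               pd_only = pd_only, plast_on = plast_on)
  t2 <- if (is.null(traj2)) list() else
    list(amp = traj2$amp, freq = traj2$freq, phase = traj2$phase)
  packL <- if (pd_only) list() else pack_hemisphere(model$left)
  packR <- if (pd_only) list() else pack_hemisphere(model$right)
  fall_thr <- if (params$kind == "robot") params$fall_threshold else Inf

  res <- cpp_run_trial(packL, packR, plant_id(params$kind),
                       plant_par_vec(params), plant_init_state(params),
                       params$u_max, fall_thr,
                       pd_vec(params$kind, gains), mfspec, cfspec, ctrl,
                       list(amp = traj$amp, freq = traj$freq,
                            phase = traj$phase), t2)

  cycles <- data.frame(cycle = seq_len(n_cycles), rse = res$rse,
                       complete = res$complete)
  trace <- NULL
  if (record_traces) {
    m <- res$trace[seq_len(res$done_steps), , drop = FALSE]
    trace <- as.data.frame(m)
    names(trace) <- c("t", "ref", "y", "u_pd", "u_cb", "u",
                      "cf_left", "cf_right", "y_pc_l", "y_pc_r")
  }
  if (!pd_only) {
    model$left$syn$pf_pc$w[1, ] <- res$wL
    model$right$syn$pf_pc$w[1, ] <- res$wR
  }
  structure(list(
    cycles = cycles, trace = trace,
    fallen = res$fallen,
    fall_step = if (res$fallen) res$fall_step else NA_integer_,
    model = if (pd_only) NULL else model,
    weights_left = if (record_weights && !pd_only) res$snapL else NULL,
    weights_right = if (record_weights && !pd_only) res$snapR else NULL,
    n_cycles = n_cycles, plant = params$kind), class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  done <- sum(x$cycles$complete)
  cat("<trial_record>", x$plant, ":", done, "/", x$n_cycles,
      "cycles", if (x$fallen) sprintf("(FALLEN at step %d)", x$fall_step)
      else "", "\n")
  if (done > 0) {
    cat("  RSE first:", format(x$cycles$rse[1], digits = 4),
        " last:", format(x$cycles$rse[done], digits = 4), "\n")
  }
  invisible(x)
}
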