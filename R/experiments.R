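#' Cycle-wise root mean square error
#'
#' `sqrt(mean((ref - actual)^2))` over one cycle's samples, in the units of
#' the controlled variable.
#'
#' @param ref,actual equal-length numeric traces covering one cycle
#' @return nonnegative scalar
#' @export
rse <- function(ref, actual) {
  if (length(ref) == 0L || length(ref) != length(actual)) {
    stop("rse: traces must be non-empty and of equal length")
  }
  sqrt(mean((ref - actual)^2))
}

#' Knockdown experiment configuration
#'
#' The full protocol: twelve GC sizes (4, 10, 20, 40, 80, 200, 400, 800,
#' 1000, 1600, 2000, 4000), five random synaptic-weight sets crossed with
#' five random connectivity tables (5 x 5 = 25 initial-condition
#' permutations, hence 25 x 12 = 300 runs per control object), at least 100
#' cycles per trial (robot/quadcopter; 180+ for the DC motor whose cycle is
#' shorter), with the untrained window at cycles #5-6 and the trained
#' window at cycles #90-91 (robot/quad) or #180-181 (DC motor). Reduced
#' grids for desk-scale work rescale the windows proportionally.
#'
#' @param plant one of "dc_motor", "robot", "quad"
#' @param gc_sizes ordered GC counts to sweep
#' @param n_weight_sets,n_net_tables factorial arms (default 5 x 5)
#' @param n_cycles cycles per trial (default 182 DC motor, 100 otherwise)
#' @param untrained_window,trained_window 2-cycle windows for the box
#'   statistics; defaults follow the protocol, scaled when `n_cycles` is
#'   reduced
#' @return list of class `experiment_config`
#' @export
experiment_config <- function(plant = c("dc_motor", "robot", "quad"),
                              gc_sizes = c(4, 10, 20, 40, 80, 200, 400,
                                           800, 1000, 1600, 2000, 4000),
                              n_weight_sets = 5L, n_net_tables = 5L,
                              n_cycles = NULL,
                              untrained_window = NULL,
                              trained_window = NULL) {
  plant <- match.arg(plant)
  full_cycles <- if (plant == "dc_motor") 182L else 100L
  full_trained <- if (plant == "dc_motor") c(180L, 181L) else c(90L, 91L)
  if (is.null(n_cycles)) n_cycles <- full_cycles
  n_cycles <- as.integer(n_cycles)
  if (is.null(untrained_window)) {
    untrained_window <- if (n_cycles >= 6L) c(5L, 6L) else
      c(1L, min(2L, n_cycles))
  }
  if (is.null(trained_window)) {
    trained_window <- if (n_cycles >= full_trained[2]) full_trained else
      c(n_cycles - 1L, n_cycles)
  }
  stopifnot(n_cycles >= trained_window[2],
            untrained_window[1] >= 1L, n_weight_sets >= 1L,
            n_net_tables >= 1L, length(gc_sizes) >= 1L)
  structure(list(plant = plant, gc_sizes = as.integer(gc_sizes),
                 n_weight_sets = as.integer(n_weight_sets),
                 n_net_tables = as.integer(n_net_tables),
                 n_cycles = n_cycles,
                 untrained_window = as.integer(untrained_window),
                 trained_window = as.integer(trained_window),
                 n_permutations = as.integer(n_weight_sets * n_net_tables),
                 n_runs = as.integer(n_weight_sets * n_net_tables *
                                       length(gc_sizes))),
            class = "experiment_config")
}

#' Sweep granule-cell knockdown across seeded initial conditions
#'
#' Builds `n_net_tables` connectivity tables (Net #1..k; fresh placement
#' and wiring per Net) crossed with `n_weight_sets` weight draws, knocks
#' each model down to every GC size, and runs the closed-loop task. A
#' falling or diverging trial is recorded and the sweep continues. The
#' expensive network construction is shared: each Net is placed and wired
#' once and re-weighted per weight set.
#'
#' @param exp_cfg an `experiment_config`
#' @param base_seed integer master seed; every Net, weight set and
#'   knockdown mask derives its own child stream from it
#' @param params plant parameters (default per plant)
#' @param config control configuration (default per plant)
#' @param counts per-hemisphere population counts
#' @param progress print one line per trial
#' @return list(results, pd): `results` is a tidy per-cycle table (gc_size,
#'   net, wset, cycle, rse, complete, fallen); `pd` is the matching
#'   PD-only cycle table
#' @export
gc_sweep <- function(exp_cfg, base_seed = 1L,
                     params = NULL, config = NULL,
                     counts = default_counts(), progress = FALSE) {
  plant <- exp_cfg$plant
  if (is.null(params)) {
    params <- switch(plant, dc_motor = dc_motor_params(),
                     robot = robot_params(), quad = quad_params())
  }
  if (is.null(config)) config <- control_config(plant)
  traj <- default_trajectory(plant)
  out <- vector("list", exp_cfg$n_runs)
  i <- 0L
  for (net_id in seq_len(exp_cfg$n_net_tables)) {
    net_seed <- derive_seed(base_seed, 1000L + net_id)
    for (wset in seq_len(exp_cfg$n_weight_sets)) {
      w_seed <- derive_seed(base_seed, 2000L + wset)
      model <- build_bicnn(counts,
                           seeds = list(placement = net_seed,
                                        connectivity = net_seed,
                                        weights = w_seed))
      for (gc_size in exp_cfg$gc_sizes) {
        i <- i + 1L
        kd_seed <- derive_seed(base_seed,
                               3000L + net_id * 101L + wset * 13L +
                                 as.integer(gc_size %% 997L))
        m <- knockdown_bicnn(model, gc_size, seed = kd_seed)
        tr <- run_trial(m, params, config, traj, exp_cfg$n_cycles,
                        record_traces = FALSE, record_weights = FALSE)
        out[[i]] <- data.frame(
          gc_size = gc_size, net = net_id, wset = wset,
          cycle = tr$cycles$cycle, rse = tr$cycles$rse,
          complete = tr$cycles$complete, fallen = tr$fallen)
        if (progress) {
          message(sprintf("net %d wset %d gc %4d : %s", net_id, wset,
                          gc_size,
                          if (tr$fallen) "FALLEN" else
                            sprintf("final RSE %.3f",
                                    tr$cycles$rse[sum(tr$cycles$complete)])))
        }
      }
    }
  }
  pd_tr <- run_trial(NULL, params, config, traj, exp_cfg$n_cycles,
                     pd_only = TRUE, record_traces = FALSE)
  pd <- data.frame(cycle = pd_tr$cycles$cycle, rse = pd_tr$cycles$rse,
                   complete = pd_tr$cycles$complete, fallen = pd_tr$fallen)
  list(results = do.call(rbind, out), pd = pd, config = exp_cfg)
}

# Pool a 2-cycle window of RSE values per (gc_size, net, wset).
pool_window <- function(results, window) {
  sub <- results[results$cycle %in% seq(window[1], window[2]) &
                   results$complete, , drop = FALSE]
  sub
}

#' Untrained vs trained box-plot statistics
#'
#' For every GC size, pools the RSE of the untrained and trained 2-cycle
#' windows over all initial-condition permutations (25 permutations x 2
#' cycles = 50 data points per box on the full grid) and reports median and
#' quartiles (linear-interpolation quantiles, type 7), plus the PD-only
#' reference. Fallen trials are excluded from the boxes and counted.
#'
#' @param sweep result of [gc_sweep()]
#' @return data.frame: gc_size (NA for the PD row), phase
#'   ("untrained"/"trained"/"pd"), n, n_fallen, q25, median, q75
#' @export
trained_vs_untrained <- function(sweep) {
  cfg <- sweep$config
  rows <- list()
  box <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), type = 7,
                                     names = FALSE)
  for (gs in cfg$gc_sizes) {
    sub <- sweep$results[sweep$results$gc_size == gs, , drop = FALSE]
    n_fallen <- length(unique(paste(sub$net, sub$wset)[sub$fallen]))
    for (phase in c("untrained", "trained")) {
      w <- if (phase == "untrained") cfg$untrained_window else
        cfg$trained_window
      vals <- pool_window(sub, w)$rse
      vals <- vals[is.finite(vals)]
      q <- if (length(vals) > 0) box(vals) else rep(NA_real_, 3L)
      rows[[length(rows) + 1L]] <- data.frame(
        gc_size = gs, phase = phase, n = length(vals),
        n_fallen = n_fallen, q25 = q[1], median = q[2], q75 = q[3])
    }
  }
  pv <- pool_window(sweep$pd, cfg$trained_window)$rse
  pv <- pv[is.finite(pv)]
  q <- if (length(pv) > 0) box(pv) else rep(NA_real_, 3L)
  rows[[length(rows) + 1L]] <- data.frame(
    gc_size = NA_integer_, phase = "pd", n = length(pv),
    n_fallen = sum(sweep$pd$fallen[1]), q25 = q[1], median = q[2],
    q75 = q[3])
  do.call(rbind, rows)
}

#' One-way ANOVA: trained model vs PD-only
#'
#' Standard one-way fixed-effects ANOVA comparing trained-window RSE
#' samples against PD-only RSE samples, as used for the per-size
#' significance asterisks (alpha = 0.05, no multiplicity correction).
#' Degenerate input (zero variance in both groups with equal means)
#' returns F = 0, p = 1.
#'
#' @param trained,pd_only numeric RSE samples (>= 2 each)
#' @param alpha significance level for the flag
#' @return list(F, p, significant, df)
#' @export
anova_pd_vs_bicnn <- function(trained, pd_only, alpha = 0.05) {
  trained <- trained[is.finite(trained)]
  pd_only <- pd_only[is.finite(pd_only)]
  if (length(trained) < 2L || length(pd_only) < 2L) {
    stop("need at least 2 finite values per group")
  }
  x <- c(trained, pd_only)
  g <- factor(rep(c("bicnn", "pd"), c(length(trained), length(pd_only))))
  if (stats::var(x) == 0) {
    return(list(F = 0, p = 1, significant = FALSE,
                df = c(1L, length(x) - 2L)))
  }
  fit <- stats::aov(x ~ g)
  s <- summary(fit)[[1]]
  Fv <- s[["F value"]][1]
  p <- s[["Pr(>F)"]][1]
  list(F = unname(Fv), p = unname(p), significant = is.finite(p) &&
         p < alpha, df = unname(s[["Df"]]))
}

#' Decompose performance variability into connectivity and weight parts
#'
#' Groups the sweep by connectivity table (Net #1..k): for each Net and GC
#' size, the mean final-window RSE over the weight sets (bar height) and
#' their standard deviation (error bar). Spread across Net means reflects
#' connectivity-induced variability; the error bars reflect weight-induced
#' variability. Fallen runs are excluded from the moments and counted.
#'
#' @param sweep result of [gc_sweep()]
#' @return data.frame: net, gc_size, n, n_fallen, mean_rse, sd_rse
#' @export
variability_decomposition <- function(sweep) {
  cfg <- sweep$config
  w <- cfg$trained_window
  rows <- list()
  for (net_id in seq_len(cfg$n_net_tables)) {
    for (gs in cfg$gc_sizes) {
      sub <- sweep$results[sweep$results$net == net_id &
                             sweep$results$gc_size == gs, , drop = FALSE]
      n_fallen <- length(unique(sub$wset[sub$fallen]))
      per_w <- vapply(sort(unique(sub$wset)), function(ws) {
        v <- pool_window(sub[sub$wset == ws & !sub$fallen, , drop = FALSE],
                         w)$rse
        if (length(v) == 0) NA_real_ else mean(v)
      }, numeric(1))
      per_w <- per_w[is.finite(per_w)]
      rows[[length(rows) + 1L]] <- data.frame(
        net = net_id, gc_size = gs, n = length(per_w),
        n_fallen = n_fallen,
        mean_rse = if (length(per_w) > 0) mean(per_w) else NA_real_,
        sd_rse = if (length(per_w) > 1) stats::sd(per_w) else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Rank granule cells by PF-PC weight and analyse their input patterns
#'
#' Sorts the GCs of one hemisphere from largest to smallest PF-PC weight at
#' a chosen cycle, classifies each GC as net-potentiated or net-depressed
#' relative to its initial weight, and, for a chosen reference rank,
#' enumerates every GC sharing that GC's exact 4-signal MF input pattern
#' together with each such GC's 4 Golgi afferents.
#'
#' @param trial a `trial_record` produced with `record_weights = TRUE`
#' @param net the `hemisphere_net` the trial used (for connectivity)
#' @param channels MF channel table from [mf_channels()]
#' @param cycle cycle index of the weight snapshot to rank on
#' @param reference_rank rank whose MF pattern is matched (default 4)
#' @param hemisphere "right" or "left"
#' @return list(ranking, pattern_sharers): `ranking` is a data.frame
#'   (gc, weight, initial_weight, rank, direction); `pattern_sharers` has
#'   one row per GC sharing the reference pattern with its GO afferents
#' @export
best_gc_analysis <- function(trial, net, channels, cycle,
                             reference_rank = 4L,
                             hemisphere = c("right", "left")) {
  hemisphere <- match.arg(hemisphere)
  snaps <- if (hemisphere == "right") trial$weights_right else
    trial$weights_left
  if (is.null(snaps)) stop("trial was run without record_weights")
  if (cycle < 1L || cycle > nrow(snaps)) {
    stop("cycle ", cycle, " outside recorded history (1..", nrow(snaps),
         ")")
  }
  w_cyc <- snaps[cycle, ]
  active <- which(net$active)
  # initial weights in GC order
  w0 <- numeric(net$counts[["GC"]])
  w0[net$syn$pf_pc$conn[1, ]] <- net$syn$pf_pc$raw[1, ] * net$syn$pf_pc$d
  ord <- order(-w_cyc[active], active)
  ranking <- data.frame(
    gc = active[ord], weight = w_cyc[active][ord],
    initial_weight = w0[active][ord],
    rank = seq_along(active))
  ranking$direction <- ifelse(ranking$weight >= ranking$initial_weight,
                              "potentiated", "depressed")
  ref_gc <- ranking$gc[reference_rank]
  mf_sig <- matrix(channels$signal[net$syn$mf_gc$conn],
                   nrow = nrow(net$syn$mf_gc$conn))
  pat <- function(g) paste(sort(mf_sig[g, ]), collapse = "-")
  ref_pat <- pat(ref_gc)
  sharers <- active[vapply(active, function(g) pat(g) == ref_pat,
                           logical(1))]
  ps <- do.call(rbind, lapply(sharers, function(g) {
    data.frame(gc = g, mf_pattern = ref_pat,
               go_inputs = paste(sort(net$syn$go_gc$conn[g, ]),
                                 collapse = "-"),
               weight = w_cyc[g],
               direction = if (w_cyc[g] >= w0[g]) "potentiated" else
                 "depressed")
  }))
  list(ranking = ranking, pattern_sharers = ps, reference_gc = ref_gc)
}
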