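test_that("MF channels partition fibers near-evenly over signal x polarity", {
  for (plant in c("dc_motor", "robot", "quad")) {
    ch <- mf_channels(plant, 257)
    n_sig <- if (plant == "dc_motor") 5L else 7L
    expect_equal(max(ch$signal), n_sig)
    expect_equal(nrow(ch), 257L)
    # every fiber maps to exactly one (signal, polarity) pair
    expect_equal(anyDuplicated(ch$fiber), 0L)
    counts <- table(paste(ch$signal, ch$pol))
    expect_lte(max(counts) - min(counts), 1L)   # near-even split
  }
})

test_that("MF encoding applies the printed scaling gains with rectification", {
  ch <- mf_channels("dc_motor", 20)
  # reference shaft angle pi with gain 0.1 -> rate 0.314 on + channels
  sig <- c(pi, 0, 0, 0, 0)
  r <- encode_mf(sig, ch)
  pos <- ch$signal == 1 & ch$pol == 1
  neg <- ch$signal == 1 & ch$pol == -1
  expect_equal(unique(r[pos]), 0.1 * pi)
  expect_equal(round(unique(r[pos]), 3), 0.314)
  expect_equal(unique(r[neg]), 0)
  # all-zero signals encode silence
  expect_true(all(encode_mf(rep(0, 5), ch) == 0))
  # rates clipped into [0, 1]
  r2 <- encode_mf(c(0, 99, -99, 0, 0), ch)
  expect_true(all(r2 >= 0 & r2 <= 1))
  # missing signal -> configuration error naming the expectation
  expect_error(encode_mf(c(1, 2), ch), "expected 5 signals")
})

test_that("a DC-motor cycle at 10 ms and 0.5 Hz spans 200 control steps", {
  model <- tiny_model(2L)
  cfg <- control_config("dc_motor")
  tr <- run_trial(model, dc_motor_params(), cfg,
                  default_trajectory("dc_motor"), 1, record_traces = TRUE)
  expect_equal(nrow(tr$trace), 200L)
  expect_equal(nrow(tr$cycles), 1L)
})

test_that("disabling the cerebellar gain reproduces the PD-only trace bit-exactly", {
  model <- tiny_model(4L)
  p <- dc_motor_params()
  cfg <- control_config("dc_motor", g_cb = 0)
  traj <- default_trajectory("dc_motor")
  with_net <- run_trial(model, p, cfg, traj, 2, plast_on = FALSE,
                        record_traces = TRUE)
  pd <- run_trial(NULL, p, cfg, traj, 2, pd_only = TRUE,
                  record_traces = TRUE)
  expect_identical(with_net$trace$y, pd$trace$y)
  expect_identical(with_net$trace$u, pd$trace$u)
  expect_identical(with_net$cycles$rse, pd$cycles$rse)
})

test_that("mirrored untrained hemispheres cancel: u is the PD command at t=0", {
  model <- tiny_model(6L, mirror = TRUE)
  cfg <- control_config("dc_motor")
  loop <- init_loop(model, dc_motor_params(), cfg,
                    default_trajectory("dc_motor"))
  loop <- run_step(loop, 0)
  expect_equal(loop$row$u_cb, 0)
  expect_equal(loop$row$u, loop$row$u_pd)
})

test_that("the efference copy lags the issued command by one step", {
  model <- tiny_model(7L)
  cfg <- control_config("dc_motor")
  loop <- init_loop(model, dc_motor_params(), cfg,
                    default_trajectory("dc_motor"))
  expect_equal(loop$u_prev, 0)
  us <- numeric(5); prevs <- numeric(5)
  for (k in 1:5) {
    prevs[k] <- loop$u_prev
    loop <- run_step(loop, (k - 1) * cfg$dt)
    us[k] <- loop$row$u
  }
  expect_equal(prevs[2:5], us[1:4])
})

test_that("the forward-error chain depresses left PF-PC weights", {
  # hold a persistent positive tracking error: reference far ahead of the
  # resting plant. cf_left must exceed spontaneous and the left weight
  # total must fall below the right one.
  model <- tiny_model(8L)
  cfg <- control_config("dc_motor", g_cb = 0)
  loop <- init_loop(model, dc_motor_params(), cfg,
                    trajectory(2, 0.001))   # near-constant positive ref
  w0l <- sum(loop$model$left$syn$pf_pc$w)
  w0r <- sum(loop$model$right$syn$pf_pc$w)
  for (k in 1:50) loop <- run_step(loop, (k - 1) * cfg$dt)
  expect_gt(loop$row$cf_left, 0.05)
  expect_lt(loop$row$cf_right, 0.05)
  dl <- sum(loop$model$left$syn$pf_pc$w) - w0l
  dr <- sum(loop$model$right$syn$pf_pc$w) - w0r
  expect_lt(dl, 0)
  expect_gt(dr, 0)
})

test_that("trial bookkeeping: cycles, switch, single-cycle and fall paths", {
  model <- tiny_model(9L)
  p <- robot_params()
  cfg <- control_config("robot")
  tr <- run_trial(model, p, cfg, default_trajectory("robot"), 4,
                  record_traces = TRUE)
  expect_equal(nrow(tr$cycles), 4L)
  # mid-trial switch at a cycle boundary (DC motor: no fall interferes);
  # the switched trajectory has a different period and restarts at phase 0
  pm <- dc_motor_params()
  cfgm <- control_config("dc_motor")
  trm <- run_trial(model, pm, cfgm, default_trajectory("dc_motor"), 4,
                   record_traces = TRUE)
  tr2 <- run_trial(model, pm, cfgm, default_trajectory("dc_motor"), 4,
                   traj2 = trajectory(2, 0.25), switch_cycle = 2,
                   record_traces = TRUE)
  spc1 <- as.integer(2 / cfgm$dt)
  expect_equal(tr2$trace$ref[2 * spc1 + 1], 0)
  expect_equal(nrow(tr2$trace), 2L * 200L + 2L * 400L)
  expect_identical(tr2$trace$ref[seq_len(2 * spc1)],
                   trm$trace$ref[seq_len(2 * spc1)])
  # the robot switched to the sum of sines is overwhelmed and falls
  trr <- run_trial(model, p, cfg, default_trajectory("robot"), 4,
                   traj2 = default_trajectory("robot_sos"),
                   switch_cycle = 2, record_traces = FALSE)
  expect_true(trr$fallen)
  # single cycle trivially works
  tr3 <- run_trial(model, p, cfg, default_trajectory("robot"), 1,
                   record_traces = FALSE)
  expect_equal(sum(tr3$cycles$complete), 1L)
  expect_error(run_trial(model, p, cfg, default_trajectory("robot"), 2,
                         traj2 = default_trajectory("robot_sos")),
               "switch_cycle")
})

test_that("learning improves DC-motor tracking at moderate GC counts", {
  model <- build_bicnn(seeds = list(placement = 31L, connectivity = 31L,
                                    weights = 32L))
  model <- knockdown_bicnn(model, 200, seed = 33L)
  cfg <- control_config("dc_motor")
  tr <- run_trial(model, dc_motor_params(), cfg,
                  default_trajectory("dc_motor"), 30,
                  record_traces = FALSE)
  r <- tr$cycles$rse
  expect_false(tr$fallen)
  expect_lt(mean(r[29:30]), mean(r[5:6]))
})
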