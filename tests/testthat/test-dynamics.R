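test_that("Purkinje activation matches closed-form values of the sigmoid", {
  p <- activation_params()    # sigma 8, mu 1/2
  expect_equal(pc_rate(0.5, p), 0)
  expect_equal(pc_rate(1.0, p), 1 / (1 + exp(-4)) - 0.5)
  expect_equal(pc_rate(1.0, p), 0.48201, tolerance = 1e-5)
  expect_equal(pc_rate(0.0, p), 1 / (1 + exp(4)) - 0.5)
  expect_equal(pc_rate(0.0, p), -0.48201, tolerance = 1e-5)
  # limits and strict monotonicity over a grid
  expect_equal(pc_rate(1e3, p), 0.5)
  expect_equal(pc_rate(-1e3, p), -0.5)
  xs <- seq(-3, 3, length.out = 201)
  expect_true(all(diff(pc_rate(xs, p)) > 0))
})

test_that("a step keeps every rate in its contractual range", {
  net <- tiny_net()
  st <- hemisphere_state(net)
  set.seed(11)
  for (k in 1:30) {
    st <- step_hemisphere(net, st, runif(net$counts[["MF"]]))
    expect_true(all(st$y_gc >= 0 & st$y_gc <= 1))
    expect_true(all(st$y_go >= 0 & st$y_go <= 1))
    expect_true(all(st$y_bc >= 0 & st$y_bc <= 1))
    expect_gte(st$y_pc, -0.5); expect_lte(st$y_pc, 0.5)
  }
})

test_that("zero MF input from rest gives the quiescent baseline rates", {
  net <- tiny_net()
  st <- step_hemisphere(net, hemisphere_state(net), rep(0, 20))
  base <- 1 / (1 + exp(8 * 0.5))    # sigmoid at zero drive
  expect_true(all(abs(st$y_gc - base) < 1e-12))
  expect_true(all(abs(st$y_go - base) < 1e-12))
  # PC pre-activation decomposes into the PF term minus the BC term
  pf <- sum(net$syn$pf_pc$w[1, ] * st$y_gc[net$syn$pf_pc$conn[1, ]])
  bc <- sum(net$syn$bc_pc$w[1, ] * st$y_bc[net$syn$bc_pc$conn[1, ]])
  expect_equal(st$x_pc, pf - bc)
})

test_that("mf input contract is enforced", {
  net <- tiny_net()
  st <- hemisphere_state(net)
  expect_error(step_hemisphere(net, st, rep(0.5, 3)), "length")
  expect_error(step_hemisphere(net, st, rep(1.5, 20)), "input-contract")
})

test_that("hemisphere combination inverts left and is antisymmetric", {
  expect_equal(combine_hemispheres(0.3, 0.3), 0)
  expect_equal(combine_hemispheres(0, 0.4), 0.4)
  g <- expand.grid(l = seq(-0.5, 0.5, 0.1), r = seq(-0.5, 0.5, 0.1))
  out <- combine_hemispheres(g$l, g$r)
  swapped <- combine_hemispheres(g$r, g$l)
  expect_equal(out, -swapped)
  expect_true(all(abs(out) <= 1))
})

test_that("with one silent GC the PC pre-activation reduces to the BC term", {
  net <- tiny_net()
  net <- knockdown_gcs(net, 1, seed = 2L)
  # give the lone survivor zero MF drive by silencing all MFs
  st0 <- hemisphere_state(net)
  st1 <- step_hemisphere(net, st0, rep(0, 20))
  st2 <- step_hemisphere(net, st1, rep(0, 20))
  # PF term is the single GC's baseline only; subtracting it leaves -BC
  pf <- net$comp_scale *
    sum(net$syn$pf_pc$w[1, ] * st2$y_gc[net$syn$pf_pc$conn[1, ]])
  bc <- sum(net$syn$bc_pc$w[1, ] * st2$y_bc[net$syn$bc_pc$conn[1, ]])
  expect_equal(st2$x_pc, pf - bc)
  expect_equal(sum(st2$y_gc > 0), 1L)
})

test_that("one step is deterministic: same state and input, same output", {
  net <- tiny_net()
  st <- hemisphere_state(net)
  mf <- runif(20)
  a <- step_hemisphere(net, st, mf)
  b <- step_hemisphere(net, st, mf)
  expect_identical(a, b)
})

test_that("compiled engine reproduces the reference R path", {
  model <- tiny_model(5L)
  model <- knockdown_bicnn(model, 20, seed = 9L)
  cfg <- control_config("dc_motor")
  p <- dc_motor_params()
  traj <- default_trajectory("dc_motor")
  tr_r <- run_trial(model, p, cfg, traj, 2, engine = "r",
                    record_weights = TRUE)
  tr_c <- run_trial(model, p, cfg, traj, 2, engine = "cpp",
                    record_weights = TRUE)
  expect_equal(tr_r$cycles$rse, tr_c$cycles$rse, tolerance = 1e-12)
  expect_equal(tr_r$trace$y, tr_c$trace$y, tolerance = 1e-12)
  expect_equal(tr_r$trace$u, tr_c$trace$u, tolerance = 1e-12)
  expect_equal(tr_r$model$left$syn$pf_pc$w, tr_c$model$left$syn$pf_pc$w,
               tolerance = 1e-12)
  expect_equal(tr_r$weights_right[2, ], tr_c$weights_right[2, ],
               tolerance = 1e-12)
})
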