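test_that("cycle RSE matches closed forms", {
  x <- sin(seq(0, 2 * pi, length.out = 100))
  expect_equal(rse(x, x), 0)
  expect_equal(rse(x, x + 0.3), 0.3)
  # RMS of a sinusoid is A/sqrt(2)
  A <- pi
  t <- seq(0, 2, length.out = 201)[-201]   # 200 samples over one cycle
  ref <- A * sin(2 * pi * 0.5 * t)
  expect_equal(rse(ref, rep(0, 200)), A / sqrt(2), tolerance = 0.01)
  expect_error(rse(numeric(0), numeric(0)))
  expect_error(rse(1:3, 1:4))
})

test_that("the full protocol enumerates 25 permutations and 300 runs", {
  cfg <- experiment_config("dc_motor")
  expect_equal(cfg$gc_sizes,
               c(4L, 10L, 20L, 40L, 80L, 200L, 400L, 800L, 1000L, 1600L,
                 2000L, 4000L))
  expect_length(cfg$gc_sizes, 12L)
  expect_equal(cfg$n_permutations, 25L)
  expect_equal(cfg$n_runs, 300L)
  expect_equal(cfg$untrained_window, c(5L, 6L))
  expect_equal(cfg$trained_window, c(180L, 181L))
  rb <- experiment_config("robot")
  expect_equal(rb$trained_window, c(90L, 91L))
  # reduced grids rescale the trained window to the shortened trial
  red <- experiment_config("dc_motor", gc_sizes = c(4, 80), n_cycles = 20)
  expect_equal(red$trained_window, c(19L, 20L))
  expect_equal(red$n_runs, 50L)
})

test_that("a reduced sweep runs the whole factorial and groups into Nets", {
  cfg <- experiment_config("dc_motor", gc_sizes = c(10L, 30L),
                           n_weight_sets = 2L, n_net_tables = 2L,
                           n_cycles = 4L)
  expect_equal(cfg$n_runs, 8L)
  sw <- gc_sweep(cfg, base_seed = 3L, counts = tiny_counts())
  res <- sw$results
  runs <- unique(res[, c("gc_size", "net", "wset")])
  expect_equal(nrow(runs), 8L)
  expect_equal(nrow(res), 8L * 4L)
  # Net grouping: each connectivity table holds sizes x weight sets runs
  for (n_id in 1:2) {
    expect_equal(nrow(runs[runs$net == n_id, ]), 4L)
  }
  expect_true(all(res$rse[res$complete] >= 0))
  # PD reference present with the same cycle structure
  expect_equal(nrow(sw$pd), 4L)
})

test_that("box statistics pool N = permutations x 2 cycles per window", {
  cfg <- experiment_config("dc_motor", gc_sizes = c(10L, 30L),
                           n_weight_sets = 2L, n_net_tables = 2L,
                           n_cycles = 8L, untrained_window = c(2L, 3L))
  sw <- gc_sweep(cfg, base_seed = 4L, counts = tiny_counts())
  tv <- trained_vs_untrained(sw)
  expect_equal(sort(unique(tv$phase)), c("pd", "trained", "untrained"))
  per_box <- tv[tv$phase == "trained" & tv$gc_size == 10L, ]
  expect_equal(per_box$n, 2L * 2L * 2L)   # 4 permutations x 2 cycles
  # quartiles agree with an independent sort-based computation
  vals <- sw$results[sw$results$gc_size == 10L &
                       sw$results$cycle %in% 7:8, "rse"]
  expect_equal(per_box$median, stats::median(vals))
  expect_equal(per_box$q25, unname(quantile(vals, 0.25, type = 7)))
  expect_equal(per_box$q75, unname(quantile(vals, 0.75, type = 7)))
  # identical data give identical boxes
  sw2 <- sw
  sw2$config$untrained_window <- sw2$config$trained_window
  tv2 <- trained_vs_untrained(sw2)
  expect_equal(tv2$median[tv2$phase == "untrained"],
               tv2$median[tv2$phase == "trained"])
})

test_that("one-way ANOVA behaves like the textbook two-group case", {
  set.seed(10)
  a <- rnorm(20, 1, 0.2)
  b <- rnorm(20, 1.4, 0.2)
  res <- anova_pd_vs_bicnn(a, b)
  # two-group one-way ANOVA F equals the squared pooled t statistic
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic^2), tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  expect_true(res$significant)
  # identical groups: F = 0; degenerate: p = 1
  same <- anova_pd_vs_bicnn(c(a, a), c(a, a))
  expect_equal(same$F, 0, tolerance = 1e-10)
  deg <- anova_pd_vs_bicnn(rep(1, 5), rep(1, 5))
  expect_equal(deg$p, 1)
  expect_error(anova_pd_vs_bicnn(1, 1:3))
})

test_that("variability decomposition recovers known group structure exactly", {
  # hand-built result table: rse depends only on (net, wset)
  cfg <- experiment_config("dc_motor", gc_sizes = c(10L, 20L),
                           n_weight_sets = 3L, n_net_tables = 2L,
                           n_cycles = 4L, untrained_window = c(1L, 2L),
                           trained_window = c(3L, 4L))
  grid <- expand.grid(gc_size = c(10L, 20L), net = 1:2, wset = 1:3,
                      cycle = 1:4)
  grid$rse <- 0.1 * grid$net + 0.01 * grid$wset
  grid$complete <- TRUE
  grid$fallen <- FALSE
  vd <- variability_decomposition(list(results = grid, pd = NULL,
                                       config = cfg))
  expect_equal(nrow(vd), 2L * 2L)    # nets x sizes
  for (i in seq_len(nrow(vd))) {
    expect_equal(vd$mean_rse[i], 0.1 * vd$net[i] + 0.01 * mean(1:3))
    expect_equal(vd$sd_rse[i], stats::sd(0.1 * vd$net[i] + 0.01 * (1:3)))
  }
  # all-identical runs give zero error bars
  grid$rse <- 0.5
  vd2 <- variability_decomposition(list(results = grid, pd = NULL,
                                        config = cfg))
  expect_true(all(vd2$mean_rse == 0.5))
  expect_true(all(vd2$sd_rse == 0))
})

test_that("best-GC ranking agrees with a sort oracle and partitions by direction", {
  counts <- c(MF = 30L, GO = 8L, GC = 60L, BC = 12L, PC = 1L)
  model <- build_bicnn(counts, seeds = list(placement = 12L,
                                            connectivity = 12L,
                                            weights = 13L))
  model <- knockdown_bicnn(model, 40L, seed = 14L)
  cfg <- control_config("robot")
  tr <- run_trial(model, robot_params(), cfg, default_trajectory("robot"),
                  4, record_weights = TRUE, record_traces = FALSE)
  ch <- mf_channels("robot", counts[["MF"]])
  ba <- best_gc_analysis(tr, model$right, ch, cycle = 4,
                         reference_rank = 2L)
  rk <- ba$ranking
  # ranking is a permutation of the active GCs, sorted by weight
  expect_equal(sort(rk$gc), which(model$right$active))
  expect_identical(order(-rk$weight), seq_len(nrow(rk)))
  expect_true(all(rk$direction %in% c("potentiated", "depressed")))
  expect_equal(sum(rk$direction == "potentiated") +
                 sum(rk$direction == "depressed"), nrow(rk))
  # every pattern sharer has the reference GC's exact MF signal pattern
  ref_sig <- sort(ch$signal[model$right$syn$mf_gc$conn[ba$reference_gc, ]])
  for (g in ba$pattern_sharers$gc) {
    expect_equal(sort(ch$signal[model$right$syn$mf_gc$conn[g, ]]), ref_sig)
  }
  expect_true(ba$reference_gc %in% ba$pattern_sharers$gc)
  expect_error(best_gc_analysis(tr, model$right, ch, cycle = 99))
})
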