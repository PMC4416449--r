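test_that("placement is uniform in the cube, seeded, and handles edge cases", {
  lay <- place_neurons("GC", 10, 100, seed = 7L)
  expect_equal(lay$count, 10L)
  expect_true(all(lay$positions >= 0 & lay$positions <= 100))
  expect_equal(dim(lay$positions), c(10L, 3L))

  empty <- place_neurons("GC", 0, 100, seed = 1L)
  expect_equal(nrow(empty$positions), 0L)

  again <- place_neurons("GC", 10, 100, seed = 7L)
  expect_identical(lay$positions, again$positions)
  other <- place_neurons("GC", 10, 100, seed = 8L)
  expect_false(identical(lay$positions, other$positions))

  expect_error(place_neurons("GC", -1, 100), "configuration error")
  expect_error(place_neurons("GC", 5, 0), "configuration error")
})

test_that("nearest-neighbour wiring matches a brute-force distance oracle", {
  tg <- place_neurons("GC", 5, 100, seed = 3L)
  src <- place_neurons("MF", 9, 100, seed = 4L)
  for (f in c(1L, 3L, 5L)) {
    conn <- wire_nearest_neighbor(tg, src, f)
    expect_identical(conn, nn_oracle(tg, src, f))
  }
  # forced single source
  one <- place_neurons("MF", 1, 100, seed = 5L)
  expect_true(all(wire_nearest_neighbor(tg, one, 1L) == 1L))
  # over-demand errors with the projection name
  expect_error(wire_nearest_neighbor(tg, src, 10L, proj = "mf_gc"),
               "mf_gc")
})

test_that("every GC has exactly 4 MF and 4 GO afferents, none duplicated", {
  net <- tiny_net()
  expect_equal(ncol(net$syn$mf_gc$conn), 4L)
  expect_equal(ncol(net$syn$go_gc$conn), 4L)
  expect_true(all(apply(net$syn$mf_gc$conn, 1, anyDuplicated) == 0L))
  expect_true(all(apply(net$syn$go_gc$conn, 1, anyDuplicated) == 0L))
  rep <- validate_structure(net)
  expect_true(attr(rep, "ok"))
})

test_that("weight initialization is truncated to [0.8, 1] and d-normalized", {
  # large draw through the actual sampler
  set.seed(1)
  x <- bicnn:::rnorm_trunc(1e5, 0.9, 0.1, 0.8, 1)
  expect_true(all(x >= 0.8 & x <= 1))
  expect_equal(mean(x), 0.9, tolerance = 0.01)

  net <- tiny_net()
  for (g in net$syn) {
    expect_true(all(g$raw >= 0.8 & g$raw <= 1))
    expect_equal(g$w, g$raw * g$d)
  }
  # d = 1 / (same-nature input count), pooled across projections:
  # GC excitatory inputs: 4 MFs -> d = 1/4
  expect_equal(net$syn$mf_gc$d, 1 / 4)
  # GO excitatory inputs: MF + PF convergence pooled
  f_mf_go <- ncol(net$syn$mf_go$conn)
  f_pf_go <- ncol(net$syn$pf_go$conn)
  expect_equal(net$syn$mf_go$d, 1 / (f_mf_go + f_pf_go))
  expect_equal(net$syn$pf_go$d, net$syn$mf_go$d)
  # single-input target: d = 1 (PC -> BC with one PC)
  expect_equal(net$syn$pc_bc$d, 1)
  # sum of d over same-sign inputs is 1 for every target population
  tab <- net$fan_tab
  for (dst in unique(tab$dst)) {
    for (sg in c("exc", "inh")) {
      rows <- tab$proj[tab$dst == dst & tab$sign == sg]
      if (length(rows) == 0) next
      s <- sum(vapply(rows, function(p)
        ncol(net$syn[[p]]$conn) * net$syn[[p]]$d, numeric(1)))
      expect_equal(s, 1)
    }
  }
})

test_that("full-size fan-in contract: PF->PC all-to-one with a single PC", {
  tab <- fan_in_table(default_counts())
  expect_equal(tab$fan_in[tab$proj == "mf_gc"], 4L)
  expect_equal(tab$fan_in[tab$proj == "go_gc"], 4L)
  expect_equal(tab$fan_in[tab$proj == "pf_pc"], 4000L)
  expect_equal(tab$fan_in[tab$proj == "pc_bc"], 1L)
  # anatomical totals keep the 1024:1 PF->PC convergence
  tab2 <- fan_in_table(anatomical_counts())
  expect_equal(tab2$fan_in[tab2$proj == "pf_pc"], 1024L)
  expect_equal(tab2$fan_in[tab2$proj == "pf_go"], 1639L)
})

test_that("hemisphere build is deterministic in its three streams", {
  a <- tiny_net(1L, 2L, 3L)
  b <- tiny_net(1L, 2L, 3L)
  expect_identical(a$layouts$GC$positions, b$layouts$GC$positions)
  expect_identical(a$syn$mf_gc$conn, b$syn$mf_gc$conn)
  expect_identical(a$syn$pf_pc$w, b$syn$pf_pc$w)
  c <- tiny_net(1L, 2L, 4L)   # new weight stream only
  expect_identical(a$syn$mf_gc$conn, c$syn$mf_gc$conn)
  expect_false(identical(a$syn$pf_pc$raw, c$syn$pf_pc$raw))
})

test_that("knockdown silences GCs, compensates drive, and spares the rest", {
  net <- tiny_net()
  kd <- knockdown_gcs(net, 10, seed = 5L)
  expect_equal(sum(kd$active), 10L)
  expect_equal(kd$comp_scale, 50 / 10)
  # non-GC populations and non-GC synapses untouched bit-exactly
  expect_identical(kd$layouts, net$layouts)
  expect_identical(kd$syn$mf_gc$w, net$syn$mf_gc$w)
  expect_identical(kd$syn$bc_pc$w, net$syn$bc_pc$w)
  # identity knockdown
  id <- knockdown_gcs(net, 50, seed = 5L)
  expect_equal(id$comp_scale, 1)
  expect_true(all(id$active))
  # refusal at 0
  expect_error(knockdown_gcs(net, 0), "refusing")
  # state contract: silenced GCs emit exactly zero
  st <- step_hemisphere(kd, hemisphere_state(kd), rep(0.5, 20))
  expect_true(all(st$y_gc[!kd$active] == 0))
})

test_that("expected summed PF drive onto the PC survives knockdown", {
  net <- tiny_net(2L, 2L, 2L)
  w_full <- net$syn$pf_pc$w[1, ]
  y <- rep(0.3, 50)      # uniform PF activity isolates the mask average
  base <- sum(w_full * y[net$syn$pf_pc$conn[1, ]])
  drives <- vapply(1:100, function(s) {
    kd <- knockdown_gcs(net, 20, seed = s)
    ya <- y * kd$active
    kd$comp_scale * sum(kd$syn$pf_pc$w[1, ] * ya[kd$syn$pf_pc$conn[1, ]])
  }, numeric(1))
  expect_equal(mean(drives), base, tolerance = 0.02)
})

test_that("structure validation flags tampered connectivity", {
  net <- tiny_net()
  net$syn$mf_gc$conn[3, 2] <- net$syn$mf_gc$conn[3, 1]  # duplicate afferent
  rep <- validate_structure(net)
  expect_false(attr(rep, "ok"))
  bad <- rep[!rep$pass, ]
  expect_match(bad$projection[1], "mf_gc")
  expect_match(bad$message[1], "3")
  # report edge totals equal an independent enumeration
  net2 <- tiny_net()
  rep2 <- validate_structure(net2)
  for (p in names(net2$syn)) {
    row <- rep2[rep2$projection == p, ]
    expect_equal(row$n_targets * row$observed_fan_in,
                 length(net2$syn[[p]]$conn))
  }
})

test_that("bi-hemispheric build: mirrored streams give identical hemispheres", {
  m <- tiny_model(3L, mirror = TRUE)
  expect_identical(m$left$syn$pf_pc$w, m$right$syn$pf_pc$w)
  expect_identical(m$left$layouts$GC$positions,
                   m$right$layouts$GC$positions)
  m2 <- tiny_model(3L)
  expect_false(identical(m2$left$syn$pf_pc$w, m2$right$syn$pf_pc$w))
})
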