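test_that("steady state matches analytic closed forms", {
  # single node, one env edge: T* = Te + Q/g
  ss <- find_steady_state(one_node_net(g_env = 2, Qm = 10, Te = 20))
  expect_equal(unname(ss["t1"]), 20 + 10 / 2, tolerance = 1e-6)

  # chain: heat Qb flows b -> a -> env, adding Q/g offsets
  ss <- find_steady_state(chain_net(g1 = 2, g2 = 0.5, Qb = 6, Te = 20))
  expect_equal(unname(ss["a"]), 20 + 6 / 2, tolerance = 1e-6)
  expect_equal(unname(ss["b"]), 20 + 6 / 2 + 6 / 0.5, tolerance = 1e-6)

  # passive node between two pinned temperatures: g-weighted mean
  ss <- find_steady_state(weighted_mean_net(g1 = 1e-8, g2 = 3e-8,
                                            QA = 10, gA = 2, QB = 30, gB = 3))
  TA <- 20 + 10 / 2
  TB <- 20 + 30 / 3
  expect_equal(unname(ss["x"]), (1e-8 * TA + 3e-8 * TB) / 4e-8,
               tolerance = 1e-6)

  # isolated source-free node relaxes to the environment
  ss <- find_steady_state(one_node_net(g_env = 1, Qm = 0, Te = 25))
  expect_equal(unname(ss["t1"]), 25, tolerance = 1e-8)
})

test_that("steady state residual is below tolerance on the species configurations", {
  for (name in c("sheep_calibrated.yaml", "human_calibrated.yaml")) {
    net <- build_network(load_parameters(parameter_file(name)))
    ss <- find_steady_state(net)
    expect_lt(max(abs(assemble_rhs(net)(ss))), 1e-8)
  }
})

test_that("sheep model settles with the brain cooler than the body", {
  ss <- find_steady_state(build_network(sheep_calibrated()))
  expect_lt(ss[["head"]], ss[["body"]])
})

test_that("collar-off run holds the steady state through both phases", {
  net <- build_network(default_parameters("sheep"))
  ss <- find_steady_state(net)
  tr <- run_protocol(net, collar = NULL,
                     simulation_protocol(settling_duration_s = 300,
                                         cooling_duration_s = 300,
                                         sample_interval_s = 30))
  for (id in state_ids(net))
    expect_lt(max(abs(tr[[id]] - ss[[id]])), 1e-4)
})

test_that("brain temperature declines monotonically during collar cooling", {
  net <- build_network(sheep_calibrated())
  tr <- run_protocol(net, collar_from_parameters(sheep_calibrated()),
                     simulation_protocol(settling_duration_s = 0))
  expect_true(all(diff(tr$head) < 1e-9))
  expect_lt(tr$head[nrow(tr)], tr$head[1])
})

test_that("cooling_rate recovers trivial and constructed rates", {
  tt <- seq(0, 3600)
  const <- fake_trace(tt, head = rep(36.5, length(tt)))
  expect_equal(cooling_rate(const, "head", 0, 3600), 0)

  ramp <- fake_trace(tt, head = 36.5 - 0.5 * tt / 3600)
  expect_equal(cooling_rate(ramp, "head", 0, 3600, smooth_window_s = 0), 0.5,
               tolerance = 1e-12)
  # moving-average endpoints leave a linear ramp's rate essentially unchanged
  expect_equal(cooling_rate(ramp, "head", 0, 3600), 0.5, tolerance = 0.01)
  expect_equal(cooling_rate_slope(ramp, "head", 0, 3600), 0.5,
               tolerance = 1e-10)

  expect_error(cooling_rate(ramp, "head", -10, 3600), "window")
})

test_that("halving integrator tolerance leaves sampled temperatures unchanged to 1e-4", {
  net <- build_network(sheep_calibrated())
  col <- collar_from_parameters(sheep_calibrated())
  proto <- simulation_protocol(settling_duration_s = 0,
                               sample_interval_s = 60)
  tr1 <- run_protocol(net, col, proto, rtol = 1e-8, atol = 1e-10)
  tr2 <- run_protocol(net, col, proto, rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(as.matrix(tr1[, -1]) - as.matrix(tr2[, -1]))), 1e-4)
})

test_that("more extraction power never cools the brain more slowly", {
  ps <- sheep_calibrated()
  rates <- vapply(c(15, 30, 60, 120), function(p) {
    psx <- param_set(ps, "collar.source_power_W", p)
    tr <- run_protocol(build_network(psx), collar_from_parameters(psx),
                       simulation_protocol(settling_duration_s = 0,
                                           sample_interval_s = 60))
    cooling_rate(tr, "head", smooth_window_s = 0)
  }, 0)
  expect_true(all(diff(rates) > -1e-9))
})

test_that("body cooling is carried by venous return into the body blood", {
  ps <- sheep_calibrated()
  ps0 <- param_set(ps, "blood_nodes.body_blood.wall_conductance_W_C", 0)
  tr <- run_protocol(build_network(ps0), collar_from_parameters(ps0),
                     simulation_protocol(settling_duration_s = 0,
                                         sample_interval_s = 60))
  expect_lt(cooling_rate(tr, "body", smooth_window_s = 0), 0.05)
  expect_gt(cooling_rate(tr, "head", smooth_window_s = 0), 0.3)
})

test_that("identical configurations produce bit-identical trace CSVs", {
  ps <- sheep_calibrated()
  run <- function() {
    tr <- run_protocol(build_network(ps), collar_from_parameters(ps),
                       simulation_protocol(settling_duration_s = 0,
                                           cooling_duration_s = 900,
                                           sample_interval_s = 30))
    f <- tempfile(fileext = ".csv")
    write_trace_csv(tr, f)
    on.exit(unlink(f))
    readLines(f)
  }
  expect_identical(run(), run())
})
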