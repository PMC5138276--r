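test_that("blood segment derivative matches the hand-evaluated balance", {
  net <- two_segment_loop(wall1 = 0, rho = 1000, cb = 4000,
                          flow = 1e-5, V = 1e-4)
  # pure advection with a 1 C upstream excess: rho*cb*flow*1 / (rho*V*cb)
  st <- c(t1 = 37, b1 = 36, b2 = 37)
  expect_equal(blood_node_derivative(net, "b1", st), 0.1, tolerance = 1e-12)

  # isothermal state is an equilibrium of the blood balance
  st_iso <- c(t1 = 37, b1 = 37, b2 = 37)
  expect_equal(blood_node_derivative(net, "b1", st_iso), 0)

  # with negligible flow, pure wall exchange relaxes toward the tissue
  net2 <- two_segment_loop(wall1 = 2, flow = 1e-15)
  expect_gt(blood_node_derivative(net2, "b1", c(t1 = 38, b1 = 36, b2 = 36)), 0)
  expect_lt(blood_node_derivative(net2, "b1", c(t1 = 34, b1 = 36, b2 = 36)), 0)
})

test_that("tissue derivative sums conduction, wall exchange and sources", {
  # isolated node without sources does not move
  iso <- thermal_network(
    tissues = list(tissue_node("t1", 1, 3500, 0)),
    blood = list(), blood_props = blood_properties(), flow_m3_s = 1e-6,
    conductances = conductance("t1", "env", 0), environment_T_C = 20)
  expect_equal(tissue_node_derivative(iso, "t1", c(t1 = 33)), 0)

  # single env edge: heating rate g*(Te - T) + Q over m*c
  net <- one_node_net(g_env = 2, Qm = 10, Te = 20)
  expect_equal(tissue_node_derivative(net, "t1", c(t1 = 24)),
               (2 * (20 - 24) + 10) / 3500, tolerance = 1e-12)

  # reciprocal wall term: heat leaving the blood enters the tissue
  loop <- two_segment_loop(wall1 = 2, wall2 = 3)
  st <- c(t1 = 30, b1 = 38, b2 = 36)
  dT_t <- tissue_node_derivative(loop, "t1", st)
  expect_equal(dT_t * 1 * 3500, 2 * (38 - 30) + 3 * (36 - 30),
               tolerance = 1e-12)
})

test_that("assembled RHS agrees with the per-node operators", {
  ps <- sheep_calibrated()
  net <- build_network(ps)
  st <- random_state(net, 42)
  f <- assemble_rhs(net)
  d <- f(st)
  for (id in names(net$tissues))
    expect_equal(unname(d[id]), tissue_node_derivative(net, id, st),
                 tolerance = 1e-12)
  for (id in names(net$blood))
    expect_equal(unname(d[id]), blood_node_derivative(net, id, st),
                 tolerance = 1e-12)
  expect_error(f(st[-1]), "length")
})

test_that("energy is conserved exactly, collar off and on", {
  for (seed in 1:10) {
    net <- random_network(seed)
    st <- random_state(net, seed + 100)
    for (collar in list(NULL, collar_state(collar_spec()))) {
      eb <- energy_balance(net, st, collar)
      scale <- max(1, abs(eb$metabolic_W), abs(eb$to_environment_W),
                   abs(eb$extraction_W))
      expect_lt(abs(eb$residual_W) / scale, 1e-9)
    }
  }
})

test_that("isothermal state with no sources and matching environment is stationary", {
  net <- random_network(3, zero_sources = TRUE)
  st <- setNames(rep(net$environment_T_C, length(state_ids(net))),
                 state_ids(net))
  expect_lt(max(abs(assemble_rhs(net)(st))), 1e-12)
})

test_that("maximum principle: source-free, collar-off trajectories stay in the initial hull", {
  for (seed in 1:25) {
    net <- random_network(seed, zero_sources = TRUE)
    st <- random_state(net, seed + 500, lo = 18, hi = 41)
    tr <- run_protocol(net, collar = NULL,
                       simulation_protocol(settling_duration_s = 0,
                                           cooling_duration_s = 600,
                                           sample_interval_s = 30,
                                           initial_state = st))
    lo <- min(c(st, net$environment_T_C)) - 1e-6
    hi <- max(c(st, net$environment_T_C)) + 1e-6
    temps <- as.matrix(tr[, -1])
    expect_true(all(temps >= lo & temps <= hi))
  }
})

test_that("validate_network reports broken loops and bad fields", {
  net <- build_network(default_parameters("sheep"))
  expect_identical(validate_network(net), character(0))

  broken <- net
  broken$blood$head_blood$upstream <- "nowhere"
  diag <- validate_network(broken)
  expect_true(any(grepl("head_blood", diag)))

  neg <- net
  neg$tissues$body$mass_kg <- -1
  diag <- validate_network(neg)
  expect_true(any(grepl("body.*mass_kg", diag)))

  # loop that skips a segment
  skip_loop <- net
  skip_loop$blood$neck_art$upstream <- "neck_ven"
  expect_true(any(grepl("closed loop", validate_network(skip_loop))))
})

test_that("network serialization round-trips", {
  net <- build_network(sheep_calibrated())
  file <- withr::local_tempfile(fileext = ".yaml")
  write_network(net, file)
  net2 <- read_network(file)
  expect_equal(find_steady_state(net2), find_steady_state(net),
               tolerance = 1e-12)
  expect_equal(network_edges(net2), network_edges(net))
  expect_equal(heat_capacities(net2), heat_capacities(net))
})

test_that("trace export writes one column per node on a regular grid", {
  net <- build_network(default_parameters("sheep"))
  tr <- run_protocol(net, collar_spec(),
                     simulation_protocol(settling_duration_s = 120,
                                         cooling_duration_s = 300,
                                         sample_interval_s = 10))
  expect_identical(names(tr), c("time_s", state_ids(net)))
  expect_equal(unique(diff(tr$time_s)), 10)
  expect_false(anyNA(tr))
  file <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, file)
  back <- utils::read.csv(file)
  expect_equal(back$head, tr$head, tolerance = 1e-10)
})
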