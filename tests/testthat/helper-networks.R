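# Small hand-built networks and randomized variants of the canonical
# topology used across the test files.

# single tissue coupled only to the environment
one_node_net <- function(g_env = 2, Qm = 10, Te = 20) {
  thermal_network(
    tissues = list(tissue_node("t1", 1, 3500, Qm)),
    blood = list(), blood_props = blood_properties(),
    flow_m3_s = 1e-6,
    conductances = conductance("t1", "env", g_env),
    environment_T_C = Te)
}

# chain env -g1- a -g2- b with heat injected in b
chain_net <- function(g1 = 2, g2 = 0.5, Qb = 6, Te = 20) {
  thermal_network(
    tissues = list(tissue_node("a", 1, 3500, 0),
                   tissue_node("b", 2, 3500, Qb)),
    blood = list(), blood_props = blood_properties(),
    flow_m3_s = 1e-6,
    conductances = rbind(conductance("a", "env", g1),
                         conductance("a", "b", g2)),
    environment_T_C = Te)
}

# two pinned tissues (env edge + source) plus a passive node x coupled to
# both through weak edges; x's steady temperature is the g-weighted mean
weighted_mean_net <- function(g1 = 1e-8, g2 = 3e-8, Te = 20,
                              QA = 10, gA = 2, QB = 30, gB = 3) {
  thermal_network(
    tissues = list(tissue_node("A", 1, 3500, QA),
                   tissue_node("B", 1, 3500, QB),
                   tissue_node("x", 1, 3500, 0)),
    blood = list(), blood_props = blood_properties(),
    flow_m3_s = 1e-6,
    conductances = rbind(conductance("A", "env", gA),
                         conductance("B", "env", gB),
                         conductance("x", "A", g1),
                         conductance("x", "B", g2)),
    environment_T_C = Te)
}

# two blood segments in a closed loop through one tissue; used for the
# hand-evaluated advection example and reciprocity checks
two_segment_loop <- function(wall1 = 0, wall2 = 0,
                             rho = 1000, cb = 4000,
                             flow = 1e-5, V = 1e-4) {
  thermal_network(
    tissues = list(tissue_node("t1", 1, 3500, 0)),
    blood = list(blood_node("b1", V, upstream = "b2", contact = "t1", wall1),
                 blood_node("b2", V, upstream = "b1", contact = "t1", wall2)),
    blood_props = blood_properties(rho, cb),
    flow_m3_s = flow,
    conductances = conductance("t1", "env", 0),
    environment_T_C = 20)
}

# canonical sheep topology with log-normal jitter on the physical scales
random_network <- function(seed, zero_sources = FALSE) {
  set.seed(seed)
  ps <- default_parameters("sheep")
  jitter_paths <- c(
    "flow_m3_s",
    "conductances.body_env", "conductances.head_env",
    "conductances.body_neck", "conductances.neck_head",
    "tissues.body.mass_kg", "tissues.head.mass_kg", "tissues.neck.mass_kg",
    "blood_nodes.neck_art.volume_m3", "blood_nodes.head_blood.volume_m3",
    "blood_nodes.neck_ven.volume_m3", "blood_nodes.body_blood.volume_m3",
    "blood_nodes.neck_art.wall_conductance_W_C",
    "blood_nodes.head_blood.wall_conductance_W_C",
    "blood_nodes.neck_ven.wall_conductance_W_C",
    "blood_nodes.body_blood.wall_conductance_W_C")
  for (p in jitter_paths)
    ps <- param_set(ps, p, param_get(ps, p) * exp(stats::rnorm(1, 0, 0.5)))
  if (zero_sources)
    ps <- param_set(ps, "basal_metabolic_kcal_day", 0)
  build_network(ps)
}

random_state <- function(net, seed, lo = 15, hi = 40) {
  set.seed(seed)
  setNames(stats::runif(length(state_ids(net)), lo, hi), state_ids(net))
}

# a trace object built directly from given series (bypassing the solver)
fake_trace <- function(time_s, ...) {
  cols <- list(...)
  tr <- data.frame(time_s = time_s, cols)
  structure(tr, phase_marks = 0, node_ids = names(cols),
            class = c("temperature_trace", "data.frame"))
}

sheep_calibrated <- function() load_parameters(parameter_file("sheep_calibrated.yaml"))
human_calibrated <- function() load_parameters(parameter_file("human_calibrated.yaml"))
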