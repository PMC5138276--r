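#' Thermal network model of head, neck and body coupled by circulating blood
#'
#' The model represents an animal (or human) as three lumped tissue
#' compartments -- body, head and neck -- exchanging heat by conduction with
#' each other and with the environment, and by convection with a closed loop
#' of blood segments (body blood -> arterial neck segment -> head blood ->
#' venous neck segment -> body blood). Each node is assumed isothermal at any
#' instant, so the dynamics are ordinary differential equations.
#'
#' Two balance laws generate every equation. For a blood segment `i` in
#' contact with tissue `t`:
#'
#'   rho_b V_i c_b dT_i/dt = g_it (T_t - T_i) + rho_b c_b phi (T_up - T_i)
#'
#' where `g_it = h_b S_v` is the vessel-wall convective conductance and
#' `phi` the volumetric blood flow, identical along the loop. For a tissue
#' node `t` with conduction neighbours `j` (tissue, cooling element or
#' environment) and contacting blood segments `i`:
#'
#'   m_t c_t dT_t/dt = sum_j g_tj (T_j - T_t) + sum_i g_it (T_i - T_t)
#'                     + Qm_t - extraction_t
#'
#' The reciprocal `g_it` term guarantees that heat leaving the blood enters
#' the tissue, so the network conserves energy exactly.
#'
#' @name thermal-network
#' @keywords internal
NULL

ENV_ID <- "env"

#' Construct a tissue node
#'
#' @param id node label, e.g. `"body"`.
#' @param mass_kg tissue mass (kg), positive.
#' @param specific_heat_J_kgC specific heat capacity (J/(kg*C)), positive.
#' @param metabolic_heat_W basal metabolic heat generated in the node (W),
#'   non-negative.
#' @return an object of class `tissue_node`.
#' @export
tissue_node <- function(id, mass_kg, specific_heat_J_kgC, metabolic_heat_W = 0) {
  structure(list(id = as.character(id),
                 mass_kg = as.numeric(mass_kg),
                 specific_heat_J_kgC = as.numeric(specific_heat_J_kgC),
                 metabolic_heat_W = as.numeric(metabolic_heat_W)),
            class = "tissue_node")
}

#' Construct a blood segment node
#'
#' Blood segments form a single closed directed loop; `upstream` names the
#' segment whose outflow feeds this one. Each segment exchanges heat through
#' its vessel walls with exactly one tissue node (`contact`), with convective
#' wall conductance `wall_conductance_W_C` (= h_b * S_v).
#'
#' @param id segment label, e.g. `"head_blood"`.
#' @param volume_m3 blood volume of the segment (m^3), positive.
#' @param upstream id of the upstream blood segment.
#' @param contact id of the tissue node the segment perfuses.
#' @param wall_conductance_W_C vessel-wall conductance (W/C), non-negative.
#' @return an object of class `blood_node`.
#' @export
blood_node <- function(id, volume_m3, upstream, contact, wall_conductance_W_C) {
  structure(list(id = as.character(id),
                 volume_m3 = as.numeric(volume_m3),
                 upstream = as.character(upstream),
                 contact = as.character(contact),
                 wall_conductance_W_C = as.numeric(wall_conductance_W_C)),
            class = "blood_node")
}

#' Blood thermophysical properties
#'
#' @param density_kg_m3 blood density (kg/m^3).
#' @param specific_heat_J_kgC blood specific heat (J/(kg*C)).
#' @return an object of class `blood_properties`.
#' @export
blood_properties <- function(density_kg_m3 = 1050, specific_heat_J_kgC = 3800) {
  structure(list(density_kg_m3 = as.numeric(density_kg_m3),
                 specific_heat_J_kgC = as.numeric(specific_heat_J_kgC)),
            class = "blood_properties")
}

#' Construct a conduction edge
#'
#' Conduction edges couple tissues to each other, to the environment
#' (`"env"`) and to collar cooling elements, with conductance
#' `g = lambda * S / L` (W/C). Heat flow is symmetric: the flux from `a` to
#' `b` is the negative of the flux from `b` to `a`.
#'
#' @param from,to endpoint ids (tissue id, element id, or `"env"`).
#' @param g_W_C conductance in W/C, non-negative.
#' @return a one-row data frame with columns `from`, `to`, `g`, `kind`.
#' @export
conductance <- function(from, to, g_W_C) {
  data.frame(from = as.character(from), to = as.character(to),
             g = as.numeric(g_W_C), kind = "conduction",
             stringsAsFactors = FALSE)
}

#' Assemble a thermal network
#'
#' @param tissues list of [tissue_node()] objects.
#' @param blood list of [blood_node()] objects forming one closed loop.
#' @param blood_props a [blood_properties()] object.
#' @param flow_m3_s volumetric blood flow along the loop (m^3/s), positive.
#' @param conductances data frame of conduction edges, e.g. built by
#'   `rbind()`-ing [conductance()] rows.
#' @param environment_T_C fixed environment temperature (C).
#' @param elements optional collar-element description, a list with fields
#'   `ids` (character vector, usually two), `mode` (`"sink"`: elements act as
#'   pure heat sinks on the contact tissue; `"dynamic"`: elements are thermal
#'   masses in the state vector), `heat_capacity_J_C` (per element, used in
#'   dynamic mode) and `contact` (tissue the collar wraps, default
#'   `"neck"`).
#' @return an object of class `thermal_network`.
#' @export
thermal_network <- function(tissues, blood, blood_props, flow_m3_s,
                            conductances, environment_T_C,
                            elements = NULL) {
  if (!is.null(elements)) {
    elements$mode <- match.arg(elements$mode %||% "sink", c("sink", "dynamic"))
    elements$contact <- elements$contact %||% "neck"
    elements$heat_capacity_J_C <- elements$heat_capacity_J_C %||% 200
  }
  net <- structure(list(
    tissues = setNames(tissues, vapply(tissues, `[[`, "", "id")),
    blood = setNames(blood, vapply(blood, `[[`, "", "id")),
    blood_props = blood_props,
    flow_m3_s = as.numeric(flow_m3_s),
    conductances = conductances,
    environment_T_C = as.numeric(environment_T_C),
    elements = elements), class = "thermal_network")
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tissue_ids <- function(net) names(net$tissues)
blood_ids <- function(net) names(net$blood)
element_ids <- function(net) if (is.null(net$elements)) character() else net$elements$ids

elements_dynamic <- function(net) {
  !is.null(net$elements) && identical(net$elements$mode, "dynamic")
}

#' State-vector node ids of a network
#'
#' The state ordering is fixed: tissues in declaration order, then blood
#' segments in declaration order, then collar elements when these are
#' dynamic thermal masses.
#'
#' @param net a [thermal_network()].
#' @return character vector of node ids making up the ODE state.
#' @export
state_ids <- function(net) {
  ids <- c(tissue_ids(net), blood_ids(net))
  if (elements_dynamic(net)) ids <- c(ids, element_ids(net))
  ids
}

#' Heat capacities of the state nodes (J/C)
#'
#' @param net a [thermal_network()].
#' @return named numeric vector, `m_t*c_t` for tissues, `rho_b*V_i*c_b` for
#'   blood segments, the configured element capacity for dynamic elements.
#' @export
heat_capacities <- function(net) {
  caps <- c(
    vapply(net$tissues, function(t) t$mass_kg * t$specific_heat_J_kgC, 0),
    vapply(net$blood, function(b) {
      net$blood_props$density_kg_m3 * b$volume_m3 *
        net$blood_props$specific_heat_J_kgC
    }, 0))
  if (elements_dynamic(net)) {
    caps <- c(caps, setNames(rep(net$elements$heat_capacity_J_C,
                                 length(element_ids(net))), element_ids(net)))
  }
  caps
}

#' Full edge table of a network
#'
#' Returns the conduction edges plus the convection edges implied by the
#' blood segments (vessel-wall couplings, `kind = "convection"`).
#'
#' @param net a [thermal_network()].
#' @return data frame with columns `from`, `to`, `g`, `kind`.
#' @export
network_edges <- function(net) {
  conv <- do.call(rbind, lapply(net$blood, function(b) {
    data.frame(from = b$id, to = b$contact, g = b$wall_conductance_W_C,
               kind = "convection", stringsAsFactors = FALSE)
  }))
  rbind(net$conductances, conv)
}

#' Validate a thermal network
#'
#' Checks the structural invariants of the model: positive masses, volumes
#' and specific heats, non-negative conductances and metabolic heats, a
#' single closed blood loop in which every segment has exactly one upstream
#' neighbour, and conduction endpoints that resolve to existing nodes or the
#' environment.
#'
#' @param net a [thermal_network()].
#' @return character vector of human-readable diagnostics; empty when the
#'   network is valid.
#' @export
validate_network <- function(net) {
  bad <- character()
  for (t in net$tissues) {
    if (!is.finite(t$mass_kg) || t$mass_kg <= 0)
      bad <- c(bad, sprintf("tissue '%s': mass_kg must be > 0", t$id))
    if (!is.finite(t$specific_heat_J_kgC) || t$specific_heat_J_kgC <= 0)
      bad <- c(bad, sprintf("tissue '%s': specific_heat_J_kgC must be > 0", t$id))
    if (!is.finite(t$metabolic_heat_W) || t$metabolic_heat_W < 0)
      bad <- c(bad, sprintf("tissue '%s': metabolic_heat_W must be >= 0", t$id))
  }
  if (net$blood_props$density_kg_m3 <= 0 ||
      net$blood_props$specific_heat_J_kgC <= 0)
    bad <- c(bad, "blood_props: density and specific heat must be > 0")
  if (length(net$blood) > 0) {
    if (!is.finite(net$flow_m3_s) || net$flow_m3_s <= 0)
      bad <- c(bad, "flow_m3_s must be > 0")
    for (b in net$blood) {
      if (!is.finite(b$volume_m3) || b$volume_m3 <= 0)
        bad <- c(bad, sprintf("blood '%s': volume_m3 must be > 0", b$id))
      if (!is.finite(b$wall_conductance_W_C) || b$wall_conductance_W_C < 0)
        bad <- c(bad, sprintf("blood '%s': wall_conductance_W_C must be >= 0", b$id))
      if (!b$contact %in% tissue_ids(net))
        bad <- c(bad, sprintf("blood '%s': contact tissue '%s' not found",
                              b$id, b$contact))
      if (is.na(b$upstream) || !b$upstream %in% blood_ids(net))
        bad <- c(bad, sprintf("blood '%s': upstream segment '%s' not found",
                              b$id, b$upstream))
    }
    # the loop must be a single closed cycle visiting every segment once
    if (all(vapply(net$blood, function(b) b$upstream %in% blood_ids(net), TRUE))) {
      seen <- character()
      cur <- blood_ids(net)[1]
      for (k in seq_along(net$blood)) {
        seen <- c(seen, cur)
        cur <- net$blood[[cur]]$upstream
      }
      if (!identical(sort(seen), sort(blood_ids(net))) ||
          cur != blood_ids(net)[1])
        bad <- c(bad, "blood segments do not form a single closed loop")
    }
  }
  known <- c(tissue_ids(net), element_ids(net), ENV_ID)
  for (k in seq_len(nrow(net$conductances))) {
    e <- net$conductances[k, ]
    if (!is.finite(e$g) || e$g < 0)
      bad <- c(bad, sprintf("conductance %s-%s: g must be >= 0", e$from, e$to))
    for (endp in c(e$from, e$to)) {
      if (!endp %in% known)
        bad <- c(bad, sprintf("conductance %s-%s: endpoint '%s' not found",
                              e$from, e$to, endp))
    }
  }
  unique(bad)
}

node_temperature <- function(net, id, state) {
  if (id == ENV_ID) return(net$environment_T_C)
  if (!id %in% names(state))
    stop(sprintf("node '%s' is not part of the state vector", id))
  unname(state[[id]])
}

#' Time derivative of a blood-segment temperature
#'
#' Implements the convective blood balance: wall exchange with the contact
#' tissue plus advection from the upstream segment, divided by the thermal
#' capacity of the segment's blood volume.
#'
#' @param net a [thermal_network()].
#' @param id id of the blood segment.
#' @param state named temperature vector (C) covering [state_ids()].
#' @return dT/dt in C/s.
#' @export
blood_node_derivative <- function(net, id, state) {
  b <- net$blood[[id]]
  if (is.null(b)) stop(sprintf("blood segment '%s' not found", id))
  if (!is.finite(b$volume_m3) || b$volume_m3 <= 0)
    stop(sprintf("blood '%s': volume_m3 must be > 0", id))
  if (is.null(net$blood[[b$upstream]]))
    stop(sprintf("blood '%s': upstream segment '%s' not found", id, b$upstream))
  rho <- net$blood_props$density_kg_m3
  cb <- net$blood_props$specific_heat_J_kgC
  Ti <- node_temperature(net, id, state)
  Tt <- node_temperature(net, b$contact, state)
  Tup <- node_temperature(net, b$upstream, state)
  (b$wall_conductance_W_C * (Tt - Ti) +
      rho * cb * net$flow_m3_s * (Tup - Ti)) /
    (rho * b$volume_m3 * cb)
}

#' Time derivative of a tissue temperature
#'
#' Sums conduction over every adjacent body (tissue, element, environment),
#' the reciprocal vessel-wall exchange with every contacting blood segment,
#' the node's metabolic heat, and any collar extraction applied to the node,
#' divided by the tissue heat capacity.
#'
#' @inheritParams blood_node_derivative
#' @param id id of the tissue node.
#' @param extraction_W heat currently being removed from this node by the
#'   collar (W); positive removes heat.
#' @return dT/dt in C/s.
#' @export
tissue_node_derivative <- function(net, id, state, extraction_W = 0) {
  t <- net$tissues[[id]]
  if (is.null(t)) stop(sprintf("tissue '%s' not found", id))
  Tt <- node_temperature(net, id, state)
  flux <- t$metabolic_heat_W - extraction_W
  ce <- net$conductances
  for (k in seq_len(nrow(ce))) {
    if (ce$from[k] == id || ce$to[k] == id) {
      other <- if (ce$from[k] == id) ce$to[k] else ce$from[k]
      if (other %in% element_ids(net) && !elements_dynamic(net)) next
      flux <- flux + ce$g[k] * (node_temperature(net, other, state) - Tt)
    }
  }
  for (b in net$blood) {
    if (b$contact == id)
      flux <- flux + b$wall_conductance_W_C *
        (node_temperature(net, b$id, state) - Tt)
  }
  flux / (t$mass_kg * t$specific_heat_J_kgC)
}

#' Assemble the right-hand side of the network ODE system
#'
#' Vectorizes the blood and tissue balances over the whole network, with the
#' collar acting either as a direct heat sink on its contact tissue
#' (`sink` element mode) or through dynamic element nodes coupled by the
#' element conductances (`dynamic` mode). The returned function maps a
#' temperature state vector, ordered as [state_ids()], to its derivative.
#'
#' @param net a validated [thermal_network()].
#' @param collar a [collar_state()] (or `NULL` for no device).
#' @return a function `f(state)` returning the named derivative vector
#'   (C/s); the function carries the attribute `"ids"` with the expected
#'   state ordering.
#' @export
assemble_rhs <- function(net, collar = NULL) {
  ids <- state_ids(net)
  n <- length(ids)
  idx <- setNames(seq_len(n), ids)
  caps <- heat_capacities(net)[ids]
  tis <- tissue_ids(net)
  Qm <- setNames(numeric(n), ids)
  Qm[tis] <- vapply(net$tissues, `[[`, 0, "metabolic_heat_W")

  rho <- net$blood_props$density_kg_m3
  cb <- net$blood_props$specific_heat_J_kgC
  adv <- rho * cb * net$flow_m3_s

  bl <- net$blood
  b_idx <- idx[blood_ids(net)]
  b_up <- idx[vapply(bl, `[[`, "", "upstream")]
  b_ct <- idx[vapply(bl, `[[`, "", "contact")]
  b_g <- vapply(bl, `[[`, 0, "wall_conductance_W_C")

  # conduction edges resolved to state indices; environment handled apart
  ce <- net$conductances
  if (!elements_dynamic(net) && length(element_ids(net)) > 0) {
    drop <- ce$from %in% element_ids(net) | ce$to %in% element_ids(net)
    ce <- ce[!drop, , drop = FALSE]
  }
  env_edge <- ce$from == ENV_ID | ce$to == ENV_ID
  ce_env <- ce[env_edge, , drop = FALSE]
  ce_int <- ce[!env_edge, , drop = FALSE]
  env_node <- idx[ifelse(ce_env$from == ENV_ID, ce_env$to, ce_env$from)]
  int_a <- idx[ce_int$from]
  int_b <- idx[ce_int$to]
  Te <- net$environment_T_C

  dynamic <- elements_dynamic(net)
  el_ids <- element_ids(net)
  sink_target <- if (!is.null(net$elements)) idx[[net$elements$contact]] else NA_integer_
  el_idx <- if (dynamic) idx[el_ids] else integer()
  n_el <- max(length(el_ids), 1L)

  f <- function(state) {
    if (length(state) != n)
      stop(sprintf("state vector has length %d, expected %d", length(state), n))
    Tn <- as.numeric(state)
    flux <- Qm
    # conduction
    if (nrow(ce_int) > 0) {
      d <- ce_int$g * (Tn[int_b] - Tn[int_a])
      for (k in seq_along(d)) {
        flux[int_a[k]] <- flux[int_a[k]] + d[k]
        flux[int_b[k]] <- flux[int_b[k]] - d[k]
      }
    }
    if (nrow(ce_env) > 0) {
      d <- ce_env$g * (Te - Tn[env_node])
      for (k in seq_along(d)) flux[env_node[k]] <- flux[env_node[k]] + d[k]
    }
    # vessel-wall convection (reciprocal) and advection along the loop
    if (length(b_idx) > 0) {
      w <- b_g * (Tn[b_ct] - Tn[b_idx])
      for (k in seq_along(w)) {
        flux[b_idx[k]] <- flux[b_idx[k]] + w[k]
        flux[b_ct[k]] <- flux[b_ct[k]] - w[k]
      }
      a <- adv * (Tn[b_up] - Tn[b_idx])
      for (k in seq_along(a)) flux[b_idx[k]] <- flux[b_idx[k]] + a[k]
    }
    # collar
    extraction <- 0
    if (!is.null(collar) && isTRUE(collar$active) && !is.na(sink_target)) {
      extraction <- collar_extraction(collar$spec, Tn[sink_target])
      if (dynamic) {
        per_el <- extraction / length(el_idx)
        for (k in el_idx) flux[k] <- flux[k] - per_el
      } else {
        flux[sink_target] <- flux[sink_target] - extraction
      }
    }
    structure(flux / caps, names = ids, extraction_W = extraction)
  }
  attr(f, "ids") <- ids
  f
}

#' Global energy bookkeeping of a network state
#'
#' Evaluates, for a given state, the capacity-weighted sum of temperature
#' derivatives and its decomposition into metabolic input, net flow to the
#' environment, and collar extraction. For a conservative model the balance
#' `sum(C dT/dt) = metabolic - to_environment - extraction` holds to
#' round-off.
#'
#' @inheritParams assemble_rhs
#' @param state named temperature vector.
#' @return list with `capacity_flux_W`, `metabolic_W`, `to_environment_W`,
#'   `extraction_W` and `residual_W` (the imbalance).
#' @export
energy_balance <- function(net, state, collar = NULL) {
  f <- assemble_rhs(net, collar)
  d <- f(state)
  caps <- heat_capacities(net)[attr(f, "ids")]
  ce <- net$conductances
  if (!elements_dynamic(net) && length(element_ids(net)) > 0) {
    drop <- ce$from %in% element_ids(net) | ce$to %in% element_ids(net)
    ce <- ce[!drop, , drop = FALSE]
  }
  env_edge <- ce$from == ENV_ID | ce$to == ENV_ID
  ce_env <- ce[env_edge, , drop = FALSE]
  to_env <- 0
  for (k in seq_len(nrow(ce_env))) {
    other <- if (ce_env$from[k] == ENV_ID) ce_env$to[k] else ce_env$from[k]
    to_env <- to_env + ce_env$g[k] *
      (node_temperature(net, other, state) - net$environment_T_C)
  }
  met <- sum(vapply(net$tissues, `[[`, 0, "metabolic_heat_W"))
  extr <- attr(d, "extraction_W") %||% 0
  cap_flux <- sum(caps * as.numeric(d))
  list(capacity_flux_W = cap_flux, metabolic_W = met,
       to_environment_W = to_env, extraction_W = extr,
       residual_W = cap_flux - (met - to_env - extr))
}

#' @export
print.thermal_network <- function(x, ...) {
  cat(sprintf("<thermal_network> %d tissue, %d blood, %d element node(s)\n",
              length(x$tissues), length(x$blood), length(element_ids(x))))
  cat(sprintf("  environment %.1f C, loop flow %.3g m^3/s\n",
              x$environment_T_C, x$flow_m3_s))
  diag <- validate_network(x)
  if (length(diag)) cat("  INVALID:", paste(diag, collapse = "; "), "\n")
  invisible(x)
}

network_to_list <- function(net) {
  list(
    environment_T_C = net$environment_T_C,
    flow_m3_s = net$flow_m3_s,
    blood_props = unclass(net$blood_props),
    tissues = lapply(net$tissues, unclass),
    blood = lapply(net$blood, unclass),
    conductances = lapply(seq_len(nrow(net$conductances)), function(k) {
      as.list(net$conductances[k, c("from", "to", "g")])
    }),
    elements = net$elements)
}

#' Write / read a network description
#'
#' Serializes the full node/edge description to a nested key-value (YAML)
#' file; `read_network()` restores an identical network.
#'
#' @param net a [thermal_network()].
#' @param file path to write to / read from.
#' @return `write_network()` returns `file` invisibly; `read_network()`
#'   returns a [thermal_network()].
#' @export
write_network <- function(net, file) {
  yaml::write_yaml(network_to_list(net), file, precision = 15)
  invisible(file)
}

#' @rdname write_network
#' @export
read_network <- function(file) {
  x <- yaml::read_yaml(file)
  thermal_network(
    tissues = lapply(x$tissues, function(t) do.call(tissue_node, t)),
    blood = lapply(x$blood, function(b) do.call(blood_node, b)),
    blood_props = do.call(blood_properties, x$blood_props),
    flow_m3_s = x$flow_m3_s,
    conductances = do.call(rbind, lapply(x$conductances, function(e) {
      conductance(e$from, e$to, e$g)
    })),
    environment_T_C = x$environment_T_C,
    elements = x$elements)
}
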