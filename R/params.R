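#' Species parameter catalogs and configuration files
#'
#' A `parameter_set` gathers every physical constant needed to instantiate
#' the thermal network for one species: compartment masses and specific
#' heats, blood properties and segment volumes, loop flow, conductances,
#' metabolic budget and its partition, environment temperature, and the
#' collar specification. Every value carries a provenance tag
#' (`"literature-default"`, `"supplement"`, `"calibrated"`, or `"file"` for
#' user overrides).
#'
#' Metabolic heat is configured as a daily basal budget (kcal/day, converted
#' as 1 kcal/day = 4184/86400 W) partitioned over the tissue nodes by
#' `metabolic_fraction`; the fractions must sum to 1.
#'
#' @name parameter-sets
NULL

#' Convert kcal/day to watts
#'
#' @param kcal_day energy rate in kcal/day.
#' @return power in W.
#' @export
kcal_day_to_W <- function(kcal_day) kcal_day * 4184 / 86400

BLOOD_SEGMENT_IDS <- c("neck_art", "head_blood", "neck_ven", "body_blood")
CONDUCTANCE_KEYS <- c("body_env", "head_env", "body_neck", "neck_head",
                      "el_env", "el_el", "el1_neck", "el2_neck")

#' Built-in species defaults
#'
#' Literature-based default parameter sets for an adult sheep (65-70 kg)
#' and a 70 kg adult human. These are starting values for simulation and
#' calibration, not fitted values; the bundled `*_calibrated.yaml` files
#' hold the sets fitted to the experimental summaries.
#'
#' @param species `"sheep"` or `"human"`.
#' @return a `parameter_set`.
#' @export
default_parameters <- function(species = c("sheep", "human")) {
  species <- match.arg(species)
  common <- list(
    basal_metabolic_kcal_day = 1200,
    environment_T_C = 23,
    blood = list(density_kg_m3 = 1050, specific_heat_J_kgC = 3800),
    collar = list(source_power_W = 60, efficiency = 0.60, n_elements = 2,
                  skin_floor_C = 5, guard_band_C = 1),
    elements = list(mode = "sink", heat_capacity_J_C = 200,
                    env_coupling = "first"))
  sp <- if (species == "sheep") list(
    species = "sheep",
    body_mass_kg = 68,
    flow_m3_s = 8.0e-6,
    tissues = list(
      body = list(mass_kg = 65.0, specific_heat_J_kgC = 3500,
                  metabolic_fraction = 0.95),
      head = list(mass_kg = 0.5, specific_heat_J_kgC = 3600,
                  metabolic_fraction = 0.03),
      neck = list(mass_kg = 2.0, specific_heat_J_kgC = 3500,
                  metabolic_fraction = 0.02)),
    blood_nodes = list(
      neck_art = list(volume_m3 = 1.5e-5, wall_conductance_W_C = 0.2),
      head_blood = list(volume_m3 = 4.0e-5, wall_conductance_W_C = 3.0),
      neck_ven = list(volume_m3 = 1.5e-5, wall_conductance_W_C = 1.0),
      body_blood = list(volume_m3 = 3.5e-3, wall_conductance_W_C = 150)),
    conductances = list(body_env = 3.8, head_env = 0.28, body_neck = 0.3,
                        neck_head = 0.05, el_env = 0.3, el_el = 0.2,
                        el1_neck = 2.0, el2_neck = 2.0)
  ) else list(
    species = "human",
    body_mass_kg = 70,
    flow_m3_s = 1.2e-5,
    tissues = list(
      body = list(mass_kg = 66.5, specific_heat_J_kgC = 3500,
                  metabolic_fraction = 0.78),
      head = list(mass_kg = 1.4, specific_heat_J_kgC = 3600,
                  metabolic_fraction = 0.20),
      neck = list(mass_kg = 1.0, specific_heat_J_kgC = 3500,
                  metabolic_fraction = 0.02)),
    blood_nodes = list(
      neck_art = list(volume_m3 = 3.0e-5, wall_conductance_W_C = 0.6),
      head_blood = list(volume_m3 = 1.5e-4, wall_conductance_W_C = 8.0),
      neck_ven = list(volume_m3 = 3.0e-5, wall_conductance_W_C = 1.2),
      body_blood = list(volume_m3 = 4.3e-3, wall_conductance_W_C = 150)),
    conductances = list(body_env = 3.3, head_env = 0.8, body_neck = 0.3,
                        neck_head = 0.1, el_env = 0.3, el_el = 0.2,
                        el1_neck = 2.0, el2_neck = 2.0)
  )
  ps <- c(sp, common)
  ps$provenance <- setNames(as.list(rep("literature-default",
                                        length(flatten_params(ps)))),
                            names(flatten_params(ps)))
  structure(ps, class = "parameter_set")
}

numeric_leaf_paths <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    path <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
    v <- x[[nm]]
    if (is.list(v)) out <- c(out, numeric_leaf_paths(v, path))
    else out[[path]] <- v
  }
  out
}

flatten_params <- function(ps) {
  x <- unclass(ps)
  x$provenance <- NULL
  numeric_leaf_paths(x)
}

#' Read / write a parameter value by dotted path
#'
#' Paths address leaves of the nested parameter set, e.g.
#' `"conductances.body_env"` or `"blood_nodes.neck_ven.wall_conductance_W_C"`.
#'
#' @param ps a `parameter_set`.
#' @param path dotted path string.
#' @param value replacement value (for `param_set`).
#' @return `param_get` returns the value; `param_set` the modified set.
#' @export
param_get <- function(ps, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  v <- unclass(ps)
  for (k in keys) {
    v <- v[[k]]
    if (is.null(v)) stop(sprintf("unknown parameter path '%s'", path))
  }
  v
}

#' @rdname param_get
#' @export
param_set <- function(ps, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  expr <- Reduce(function(acc, k) call("[[", acc, k), keys, quote(ps))
  if (is.null(eval(expr))) stop(sprintf("unknown parameter path '%s'", path))
  eval(call("<-", expr, value))
  ps
}

validate_parameter_list <- function(ps) {
  must_pos <- c("body_mass_kg", "flow_m3_s",
                "blood.density_kg_m3", "blood.specific_heat_J_kgC",
                paste0("tissues.", names(ps$tissues), ".mass_kg"),
                paste0("tissues.", names(ps$tissues), ".specific_heat_J_kgC"),
                paste0("blood_nodes.", names(ps$blood_nodes), ".volume_m3"))
  must_nonneg <- c(paste0("conductances.", names(ps$conductances)),
                   paste0("blood_nodes.", names(ps$blood_nodes),
                          ".wall_conductance_W_C"),
                   paste0("tissues.", names(ps$tissues), ".metabolic_fraction"))
  for (p in must_pos) {
    v <- param_get(ps, p)
    if (!is.numeric(v) || !is.finite(v) || v <= 0)
      stop(sprintf("parameter '%s' must be a positive number (got %s)", p, v))
  }
  for (p in must_nonneg) {
    v <- param_get(ps, p)
    if (!is.numeric(v) || !is.finite(v) || v < 0)
      stop(sprintf("parameter '%s' must be non-negative (got %s)", p, v))
  }
  fr <- sum(vapply(ps$tissues, `[[`, 0, "metabolic_fraction"))
  if (abs(fr - 1) > 0.01)
    stop(sprintf("metabolic fractions must sum to 1 (got %.4f)", fr))
  if (!setequal(names(ps$blood_nodes), BLOOD_SEGMENT_IDS))
    stop("blood_nodes must define exactly: ",
         paste(BLOOD_SEGMENT_IDS, collapse = ", "))
  if (!all(names(ps$conductances) %in% CONDUCTANCE_KEYS))
    stop("unknown conductance key(s): ",
         paste(setdiff(names(ps$conductances), CONDUCTANCE_KEYS),
               collapse = ", "))
  invisible(ps)
}

merge_into_defaults <- function(defaults, override, prov, prefix = "") {
  for (nm in names(override)) {
    path <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
    if (!nm %in% names(defaults))
      stop(sprintf("unknown parameter key '%s'", path))
    if (is.list(defaults[[nm]]) && is.list(override[[nm]])) {
      res <- merge_into_defaults(defaults[[nm]], override[[nm]], prov, path)
      defaults[[nm]] <- res$value
      prov <- res$prov
    } else {
      defaults[[nm]] <- override[[nm]]
      prov[[path]] <- prov_override_tag
    }
  }
  list(value = defaults, prov = prov)
}
prov_override_tag <- "file"

#' Load a parameter configuration file
#'
#' Reads a structured (YAML) parameter file, fills any missing keys from
#' the built-in defaults of the file's species (flagging them
#' `"literature-default"`), rejects unknown keys, and validates physical
#' constraints. Keys present in the file are flagged `"file"` unless the
#' file carries its own `provenance` section.
#'
#' @param file path to the configuration file.
#' @param species species defaults to merge into; default the file's
#'   `species` entry.
#' @return a validated `parameter_set`.
#' @export
load_parameters <- function(file, species = NULL) {
  x <- yaml::read_yaml(file)
  species <- species %||% x$species %||% "sheep"
  defaults <- default_parameters(species)
  prov_in <- x$provenance
  x$provenance <- NULL
  x$species <- NULL
  merged <- merge_into_defaults(unclass(defaults)[setdiff(names(defaults), "provenance")],
                                x, defaults$provenance)
  ps <- structure(merged$value, class = "parameter_set")
  ps$species <- species
  ps$provenance <- merged$prov
  for (nm in names(prov_in)) ps$provenance[[nm]] <- prov_in[[nm]]
  validate_parameter_list(ps)
  ps
}

#' Write a parameter set to a configuration file
#'
#' @param ps a `parameter_set`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_parameters <- function(ps, file) {
  yaml::write_yaml(unclass(ps), file, precision = 15)
  invisible(file)
}

#' Metabolic heat of each tissue node (W)
#'
#' @param ps a `parameter_set`.
#' @return named vector of nodal metabolic heats summing to the basal
#'   budget.
#' @export
metabolic_heats <- function(ps) {
  total <- kcal_day_to_W(ps$basal_metabolic_kcal_day)
  vapply(ps$tissues, function(t) t$metabolic_fraction * total, 0)
}

#' Build the canonical thermal network from a parameter set
#'
#' Instantiates the three-compartment topology: tissues body/head/neck; the
#' closed blood loop body_blood -> neck_art -> head_blood -> neck_ven ->
#' body_blood; conduction edges body-env, head-env, body-neck, neck-head;
#' and two collar elements on the neck (element-element, element(s)-env and
#' element-neck edges). The neck has no direct environment edge: the collar
#' covers its surface.
#'
#' @param ps a validated `parameter_set`.
#' @return a `thermal_network` for which [validate_network()] returns no
#'   diagnostics.
#' @export
build_network <- function(ps) {
  validate_parameter_list(ps)
  qm <- metabolic_heats(ps)
  tissues <- lapply(names(ps$tissues), function(id) {
    t <- ps$tissues[[id]]
    tissue_node(id, t$mass_kg, t$specific_heat_J_kgC, qm[[id]])
  })
  upstream <- c(neck_art = "body_blood", head_blood = "neck_art",
                neck_ven = "head_blood", body_blood = "neck_ven")
  contact <- c(neck_art = "neck", head_blood = "head",
               neck_ven = "neck", body_blood = "body")
  blood <- lapply(BLOOD_SEGMENT_IDS, function(id) {
    b <- ps$blood_nodes[[id]]
    blood_node(id, b$volume_m3, upstream[[id]], contact[[id]],
               b$wall_conductance_W_C)
  })
  g <- ps$conductances
  edges <- rbind(
    conductance("body", "env", g$body_env),
    conductance("head", "env", g$head_env),
    conductance("body", "neck", g$body_neck),
    conductance("neck", "head", g$neck_head),
    conductance("el1", "env", g$el_env),
    conductance("el1", "el2", g$el_el),
    conductance("el1", "neck", g$el1_neck),
    conductance("el2", "neck", g$el2_neck))
  if (identical(ps$elements$env_coupling, "both"))
    edges <- rbind(edges, conductance("el2", "env", g$el_env))
  net <- thermal_network(
    tissues = tissues, blood = blood,
    blood_props = do.call(blood_properties, ps$blood),
    flow_m3_s = ps$flow_m3_s,
    conductances = edges,
    environment_T_C = ps$environment_T_C,
    elements = list(ids = c("el1", "el2"), mode = ps$elements$mode,
                    heat_capacity_J_C = ps$elements$heat_capacity_J_C,
                    contact = "neck"))
  diag <- validate_network(net)
  if (length(diag)) stop("invalid network from parameters: ",
                         paste(diag, collapse = "; "))
  net
}

#' Collar specification from a parameter set
#'
#' @param ps a `parameter_set`.
#' @return a [collar_spec()].
#' @export
collar_from_parameters <- function(ps) {
  c <- ps$collar
  collar_spec(c$source_power_W, c$efficiency, c$n_elements,
              c$skin_floor_C, c$guard_band_C %||% 1)
}

#' Path to a bundled parameter file
#'
#' Bundled files: `sheep_default.yaml`, `human_default.yaml` (literature
#' defaults), `sheep_calibrated.yaml`, `human_calibrated.yaml` (fitted to
#' the experimental summary statistics; see [calibrate()]).
#'
#' @param name file name, e.g. `"sheep_calibrated.yaml"`.
#' @return absolute path to the installed file.
#' @export
parameter_file <- function(name) {
  p <- system.file("extdata", name, package = "neckcool")
  if (p == "") stop(sprintf("no bundled parameter file '%s'", name))
  p
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set> species %s, %g kg, basal %g kcal/day, env %g C\n",
              x$species, x$body_mass_kg, x$basal_metabolic_kcal_day,
              x$environment_T_C))
  invisible(x)
}
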