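#' Cooling-collar specification
#'
#' Describes the wearable cooling collar: electrical source power, average
#' conversion efficiency of the cooling elements, number of elements, and
#' the skin-temperature safety floor the feedback controller must not cross.
#' The effective heat removal available to the tissue is
#' `source_power_W * efficiency` (36 W for the default 60 W / 60% device).
#'
#' @param source_power_W electrical power of the source (W).
#' @param efficiency fraction of source power converted to heat removal,
#'   in (0, 1].
#' @param n_elements number of cooling elements (one per carotid).
#' @param skin_floor_C lowest skin temperature the controller allows (C).
#' @param guard_band_C temperature band above the floor over which the
#'   controller linearly throttles extraction to zero (C).
#' @return an object of class `collar_spec`.
#' @export
collar_spec <- function(source_power_W = 60, efficiency = 0.60,
                        n_elements = 2, skin_floor_C = 5,
                        guard_band_C = 1) {
  stopifnot(source_power_W >= 0, efficiency > 0, efficiency <= 1,
            n_elements >= 1, guard_band_C > 0)
  structure(list(source_power_W = source_power_W, efficiency = efficiency,
                 n_elements = n_elements, skin_floor_C = skin_floor_C,
                 guard_band_C = guard_band_C),
            class = "collar_spec")
}

#' Effective heat extraction of a collar
#'
#' @param spec a [collar_spec()].
#' @return total heat removal capacity in W (`source_power_W * efficiency`).
#' @export
effective_extraction <- function(spec) {
  spec$source_power_W * spec$efficiency
}

#' Instantaneous collar extraction under the floor guard
#'
#' The controller runs the elements at the power limit while the contact
#' skin is well above the safety floor, and throttles extraction linearly to
#' zero over the last `guard_band_C` degrees above the floor, so the floor
#' is never crossed. In the lumped model the collar's contact-tissue (neck)
#' temperature stands in for skin temperature.
#'
#' @param spec a [collar_spec()].
#' @param skin_T_C current contact-skin temperature (C).
#' @return total extraction in W.
#' @export
collar_extraction <- function(spec, skin_T_C) {
  frac <- (skin_T_C - spec$skin_floor_C) / spec$guard_band_C
  effective_extraction(spec) * min(max(frac, 0), 1)
}

#' Collar controller state
#'
#' @param spec a [collar_spec()].
#' @param active logical; is the device switched on?
#' @param extraction_per_element_W current heat removal per element (W).
#' @param element_temperatures_C element temperatures (dynamic element mode
#'   only; `NA` for pure-sink elements).
#' @param controller_mode `"power_limited"` when extraction sits at the
#'   power budget, `"floor_limited"` when the skin floor guard throttles it,
#'   `"off"` when inactive.
#' @return an object of class `collar_state`.
#' @export
collar_state <- function(spec, active = TRUE, extraction_per_element_W = 0,
                         element_temperatures_C = NA_real_,
                         controller_mode = c("power_limited", "floor_limited",
                                             "off")) {
  structure(list(spec = spec, active = active,
                 extraction_per_element_W = extraction_per_element_W,
                 element_temperatures_C = element_temperatures_C,
                 controller_mode = match.arg(controller_mode)),
            class = "collar_state")
}

#' Advance the collar controller one feedback step
#'
#' Recomputes the commanded extraction from the current contact-skin
#' temperature: at the power limit away from the floor, throttled inside the
#' guard band, and zero when inactive.
#'
#' @param state a [collar_state()].
#' @param spec a [collar_spec()].
#' @param skin_T_C measured contact-skin temperature (C).
#' @return an updated [collar_state()].
#' @export
collar_update <- function(state, spec, skin_T_C) {
  stopifnot(is.finite(skin_T_C))
  if (!isTRUE(state$active)) {
    state$extraction_per_element_W <- 0
    state$controller_mode <- "off"
    return(state)
  }
  total <- collar_extraction(spec, skin_T_C)
  state$extraction_per_element_W <- total / spec$n_elements
  state$controller_mode <-
    if (total >= effective_extraction(spec)) "power_limited" else "floor_limited"
  state$spec <- spec
  state
}

#' @export
print.collar_spec <- function(x, ...) {
  cat(sprintf("<collar_spec> %g W source x %.0f%% efficiency = %g W extraction, %d elements, skin floor %g C\n",
              x$source_power_W, 100 * x$efficiency, effective_extraction(x),
              x$n_elements, x$skin_floor_C))
  invisible(x)
}
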