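#' Simulation protocol: settle, then cool
#'
#' The experiment protocol has two phases: a settling phase during which the
#' model relaxes to its no-device steady state (presented as 100 min in
#' trajectory figures), followed by one hour of collar cooling sampled at
#' 1 Hz. Settling is resolved by root-finding by default; the settling-phase
#' samples of the trace then simply hold the steady state, unless an
#' `initial_state` is supplied, in which case the settling phase is
#' integrated from it.
#'
#' @param settling_duration_s settling phase length (s), default 6000
#'   (100 min).
#' @param cooling_duration_s cooling phase length (s), default 3600.
#' @param sample_interval_s output sampling interval (s), default 1 (1 Hz).
#' @param initial_state optional named temperature vector to start the
#'   settling phase from (defaults to the computed steady state).
#' @return an object of class `simulation_protocol`.
#' @export
simulation_protocol <- function(settling_duration_s = 6000,
                                cooling_duration_s = 3600,
                                sample_interval_s = 1,
                                initial_state = NULL) {
  stopifnot(settling_duration_s >= 0, cooling_duration_s >= 0,
            sample_interval_s > 0)
  structure(list(settling_duration_s = settling_duration_s,
                 cooling_duration_s = cooling_duration_s,
                 sample_interval_s = sample_interval_s,
                 initial_state = initial_state),
            class = "simulation_protocol")
}

# deSolve adapter around assemble_rhs()
desolve_func <- function(f) {
  function(t, y, parms) list(as.numeric(f(y)))
}

integrate_phase <- function(net, collar, y0, times, rtol = 1e-8, atol = 1e-10) {
  f <- assemble_rhs(net, collar)
  out <- deSolve::ode(y = y0, times = times, func = desolve_func(f),
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed; last accepted state: ",
         paste(sprintf("%s=%.4f", names(y0), out[nrow(out), -1]), collapse = ", "))
  out
}

#' Steady state of a network with the collar off
#'
#' The collar-off network is affine in the temperatures, so the stationary
#' state is obtained exactly by assembling the system matrix column by
#' column from the right-hand side and solving the linear system. If the
#' residual of the solved state exceeds tolerance (e.g. a numerically
#' singular configuration), the state is refined by long integration.
#'
#' @param net a validated [thermal_network()].
#' @param tol maximum admissible `|dT/dt|` (C/s) of the returned state.
#' @return named temperature vector at steady state.
#' @export
find_steady_state <- function(net, tol = 1e-8) {
  diag <- validate_network(net)
  if (length(diag)) stop("invalid network: ", paste(diag, collapse = "; "))
  f <- assemble_rhs(net, collar = NULL)
  ids <- attr(f, "ids")
  n <- length(ids)
  zero <- setNames(numeric(n), ids)
  b <- as.numeric(f(zero))
  A <- matrix(0, n, n)
  for (k in seq_len(n)) {
    e <- zero
    e[k] <- 1
    A[, k] <- as.numeric(f(e)) - b
  }
  x <- tryCatch(setNames(as.numeric(solve(A, -b)), ids), error = function(e) NULL)
  ok <- !is.null(x) && max(abs(f(x))) < tol
  if (!ok) {
    # fall back to relaxation from environment temperature
    y <- setNames(rep(net$environment_T_C, n), ids)
    for (span in c(1e5, 1e6, 1e7)) {
      out <- integrate_phase(net, NULL, y, c(0, span))
      y <- setNames(as.numeric(out[nrow(out), -1]), ids)
      if (max(abs(f(y))) < tol) return(y)
    }
    stop(sprintf("steady state not found: residual %.3g C/s after relaxation",
                 max(abs(f(y)))))
  }
  x
}

#' Run the two-phase cooling protocol
#'
#' Integrates the settling phase with the collar off, then the cooling phase
#' with the collar active, using a stiff-capable adaptive integrator
#' (`lsoda`, rtol 1e-8 / atol 1e-10) sampled on the protocol grid. Time 0 of
#' the returned trace is protocol start; the collar activates at
#' `settling_duration_s` (recorded in `phase_marks`).
#'
#' @param net a validated [thermal_network()].
#' @param collar a [collar_spec()], or `NULL` for a no-device run.
#' @param protocol a [simulation_protocol()].
#' @param rtol,atol integrator tolerances.
#' @return a `temperature_trace`: a data frame with column `time_s` and one
#'   temperature column per state node, with attributes `phase_marks` and
#'   `node_ids`.
#' @export
run_protocol <- function(net, collar = NULL,
                         protocol = simulation_protocol(),
                         rtol = 1e-8, atol = 1e-10) {
  diag <- validate_network(net)
  if (length(diag)) stop("invalid network: ", paste(diag, collapse = "; "))
  ids <- state_ids(net)
  dt <- protocol$sample_interval_s
  t_settle <- protocol$settling_duration_s
  t_cool <- protocol$cooling_duration_s

  steady <- NULL
  if (is.null(protocol$initial_state)) {
    steady <- find_steady_state(net)
    y0 <- steady
    settle_block <- NULL
    if (t_settle > 0) {
      tt <- seq(0, t_settle - dt, by = dt)
      settle_block <- cbind(time_s = tt,
                            matrix(rep(steady, each = length(tt)),
                                   nrow = length(tt), dimnames = list(NULL, ids)))
    }
  } else {
    y0 <- protocol$initial_state[ids]
    settle_block <- NULL
    if (t_settle > 0) {
      out <- integrate_phase(net, NULL, y0, seq(0, t_settle, by = dt),
                             rtol, atol)
      settle_block <- out[-nrow(out), , drop = FALSE]
      colnames(settle_block)[1] <- "time_s"
      y0 <- setNames(as.numeric(out[nrow(out), -1]), ids)
    }
  }

  cool_state <- if (is.null(collar)) NULL else collar_state(collar, active = TRUE)
  out <- integrate_phase(net, cool_state, y0,
                         seq(0, t_cool, by = dt), rtol, atol)
  cool_block <- out
  colnames(cool_block)[1] <- "time_s"
  cool_block[, 1] <- cool_block[, 1] + t_settle

  tr <- as.data.frame(rbind(settle_block, cool_block))
  names(tr) <- c("time_s", ids)
  structure(tr, phase_marks = t_settle, node_ids = ids,
            class = c("temperature_trace", "data.frame"))
}

#' Cooling rate of a node over a time window
#'
#' Computes `(T(start) - T(end)) / hours` from moving-average-smoothed
#' endpoints, the same summary used for the experimental recordings
#' (positive values mean cooling).
#'
#' @param trace a `temperature_trace` from [run_protocol()].
#' @param node node id (e.g. `"head"` for the brain compartment).
#' @param window_start_s,window_end_s window bounds in trace time (s);
#'   default the cooling phase.
#' @param smooth_window_s moving-average window applied before reading the
#'   endpoints (s); `0` disables smoothing.
#' @return cooling rate in C/h.
#' @export
cooling_rate <- function(trace, node,
                         window_start_s = attr(trace, "phase_marks")[1],
                         window_end_s = max(trace$time_s),
                         smooth_window_s = 60) {
  stopifnot(node %in% names(trace), window_end_s > window_start_s)
  tt <- trace$time_s
  if (window_start_s < min(tt) || window_end_s > max(tt))
    stop("window outside trace")
  x <- trace[[node]]
  if (smooth_window_s > 0) x <- moving_average(x, smooth_window_s)
  i0 <- which.min(abs(tt - window_start_s))
  i1 <- which.min(abs(tt - window_end_s))
  (x[i0] - x[i1]) / ((tt[i1] - tt[i0]) / 3600)
}

#' Regression-slope cooling rate
#'
#' Alternative to the endpoint-difference definition: the negated slope of
#' an ordinary least-squares line fitted to the node temperature over the
#' window, in C/h.
#'
#' @inheritParams cooling_rate
#' @return cooling rate in C/h (positive = cooling).
#' @export
cooling_rate_slope <- function(trace, node,
                               window_start_s = attr(trace, "phase_marks")[1],
                               window_end_s = max(trace$time_s)) {
  sel <- trace$time_s >= window_start_s & trace$time_s <= window_end_s
  if (!any(sel)) stop("window outside trace")
  fit <- stats::lm.fit(cbind(1, trace$time_s[sel] / 3600),
                       trace[[node]][sel])
  -unname(fit$coefficients[2])
}

#' Write a temperature trace to CSV
#'
#' @param trace a `temperature_trace`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_trace_csv <- function(trace, file) {
  utils::write.csv(as.data.frame(trace), file, row.names = FALSE)
  invisible(file)
}

#' @export
print.temperature_trace <- function(x, ...) {
  cat(sprintf("<temperature_trace> %d samples x %d nodes, collar on at t=%g s\n",
              nrow(x), length(attr(x, "node_ids")), attr(x, "phase_marks")[1]))
  invisible(x)
}
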