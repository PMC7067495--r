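## Stimulus / perturbation protocols and trajectory integration.

#' Simulation protocol
#'
#' An ordered list of events applied to a resting system.  Supported events:
#' * [ev_sap_pulse()] — instantaneous addition of extracellular SAP,
#'   `S(t+) = S(t) + S0` (the standard stimulus is a single pulse at t = 0);
#' * [ev_clamp_ph()] — intracellular pH fixed at a target value from the
#'   event time onward (the proton ODE is removed from the active system;
#'   emulates sustained alkalinisation, e.g. by NH4Cl);
#' * [ev_voltage_pulse()] — membrane potential clamped to a value for a
#'   fixed duration, then released.
#'
#' @param ... event objects created by the `ev_*` constructors.
#' @param t_start start of the simulation (s); negative values provide a
#'   pre-stimulus baseline window.
#' @param end_time end of the simulation (s).
#' @param dt output sampling interval (s).
#' @return an object of class `flag_protocol`.
#' @export
protocol <- function(..., t_start = -2, end_time = 25, dt = 0.005) {
  events <- list(...)
  if (length(events)) {
    times <- vapply(events, `[[`, 0, "time")
    if (is.unsorted(times)) events <- events[order(times)]
    if (any(times < t_start) || any(times > end_time))
      stop("protocol(): event times must lie within [t_start, end_time]")
  }
  structure(list(events = events, t_start = t_start, end_time = end_time,
                 dt = dt), class = "flag_protocol")
}

#' @rdname protocol
#' @param time event time (s).
#' @param S0 SAP concentration added (nM).
#' @export
ev_sap_pulse <- function(time = 0, S0 = 25) {
  stopifnot(S0 >= 0)
  list(kind = "sap_pulse", time = time, S0 = S0)
}

#' @rdname protocol
#' @param pH_target clamped intracellular pH, held until `end_time`.
#' @export
ev_clamp_ph <- function(time, pH_target) {
  list(kind = "clamp_ph", time = time, pH_target = pH_target)
}

#' @rdname protocol
#' @param V_clamp clamped membrane potential (mV).
#' @param duration clamp duration (s, > 0).
#' @export
ev_voltage_pulse <- function(time, V_clamp, duration) {
  stopifnot(duration > 0)
  list(kind = "voltage_pulse", time = time, V_clamp = V_clamp,
       duration = duration)
}

#' Integrate a model variant under a protocol
#'
#' Starts from [resting_state()] (unless `state0` overrides it), applies the
#' protocol events and integrates with a stiff solver
#' ([deSolve::lsoda()] by default; the system mixes millisecond gating with
#' ten-second envelopes).  Clamped variables are held exactly: their ODE is
#' removed from the active system for the duration of the clamp, so the
#' output satisfies d(clamped)/dt = 0 identically.
#'
#' Equilibrium-constrained parameters are re-derived via
#' [derive_parameters()] before integration unless `derive = FALSE`, so that
#' an event-free protocol yields a constant trajectory.
#'
#' @param params a `flag_params` object.
#' @param config a `flag_config` object (or module name).
#' @param proto a `flag_protocol`; default: single 25-nM SAP pulse at t = 0.
#' @param state0 optional initial state overriding the resting state.
#' @param rtol,atol solver tolerances; `atol` defaults to 1e-6 of the
#'   typical scale of each variable.
#' @param method solver method passed to [deSolve::ode()].
#' @param derive re-derive `E_L`, `sigma_C`, `delta_H` before integrating.
#' @return a `flag_ts` data frame: `time`, the state columns, `pH` (when
#'   protons are modelled) and per-channel current densities.  Attributes
#'   `config`, `params` and `protocol` carry the provenance.
#' @export
simulate_model <- function(params, config, proto = protocol(ev_sap_pulse()),
                           state0 = NULL, rtol = 1e-8, atol = NULL,
                           method = "lsoda", derive = TRUE) {
  if (is.character(config)) config <- module_config(config)
  if (derive) params <- derive_parameters(params, config)
  nm <- state_names(config)
  if (is.null(atol)) atol <- .state_atol(config)
  y <- if (is.null(state0)) resting_state(params, config) else state0[nm]

  ## split [t_start, end_time] into segments at event times and clamp
  ## releases; track the set of clamped variables per segment
  evs <- proto$events
  breaks <- proto$t_start
  for (e in evs) {
    breaks <- c(breaks, e$time)
    if (e$kind == "voltage_pulse") breaks <- c(breaks, e$time + e$duration)
  }
  breaks <- sort(unique(c(breaks, proto$end_time)))
  breaks <- breaks[breaks >= proto$t_start & breaks <= proto$end_time]

  grid <- seq(proto$t_start, proto$end_time, by = proto$dt)
  out <- NULL
  v_release <- Inf
  clamped <- character(0)

  for (k in seq_len(length(breaks) - 1)) {
    t0 <- breaks[k]; t1 <- breaks[k + 1]
    for (e in evs) {
      if (isTRUE(all.equal(e$time, t0)) || e$time == t0) {
        if (e$kind == "sap_pulse") y["S"] <- y["S"] + e$S0
        if (e$kind == "clamp_ph") {
          if (!("H" %in% nm))
            stop("clamp_ph requires a configuration with proton dynamics")
          y["H"] <- 10^(-e$pH_target)
          clamped <- union(clamped, "H")
        }
        if (e$kind == "voltage_pulse") {
          y["V"] <- e$V_clamp
          clamped <- union(clamped, "V")
          v_release <- e$time + e$duration
        }
      }
    }
    if (t0 >= v_release) { clamped <- setdiff(clamped, "V"); v_release <- Inf }

    seg_grid <- unique(c(t0, grid[grid > t0 & grid < t1], t1))
    idx_cl <- match(clamped, nm)
    rhs <- .make_rhs(params, config)
    fn <- if (length(idx_cl)) {
      function(t, yy, pp) { dd <- rhs(yy); dd[idx_cl] <- 0; list(dd) }
    } else function(t, yy, pp) list(rhs(yy))
    sol <- deSolve::ode(y = y, times = seg_grid, func = fn, parms = NULL,
                        method = method, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("solver failure in segment [%g, %g] near t = %g",
                   t0, t1, sol[nrow(sol), "time"]))
    y <- sol[nrow(sol), -1]
    keep <- if (k < length(breaks) - 1) sol[-nrow(sol), , drop = FALSE]
            else sol
    out <- rbind(out, keep)
  }

  out <- as.data.frame(out)
  names(out) <- c("time", nm)
  out <- out[!duplicated(out$time), ]
  rownames(out) <- NULL
  if ("H" %in% nm) out$pH <- -log10(out$H)
  out <- cbind(out, current_densities(out, params, config))
  structure(out, params = params, config = config, protocol = proto,
            class = c("flag_ts", "data.frame"))
}

#' Reference run of the upstream module
#'
#' Integrates the isolated upstream module (state
#' `{S, R_F, R_H, R_L, G, f_kn, m_hc, V}`) under a single SAP pulse.  The
#' cGMP trace is biphasic (fast peak, slow quasi-plateau decay) and the
#' membrane potential shows a transient hyperpolarisation with partial
#' recovery; a variant with `g_hc = 0` (KCNG only) approaches the potassium
#' equilibrium potential instead.
#'
#' @param params a `flag_params` object (upstream block used).
#' @param S0 SAP pulse amplitude (nM).
#' @param end_time simulation end (s).
#' @param ... passed to [simulate_model()].
#' @return a `flag_ts` data frame.
#' @export
upstream_reference_run <- function(params = reference_params("upstream"),
                                   S0 = 25, end_time = 10, ...) {
  cfg <- module_config("upstream")
  simulate_model(params, cfg,
                 protocol(ev_sap_pulse(0, S0), end_time = end_time,
                          dt = 0.002),
                 ...)
}

#' Write / read a trajectory as tidy CSV with a JSON metadata sidecar
#'
#' One row per sample; the sidecar (same path with `.json` appended) stores
#' the module configuration and the full parameter set.
#'
#' @param ts a `flag_ts` data frame.
#' @param path CSV file path.
#' @return `write_timeseries()` returns `path` invisibly;
#'   `read_timeseries()` returns a data frame (metadata in attributes when
#'   the sidecar is present).
#' @export
write_timeseries <- function(ts, path) {
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE)
  cfg <- attr(ts, "config")
  par <- attr(ts, "params")
  meta <- list(module = if (!is.null(cfg)) cfg$module else NA,
               theta_cv = cfg$theta_cv, theta_cs = cfg$theta_cs,
               params = if (!is.null(par)) unclass(par) else NULL)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path)
  side <- paste0(path, ".json")
  if (file.exists(side))
    attr(df, "meta") <- jsonlite::read_json(side, simplifyVector = TRUE)
  df
}
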