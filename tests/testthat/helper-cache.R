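# Memoised reference simulations shared across test files (each is a plain
# package call; caching only avoids recomputing identical trajectories).
.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache))
    assign(key, force(expr), envir = .run_cache)
  get(key, envir = .run_cache)
}

# CaV+BK reference response to the standard 25 nM SAP pulse.
ref_run_cav <- function() cached("cav25", {
  simulate_model(reference_params("cav_bk"), module_config("cav_bk"),
                 protocol(ev_sap_pulse(0, 25), t_start = -2, end_time = 25))
})

# CatSper+NHE response at a stimulus inside the module's oscillatory window
# (10 nM; see the methods vignette on the stimulus choice).
ref_run_cs <- function() cached("cs10", {
  simulate_model(reference_params("catsper_nhe"),
                 module_config("catsper_nhe"),
                 protocol(ev_sap_pulse(0, 10), t_start = -2, end_time = 30))
})

# CatSper+NHE response at the 25 nM stimulus of the standard protocol.
ref_run_cs25 <- function() cached("cs25", {
  simulate_model(reference_params("catsper_nhe"),
                 module_config("catsper_nhe"),
                 protocol(ev_sap_pulse(0, 25), t_start = -2, end_time = 30))
})

# Random admissible state for a configuration (away from rate singularities
# with probability one).
random_state <- function(config, params) {
  st <- resting_state(params, config)
  st["S"] <- stats::runif(1, 0, 30)
  st["R_F"] <- stats::runif(1, 0, params$R_T)
  st["R_H"] <- stats::runif(1, 0, 0.2 * params$R_T)
  st["R_L"] <- stats::runif(1, 0, 0.5 * params$R_T)
  st["G"] <- stats::runif(1, 0.2, 50)
  st["V"] <- stats::runif(1, -85, 25)
  for (v in intersect(c("f_kn", "m_hc", "f_bk", "m_cs", "h_cs", "f_nh"),
                      names(st)))
    st[v] <- stats::runif(1)
  if ("f_cv_o" %in% names(st)) {
    u <- stats::runif(2)
    st["f_cv_o"] <- min(u) * 0.999
    st["f_cv_c"] <- (max(u) - min(u)) * 0.999
  }
  if ("C" %in% names(st)) st["C"] <- stats::runif(1, 5, 3000)
  if ("H" %in% names(st)) st["H"] <- 10^(-stats::runif(1, 6.5, 8))
  st
}
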