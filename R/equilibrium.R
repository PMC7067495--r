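## Resting state at S = 0 and the equilibrium-constrained parameters.
##
## Three parameters are not free but pinned by the requirement that the
## system rests at (V = E_m, G = G_r, C = C_r, pH = pH_r) in the absence of
## SAP: the leak reversal potential E_L (charge balance), the
## channel-independent calcium source sigma_C (calcium balance) and the
## proton leak rate delta_H (proton balance).  They are derived here in
## closed form from the resting gate fractions.

# Steady-state gate fractions at a given operating point.
.gate_steady <- function(params, V, G, C, H) {
  p <- params
  kn <- kcng_equilibrium(G, p$alpha_kn, p$beta_kn)
  hc <- sphcn_gate(V, p$h1, p$h2, p$h3, p$h4, p$h5, p$h6)
  cv <- cav_rates(V, p$v1, p$v2, p$v3, p$v4, p$v5, p$v6, p$v7, p$v8, p$v9)
  den <- cv$alpha * cv$beta + cv$beta * cv$gamma + cv$alpha * cv$gamma
  f_cv_o <- cv$alpha * cv$beta / den
  f_cv_c <- cv$alpha * cv$gamma / den
  a_bk <- bk_opening_rate(C, p$b1, p$b2, p$b3)
  nh <- nhe_rates(V, p$n1, p$n2, p$n3, p$n4, p$n5, p$n6)
  cs <- catsper_gates(V, C, H, p$s1, p$s2, p$s3, p$s4, p$s5, p$s6, p$s7,
                      p$s8, p$s9, p$s10)
  list(f_kn = kn$f_open, m_hc = hc$m, f_hc = hc$f_open,
       f_cv_o = f_cv_o, f_cv_c = f_cv_c,
       f_bk = a_bk / (a_bk + p$beta_bk),
       f_nh = nh$alpha / (nh$alpha + nh$beta),
       m_cs = cs$m_inf, h_cs = cs$h_inf, f_cs = cs$m_inf * cs$h_inf)
}

#' Resting state in the absence of SAP
#'
#' Every gating variable at its steady state given the imposed resting
#' operating point (`V = E_m`, `G = G_r`, `C = C_r`, `H = 10^-pH_r`), with
#' `S = 0` and all receptors free.
#'
#' @param params a `flag_params` object.
#' @param config a `flag_config` object.
#' @return named state vector matching [state_names()].
#' @export
resting_state <- function(params, config) {
  p <- params
  H_r <- 10^(-p$pH_r)
  g <- .gate_steady(p, p$E_m, p$G_r, p$C_r, H_r)
  st <- c(S = 0, R_F = p$R_T, R_H = 0, R_L = 0, G = p$G_r,
          f_kn = g$f_kn, m_hc = g$m_hc, V = p$E_m)
  if (config$has_cav) st <- c(st, f_cv_o = g$f_cv_o, f_cv_c = g$f_cv_c)
  if (config$has_bk) st <- c(st, f_bk = g$f_bk)
  if (config$has_catsper) st <- c(st, m_cs = g$m_cs, h_cs = g$h_cs)
  if (config$has_nhe) st <- c(st, f_nh = g$f_nh)
  if (config$has_calcium) st <- c(st, C = p$C_r)
  if (config$has_nhe) st <- c(st, H = H_r)
  st
}

# Resting current densities of the channels present in a configuration.
.resting_currents <- function(params, config, rest = NULL) {
  if (is.null(rest)) rest <- resting_state(params, config)
  current_densities(as.data.frame(as.list(rest)), params, config)
}

#' Leak reversal potential from the resting charge balance
#'
#' Zero net current at rest requires
#' `g_L (E_m - E_L) + sum_i g_i f_i (E_m - E_i) = 0`, i.e.
#' `E_L = E_m + (1/g_L) sum_i g_i f_i (E_m - E_i)` over the channels of the
#' configuration.  (This charge-balance form, rather than a product form, is
#' the dimensionally consistent constraint and reproduces both tabulated
#' reference values.)
#'
#' @param params a `flag_params` object (`g_L > 0`).
#' @param config a `flag_config` object.
#' @param rest optional precomputed resting state.
#' @return leak reversal potential (mV).
#' @export
derive_leak_reversal <- function(params, config, rest = NULL) {
  if (params$g_L <= 0) stop("derive_leak_reversal(): g_L must be positive")
  cur <- .resting_currents(params, config, rest)
  chan <- setdiff(names(cur), "I_L")
  params$E_m + sum(unlist(cur[chan])) / params$g_L
}

#' Channel-independent calcium source from the resting calcium balance
#'
#' `sigma_C = delta_C C_r + (s_f / 2 v_f F) sum_j I_j(rest)` over the
#' calcium-carrying channels `j` of the configuration.  Resting calcium
#' currents are inward (negative), so the derived source is smaller than the
#' bare extrusion term `delta_C C_r`.
#'
#' @inheritParams derive_leak_reversal
#' @return calcium source rate (nM s^-1).
#' @export
derive_calcium_source <- function(params, config, rest = NULL) {
  cur <- .resting_currents(params, config, rest)
  I_ca <- 0
  if (!is.null(cur$I_cv)) I_ca <- I_ca + cur$I_cv
  if (!is.null(cur$I_cs)) I_ca <- I_ca + cur$I_cs
  params$delta_C * params$C_r + calcium_flux_factor(params) * I_ca
}

#' Proton leak rate from the resting proton balance
#'
#' `delta_H = (sigma_H - J_H(rest) / v_f) / H_r` with `H_r = 10^-pH_r` and
#' the resting exchanger flux evaluated at the resting NHE active fraction.
#'
#' @inheritParams derive_leak_reversal
#' @return proton extrusion/consumption rate constant (s^-1).
#' @export
derive_proton_leak <- function(params, config = NULL, rest = NULL) {
  p <- params
  H_r <- 10^(-p$pH_r)
  nh <- nhe_rates(p$E_m, p$n1, p$n2, p$n3, p$n4, p$n5, p$n6)
  f_nh <- nh$alpha / (nh$alpha + nh$beta)
  J <- nhe_proton_flux(f_nh, H_r, p$J_max, p$Na_out, p$Na_in, p$K_Na,
                       p$pH_out)
  dH <- (p$sigma_H - J / p$v_f) / H_r
  if (dH < 0)
    stop("derive_proton_leak(): negative rate; sigma_H and J_max inconsistent")
  dH
}

#' Unit-conversion factors of the receptor/cGMP block
#'
#' `theta_G = 1 / (v_f B_G N_A)` converts a per-cell cGMP synthesis rate
#' into an effective intraflagellar concentration rate (nM cell);
#' `theta_R = s / N_A` converts receptor-bound SAP molecules per cell into
#' the solution concentration they deplete (nM cell), with `s` the sperm
#' density per litre.
#'
#' @param params a `flag_params` object (uses `v_f`, `B_G`, `s_density`).
#' @return named numeric vector with `theta_G` and `theta_R` (nM cell).
#' @export
conversion_factors <- function(params) {
  NAv <- physical_constants[["NA_const"]]
  theta_G <- 1 / (params$v_f * 1e-15 * params$B_G * NAv) * 1e9
  theta_R <- params$s_density * 1e3 / NAv * 1e9
  c(theta_G = theta_G, theta_R = theta_R)
}

#' Channels per flagellum implied by a conductance density
#'
#' @param g_density maximal conductance density (pS um^-2).
#' @param membrane_area flagellar membrane area (um^2).
#' @param unitary_conductance single-channel conductance (pS).
#' @return implied channel count (not rounded).
#' @export
channel_count <- function(g_density, membrane_area, unitary_conductance) {
  if (any(c(g_density, membrane_area, unitary_conductance) <= 0))
    stop("channel_count(): all inputs must be positive")
  g_density * membrane_area / unitary_conductance
}

#' Derive the equilibrium-constrained parameters of a configuration
#'
#' Replaces `E_L`, `sigma_C` (when the configuration carries calcium) and
#' `delta_H` (always, so that proton machinery attached to any variant is
#' equilibrated) by their closed-form values at the resting condition.
#' After this call the model vector field vanishes at [resting_state()] to
#' solver precision.
#'
#' @param params a `flag_params` object.
#' @param config a `flag_config` object.
#' @return the updated parameter set.
#' @export
derive_parameters <- function(params, config) {
  rest <- resting_state(params, config)
  params$E_L <- derive_leak_reversal(params, config, rest)
  if (config$has_calcium)
    params$sigma_C <- derive_calcium_source(params, config, rest)
  params$delta_H <- derive_proton_leak(params)
  params
}

#' Table of derived equilibrium quantities
#'
#' Summarises, for a module preset, the derived parameters, the resting gate
#' fractions, the per-channel resting current densities and the implied
#' channel counts per flagellum (at the tabulated unitary conductances:
#' KCNG 110 pS, spHCN 43 pS, CaV 4.7 pS, BK 70 pS).
#'
#' @param module module preset name, or a `flag_params` object.
#' @param config optional `flag_config`; defaults to the module of `params`.
#' @return a list with elements `derived`, `resting_fractions`,
#'   `resting_currents` and `channel_counts`.
#' @export
derived_table <- function(module = "cav_bk", config = NULL) {
  params <- if (inherits(module, "flag_params")) module else
    reference_params(module)
  if (is.null(config)) config <- module_config(attr(params, "module"))
  params <- derive_parameters(params, config)
  rest <- resting_state(params, config)
  cf <- conversion_factors(params)
  counts <- c(kcng = channel_count(params$g_kn, params$s_f, 110),
              sphcn = channel_count(params$g_hc, params$s_f, 43))
  if (config$has_cav)
    counts["cav"] <- channel_count(params$g_cv, params$s_f, 4.7)
  if (config$has_bk)
    counts["bk"] <- channel_count(params$g_bk, params$s_f, 70)
  gate_cols <- intersect(c("f_kn", "m_hc", "f_cv_o", "f_cv_c", "f_bk",
                           "m_cs", "h_cs", "f_nh"), names(rest))
  list(derived = c(E_L = params$E_L, sigma_C = params$sigma_C,
                   delta_H = params$delta_H, cf),
       resting_fractions = rest[gate_cols],
       resting_currents = unlist(.resting_currents(params, config, rest)),
       channel_counts = counts)
}
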