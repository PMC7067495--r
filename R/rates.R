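## Gating-rate primitives shared by all model variants.
##
## Internal unit conventions (used consistently across the package):
##   voltage mV, time s, conductance density pS um^-2, current density
##   fA um^-2, capacitance pF um^-2, cGMP and Ca2+ in nM, protons in M,
##   flagellar volume fL, membrane area um^2.

#' Physical constants
#'
#' Faraday constant (C mol^-1), molar gas constant (J K^-1 mol^-1) and the
#' Avogadro constant (mol^-1), as used internally for flux conversions.
#'
#' @format A named numeric vector with elements `F`, `R` and `NA_const`.
#' @export
physical_constants <- c(F = 96485.33212, R = 8.31446262, NA_const = 6.02214076e23)

#' Exponential-linear kernel x / (exp(x) - 1)
#'
#' All voltage-dependent opening/closing rates of the CaV, BK and NHE models
#' are of the exponential-linear form `a * x / (exp(x/b) - 1)`, which has a
#' removable singularity at `x = 0`.  This kernel evaluates
#' `x / (exp(x) - 1)` switching to its Taylor expansion
#' `1 - x/2 + x^2/12` for `|x| < 1e-4`, where the direct expression loses
#' precision; the switch keeps the function continuous to better than 1e-9.
#'
#' @param x numeric vector.
#' @return numeric vector, `x / (exp(x) - 1)` with `explin(0) = 1`.
#' @keywords internal
explin <- function(x) {
  out <- x / expm1(x)
  small <- abs(x) < 1e-4
  if (any(small)) out[small] <- 1 - x[small] / 2 + x[small]^2 / 12
  out
}

#' Nernst equilibrium potential
#'
#' `E = (RT / zF) log(conc_out / conc_in)`, returned in mV.  Temperature is
#' supplied in degrees Celsius and converted to kelvin.  Both concentrations
#' must be in the same unit.
#'
#' @param valence ion charge number (non-zero integer).
#' @param conc_out,conc_in outer and inner concentrations (> 0, same unit).
#' @param temperature_C temperature in degrees Celsius (default 17, the
#'   sea-water temperature the reference potentials were computed at).
#' @return equilibrium potential in mV.
#' @examples
#' nernst_potential(1, 9, 219)          # K+  ~ -80 mV
#' nernst_potential(2, 10e-3, 100e-9)   # Ca2+ ~ 144 mV
#' @export
nernst_potential <- function(valence, conc_out, conc_in, temperature_C = 17) {
  if (any(conc_out <= 0) || any(conc_in <= 0))
    stop("nernst_potential(): concentrations must be positive")
  if (any(valence == 0))
    stop("nernst_potential(): valence must be non-zero")
  TK <- temperature_C + 273.15
  1000 * physical_constants[["R"]] * TK /
    (valence * physical_constants[["F"]]) * log(conc_out / conc_in)
}

#' KCNG channel: steady-state open fraction and time constant
#'
#' Non-cooperative cGMP gating: opening rate `alpha_kn * G`, closing rate
#' `beta_kn`, so the steady state is `G / (G + K_kn)` with
#' `K_kn = beta_kn / alpha_kn` and the relaxation time
#' `1 / (alpha_kn * (G + K_kn))`.
#'
#' @param G cGMP concentration (nM, >= 0).
#' @param alpha_kn opening rate constant (nM^-1 s^-1).
#' @param beta_kn closing rate constant (s^-1).
#' @return list with `f_open` (steady-state open fraction) and `tau` (s).
#' @export
kcng_equilibrium <- function(G, alpha_kn, beta_kn) {
  if (any(G < 0)) stop("kcng_equilibrium(): G must be non-negative")
  if (alpha_kn <= 0 || beta_kn <= 0)
    stop("kcng_equilibrium(): rates must be positive")
  K <- beta_kn / alpha_kn
  list(f_open = G / (G + K), tau = 1 / (alpha_kn * (G + K)))
}

#' spHCN channel: steady-state gate and time constant
#'
#' Boltzmann activation (opening on hyperpolarisation) with a Gaussian
#' voltage dependence of the gating time constant.  The channel opens with
#' three independent gates, so the open-channel fraction is `m^3`.
#'
#' @param V membrane potential (mV).
#' @param h1 half-activation voltage (mV).
#' @param h2 voltage sensitivity (mV, non-zero).
#' @param h3 basal time constant (s).
#' @param h4 time-constant amplitude (s).
#' @param h5 voltage of maximal time constant (mV).
#' @param h6 width of the time-constant peak (mV, non-zero).
#' @return list with `m` (steady-state gate), `tau` (s) and `f_open`
#'   (`= m^3`).
#' @export
sphcn_gate <- function(V, h1, h2, h3, h4, h5, h6) {
  if (h2 == 0 || h6 == 0) stop("sphcn_gate(): h2 and h6 must be non-zero")
  m <- 1 / (1 + exp((V - h1) / h2))
  tau <- h3 + h4 * exp(-((V - h5) / h6)^2)
  list(m = m, tau = tau, f_open = m^3)
}

#' CaV channel transition rates
#'
#' Voltage-dependent rates of the irreversible inactive -> closed -> open ->
#' inactive cycle: `alpha` (recovery from inactivation, favoured by
#' hyperpolarisation), `beta` (opening) and `gamma` (inactivation).  All are
#' exponential-linear with removable singularities at `v2`, `v5` and `v8`,
#' evaluated through [explin()].
#'
#' @param V membrane potential (mV).
#' @param v1,v2,v3 recovery rate constant (mV^-1 s^-1), inflexion (mV),
#'   sensitivity (mV).
#' @param v4,v5,v6 opening rate parameters (same roles).
#' @param v7,v8,v9 inactivation rate parameters (same roles).
#' @return list with rates `alpha`, `beta`, `gamma` (s^-1).
#' @export
cav_rates <- function(V, v1, v2, v3, v4, v5, v6, v7, v8, v9) {
  list(alpha = v1 * v3 * explin((V - v2) / v3),
       beta  = v4 * v6 * explin(-(V - v5) / v6),
       gamma = v7 * v9 * explin(-(V - v8) / v9))
}

#' BK channel calcium-dependent opening rate
#'
#' `alpha_bk = b1 (b2 - C) / (exp((b2 - C)/b3) - 1)`, monotone increasing in
#' C, with the removable singularity at `C = b2` evaluated by [explin()].
#'
#' @param C intraflagellar calcium (nM, >= 0).
#' @param b1 rate constant (nM^-1 s^-1).
#' @param b2 calcium inflexion point (nM).
#' @param b3 calcium sensitivity (nM, non-zero).
#' @return opening rate (s^-1).
#' @export
bk_opening_rate <- function(C, b1, b2, b3) {
  if (b3 == 0) stop("bk_opening_rate(): b3 must be non-zero")
  b1 * b3 * explin((b2 - C) / b3)
}

#' NHE voltage-dependent activation and inactivation rates
#'
#' The sodium/proton exchanger carries a voltage-sensor domain; activation is
#' favoured by hyperpolarisation, inactivation by depolarisation.  Both rates
#' are exponential-linear with removable singularities at `n2` and `n5`.
#'
#' @param V membrane potential (mV).
#' @param n1,n2,n3 activation rate constant (mV^-1 s^-1), inflexion (mV),
#'   sensitivity (mV).
#' @param n4,n5,n6 inactivation rate parameters (same roles).
#' @return list with `alpha` (activation) and `beta` (inactivation), s^-1.
#' @export
nhe_rates <- function(V, n1, n2, n3, n4, n5, n6) {
  list(alpha = n1 * n3 * explin((V - n2) / n3),
       beta  = n4 * n6 * explin(-(V - n5) / n6))
}

#' NHE proton flux (reversible rapid-equilibrium random-order bi-bi kinetics)
#'
#' Per-cell proton efflux carried by the active exchangers.  All
#' concentrations are converted to molar before evaluation (sodium and the
#' sodium dissociation constant are supplied in mM, protons in M); `J_max` is
#' in fmol s^-1, so dividing the returned flux by the flagellar volume in fL
#' yields a rate in M s^-1 directly.
#'
#' @param f_active fraction of active exchangers (0..1).
#' @param H intraflagellar proton concentration (M, > 0).
#' @param J_max maximal exchange rate (fmol s^-1).
#' @param Na_out,Na_in extracellular / intraflagellar sodium (mM).
#' @param K_Na sodium dissociation constant (mM).
#' @param pH_out extracellular pH.
#' @return proton efflux (fmol s^-1).  Zero at `f_active = 0` and at the
#'   thermodynamic reversal point `H = 10^-pH_out * Na_in / Na_out`.
#' @export
nhe_proton_flux <- function(f_active, H, J_max, Na_out, Na_in, K_Na, pH_out) {
  if (any(H <= 0)) stop("nhe_proton_flux(): H must be positive")
  nao <- Na_out * 1e-3
  nai <- Na_in * 1e-3
  kna <- K_Na * 1e-3
  ho <- 10^(-pH_out)
  f_active * J_max * (H * nao - ho * nai) /
    (H * nao + kna * (H + ho) + ho * nai)
}

#' CatSper half-activation voltage as a function of intracellular pH
#'
#' A Hill function of pH_i shifts the voltage gate towards more negative
#' potentials on alkalinisation:
#' `v_cs = s3 * s4^s5 / (pH^s5 + s4^s5) + s6` with `pH = -log10(H)`.
#'
#' @param H proton concentration (M, > 0).
#' @param s3 amplitude of the pH response (mV).
#' @param s4 pH of half-maximal shift.
#' @param s5 Hill coefficient.
#' @param s6 pH-independent minimal half-activation voltage (mV).
#' @return half-activation voltage (mV), monotone decreasing in pH.
#' @export
catsper_vhalf <- function(H, s3, s4, s5, s6) {
  if (any(H <= 0)) stop("catsper_vhalf(): H must be positive")
  pH <- -log10(H)
  s3 / (1 + (pH / s4)^s5) + s6
}

#' CatSper gating rates and steady states
#'
#' The voltage/pH gate `m` has symmetric exponential rates
#' `alpha_m = s1 exp(-(v_cs - V)/(2 s2))`, `beta_m = s1 exp((v_cs - V)/(2 s2))`
#' giving a Boltzmann steady state; the calcium-inactivation gate `h` has
#' rates `alpha_h = s10 (s8/s7)^s9`, `beta_h = s10 (C/s7)^s9` giving a Hill
#' steady state with IC50 `s8`.  The open-channel fraction is `m * h`.
#'
#' @param V membrane potential (mV).
#' @param C intraflagellar calcium (nM, >= 0).
#' @param H proton concentration (M, > 0).
#' @param s1,s2 voltage-gate rate constant (s^-1) and sensitivity (mV).
#' @param s3,s4,s5,s6 parameters of [catsper_vhalf()].
#' @param s7 calcium scaling factor (nM).
#' @param s8 calcium IC50 (nM).
#' @param s9 Hill coefficient of calcium inactivation.
#' @param s10 calcium-inactivation rate constant (nM^-1 s^-1).
#' @return list with rates `alpha_m`, `beta_m`, `alpha_h`, `beta_h` and
#'   steady states `m_inf`, `h_inf`, plus `v_cs`.
#' @export
catsper_gates <- function(V, C, H, s1, s2, s3, s4, s5, s6, s7, s8, s9, s10) {
  if (s2 == 0) stop("catsper_gates(): s2 must be non-zero")
  if (s7 <= 0) stop("catsper_gates(): s7 must be positive")
  vcs <- catsper_vhalf(H, s3, s4, s5, s6)
  u <- (vcs - V) / (2 * s2)
  am <- s1 * exp(-u)
  bm <- s1 * exp(u)
  ah <- s10 * (s8 / s7)^s9
  bh <- s10 * (C / s7)^s9
  list(alpha_m = am, beta_m = bm, alpha_h = ah, beta_h = bh,
       m_inf = am / (am + bm), h_inf = ah / (ah + bh), v_cs = vcs)
}

#' Ohmic ionic current density
#'
#' `I = g * f_open * (V - E_rev)` in fA um^-2.  Positive current is outward
#' (hyperpolarising in the charge-balance equation).
#'
#' @param g maximal conductance density (pS um^-2, >= 0).
#' @param f_open open-channel fraction (0..1).
#' @param V membrane potential (mV).
#' @param E_rev reversal potential (mV).
#' @return current density (fA um^-2).
#' @export
current_density <- function(g, f_open, V, E_rev) {
  g * f_open * (V - E_rev)
}
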