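## Module configurations, state templates and the model vector field.

#' Module configuration
#'
#' Selects which downstream channels feed the voltage and calcium balances.
#' The upstream chain (SAP receptor, cGMP, KCNG, spHCN) is present in every
#' variant.  For the `"mixed"` variant the two module weights scale the
#' CaV/BK and CatSper conductances (see [mixed_parameters()]); the weight
#' pairs (1, 0) and (0, 1) reproduce the pure modules exactly.
#'
#' @param module `"upstream"`, `"cav_bk"`, `"catsper_nhe"` or `"mixed"`.
#' @param theta_cv,theta_cs non-negative module weights (mixed only).
#' @return an object of class `flag_config`.
#' @export
module_config <- function(module = c("cav_bk", "catsper_nhe", "upstream",
                                     "mixed"),
                          theta_cv = NULL, theta_cs = NULL) {
  module <- match.arg(module)
  if (module == "mixed") {
    if (is.null(theta_cv) || is.null(theta_cs))
      stop("mixed configuration needs theta_cv and theta_cs")
    if (theta_cv < 0 || theta_cs < 0)
      stop("module weights must be non-negative")
  }
  structure(list(module = module,
                 theta_cv = theta_cv, theta_cs = theta_cs,
                 has_cav = module %in% c("cav_bk", "mixed"),
                 has_bk = module %in% c("cav_bk", "mixed"),
                 has_catsper = module %in% c("catsper_nhe", "mixed"),
                 has_nhe = module %in% c("catsper_nhe", "mixed"),
                 has_calcium = module != "upstream"),
            class = "flag_config")
}

#' State variable names of a configuration
#'
#' @param config a `flag_config` object.
#' @return character vector of dynamical variable names, in canonical order.
#' @export
state_names <- function(config) {
  nm <- c("S", "R_F", "R_H", "R_L", "G", "f_kn", "m_hc", "V")
  if (config$has_cav) nm <- c(nm, "f_cv_o", "f_cv_c")
  if (config$has_bk) nm <- c(nm, "f_bk")
  if (config$has_catsper) nm <- c(nm, "m_cs", "h_cs")
  if (config$has_nhe) nm <- c(nm, "f_nh")
  if (config$has_calcium) nm <- c(nm, "C")
  if (config$has_nhe) nm <- c(nm, "H")
  nm
}

# Per-variable absolute tolerances on the natural scale of each variable.
.state_atol <- function(config) {
  tol <- c(S = 1e-6, R_F = 1e-1, R_H = 1e-1, R_L = 1e-1, G = 1e-6,
           f_kn = 1e-9, m_hc = 1e-9, V = 1e-6, f_cv_o = 1e-12,
           f_cv_c = 1e-9, f_bk = 1e-9, m_cs = 1e-9, h_cs = 1e-9,
           f_nh = 1e-9, C = 1e-4, H = 1e-16)
  unname(tol[state_names(config)])
}

# Conversion from summed Ca2+ current density (fA um^-2) to a concentration
# rate (nM s^-1): s_f/(2 v_f F); the femto prefixes of fA and fL cancel and
# the 1e9 rescales M to nM.
calcium_flux_factor <- function(params) {
  params$s_f / (2 * physical_constants[["F"]] * params$v_f) * 1e9
}

#' Model vector field
#'
#' Time derivative of the model state for any configuration, in native units
#' (see [reference_params()]).  The receptor chain conserves
#' `R_F + R_H + R_L + R_I = R_T` with `R_I` implicit; cGMP production by
#' active receptors is `theta_G * (k_H R_H + k_L R_L)`; calcium balance is
#' `sigma_C - delta_C C - (s_f / 2 v_f F) * sum(I_Ca)` where inward calcium
#' currents are negative, so the current term is a positive influx; the
#' proton balance (present with NHE) is `sigma_H - delta_H H - J_H / v_f`.
#'
#' @param state named numeric vector matching [state_names()] of `config`.
#' @param params a `flag_params` object.
#' @param config a `flag_config` object.
#' @param time time (s); the system is autonomous, the argument exists for
#'   solver compatibility.
#' @return named numeric vector of derivatives.
#' @export
model_rhs <- function(state, params, config, time = 0) {
  nm <- state_names(config)
  if (length(state) != length(nm))
    stop(sprintf("state has %d components; configuration '%s' needs %d (%s)",
                 length(state), config$module, length(nm),
                 paste(nm, collapse = ", ")))
  if (is.null(names(state))) names(state) <- nm
  d <- .rhs_core(state, params, config)
  names(d) <- nm
  d
}

# Build a fast derivative closure for a fixed (params, config) pair: all
# parameter values and structural indices are captured once, so the per-call
# cost is pure arithmetic.  Returns function(y) -> derivative vector.
.make_rhs <- function(p, config) {
  has_cav <- config$has_cav; has_bk <- config$has_bk
  has_cs <- config$has_catsper; has_nhe <- config$has_nhe
  has_ca <- config$has_calcium
  nm <- state_names(config)
  i_cv <- match("f_cv_o", nm); i_bk <- match("f_bk", nm)
  i_cs <- match("m_cs", nm); i_nh <- match("f_nh", nm)
  i_C <- match("C", nm); i_H <- match("H", nm)
  theta_R <- p$theta_R; r1 <- p$r1; r2 <- p$r2; r3 <- p$r3
  sigma_G <- p$sigma_G; delta_G <- p$delta_G; theta_G <- p$theta_G
  k_H <- p$k_H; k_L <- p$k_L
  alpha_kn <- p$alpha_kn; beta_kn <- p$beta_kn
  h1 <- p$h1; h2 <- p$h2; h3 <- p$h3; h4 <- p$h4; h5 <- p$h5; h6 <- p$h6
  g_kn <- p$g_kn; g_hc <- p$g_hc; E_K <- p$E_K; E_hc <- p$E_hc
  E_Ca <- p$E_Ca; g_L <- p$g_L; E_L <- p$E_L; C_m <- p$C_m
  v1 <- p$v1; v2 <- p$v2; v3 <- p$v3; v4 <- p$v4; v5 <- p$v5; v6 <- p$v6
  v7 <- p$v7; v8 <- p$v8; v9 <- p$v9; g_cv <- p$g_cv
  b1 <- p$b1; b2 <- p$b2; b3 <- p$b3; beta_bk <- p$beta_bk; g_bk <- p$g_bk
  s1 <- p$s1; s2 <- p$s2; s3 <- p$s3; s4 <- p$s4; s5 <- p$s5; s6 <- p$s6
  s7 <- p$s7; s8 <- p$s8; s9 <- p$s9; s10 <- p$s10; g_cs <- p$g_cs
  n1 <- p$n1; n2 <- p$n2; n3 <- p$n3; n4 <- p$n4; n5 <- p$n5; n6 <- p$n6
  J_max <- p$J_max; Na_out <- p$Na_out; Na_in <- p$Na_in; K_Na <- p$K_Na
  pH_out <- p$pH_out; sigma_C <- p$sigma_C; delta_C <- p$delta_C
  sigma_H <- p$sigma_H; delta_H <- p$delta_H; v_f <- p$v_f
  kC <- calcium_flux_factor(p)
  n_state <- length(nm)

  function(y) {
    S <- y[1]; R_F <- y[2]; R_H <- y[3]; R_L <- y[4]
    G <- y[5]; f_kn <- y[6]; m_hc <- y[7]; V <- y[8]
    d <- numeric(n_state)
    bind <- r1 * S * R_F
    d[1] <- -theta_R * bind
    d[2] <- -bind
    d[3] <- bind - r2 * R_H
    d[4] <- r2 * R_H - r3 * R_L
    d[5] <- sigma_G - delta_G * G + theta_G * (k_H * R_H + k_L * R_L)
    d[6] <- alpha_kn * G * (1 - f_kn) - beta_kn * f_kn
    m_inf <- 1 / (1 + exp((V - h1) / h2))
    d[7] <- (m_inf - m_hc) / (h3 + h4 * exp(-((V - h5) / h6)^2))
    I_sum <- g_kn * f_kn * (V - E_K) + g_hc * m_hc^3 * (V - E_hc)
    I_ca <- 0
    if (has_ca) C <- y[i_C]
    if (has_nhe) H <- y[i_H]
    if (has_cav) {
      f_cv_o <- y[i_cv]; f_cv_c <- y[i_cv + 1]
      a <- v1 * v3 * explin((V - v2) / v3)
      b <- v4 * v6 * explin(-(V - v5) / v6)
      g <- v7 * v9 * explin(-(V - v8) / v9)
      d[i_cv] <- b * f_cv_c - g * f_cv_o
      d[i_cv + 1] <- a * (1 - f_cv_c - f_cv_o) - b * f_cv_c
      I_cv <- g_cv * f_cv_o * (V - E_Ca)
      I_sum <- I_sum + I_cv
      I_ca <- I_ca + I_cv
    }
    if (has_bk) {
      f_bk <- y[i_bk]
      d[i_bk] <- b1 * b3 * explin((b2 - C) / b3) * (1 - f_bk) -
        beta_bk * f_bk
      I_sum <- I_sum + g_bk * f_bk * (V - E_K)
    }
    if (has_cs) {
      m_cs <- y[i_cs]; h_cs <- y[i_cs + 1]
      pH <- -log10(H)
      vcs <- s3 / (1 + (pH / s4)^s5) + s6
      u <- (vcs - V) / (2 * s2)
      d[i_cs] <- s1 * exp(-u) * (1 - m_cs) - s1 * exp(u) * m_cs
      d[i_cs + 1] <- s10 * (s8 / s7)^s9 * (1 - h_cs) -
        s10 * (C / s7)^s9 * h_cs
      I_cs <- g_cs * m_cs * h_cs * (V - E_Ca)
      I_sum <- I_sum + I_cs
      I_ca <- I_ca + I_cs
    }
    if (has_nhe) {
      f_nh <- y[i_nh]
      d[i_nh] <- n1 * n3 * explin((V - n2) / n3) * (1 - f_nh) -
        n4 * n6 * explin(-(V - n5) / n6) * f_nh
    }
    if (has_ca) d[i_C] <- sigma_C - delta_C * C - kC * I_ca
    if (has_nhe) {
      J_H <- nhe_proton_flux(f_nh, H, J_max, Na_out, Na_in, K_Na, pH_out)
      d[i_H] <- sigma_H - delta_H * H - J_H / v_f
    }
    d[8] <- -(g_L * (V - E_L) + I_sum) / C_m
    d
  }
}

# Core derivative computation on an unnamed numeric vector ordered as
# state_names(config); thin wrapper over the compiled closure (callers on
# hot paths should build and reuse .make_rhs directly).
.rhs_core <- function(y, p, config) .make_rhs(p, config)(y)

#' Per-channel current densities along a trajectory
#'
#' Vectorised over the rows of a state matrix/data frame; returns the ohmic
#' current density (fA um^-2) of each channel present in the configuration,
#' plus the leak.
#'
#' @param states data frame or matrix with the state columns of `config`.
#' @param params a `flag_params` object.
#' @param config a `flag_config` object.
#' @return data frame with columns `I_kn`, `I_hc`, `I_L` and, as present,
#'   `I_cv`, `I_bk`, `I_cs`.
#' @export
current_densities <- function(states, params, config) {
  states <- as.data.frame(states)
  V <- states$V
  out <- data.frame(
    I_kn = params$g_kn * states$f_kn * (V - params$E_K),
    I_hc = params$g_hc * states$m_hc^3 * (V - params$E_hc),
    I_L = params$g_L * (V - params$E_L))
  if (config$has_cav)
    out$I_cv <- params$g_cv * states$f_cv_o * (V - params$E_Ca)
  if (config$has_bk)
    out$I_bk <- params$g_bk * states$f_bk * (V - params$E_K)
  if (config$has_catsper)
    out$I_cs <- params$g_cs * states$m_cs * states$h_cs * (V - params$E_Ca)
  out
}
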