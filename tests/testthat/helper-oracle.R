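# Independent, literal transcription of the model equations, written
# directly from the rate definitions with no shared code path (plain
# x/(exp(x)-1) quotients, named-vector arithmetic).  Serves as the
# dual-implementation oracle for the packaged vector field.

oracle_rhs <- function(st, p, config) {
  FARADAY <- 96485.33212
  V <- st[["V"]]; G <- st[["G"]]
  d <- list()
  d$S <- -p$r1 * p$theta_R * st[["S"]] * st[["R_F"]]
  d$R_F <- -p$r1 * st[["S"]] * st[["R_F"]]
  d$R_H <- p$r1 * st[["S"]] * st[["R_F"]] - p$r2 * st[["R_H"]]
  d$R_L <- p$r2 * st[["R_H"]] - p$r3 * st[["R_L"]]
  rho_G <- p$k_H * st[["R_H"]] + p$k_L * st[["R_L"]]
  d$G <- p$sigma_G - p$delta_G * G + p$theta_G * rho_G
  d$f_kn <- p$alpha_kn * G * (1 - st[["f_kn"]]) - p$beta_kn * st[["f_kn"]]
  m_hat <- 1 / (1 + exp((V - p$h1) / p$h2))
  tau <- p$h3 + p$h4 * exp(-((V - p$h5) / p$h6)^2)
  d$m_hc <- (m_hat - st[["m_hc"]]) / tau
  I <- p$g_kn * st[["f_kn"]] * (V - p$E_K) +
    p$g_hc * st[["m_hc"]]^3 * (V - p$E_hc)
  I_ca <- 0
  if (config$has_cav) {
    a <- p$v1 * (V - p$v2) / (exp((V - p$v2) / p$v3) - 1)
    b <- -p$v4 * (V - p$v5) / (exp(-(V - p$v5) / p$v6) - 1)
    g <- -p$v7 * (V - p$v8) / (exp(-(V - p$v8) / p$v9) - 1)
    d$f_cv_o <- b * st[["f_cv_c"]] - g * st[["f_cv_o"]]
    d$f_cv_c <- a * (1 - st[["f_cv_c"]] - st[["f_cv_o"]]) -
      b * st[["f_cv_c"]]
    Icv <- p$g_cv * st[["f_cv_o"]] * (V - p$E_Ca)
    I <- I + Icv; I_ca <- I_ca + Icv
  }
  if (config$has_bk) {
    Cc <- st[["C"]]
    abk <- p$b1 * (p$b2 - Cc) / (exp((p$b2 - Cc) / p$b3) - 1)
    d$f_bk <- abk * (1 - st[["f_bk"]]) - p$beta_bk * st[["f_bk"]]
    I <- I + p$g_bk * st[["f_bk"]] * (V - p$E_K)
  }
  if (config$has_catsper) {
    Cc <- st[["C"]]; H <- st[["H"]]
    pH <- -log10(H)
    vcs <- p$s3 * p$s4^p$s5 / (pH^p$s5 + p$s4^p$s5) + p$s6
    am <- p$s1 * exp(-(vcs - V) / (2 * p$s2))
    bm <- p$s1 * exp((vcs - V) / (2 * p$s2))
    d$m_cs <- am * (1 - st[["m_cs"]]) - bm * st[["m_cs"]]
    ah <- p$s10 * (p$s8 / p$s7)^p$s9
    bh <- p$s10 * (Cc / p$s7)^p$s9
    d$h_cs <- ah * (1 - st[["h_cs"]]) - bh * st[["h_cs"]]
    Ics <- p$g_cs * st[["m_cs"]] * st[["h_cs"]] * (V - p$E_Ca)
    I <- I + Ics; I_ca <- I_ca + Ics
  }
  if (config$has_nhe) {
    anh <- p$n1 * (V - p$n2) / (exp((V - p$n2) / p$n3) - 1)
    bnh <- -p$n4 * (V - p$n5) / (exp(-(V - p$n5) / p$n6) - 1)
    d$f_nh <- anh * (1 - st[["f_nh"]]) - bnh * st[["f_nh"]]
  }
  if (config$has_calcium) {
    fac <- p$s_f / (2 * p$v_f * FARADAY) * 1e9
    d$C <- p$sigma_C - p$delta_C * st[["C"]] - fac * I_ca
  }
  if (config$has_nhe) {
    H <- st[["H"]]
    nao <- p$Na_out / 1000; nai <- p$Na_in / 1000
    kna <- p$K_Na / 1000; ho <- 10^(-p$pH_out)
    J <- st[["f_nh"]] * p$J_max * (H * nao - ho * nai) /
      (H * nao + kna * (H + ho) + ho * nai)
    d$H <- p$sigma_H - p$delta_H * H - J / p$v_f
  }
  d$V <- -(p$g_L * (V - p$E_L) + I) / p$C_m
  unlist(d)[state_names(config)]
}

# Closed-form ordinary-least-squares slope of y over the index 1..n.
ols_slope_oracle <- function(y) {
  k <- seq_along(y)
  sum((k - mean(k)) * (y - mean(y))) / sum((k - mean(k))^2)
}

# Winding-number point-in-polygon oracle (angle summation).
winding_inside <- function(x, y, poly) {
  n <- nrow(poly)
  ang <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    a1 <- atan2(poly[i, 2] - y, poly[i, 1] - x)
    a2 <- atan2(poly[j, 2] - y, poly[j, 1] - x)
    dd <- a2 - a1
    if (dd > pi) dd <- dd - 2 * pi
    if (dd < -pi) dd <- dd + 2 * pi
    ang <- ang + dd
  }
  abs(ang) > pi
}
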