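# Gating-rate primitives: closed-form oracle values computed by direct
# evaluation of each rate expression at the reference parameters, plus
# continuity across the removable singularities.

p <- reference_params("cav_bk")

test_that("Nernst potentials reproduce the tabulated reversal potentials", {
  expect_equal(round(nernst_potential(1, 9, 219, 17)), -80)
  expect_equal(round(nernst_potential(2, 10e-3, 100e-9, 17)), 144)
  expect_equal(nernst_potential(1, 9, 219, 17), -79.80636868,
               tolerance = 1e-8)
  expect_equal(nernst_potential(2, 5, 5, 17), 0)
  expect_error(nernst_potential(1, 0, 10), "positive")
  expect_error(nernst_potential(0, 1, 10), "valence")
})

test_that("KCNG steady state is a one-site saturation curve in cGMP", {
  K <- p$beta_kn / p$alpha_kn
  expect_equal(kcng_equilibrium(K, p$alpha_kn, p$beta_kn)$f_open, 0.5)
  expect_equal(kcng_equilibrium(0, p$alpha_kn, p$beta_kn)$f_open, 0)
  ref <- kcng_equilibrium(1.25, p$alpha_kn, p$beta_kn)
  expect_equal(ref$f_open, 0.04638218924, tolerance = 1e-9)
  expect_equal(ref$tau, 0.003710575139, tolerance = 1e-9)
  expect_error(kcng_equilibrium(-1, p$alpha_kn, p$beta_kn), "non-negative")
})

test_that("spHCN gate activates on hyperpolarisation with a Gaussian tau", {
  g <- sphcn_gate(p$h1, p$h1, p$h2, p$h3, p$h4, p$h5, p$h6)
  expect_equal(g$m, 0.5)
  expect_equal(sphcn_gate(-500, p$h1, p$h2, p$h3, p$h4, p$h5, p$h6)$m, 1,
               tolerance = 1e-12)
  gmax <- sphcn_gate(p$h5, p$h1, p$h2, p$h3, p$h4, p$h5, p$h6)
  expect_equal(gmax$tau, p$h3 + p$h4)
  expect_equal(gmax$tau, 1.1918, tolerance = 1e-10)
  expect_equal(g$f_open, g$m^3)
})

test_that("CaV rates match direct evaluation and their singular limits", {
  r <- cav_rates(-40, p$v1, p$v2, p$v3, p$v4, p$v5, p$v6, p$v7, p$v8, p$v9)
  expect_equal(r$alpha, 0.003915670064, tolerance = 1e-9)
  rlim <- cav_rates(p$v2, p$v1, p$v2, p$v3, p$v4, p$v5, p$v6, p$v7, p$v8,
                    p$v9)
  expect_equal(rlim$alpha, p$v1 * p$v3)   # 14.342 s^-1
  rlim5 <- cav_rates(p$v5, p$v1, p$v2, p$v3, p$v4, p$v5, p$v6, p$v7, p$v8,
                     p$v9)
  expect_equal(rlim5$beta, p$v4 * p$v6)   # 70.98 s^-1
})

test_that("BK opening rate is monotone in calcium with the b2 limit", {
  expect_equal(bk_opening_rate(p$b2, p$b1, p$b2, p$b3), p$b1 * p$b3)
  expect_equal(bk_opening_rate(100, p$b1, p$b2, p$b3), 0.1565415303,
               tolerance = 1e-9)
  Cs <- seq(p$b2, 3000, by = 50)
  expect_true(all(diff(bk_opening_rate(Cs, p$b1, p$b2, p$b3)) > 0))
})

test_that("NHE rates match their singular limits and resting activation", {
  r2 <- nhe_rates(p$n2, p$n1, p$n2, p$n3, p$n4, p$n5, p$n6)
  expect_equal(r2$alpha, p$n1 * p$n3)     # 10.57 s^-1
  r5 <- nhe_rates(p$n5, p$n1, p$n2, p$n3, p$n4, p$n5, p$n6)
  expect_equal(r5$beta, p$n4 * p$n6)      # 6.3 s^-1
  r <- nhe_rates(-40, p$n1, p$n2, p$n3, p$n4, p$n5, p$n6)
  expect_equal(r$alpha / (r$alpha + r$beta), 0.2779695856, tolerance = 1e-9)
})

test_that("NHE flux vanishes at zero activation and at thermodynamic
           reversal, and saturates as expected at rest", {
  expect_equal(nhe_proton_flux(0, 1e-7, p$J_max, p$Na_out, p$Na_in, p$K_Na,
                               p$pH_out), 0)
  H_rev <- 10^(-p$pH_out) * p$Na_in / p$Na_out
  expect_lt(abs(nhe_proton_flux(0.5, H_rev, p$J_max, p$Na_out, p$Na_in,
                                p$K_Na, p$pH_out)), 1e-20)
  sat <- nhe_proton_flux(1, 10^(-7.1), p$J_max, p$Na_out, p$Na_in, p$K_Na,
                         p$pH_out) / p$J_max
  expect_equal(sat, 0.9268557126, tolerance = 1e-9)
  expect_error(nhe_proton_flux(1, -1e-8, p$J_max, p$Na_out, p$Na_in,
                               p$K_Na, p$pH_out), "positive")
})

test_that("CatSper half-activation voltage shifts with pH as a Hill curve", {
  expect_equal(catsper_vhalf(10^(-p$s4), p$s3, p$s4, p$s5, p$s6),
               p$s3 / 2 + p$s6)           # -1.15 mV at the half point
  expect_equal(catsper_vhalf(1e-12, p$s3, p$s4, p$s5, p$s6), p$s6,
               tolerance = 1e-6)          # alkaline limit -41 mV
  expect_equal(catsper_vhalf(10^(-7.1), p$s3, p$s4, p$s5, p$s6),
               8.549887108, tolerance = 1e-8)
  pHs <- seq(6.6, 8.0, by = 0.1)
  v <- catsper_vhalf(10^(-pHs), p$s3, p$s4, p$s5, p$s6)
  expect_true(all(diff(v) < 0))
  expect_error(catsper_vhalf(0, p$s3, p$s4, p$s5, p$s6), "positive")
})

test_that("CatSper gates give Boltzmann / Hill steady states", {
  g0 <- catsper_gates(8.549887108, 100, 10^(-7.1), p$s1, p$s2, p$s3, p$s4,
                      p$s5, p$s6, p$s7, p$s8, p$s9, p$s10)
  expect_equal(g0$m_inf, 0.5, tolerance = 1e-9)
  g1 <- catsper_gates(-40, p$s8, 10^(-7.1), p$s1, p$s2, p$s3, p$s4, p$s5,
                      p$s6, p$s7, p$s8, p$s9, p$s10)
  expect_equal(g1$h_inf, 0.5)
  g2 <- catsper_gates(-40, 100, 10^(-7.1), p$s1, p$s2, p$s3, p$s4, p$s5,
                      p$s6, p$s7, p$s8, p$s9, p$s10)
  expect_equal(g2$m_inf * g2$h_inf, 0.007670051766, tolerance = 1e-9)
})

test_that("ohmic current density has the right zeros and resting value", {
  expect_equal(current_density(100, 0.5, -80, -80), 0)
  expect_equal(current_density(100, 0, -40, -80), 0)
  expect_equal(current_density(p$g_kn, 0.04638218924, -40, p$E_K),
               251.0204082, tolerance = 1e-6)
})

test_that("rates are continuous across their removable singularities", {
  cases <- list(
    list(f = function(V) cav_rates(V, p$v1, p$v2, p$v3, p$v4, p$v5, p$v6,
                                   p$v7, p$v8, p$v9)$alpha,
         x0 = p$v2, lim = p$v1 * p$v3),
    list(f = function(V) cav_rates(V, p$v1, p$v2, p$v3, p$v4, p$v5, p$v6,
                                   p$v7, p$v8, p$v9)$beta,
         x0 = p$v5, lim = p$v4 * p$v6),
    list(f = function(V) cav_rates(V, p$v1, p$v2, p$v3, p$v4, p$v5, p$v6,
                                   p$v7, p$v8, p$v9)$gamma,
         x0 = p$v8, lim = p$v7 * p$v9),
    list(f = function(C) bk_opening_rate(C, p$b1, p$b2, p$b3),
         x0 = p$b2, lim = p$b1 * p$b3),
    list(f = function(V) nhe_rates(V, p$n1, p$n2, p$n3, p$n4, p$n5,
                                   p$n6)$alpha,
         x0 = p$n2, lim = p$n1 * p$n3),
    list(f = function(V) nhe_rates(V, p$n1, p$n2, p$n3, p$n4, p$n5,
                                   p$n6)$beta,
         x0 = p$n5, lim = p$n4 * p$n6))
  for (cs in cases) {
    ## the deviation from the analytic limit shrinks linearly with the
    ## offset (slope 1/(2*sensitivity) with every sensitivity above 1.4)
    for (eps in 10^-(1:10)) {
      expect_lt(abs(cs$f(cs$x0 + eps) - cs$lim) / cs$lim,
                max(0.5 * eps, 1e-9))
      expect_lt(abs(cs$f(cs$x0 - eps) - cs$lim) / cs$lim,
                max(0.5 * eps, 1e-9))
    }
    devs <- abs(c(cs$f(cs$x0 + 10^-(4:10)), cs$f(cs$x0 - 10^-(4:10))) -
                cs$lim) / cs$lim
    expect_lt(max(devs), 1e-4)
  }
})
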