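# Resting-state solution and the equilibrium-constrained parameter
# derivations, checked against the tabulated reference values and against
# the vector field itself.

test_that("derived parameters reproduce the tabulated values within 1%", {
  p1 <- derive_parameters(reference_params("cav_bk"),
                          module_config("cav_bk"))
  p2 <- derive_parameters(reference_params("catsper_nhe"),
                          module_config("catsper_nhe"))
  expect_equal(p1$E_L, 80.05, tolerance = 0.01)
  expect_equal(p2$E_L, -20.4, tolerance = 0.01)
  expect_equal(p1$sigma_C, 1.14e8, tolerance = 0.01)
  expect_equal(p2$sigma_C, 3.72e7, tolerance = 0.01)
  expect_equal(p2$delta_H, 1.28, tolerance = 0.01)
})

test_that("conversion factors match the tabulated values within 1%", {
  cf <- conversion_factors(reference_params("upstream"))
  expect_equal(cf[["theta_G"]], 1.89e-4, tolerance = 0.01)
  expect_equal(cf[["theta_R"]], 6.14e-5, tolerance = 0.01)
  ## doubling the buffering power halves theta_G
  cf2 <- conversion_factors(set_params(reference_params("upstream"),
                                       B_G = 2 * 5.49e3))
  expect_equal(cf2[["theta_G"]], cf[["theta_G"]] / 2)
})

test_that("implied channel counts per flagellum match the tabulated ones", {
  expect_equal(round(channel_count(135.30, 30, 110)), 37)
  expect_equal(round(channel_count(193.50, 30, 43)), 135)
  expect_equal(round(channel_count(214.50, 30, 70)), 92)
  expect_equal(round(channel_count(185.16, 30, 4.7)), 1182)
  expect_error(channel_count(0, 30, 110), "positive")
})

test_that("resting gate fractions equal their closed-form values", {
  cfg <- module_config("catsper_nhe")
  st <- resting_state(reference_params("catsper_nhe"), cfg)
  expect_equal(st[["f_kn"]], 0.04638218924, tolerance = 1e-9)
  expect_equal(st[["m_hc"]]^3, 0.004327597002, tolerance = 1e-9)
  expect_equal(st[["f_nh"]], 0.2779695856, tolerance = 1e-9)
  expect_equal(st[["m_cs"]] * st[["h_cs"]], 0.007670051766,
               tolerance = 1e-9)
  stc <- resting_state(reference_params("cav_bk"), module_config("cav_bk"))
  expect_equal(stc[["f_bk"]], 0.001611229957, tolerance = 1e-9)
  expect_equal(stc[["f_cv_o"]], 0.0003907309705, tolerance = 1e-9)
})

test_that("full circle: derived rest is a fixed point of every module", {
  for (m in c("upstream", "cav_bk", "catsper_nhe")) {
    cfg <- module_config(m)
    p <- derive_parameters(reference_params(m), cfg)
    st <- resting_state(p, cfg)
    expect_lt(max(abs(model_rhs(st, p, cfg))), 1e-6)
  }
  for (w in list(c(1, 1), c(0.5, 0.5), c(0.2, 1.7))) {
    cfg <- module_config("mixed", w[1], w[2])
    p <- mixed_parameters(w[1], w[2])
    expect_lt(max(abs(model_rhs(resting_state(p, cfg), p, cfg))), 1e-6)
  }
})

test_that("degenerate inputs are handled as documented", {
  p <- reference_params("cav_bk")
  ## all channel conductances zero: the leak rests at E_m
  p0 <- set_params(p, g_kn = 0, g_hc = 0, g_cv = 0, g_bk = 0)
  expect_equal(derive_leak_reversal(p0, module_config("cav_bk")), p$E_m)
  expect_error(derive_leak_reversal(set_params(p, g_L = 0),
                                    module_config("cav_bk")), "positive")
  ## no exchanger flux: delta_H reduces to sigma_H / H_r
  pn <- set_params(reference_params("catsper_nhe"), J_max = 0)
  expect_equal(derive_proton_leak(pn), 1.5e-7 / 10^(-7.1))
  ## no resting calcium current: sigma_C reduces to delta_C * C_r
  pz <- set_params(reference_params("cav_bk"), g_cv = 0)
  expect_equal(derive_calcium_source(pz, module_config("cav_bk")),
               pz$delta_C * pz$C_r)
})

test_that("the resting state is locally stable in both modules", {
  ## CaV+BK: a small perturbation relaxes back to rest
  cfg <- module_config("cav_bk")
  p <- derive_parameters(reference_params("cav_bk"), cfg)
  st <- resting_state(p, cfg)
  st["V"] <- st["V"] + 1
  st["C"] <- st["C"] + 5
  ts <- simulate_model(p, cfg, protocol(t_start = 0, end_time = 10,
                                        dt = 0.01),
                       state0 = st, derive = FALSE)
  tail_row <- ts[nrow(ts), ]
  expect_equal(tail_row$V, p$E_m, tolerance = 1e-3)
  expect_equal(tail_row$C, p$C_r, tolerance = 1e-3)
  ## CatSper+NHE: eigenvalues of the clamped-G Jacobian at rest are in the
  ## left half plane
  m <- clamped_model(reference_params("catsper_nhe"), "catsper_nhe",
                     G_value = 1.25)
  rest <- resting_state(m$params, m$config)[m$state_names]
  J <- flagspike:::.num_jacobian(m, rest)
  expect_lt(max(Re(eigen(J, only.values = TRUE)$values)), 0)
})

test_that("the derived-quantity table is complete for both presets", {
  for (m in c("cav_bk", "catsper_nhe")) {
    tab <- derived_table(m)
    expect_named(tab, c("derived", "resting_fractions", "resting_currents",
                        "channel_counts"))
    expect_true(all(is.finite(tab$derived)))
  }
})
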