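# Clamped-cGMP submodels and the brute-force attractor machinery.

test_that("the reduced model drops the upstream variables and equals the
           full field on the remaining coordinates", {
  set.seed(31)
  m <- clamped_model(reference_params("cav_bk"), "cav_bk", G_value = 12)
  expect_equal(m$state_names,
               c("f_kn", "m_hc", "V", "f_cv_o", "f_cv_c", "f_bk", "C"))
  m2 <- clamped_model(reference_params("catsper_nhe"), "catsper_nhe", 5)
  expect_equal(m2$state_names,
               c("f_kn", "m_hc", "V", "m_cs", "h_cs", "f_nh", "C", "H"))
  cfg <- module_config("cav_bk")
  for (i in 1:25) {
    st <- random_state(cfg, m$params)
    st["S"] <- 0; st["G"] <- 12
    red <- m$rhs(st[m$state_names])
    full <- model_rhs(st, m$params, cfg)
    expect_equal(unname(red), unname(full[m$state_names]),
                 tolerance = 1e-12)
  }
})

test_that("the resting state is a fixed point of the basal-G reduced
           model", {
  m <- clamped_model(reference_params("cav_bk"), "cav_bk", G_value = 1.25)
  rest <- resting_state(m$params, m$config)[m$state_names]
  expect_lt(max(abs(m$rhs(rest))), 1e-6)
})

test_that("a linear contraction yields one stable fixed point, no cycles", {
  lin <- structure(list(rhs = function(y, t = 0) -y,
                        state_names = c("V", "C"),
                        atol = c(1e-8, 1e-8), G_value = 0),
                   class = "flag_clamped")
  tab <- find_attractors(lin, n_init = 5, t_transient = 30, t_record = 5,
                         seed = 4, box = list(V = c(-1, 1), C = c(0.1, 2),
                                              pH = c(6.5, 8)))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$kind, "stable fixed point")
  expect_lt(abs(tab$C), 1e-6)
  expect_lt(tab$leading_eig, 0)
})

test_that("the CatSper submodel has two coexisting stable equilibria at
           basal cGMP", {
  m <- clamped_model(reference_params("catsper_nhe"), "catsper_nhe",
                     G_value = 1.25)
  tab <- find_attractors(m, n_init = 10, t_transient = 80, t_record = 15,
                         seed = 3)
  stable <- tab[tab$kind == "stable fixed point", ]
  expect_equal(nrow(stable), 2)
  expect_lt(min(stable$C), 150)     # basal branch near C_r
  expect_gt(max(stable$C), 300)     # elevated coexisting branch
  expect_true(all(stable$leading_eig < 0))
})

test_that("attractor detection is reproducible across RNG seeds", {
  m <- clamped_model(reference_params("catsper_nhe"), "catsper_nhe",
                     G_value = 1.25)
  t1 <- find_attractors(m, n_init = 8, t_transient = 80, t_record = 15,
                        seed = 1)
  t2 <- find_attractors(m, n_init = 8, t_transient = 80, t_record = 15,
                        seed = 99)
  s1 <- sort(t1$C[t1$kind == "stable fixed point"])
  s2 <- sort(t2$C[t2$kind == "stable fixed point"])
  expect_equal(length(s1), length(s2))
  expect_equal(s1, s2, tolerance = 1e-4)
})

test_that("full-model spikes track the clamped-model limit cycle at the
           instantaneous cGMP level", {
  ts <- ref_run_cav()
  tr <- detect_spikes(ts)$spikes
  p <- reference_params("cav_bk")
  periods <- numeric(0)
  for (k in c(5, 10)) {
    t_k <- tr$t[k]
    G_k <- ts$G[which.min(abs(ts$time - t_k))]
    m <- clamped_model(p, "cav_bk", G_value = G_k)
    y0 <- unlist(ts[which.min(abs(ts$time - t_k)), m$state_names])
    sol <- deSolve::lsoda(y0, seq(0, 18, by = 0.005),
                          function(t, y, pp) list(m$rhs(y)), NULL,
                          rtol = 1e-8, atol = m$atol, maxsteps = 50000)
    Cc <- sol[sol[, "time"] > 8, "C"]
    tt <- sol[sol[, "time"] > 8, "time"]
    n <- length(Cc)
    im <- which(Cc[2:(n - 1)] > Cc[1:(n - 2)] & Cc[2:(n - 1)] >= Cc[3:n]) + 1
    expect_gt(length(im), 3)
    cyc_amp <- max(Cc[im])
    cyc_per <- mean(diff(tt[im]))
    ## raw full-model spike amplitude and following interval vs the
    ## asymptotic cycle at that G (15% band)
    raw_amp <- max(ts$C[abs(ts$time - t_k) < 0.1])
    expect_lt(abs(raw_amp - cyc_amp) / cyc_amp, 0.15)
    expect_lt(abs((tr$t[k + 1] - tr$t[k]) - cyc_per) / cyc_per, 0.15)
    periods <- c(periods, cyc_per)
  }
  ## upper-branch period grows as cGMP decays along the train
  expect_gt(periods[2], periods[1])
})
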