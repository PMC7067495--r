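# Spike detection, envelope features, selection criteria and their
# brute-force oracles.

test_that("a constant noisy series yields no spikes", {
  set.seed(5)
  df <- data.frame(time = seq(-2, 20, by = 0.02))
  df$value <- 100 + rnorm(nrow(df), 0, 3)
  tr <- detect_spikes(df, stimulus_time = 0, value_col = "value")
  expect_equal(nrow(tr$spikes), 0)
})

test_that("a synthetic train of six bumps at SNR 10 is fully recovered", {
  tr_in <- make_constructed_train(n_spikes = 6, A1 = 100, T1 = 1.2,
                                  b_A = -0.08, b_T = 0.06, width = 0.1,
                                  baseline = 20, noise_sd = 10, seed = 3)
  gt <- attr(tr_in, "ground_truth")
  tr <- detect_spikes(tr_in, stimulus_time = 0, value_col = "value")
  expect_equal(nrow(tr$spikes), 6)
  expect_lt(max(abs(tr$spikes$t - gt$t)), 0.06)  # within half a bump width
})

test_that("detection on the model's own trace agrees with a brute-force
           discrete argmax oracle on the smoothed curve", {
  ts <- ref_run_cav()
  tr <- detect_spikes(ts)
  ## oracle: independent smoothing + exhaustive scan with the same
  ## threshold/prominence definition
  nk <- min(nrow(ts), max(100, ceiling(diff(range(ts$time)) / 0.01)))
  sm <- predict(smooth.spline(ts$time, ts$C, nknots = nk), ts$time)$y
  pre <- ts$time < 0
  drop <- max(3 * sd(ts$C[pre]),
              0.05 * (max(sm[!pre]) - mean(ts$C[pre])))
  thr <- mean(ts$C[pre]) + drop
  cand <- integer(0)
  for (i in 2:(length(sm) - 1))
    if (sm[i] > sm[i - 1] && sm[i] >= sm[i + 1] && sm[i] > thr &&
        ts$time[i] > 0) cand <- c(cand, i)
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]; h <- sm[i]
    j <- i; vl <- h
    while (j > 1 && sm[j] <= h) { vl <- min(vl, sm[j]); j <- j - 1 }
    j <- i; vr <- h
    while (j < length(sm) && sm[j] <= h) { vr <- min(vr, sm[j]); j <- j + 1 }
    keep[k] <- (h - max(vl, vr)) >= drop
  }
  expect_equal(nrow(tr$spikes), sum(keep))
  expect_equal(tr$spikes$t, ts$time[cand[keep]])
})

test_that("envelope features match the closed-form OLS oracle", {
  ## uniform train: zero slopes
  sp <- data.frame(t = seq(1, 6), A = rep(2, 6))
  ft <- spike_features(sp)
  expect_equal(ft[["b_A"]], 0)
  expect_equal(ft[["b_T"]], 0)
  expect_equal(ft[["T_bar"]], 1)
  ## linear amplitude ramp: slope recovered exactly
  k <- 1:8
  sp2 <- data.frame(t = cumsum(c(1, rep(1, 7))), A = 5 * (1 - 0.1 * (k - 1)))
  expect_equal(spike_features(sp2)[["b_A"]], -0.1)
  ## random train against the closed-form oracle
  set.seed(11)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    sp3 <- data.frame(t = cumsum(runif(n, 0.3, 2)), A = runif(n, 1, 10))
    ft3 <- spike_features(sp3)
    expect_equal(ft3[["b_A"]], ols_slope_oracle(sp3$A / sp3$A[1]))
    Tk <- diff(sp3$t)
    expect_equal(ft3[["b_T"]], ols_slope_oracle(Tk / Tk[1]))
  }
  ## too few spikes: features marked unavailable
  expect_true(is.na(spike_features(sp3[1:2, ])[["b_A"]]))
  expect_true(is.na(spike_features(sp3[1:3, ])[["b_T"]]))
})

test_that("spike statistics are invariant under positive rescaling of the
           signal", {
  ts <- ref_run_cs()
  base <- detect_spikes(ts)
  for (c_scale in c(0.37, 1000)) {
    df <- data.frame(time = ts$time, value = c_scale * ts$C)
    sc <- detect_spikes(df, stimulus_time = 0, value_col = "value")
    expect_equal(sc$spikes$t, base$spikes$t)
    expect_equal(spike_features(sc)[c("b_A", "b_T")],
                 spike_features(base)[c("b_A", "b_T")], tolerance = 1e-8)
  }
})

test_that("point-in-polygon agrees with a winding-number oracle", {
  set.seed(21)
  polys <- list(default_hull(),
                cbind(c(0, 2, 2, 1, 0), c(0, 0, 2, 0.5, 2)))  # concave
  for (poly in polys) {
    px <- runif(500, min(poly[, 1]) - 0.5, max(poly[, 1]) + 0.5)
    py <- runif(500, min(poly[, 2]) - 0.5, max(poly[, 2]) + 0.5)
    got <- point_in_polygon(px, py, poly)
    want <- vapply(seq_along(px),
                   function(i) winding_inside(px[i], py[i], poly),
                   logical(1))
    expect_equal(got, want)
  }
  expect_error(point_in_polygon(0, 0, cbind(1:2, 1:2)), "vertices")
})

test_that("selection criteria combine interval, envelope and resting level", {
  ok <- c(T_bar = 0.8, b_A = -0.05, b_T = 0.04, n_spikes = 10)
  expect_true(meets_selection_criteria(ok, resting_C = 100))
  expect_false(meets_selection_criteria(
    replace(ok, "b_A", +0.01), resting_C = 100))       # wrong quadrant
  expect_false(meets_selection_criteria(
    replace(ok, "T_bar", 2.0), resting_C = 100))       # interval too long
  expect_false(meets_selection_criteria(ok, resting_C = 115))
  checks <- attr(meets_selection_criteria(ok, resting_C = 100), "checks")
  expect_named(checks, c("interval", "envelope", "resting"))
})

test_that("detection requires a pre-stimulus baseline window", {
  df <- data.frame(time = seq(0.5, 10, 0.01), value = rnorm(951))
  expect_error(detect_spikes(df, stimulus_time = 1, value_col = "value"),
               "pre-stimulus")
})
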