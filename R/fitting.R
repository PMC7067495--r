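## Fitting the upstream module: bulk cGMP kinetics at multiple SAP doses
## and the early membrane-potential response.

# pmol per 10^8 cells per (molecule per cell): converts the per-cell
# guanylate-cyclase output into the bulk assay unit.
.bulk_factor <- function() 1e8 / (physical_constants[["NA_const"]] * 1e-12)

# Basal bulk cGMP equivalent to the single-cell resting point: total
# molecules per cell G_r / theta_G, expressed in pmol per 10^8 cells.
.bulk_baseline <- function(params)
  params$G_r / params$theta_G * .bulk_factor()

# Integrate the bulk upstream model {S, R_F, R_H, R_L, G_bulk} for one dose.
# G is in pmol per 10^8 cells; the intraflagellar scaling factor theta_G is
# deliberately not applied in this unit system.
.bulk_cgmp_curve <- function(dose, times, p, Gb_r) {
  rhs <- function(t, y, dummy) {
    bind <- p$r1 * y[1] * y[2]
    dG <- p$delta_G * (Gb_r - y[5]) +
      .bulk_factor() * (p$k_H * y[3] + p$k_L * y[4])
    list(c(-p$theta_R * bind, -bind, bind - p$r2 * y[3],
           p$r2 * y[3] - p$r3 * y[4], dG))
  }
  y0 <- c(S = dose, R_F = p$R_T, R_H = 0, R_L = 0, G = Gb_r)
  sol <- deSolve::lsoda(y0, unique(c(0, times)), rhs, NULL,
                        rtol = 1e-8, atol = c(1e-8, 1e-2, 1e-2, 1e-2, 1e-8))
  sol[match(times, sol[, "time"]), "G"]
}

#' Differential-evolution global optimiser
#'
#' Minimal rand/1/bin differential evolution with box constraints and a
#' fixed seed, used as the global stage before derivative-based polishing.
#'
#' @param fn objective function of a numeric vector.
#' @param lower,upper box constraints.
#' @param n_pop population size (default `10 * length(lower)`).
#' @param n_gen number of generations.
#' @param F_weight,CR differential weight and crossover rate.
#' @param seed RNG seed.
#' @return list with `par`, `value`, `trace` (best value per generation).
#' @export
de_optim <- function(fn, lower, upper, n_pop = 10 * length(lower),
                     n_gen = 60, F_weight = 0.7, CR = 0.9, seed = 1) {
  set.seed(seed)
  d <- length(lower)
  pop <- matrix(stats::runif(n_pop * d, lower, upper), n_pop, d,
                byrow = TRUE)
  val <- apply(pop, 1, fn)
  trace <- numeric(n_gen)
  for (g in seq_len(n_gen)) {
    for (i in seq_len(n_pop)) {
      idx <- sample(setdiff(seq_len(n_pop), i), 3)
      trial <- pop[idx[1], ] + F_weight * (pop[idx[2], ] - pop[idx[3], ])
      cross <- stats::runif(d) < CR
      cross[sample.int(d, 1)] <- TRUE
      trial <- ifelse(cross, trial, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      v <- fn(trial)
      if (v <= val[i]) { pop[i, ] <- trial; val[i] <- v }
    }
    trace[g] <- min(val)
  }
  best <- which.min(val)
  list(par = pop[best, ], value = val[best], trace = trace)
}

#' Fit the upstream module to multi-dose bulk cGMP kinetics
#'
#' Joint (unweighted) least squares of the bulk upstream model over all
#' doses of a dataset.  Free parameters (default `R_T`, `r2`, `r3`,
#' `delta_G`, `k_L`, `k_H`) are fitted on a log10 scale within box
#' constraints; `r1`, `theta_R` and the basal bulk cGMP level are fixed.
#' The basal synthesis rate is eliminated structurally through
#' `sigma = delta_G * G_basal`, so the resting constraint holds exactly at
#' any parameter value.  Optimisation runs a seeded differential-evolution
#' global stage (skipped by `method = "polish"`, which instead multistarts
#' from jittered box midpoints) followed by Levenberg-Marquardt polishing
#' ([minpack.lm::nls.lm()]).
#'
#' @param dataset data frame with columns `dose_nM`, `time_s`, `value`
#'   (pmol per 10^8 cells), e.g. from [make_cgmp_dataset()].  At least two
#'   doses are required for a joint fit; a single-dose fit runs but leaves
#'   `R_T` and `k_H` weakly identified.
#' @param params parameter set supplying the fixed values.
#' @param free names of the free parameters.
#' @param lower,upper named box constraints (natural scale); defaults span
#'   a factor 30 around the reference values.
#' @param method `"hybrid"` (DE + polish) or `"polish"` (multistart
#'   Levenberg-Marquardt only, considerably faster; the first start is
#'   the box midpoint — the reference prior — and the rest are random
#'   log-scale jitters around it).
#' @param n_gen,n_pop DE budget (hybrid method).
#' @param n_starts multistart count (polish method).
#' @param seed RNG seed.
#' @return an object of class `flag_fit`: list with `estimates`, `se`
#'   (linearised standard errors), `fixed`, `rss`, `converged`, `n_obs`
#'   and `residuals`.
#' @export
fit_upstream_cgmp <- function(dataset, params = reference_params("upstream"),
                              free = c("R_T", "r2", "r3", "delta_G", "k_L",
                                       "k_H"),
                              lower = NULL, upper = NULL,
                              method = c("hybrid", "polish"),
                              n_gen = 40, n_pop = 24, n_starts = 3,
                              seed = 1) {
  method <- match.arg(method)
  stopifnot(all(c("dose_nM", "time_s", "value") %in% names(dataset)))
  if (any(dataset$time_s < 0) || any(dataset$dose_nM <= 0))
    stop("fit_upstream_cgmp(): times must be >= 0 and doses > 0")
  doses <- sort(unique(dataset$dose_nM))
  if (length(doses) < 2)
    message("single-dose dataset: R_T and k_H will be weakly identified")
  Gb_r <- .bulk_baseline(params)

  ref <- unlist(params[free])
  if (is.null(lower)) lower <- ref / 30
  if (is.null(upper)) upper <- ref * 30
  llo <- log10(lower); lup <- log10(upper)

  model_resid <- function(theta_log) {
    p <- params
    p[free] <- as.list(10^theta_log)
    res <- unlist(lapply(doses, function(dd) {
      sub <- dataset[dataset$dose_nM == dd, ]
      pred <- tryCatch(.bulk_cgmp_curve(dd, sub$time_s, p, Gb_r),
                       error = function(e) rep(1e6, nrow(sub)))
      pred - sub$value
    }))
    res[!is.finite(res)] <- 1e6
    res
  }
  obj <- function(theta_log) sum(model_resid(theta_log)^2)

  if (method == "hybrid") {
    glob <- de_optim(obj, llo, lup, n_pop = n_pop, n_gen = n_gen,
                     seed = seed)
    starts <- list(glob$par)
  } else {
    set.seed(seed)
    mid <- (llo + lup) / 2
    starts <- c(list(mid), lapply(seq_len(max(n_starts - 1, 0)),
      function(i)
        pmin(pmax(mid + stats::rnorm(length(mid), 0, 0.25), llo), lup)))
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(minpack.lm::nls.lm(
      par = st, fn = model_resid, lower = llo, upper = lup,
      control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-12,
                                           ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("fit_upstream_cgmp(): optimisation failed from every start")

  est <- 10^best$par
  names(est) <- free
  se <- tryCatch({
    cov_log <- vcov(best)
    sqrt(diag(cov_log)) * est * log(10)  # delta method back to natural scale
  }, error = function(e) rep(NA_real_, length(free)))
  names(se) <- free
  structure(list(estimates = est, se = se,
                 fixed = c(r1 = params$r1, theta_R = params$theta_R,
                           G_basal_bulk = Gb_r),
                 rss = best$deviance,
                 converged = best$info %in% 1:4,
                 n_obs = nrow(dataset),
                 residuals = model_resid(best$par)),
            class = "flag_fit")
}

#' @export
print.flag_fit <- function(x, ...) {
  cat("<flag_fit> RSS =", format(x$rss, digits = 6),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(data.frame(estimate = x$estimates, se = x$se))
  invisible(x)
}

#' Fit channel densities to the early membrane-potential response
#'
#' Least squares of the upstream module's membrane potential on the first
#' second after the stimulus (only the early response is informative before
#' the downstream calcium channels act).  Free parameters default to the
#' KCNG and spHCN conductance densities and the cGMP buffering power `B_G`
#' (which enters through `theta_G = 1/(v_f B_G N_A)`); the leak reversal
#' potential is re-derived from the charge balance at every evaluation.
#'
#' @param v_dataset data frame with columns `time_s` and `V_mV`; the
#'   stimulus is at time 0 and samples up to `t_max` are used.
#' @param params parameter set supplying the fixed values.
#' @param S0 stimulus amplitude of the recorded response (nM).
#' @param free free parameter names (subset of `g_kn`, `g_hc`, `B_G`).
#' @param t_max fitting window end (s).
#' @param method,n_gen,n_pop,n_starts,seed as in [fit_upstream_cgmp()].
#' @return a `flag_fit` object.
#' @export
fit_membrane_early <- function(v_dataset,
                               params = reference_params("upstream"),
                               S0 = 25, free = c("g_kn", "g_hc", "B_G"),
                               t_max = 1, method = c("hybrid", "polish"),
                               n_gen = 40, n_pop = 24, n_starts = 3,
                               seed = 1) {
  method <- match.arg(method)
  stopifnot(all(c("time_s", "V_mV") %in% names(v_dataset)))
  sub <- v_dataset[v_dataset$time_s >= 0 & v_dataset$time_s <= t_max, ]
  if (max(sub$time_s) < t_max - 0.05)
    stop("fit_membrane_early(): need samples covering [0, ", t_max, "] s")
  cfg <- module_config("upstream")

  ref <- unlist(params[free])
  llo <- log10(ref / 30); lup <- log10(ref * 30)

  model_resid <- function(theta_log) {
    p <- params
    p[free] <- as.list(10^theta_log)
    if ("B_G" %in% free)
      p$theta_G <- unname(conversion_factors(p)["theta_G"])
    pred <- tryCatch({
      ts <- simulate_model(p, cfg,
                           protocol(ev_sap_pulse(0, S0), t_start = -0.1,
                                    end_time = t_max, dt = 0.002))
      stats::approx(ts$time, ts$V, xout = sub$time_s)$y
    }, error = function(e) rep(1e3, nrow(sub)))
    res <- pred - sub$V_mV
    res[!is.finite(res)] <- 1e3
    res
  }
  obj <- function(th) sum(model_resid(th)^2)

  if (method == "hybrid") {
    glob <- de_optim(obj, llo, lup, n_pop = n_pop, n_gen = n_gen,
                     seed = seed)
    starts <- list(glob$par)
  } else {
    set.seed(seed)
    mid <- (llo + lup) / 2
    starts <- c(list(mid), lapply(seq_len(max(n_starts - 1, 0)),
      function(i)
        pmin(pmax(mid + stats::rnorm(length(mid), 0, 0.25), llo), lup)))
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(minpack.lm::nls.lm(
      par = st, fn = model_resid, lower = llo, upper = lup,
      control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-12,
                                           ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best))
    stop("fit_membrane_early(): optimisation failed from every start")
  est <- 10^best$par
  names(est) <- free
  se <- tryCatch(sqrt(diag(vcov(best))) * est * log(10),
                 error = function(e) rep(NA_real_, length(free)))
  names(se) <- free
  structure(list(estimates = est, se = se, fixed = c(S0 = S0),
                 rss = best$deviance, converged = best$info %in% 1:4,
                 n_obs = nrow(sub), residuals = model_resid(best$par)),
            class = "flag_fit")
}
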