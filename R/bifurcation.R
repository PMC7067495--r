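## Clamped-cGMP submodels and brute-force attractor analysis.
##
## With cGMP held constant the upstream receptor chain decouples and the
## downstream oscillator can be studied as a function of G.  No numerical
## continuation is attempted: attractors are found by integrating from
## randomised initial conditions past a long transient, classifying the
## tail as a fixed point (then polished by Newton iteration and classified
## by Jacobian eigenvalues) or a limit cycle (period from recurrent calcium
## peaks), and merging duplicates.  This brute-force approach also finds
## the attractors that defeat continuation software on this system.

#' Reduced model with clamped cGMP
#'
#' Removes the upstream variables and treats G as a constant input.  The
#' state space is `{f_kn, m_hc, V, f_cv_o, f_cv_c, f_bk, C}` for the CaV+BK
#' module and `{f_kn, m_hc, V, m_cs, h_cs, f_nh, C, H}` for CatSper+NHE.
#'
#' @param params a `flag_params` object (derived or underived; the
#'   equilibrium block is re-derived unless `derive = FALSE`).
#' @param module `"cav_bk"` or `"catsper_nhe"`.
#' @param G_value clamped cGMP concentration (nM).
#' @param derive re-derive equilibrium-constrained parameters.
#' @return an object of class `flag_clamped`: list with `rhs(y, t)`,
#'   `state_names`, `params`, `config`, `G_value`, `atol`.
#' @export
clamped_model <- function(params, module = c("cav_bk", "catsper_nhe"),
                          G_value, derive = TRUE) {
  module <- match.arg(module)
  config <- module_config(module)
  if (derive) params <- derive_parameters(params, config)
  full_nm <- state_names(config)
  keep <- setdiff(full_nm, c("S", "R_F", "R_H", "R_L", "G"))
  idx <- match(keep, full_nm)
  head_state <- c(S = 0, R_F = params$R_T, R_H = 0, R_L = 0, G = G_value)
  full_rhs <- .make_rhs(params, config)
  rhs <- function(y, t = 0) {
    d <- full_rhs(c(head_state, y))
    d[idx]
  }
  structure(list(rhs = rhs, state_names = keep, params = params,
                 config = config, G_value = G_value,
                 atol = .state_atol(config)[idx]),
            class = "flag_clamped")
}

# Random initial condition inside a physiologically bounded box.
.random_init <- function(model, box = NULL) {
  nm <- model$state_names
  y <- numeric(length(nm))
  names(y) <- nm
  for (v in nm) {
    y[v] <- switch(v,
      V = stats::runif(1, if (is.null(box)) -90 else box$V[1],
                       if (is.null(box)) 30 else box$V[2]),
      C = stats::runif(1, if (is.null(box)) 10 else box$C[1],
                       if (is.null(box)) 3000 else box$C[2]),
      H = 10^(-stats::runif(1, if (is.null(box)) 6.5 else box$pH[1],
                            if (is.null(box)) 8.0 else box$pH[2])),
      stats::runif(1))
  }
  ## keep the CaV state simplex consistent
  if (all(c("f_cv_o", "f_cv_c") %in% nm) && y["f_cv_o"] + y["f_cv_c"] > 1) {
    s <- y["f_cv_o"] + y["f_cv_c"]
    y["f_cv_o"] <- y["f_cv_o"] / s
    y["f_cv_c"] <- y["f_cv_c"] / s
  }
  y
}

# Numerical Jacobian of a clamped model at a state.
.num_jacobian <- function(model, y) {
  n <- length(y)
  J <- matrix(0, n, n)
  f0 <- model$rhs(y)
  scale <- pmax(abs(y), model$atol * 1e3)
  for (j in seq_len(n)) {
    h <- 1e-6 * scale[j]
    yp <- y; yp[j] <- yp[j] + h
    ym <- y; ym[j] <- ym[j] - h
    J[, j] <- (model$rhs(yp) - model$rhs(ym)) / (2 * h)
  }
  J
}

# Newton polish of a fixed-point candidate; returns NULL on failure.
.newton_fp <- function(model, y, max_iter = 30, tol = 1e-10) {
  for (it in seq_len(max_iter)) {
    f <- model$rhs(y)
    scale <- pmax(abs(y), model$atol * 1e3)
    if (max(abs(f / scale)) < tol) return(y)
    J <- .num_jacobian(model, y)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    ## damped update; states must stay in their natural domain
    lambda <- 1
    repeat {
      y_new <- y + lambda * step
      ok <- all(is.finite(y_new)) &&
        (!("H" %in% names(y)) || y_new["H"] > 0) &&
        (!("C" %in% names(y)) || y_new["C"] > 0)
      if (ok || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    if (!ok) return(NULL)
    y <- y_new
  }
  NULL
}

#' Locate attractors of a clamped submodel
#'
#' Integrates `n_init` random initial conditions for `t_transient` seconds,
#' then records `t_record` seconds and classifies the tail.  Fixed points
#' are polished by Newton iteration and labelled stable/unstable by the
#' leading eigenvalue of the numerical Jacobian; periodic attractors are
#' accepted when the recorded calcium peaks recur with a period stable to
#' better than 1%.  Duplicates are merged by relative state-space distance
#' (fixed points) or by period and amplitude (cycles).  Initial conditions
#' whose integration fails are discarded with a message.
#'
#' @param model a `flag_clamped` model.
#' @param n_init number of random initial conditions (>= 1).
#' @param t_transient transient time discarded before recording (s).
#' @param t_record recording window (s).
#' @param seed RNG seed for the initial conditions.
#' @param box optional list with elements `V`, `C`, `pH` (each a length-2
#'   range) bounding the random initial conditions.
#' @param rtol solver relative tolerance (looser values speed up broad
#'   sweeps; the default matches [simulate_model()]).
#' @return data frame with one row per attractor: `G`, `kind` (`"stable
#'   fixed point"`, `"unstable fixed point"`, `"stable limit cycle"`),
#'   `period`, `C_min`, `C_max`, `V`, `C`, `leading_eig`, `n_hits`.
#' @export
find_attractors <- function(model, n_init = 12, t_transient = 100,
                            t_record = 25, seed = 1, box = NULL,
                            rtol = 1e-8) {
  stopifnot(n_init >= 1)
  set.seed(seed)
  fps <- list(); cycles <- list()
  i_C <- match("C", model$state_names)
  for (k in seq_len(n_init)) {
    y0 <- .random_init(model, box)
    sol <- tryCatch(suppressWarnings(deSolve::lsoda(
      y0, seq(0, t_transient, length.out = 51),
      function(t, y, p) list(model$rhs(y, t)),
      NULL, rtol = rtol, atol = model$atol, maxsteps = 50000)),
      error = function(e) NULL)
    if (is.null(sol) || nrow(sol) < 2 ||
        abs(sol[nrow(sol), 1] - t_transient) > 1e-8) {
      message("find_attractors(): init ", k, " discarded (no convergence)")
      next
    }
    y1 <- sol[nrow(sol), -1]
    rec <- tryCatch(suppressWarnings(deSolve::lsoda(
      y1, seq(0, t_record, by = 0.005),
      function(t, y, p) list(model$rhs(y, t)),
      NULL, rtol = rtol, atol = model$atol, maxsteps = 50000)),
      error = function(e) NULL)
    if (is.null(rec) || abs(rec[nrow(rec), 1] - t_record) > 1e-8) {
      message("find_attractors(): init ", k, " discarded (no convergence)")
      next
    }
    Cc <- rec[, 1 + i_C]
    tt <- rec[, 1]
    if (diff(range(Cc)) < max(1e-3 * mean(abs(Cc)), 1e-3)) {
      fp <- .newton_fp(model, rec[nrow(rec), -1])
      if (is.null(fp)) next
      fps[[length(fps) + 1]] <- fp
    } else {
      n <- length(Cc)
      imax <- which(Cc[2:(n - 1)] > Cc[1:(n - 2)] &
                    Cc[2:(n - 1)] >= Cc[3:n]) + 1
      imax <- imax[Cc[imax] > min(Cc) + 0.25 * diff(range(Cc))]
      if (length(imax) < 3) next
      per <- diff(tt[imax])
      if (stats::sd(per) / mean(per) > 0.01) next
      cycles[[length(cycles) + 1]] <-
        list(period = mean(per), C_min = min(Cc), C_max = max(Cc),
             V = mean(rec[, 1 + match("V", model$state_names)]),
             C = mean(Cc))
    }
  }

  rows <- list()
  if (length(fps)) {
    used <- rep(FALSE, length(fps))
    for (a in seq_along(fps)) {
      if (used[a]) next
      hits <- 1
      for (b in seq_along(fps)) {
        if (b == a || used[b]) next
        rel <- abs(fps[[a]] - fps[[b]]) /
          pmax(abs(fps[[a]]), model$atol * 1e3)
        if (max(rel) < 1e-3) { used[b] <- TRUE; hits <- hits + 1 }
      }
      J <- .num_jacobian(model, fps[[a]])
      lead <- max(Re(eigen(J, only.values = TRUE)$values))
      rows[[length(rows) + 1]] <- data.frame(
        G = model$G_value,
        kind = if (lead < 0) "stable fixed point" else "unstable fixed point",
        period = NA_real_, C_min = fps[[a]][[i_C]], C_max = fps[[a]][[i_C]],
        V = fps[[a]][["V"]], C = fps[[a]][[i_C]], leading_eig = lead,
        n_hits = hits)
    }
  }
  if (length(cycles)) {
    used <- rep(FALSE, length(cycles))
    for (a in seq_along(cycles)) {
      if (used[a]) next
      hits <- 1
      for (b in seq_along(cycles)) {
        if (b == a || used[b]) next
        if (abs(cycles[[a]]$period - cycles[[b]]$period) /
              cycles[[a]]$period < 0.02 &&
            abs(cycles[[a]]$C_max - cycles[[b]]$C_max) /
              max(cycles[[a]]$C_max, 1) < 0.05) {
          used[b] <- TRUE; hits <- hits + 1
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        G = model$G_value, kind = "stable limit cycle",
        period = cycles[[a]]$period, C_min = cycles[[a]]$C_min,
        C_max = cycles[[a]]$C_max, V = cycles[[a]]$V, C = cycles[[a]]$C,
        leading_eig = NA_real_, n_hits = hits)
    }
  }
  if (!length(rows))
    return(data.frame(G = numeric(0), kind = character(0),
                      period = numeric(0), C_min = numeric(0),
                      C_max = numeric(0), V = numeric(0), C = numeric(0),
                      leading_eig = numeric(0), n_hits = integer(0)))
  do.call(rbind, rows)
}

#' Attractor diagram over a cGMP grid (optionally scaled BK conductance)
#'
#' Runs [find_attractors()] for every combination of clamped G and BK
#' conductance scale factor, returning a tidy diagram table.  For the
#' CaV+BK module the family of diagrams shows how BK generates bistability:
#' at scale 0 a single limit-cycle branch of near-constant period remains,
#' while at the reference scale an upper limit cycle (whose period grows as
#' G decreases) coexists with a lower small-amplitude one.
#'
#' @param params a `flag_params` object.
#' @param module `"cav_bk"` or `"catsper_nhe"`.
#' @param G_grid clamped cGMP values (nM, non-empty).
#' @param g_bk_scale BK conductance scale factors (CaV+BK only).
#' @param ... forwarded to [find_attractors()].
#' @return data frame: the [find_attractors()] columns plus `g_bk_scale`.
#' @export
attractor_sweep <- function(params, module = "cav_bk", G_grid,
                            g_bk_scale = 1, ...) {
  stopifnot(length(G_grid) >= 1, length(g_bk_scale) >= 1)
  out <- list()
  for (sc in g_bk_scale) {
    p <- params
    p$g_bk <- params$g_bk * sc
    for (G in G_grid) {
      mod <- clamped_model(p, module, G)
      tab <- find_attractors(mod, ...)
      if (nrow(tab)) {
        tab$g_bk_scale <- sc
        out[[length(out) + 1]] <- tab
      }
    }
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}
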