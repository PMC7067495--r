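## Mixed scenarios, module titrations and the two-phase evolutionary
## exploration of the downstream parameter space.

#' Parameter set of a weighted module mixture
#'
#' Builds the extended model (all channels present) whose CaV and BK
#' conductances are scaled by `theta_cv`, the CatSper conductance by
#' `theta_cs`, and whose leak conductance and calcium extrusion rate are the
#' corresponding weighted sums of the two pure-module reference values:
#' `g_L = theta_cv g_L^cv + theta_cs g_L^cs`,
#' `delta_C = theta_cv delta_C^cv + theta_cs delta_C^cs`.  All other
#' parameters keep their reference values; the equilibrium-constrained
#' parameters are re-derived for the mixture.  The weight pairs (1, 0) and
#' (0, 1) reproduce the pure CaV+BK and CatSper+NHE parameterisations
#' exactly.
#'
#' @param theta_cv,theta_cs non-negative module weights.
#' @param ref_cv,ref_cs reference parameter sets of the two pure modules.
#' @param derive re-derive `E_L`, `sigma_C`, `delta_H` for the mixture.
#' @return a `flag_params` object tagged `module = "mixed"`, with
#'   attributes `theta_cv`, `theta_cs` and `r_g` (total CatSper/CaV
#'   conductance ratio `theta_cs g_cs / (theta_cv g_cv)`).
#' @export
mixed_parameters <- function(theta_cv, theta_cs,
                             ref_cv = reference_params("cav_bk"),
                             ref_cs = reference_params("catsper_nhe"),
                             derive = TRUE) {
  if (theta_cv < 0 || theta_cs < 0)
    stop("mixed_parameters(): weights must be non-negative")
  p <- ref_cv
  p$g_cv <- theta_cv * ref_cv$g_cv
  p$g_bk <- theta_cv * ref_cv$g_bk
  p$g_cs <- theta_cs * ref_cs$g_cs
  p$g_L <- theta_cv * ref_cv$g_L + theta_cs * ref_cs$g_L
  p$delta_C <- theta_cv * ref_cv$delta_C + theta_cs * ref_cs$delta_C
  attr(p, "module") <- "mixed"
  attr(p, "theta_cv") <- theta_cv
  attr(p, "theta_cs") <- theta_cs
  attr(p, "r_g") <- if (theta_cv > 0)
    theta_cs * ref_cs$g_cs / (theta_cv * ref_cv$g_cv) else Inf
  if (derive)
    p <- derive_parameters(p, module_config("mixed", theta_cv, theta_cs))
  p
}

#' Titrate one module into the other
#'
#' Interpolation schemes between the two pure modules:
#' * `"cav_and_bk"` — `theta_cv = theta`, `theta_cs = 1 - theta` (CaV and
#'   BK added together while CatSper is proportionally removed);
#' * `"cav_only"` — same weights but `g_bk` forced to 0;
#' * `"bk_only"` — pure CatSper+NHE background (`theta_cv = 0`,
#'   `theta_cs = 1`) with `g_bk = theta * g_bk^cv` titrated in.
#'
#' Each titration point is simulated under `proto` and quantified with
#' [detect_spikes()] / [spike_features()].
#'
#' @param scheme titration scheme (see above).
#' @param theta_grid weight values in [0, 1].
#' @param proto simulation protocol (the stimulus should elicit a spike
#'   train at `theta = 0`; see the package vignette on the choice of the
#'   stimulus amplitude).
#' @param keep_ts also return the trajectories.
#' @return list with `summary` (data frame: `theta`, `r_g`, `g_bk`,
#'   `n_spikes`, `T_bar`, `b_A`, `b_T`, `oscillating`), `theta_lost` (the
#'   smallest theta at which fewer than 3 spikes remain, `NA` when none)
#'   and, if requested, `trajectories`.
#' @export
titrate <- function(scheme = c("cav_and_bk", "cav_only", "bk_only"),
                    theta_grid = seq(0, 1, by = 0.1),
                    proto = protocol(ev_sap_pulse(0, 10), end_time = 30),
                    keep_ts = FALSE) {
  scheme <- match.arg(scheme)
  ref_cv <- reference_params("cav_bk")
  rows <- list(); tss <- list()
  for (th in theta_grid) {
    if (scheme == "bk_only") {
      p <- mixed_parameters(0, 1, derive = FALSE)
      p$g_bk <- th * ref_cv$g_bk
      cfg <- module_config("mixed", 0, 1)
      p <- derive_parameters(p, cfg)
      g_bk_val <- p$g_bk
    } else {
      p <- mixed_parameters(th, 1 - th, derive = FALSE)
      if (scheme == "cav_only") p$g_bk <- 0
      cfg <- module_config("mixed", th, 1 - th)
      p <- derive_parameters(p, cfg)
      g_bk_val <- p$g_bk
    }
    ts <- simulate_model(p, cfg, proto, derive = FALSE)
    tr <- detect_spikes(ts, stimulus_time = 0)
    ft <- spike_features(tr)
    rows[[length(rows) + 1]] <- data.frame(
      theta = th, r_g = attr(p, "r_g") %||% NA, g_bk = g_bk_val,
      n_spikes = ft[["n_spikes"]], T_bar = ft[["T_bar"]],
      b_A = ft[["b_A"]], b_T = ft[["b_T"]],
      oscillating = ft[["n_spikes"]] >= 3)
    if (keep_ts) tss[[as.character(th)]] <- ts
  }
  summary <- do.call(rbind, rows)
  lost <- summary$theta[!summary$oscillating]
  out <- list(summary = summary,
              theta_lost = if (length(lost)) min(lost) else NA_real_)
  if (keep_ts) out$trajectories <- tss
  out
}

# Parameters the evolutionary search perturbs: the downstream blocks.  The
# upstream module (receptor, cGMP, KCNG, spHCN) is fixed at its fitted point
# estimates; physical constants, imposed resting concentrations and the
# derived equilibrium parameters (re-derived after each mutation) are not
# free either.
.mutable_params <- function() {
  unlist(.param_blocks[c("cav", "bk", "nhe", "catsper")], use.names = FALSE)
}

#' Lognormal mutation of a parameter vector
#'
#' Each mutable (downstream) parameter is multiplied by an independent
#' lognormal factor `exp(x)`, `x ~ N(0, sd_log)`; upstream and structural
#' parameters are untouched and the equilibrium-constrained parameters are
#' re-derived afterwards so the daughter rests at the imposed operating
#' point.  Signed parameters (voltage inflexion points etc.) are perturbed
#' on their magnitude, preserving sign.
#'
#' @param params a `flag_params` object (typically a mixture).
#' @param sd_log standard deviation of the log-factor (default 0.04).
#' @param config configuration used to re-derive equilibrium parameters.
#' @param derive re-derive the equilibrium-constrained parameters (disable
#'   only when the caller re-derives later, e.g. in bulk statistical
#'   checks of the mutation kernel).
#' @return the mutated parameter set.
#' @export
mutate_params <- function(params, sd_log = 0.04,
                          config = module_config("mixed", 1, 1),
                          derive = TRUE) {
  stopifnot(sd_log >= 0)
  if (sd_log > 0) {
    for (nm in .mutable_params()) {
      fac <- exp(stats::rnorm(1, 0, sd_log))
      params[[nm]] <- params[[nm]] * fac
    }
    if (derive) params <- derive_parameters(params, config)
  }
  params
}

#' Regular seed grid of module weights
#'
#' @param theta_values grid values of each weight; the default
#'   `{0.0001, 0.1, 0.2, ..., 2.0}` gives a 21 x 21 = 441 vector grid.
#' @return data frame with columns `theta_cv`, `theta_cs`.
#' @export
seed_grid <- function(theta_values = c(1e-4, seq(0.1, 2.0, by = 0.1))) {
  expand.grid(theta_cv = theta_values, theta_cs = theta_values,
              KEEP.OUT.ATTRS = FALSE)
}

#' Default evaluation of a parameter vector
#'
#' Simulates the extended model under a SAP pulse, quantifies the calcium
#' spike train and applies [meets_selection_criteria()].
#'
#' @param params a mixed `flag_params` object (already derived).
#' @param S0 stimulus amplitude (nM).
#' @param end_time simulation end (s).
#' @return list with `features` and logical `selected`.
#' @export
evaluate_vector <- function(params, S0 = 25, end_time = 25) {
  cfg <- module_config("mixed", attr(params, "theta_cv") %||% 1,
                       attr(params, "theta_cs") %||% 1)
  ft <- tryCatch({
    ts <- simulate_model(params, cfg,
                         protocol(ev_sap_pulse(0, S0), end_time = end_time,
                                  dt = 0.01),
                         derive = FALSE)
    spike_features(detect_spikes(ts, stimulus_time = 0))
  }, error = function(e) c(T_bar = NA, b_A = NA, b_T = NA, n_spikes = 0))
  sel <- isTRUE(meets_selection_criteria(ft, resting_C = params$C_r))
  list(features = ft, selected = sel)
}

#' Two-phase evolutionary exploration of the mixed parameter space
#'
#' Phase 1 (neutral): starting from the seed grid of module weights, random
#' parents are drawn uniformly from the whole current population and
#' lognormally mutated daughters are appended unconditionally, each
#' immediately eligible as a parent.  Phase 2 (selective): parents are
#' drawn only from the vectors satisfying the selection predicate; daughters
#' that pass join the selected pool, daughters that fail are stored as
#' unselected.  The process is budgeted by daughter counts and is fully
#' reproducible for a fixed seed under serial execution.
#'
#' @param seeds data frame of weights as from [seed_grid()].
#' @param budget_neutral,budget_selective number of daughters generated in
#'   each phase.
#' @param evaluate_fn function `params -> list(features, selected)`;
#'   defaults to [evaluate_vector()].
#' @param sd_log mutation size (see [mutate_params()]).
#' @param seed RNG seed.
#' @param parents_phase1 `"population"` (any current vector may seed, the
#'   default) or `"grid"` (only the original grid vectors seed).
#' @return an object of class `flag_population`: data frame with one row
#'   per vector (`id`, `parent`, `phase`, `theta_cv`, `theta_cs`, `g_cv`,
#'   `g_cs`, `selected`, the feature columns and `cluster`, filled by
#'   [cluster_population()]), plus the parameter sets in
#'   `attr(, "params")`.
#' @export
evolve_population <- function(seeds = seed_grid(),
                              budget_neutral = 50, budget_selective = 50,
                              evaluate_fn = evaluate_vector, sd_log = 0.04,
                              seed = 1, parents_phase1 = c("population",
                                                           "grid")) {
  parents_phase1 <- match.arg(parents_phase1)
  set.seed(seed)
  params_list <- list()
  rows <- list()
  add_vec <- function(p, parent, phase, ev) {
    id <- length(params_list) + 1
    params_list[[id]] <<- p
    rows[[id]] <<- data.frame(
      id = id, parent = parent, phase = phase,
      theta_cv = attr(p, "theta_cv") %||% NA,
      theta_cs = attr(p, "theta_cs") %||% NA,
      g_cv = p$g_cv, g_cs = p$g_cs,
      selected = ev$selected,
      T_bar = ev$features[["T_bar"]], b_A = ev$features[["b_A"]],
      b_T = ev$features[["b_T"]], n_spikes = ev$features[["n_spikes"]])
    id
  }
  for (i in seq_len(nrow(seeds))) {
    p <- mixed_parameters(seeds$theta_cv[i], seeds$theta_cs[i])
    add_vec(p, NA_integer_, "seed", evaluate_fn(p))
  }
  n_seeds <- length(params_list)
  cfg_m <- module_config("mixed", 1, 1)
  for (i in seq_len(budget_neutral)) {
    pool <- if (parents_phase1 == "grid") seq_len(n_seeds)
            else seq_along(params_list)
    parent <- sample(pool, 1)
    d <- mutate_params(params_list[[parent]], sd_log, cfg_m)
    add_vec(d, parent, "neutral", evaluate_fn(d))
  }
  pop <- do.call(rbind, rows)
  sel_ids <- pop$id[pop$selected]
  if (!length(sel_ids)) {
    warning("no selected vectors after the neutral phase; selective phase skipped")
  } else {
    for (i in seq_len(budget_selective)) {
      parent <- if (length(sel_ids) == 1) sel_ids else sample(sel_ids, 1)
      d <- mutate_params(params_list[[parent]], sd_log, cfg_m)
      ev <- evaluate_fn(d)
      id <- add_vec(d, parent, if (ev$selected) "selected" else "unselected",
                    ev)
      if (ev$selected) sel_ids <- c(sel_ids, id)
    }
  }
  pop <- do.call(rbind, rows)
  pop$cluster <- NA_integer_
  structure(pop, params = params_list, class = c("flag_population",
                                                 "data.frame"))
}

#' Cluster a population in the conductance plane
#'
#' Connectivity-based (single-linkage) clustering on the log-scaled
#' coordinates `log10(g_cv + eps)`, `log10(g_cs + eps)`; two vectors belong
#' to the same cluster when they can be joined by a chain of steps shorter
#' than `cut_height`.  This handles the irregular, elongated clouds the
#' exploration produces and is invariant under permutation of the input
#' order (labels are canonicalised by cluster mean position).  The
#' per-cluster fraction of selected vectors is a coarse sensitivity
#' measure: the smaller the fraction, the more parameter-sensitive the
#' regime.
#'
#' @param population a `flag_population` (or data frame with `g_cv`,
#'   `g_cs`, `selected`).
#' @param eps offset before the log transform (accommodates the 1e-4 grid
#'   weight; default 1e-4 of the reference conductances).
#' @param cut_height linkage distance threshold (log10 units).
#' @return the population with the `cluster` column filled, plus attribute
#'   `cluster_summary` (data frame: `cluster`, `n`, `n_selected`,
#'   `fraction_selected`, `mean_g_cv`, `mean_g_cs`).
#' @export
cluster_population <- function(population, eps = 1e-4, cut_height = 0.3) {
  stopifnot(nrow(population) >= 2)
  xy <- cbind(log10(population$g_cv + eps * reference_params("cav_bk")$g_cv),
              log10(population$g_cs +
                    eps * reference_params("catsper_nhe")$g_cs))
  hc <- stats::hclust(stats::dist(xy), method = "single")
  lab <- stats::cutree(hc, h = cut_height)
  ## canonical labels: order clusters by mean position
  means <- vapply(sort(unique(lab)), function(l)
    mean(xy[lab == l, 1]) + 1e-6 * mean(xy[lab == l, 2]), 0)
  relab <- match(lab, sort(unique(lab))[order(means)])
  population$cluster <- relab
  summ <- do.call(rbind, lapply(sort(unique(relab)), function(l) {
    sel <- population$selected[relab == l]
    data.frame(cluster = l, n = length(sel), n_selected = sum(sel),
               fraction_selected = mean(sel),
               mean_g_cv = mean(population$g_cv[relab == l]),
               mean_g_cs = mean(population$g_cs[relab == l]))
  }))
  attr(population, "cluster_summary") <- summ
  population
}

#' Which module components are essential for a parameter vector?
#'
#' Re-simulates a vector with the CatSper conductance cancelled
#' (`g_cs = 0`) and with the CaV and BK conductances cancelled
#' (`g_cv = g_bk = 0`), and compares spike count and envelope features with
#' the intact run.  A component set is `"irrelevant"` when the spike count
#' is unchanged and the features move by less than `tol` (relative),
#' `"essential"` when the oscillations are lost or the features leave the
#' selection region, `"modulatory"` otherwise.  A vector that does not
#' oscillate intact is flagged `"degenerate"`.
#'
#' @param params a mixed `flag_params` object (derived).
#' @param evaluate_fn evaluation function as in [evolve_population()].
#' @param tol relative feature-change threshold (default 0.1).
#' @return list with `catsper` and `cav_bk` verdicts plus the three feature
#'   sets.
#' @export
module_necessity <- function(params, evaluate_fn = evaluate_vector,
                             tol = 0.1) {
  cfg <- module_config("mixed", attr(params, "theta_cv") %||% 1,
                       attr(params, "theta_cs") %||% 1)
  base <- evaluate_fn(params)
  verdict <- function(drop_names) {
    p2 <- params
    for (nm in drop_names) p2[[nm]] <- 0
    p2 <- derive_parameters(p2, cfg)
    ev <- evaluate_fn(p2)
    if (base$features[["n_spikes"]] < 3)
      return(list(verdict = "degenerate", features = ev$features))
    if (ev$features[["n_spikes"]] < 3 || !ev$selected)
      return(list(verdict = "essential", features = ev$features))
    rel <- abs(ev$features[c("T_bar", "b_A", "b_T")] -
               base$features[c("T_bar", "b_A", "b_T")]) /
      pmax(abs(base$features[c("T_bar", "b_A", "b_T")]), 1e-6)
    same_count <- ev$features[["n_spikes"]] == base$features[["n_spikes"]]
    if (same_count && all(rel < tol, na.rm = TRUE))
      list(verdict = "irrelevant", features = ev$features)
    else list(verdict = "modulatory", features = ev$features)
  }
  cs <- verdict("g_cs")
  cv <- verdict(c("g_cv", "g_bk"))
  list(catsper = cs$verdict, cav_bk = cv$verdict,
       features = list(intact = base$features, no_catsper = cs$features,
                       no_cav_bk = cv$features))
}

#' Write / read a population as JSON lines
#'
#' One JSON object per line: the summary row plus the full parameter
#' vector.
#'
#' @param population a `flag_population`.
#' @param path file path.
#' @return `write_population()` returns `path` invisibly;
#'   `read_population()` returns a data frame with a `params` attribute.
#' @export
write_population <- function(population, path) {
  pl <- attr(population, "params")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(population))) {
    rec <- c(as.list(population[i, ]),
             list(params = unclass(pl[[population$id[i]]])))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  pop <- do.call(rbind, lapply(recs, function(r) {
    row <- r[setdiff(names(r), "params")]
    row <- lapply(row, function(v) if (is.null(v)) NA else v)
    as.data.frame(row)
  }))
  params <- lapply(recs, function(r)
    structure(r$params, module = "mixed", class = "flag_params"))
  structure(pop, params = params, class = c("flag_population", "data.frame"))
}
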