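## Reference parameter sets and their serialisation.

# Parameter names by block; the single authority for grouping and for the
# set of parameters the evolutionary explorer is allowed to perturb.
.param_blocks <- list(
  receptor = c("R_T", "theta_R", "s_density", "r1", "r2", "r3"),
  cgmp     = c("G_r", "sigma_G", "delta_G", "k_L", "k_H", "B_G", "theta_G"),
  kcng     = c("alpha_kn", "beta_kn", "g_kn"),
  sphcn    = c("h1", "h2", "h3", "h4", "h5", "h6", "g_hc", "E_hc"),
  cav      = c("v1", "v2", "v3", "v4", "v5", "v6", "v7", "v8", "v9", "g_cv"),
  bk       = c("b1", "b2", "b3", "beta_bk", "g_bk"),
  nhe      = c("n1", "n2", "n3", "n4", "n5", "n6", "J_max", "K_Na"),
  catsper  = c("s1", "s2", "s3", "s4", "s5", "s6", "s7", "s8", "s9", "s10",
               "g_cs"),
  equilibrium = c("g_L", "E_L", "sigma_C", "delta_C"),
  protons  = c("sigma_H", "delta_H"),
  common   = c("E_m", "C_m", "v_f", "s_f", "K_out", "K_in", "Na_out",
               "Na_in", "pH_out", "pH_r", "Ca_out", "C_r", "E_K", "E_Ca",
               "temperature_C")
)

# Non-negative parameters (conductances, rates, concentrations, volumes,
# capacitance); checked by validate_params().
.nonneg_params <- c(
  "R_T", "theta_R", "s_density", "r1", "r2", "r3", "G_r", "sigma_G",
  "delta_G", "k_L", "k_H", "B_G", "theta_G", "alpha_kn", "beta_kn", "g_kn",
  "h3", "h4", "g_hc", "v1", "v4", "v7", "g_cv", "b1", "b2", "b3", "beta_bk",
  "g_bk", "n1", "n4", "J_max", "K_Na", "s1", "s7", "s8", "s9", "s10", "g_cs",
  "g_L", "sigma_C", "delta_C", "sigma_H", "delta_H", "K_out", "K_in",
  "Na_out", "Na_in", "Ca_out", "C_r")

#' Reference parameter set of a model variant
#'
#' Returns the complete reference parameter set for the requested module,
#' with every constant in its tabulated unit (voltages mV, conductance
#' densities pS um^-2, cGMP/calcium nM, protons M, rates s^-1 or per-unit
#' concentration per second, volume fL, area um^2).  The equilibrium block
#' (`E_L`, `sigma_C`, `delta_H`) holds the tabulated point values; call
#' [derive_parameters()] to recompute them self-consistently from the
#' resting condition (recommended before simulating, and done by default in
#' [simulate_model()]).
#'
#' @param module one of `"upstream"`, `"cav_bk"`, `"catsper_nhe"`,
#'   `"mixed"`.  The upstream block is identical in all variants; the
#'   module choice selects the leak conductance, calcium extrusion rate and
#'   tabulated equilibrium values.  For `"mixed"` see [mixed_parameters()].
#' @return an object of class `flag_params` (a named list of numeric
#'   scalars plus a `module` tag).
#' @export
reference_params <- function(module = c("cav_bk", "catsper_nhe", "upstream",
                                        "mixed")) {
  module <- match.arg(module)
  p <- list(
    # SAP receptor and guanylate cyclase
    R_T = 7.36e5,                 # receptors per cell
    theta_R = 3.706e7 * 1e3 / physical_constants[["NA_const"]] * 1e9,
                                  # nM cell, = s/N_A with s in cell L^-1
    s_density = 3.706e7,          # cells mL^-1
    r1 = 2.70e-2,                 # nM^-1 s^-1
    r2 = 8.70,                    # s^-1
    r3 = 5.70e-2,                 # s^-1
    # cGMP turnover
    G_r = 1.25,                   # nM
    sigma_G = 23.65,              # nM s^-1
    delta_G = 18.92,              # s^-1
    k_L = 3.25,                   # s^-1
    k_H = 40.20,                  # s^-1
    B_G = 5.49e3,                 # cell^-1
    theta_G = 1.89e-4,            # nM cell
    # KCNG
    alpha_kn = 10, beta_kn = 257, g_kn = 135.30,
    # spHCN
    h1 = -50.80, h2 = 6.60, h3 = 9.18e-2, h4 = 1.10, h5 = -42, h6 = 18.50,
    g_hc = 193.50, E_hc = -18,
    # CaV
    v1 = 10.10, v2 = -55, v3 = 1.42, v4 = 33.80, v5 = -39, v6 = 2.10,
    v7 = 8.10, v8 = -18, v9 = 7.50, g_cv = 185.16,
    # BK
    b1 = 0.97, b2 = 316, b3 = 30, beta_bk = 97, g_bk = 214.50,
    # NHE
    n1 = 1.51, n2 = -65, n3 = 7, n4 = 0.90, n5 = -30, n6 = 7,
    J_max = 3e-7,                 # fmol s^-1
    K_Na = 25,                    # mM
    # CatSper
    s1 = 270, s2 = 10, s3 = 79.70, s4 = 7.20, s5 = 35.52, s6 = -41,
    s7 = 1, s8 = 700, s9 = 2.50, s10 = 1.40e-4, g_cs = 39.90,
    # protons
    sigma_H = 1.50e-7,            # M s^-1
    delta_H = 1.28,               # s^-1
    # common
    E_m = -40, C_m = 1e-2, v_f = 1.60, s_f = 30,
    K_out = 9, K_in = 219, Na_out = 423, Na_in = 20,
    pH_out = 8, pH_r = 7.10, Ca_out = 10, C_r = 100,
    E_K = -80, E_Ca = 144, temperature_C = 17
  )
  eq <- switch(module,
    cav_bk      = list(g_L = 1.94, E_L = 80.05, sigma_C = 1.14e8,
                       delta_C = 1.16e6),
    catsper_nhe = list(g_L = 9, E_L = -20.4, sigma_C = 3.72e7,
                       delta_C = 4.27e5),
    upstream    = list(g_L = 1.94, E_L = NA_real_, sigma_C = NA_real_,
                       delta_C = NA_real_),
    mixed       = list(g_L = 1.94 + 9, E_L = NA_real_, sigma_C = NA_real_,
                       delta_C = 1.16e6 + 4.27e5)
  )
  p <- c(p, eq)
  structure(p, module = module, class = "flag_params")
}

#' Validate a parameter set
#'
#' Checks sign constraints (conductances, rates, concentrations, volume and
#' capacitance non-negative; `v_f`, `s_f`, `C_m` strictly positive) and the
#' internal consistency `G_r = sigma_G / delta_G` (1e-3 relative tolerance).
#'
#' @param params a `flag_params` object.
#' @return the validated parameter set, invisibly.  Errors on violation.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "flag_params"))
  for (nm in .nonneg_params) {
    v <- params[[nm]]
    if (!is.null(v) && is.finite(v) && v < 0)
      stop(sprintf("parameter %s must be non-negative (got %g)", nm, v))
  }
  for (nm in c("v_f", "s_f", "C_m"))
    if (params[[nm]] <= 0) stop(sprintf("parameter %s must be positive", nm))
  rel <- abs(params$G_r - params$sigma_G / params$delta_G) / params$G_r
  if (rel > 1e-3)
    stop(sprintf("G_r and sigma_G/delta_G disagree (relative error %.2g)", rel))
  invisible(params)
}

#' @export
print.flag_params <- function(x, ...) {
  cat("<flag_params> module:", attr(x, "module"), "\n")
  for (blk in names(.param_blocks)) {
    nm <- intersect(.param_blocks[[blk]], names(x))
    if (!length(nm)) next
    vals <- vapply(nm, function(n) format(x[[n]], digits = 5), "")
    cat(sprintf("  %-11s %s\n", blk,
                paste(nm, vals, sep = "=", collapse = "  ")))
  }
  invisible(x)
}

#' Modify parameters in a set
#'
#' @param params a `flag_params` object.
#' @param ... named replacement values.
#' @return the updated parameter set.
#' @export
set_params <- function(params, ...) {
  upd <- list(...)
  unknown <- setdiff(names(upd), names(params))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  params[names(upd)] <- upd
  params
}

#' Write / read a parameter set as YAML or JSON
#'
#' The file format is a flat mapping of parameter names to values plus a
#' `module` entry; the extension (`.yaml`/`.yml` or `.json`) selects the
#' serialiser.
#'
#' @param params a `flag_params` object.
#' @param path file path.
#' @return `write_params()` returns `path` invisibly; `read_params()`
#'   returns a `flag_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "flag_params"))
  x <- c(list(module = attr(params, "module")), unclass(params))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path, precision = 15)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else stop("unsupported parameter file extension: ", path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unsupported parameter file extension: ", path)
  module <- x$module %||% "cav_bk"
  x$module <- NULL
  x <- lapply(x, function(v) if (is.null(v)) NA_real_ else as.numeric(v))
  structure(x, module = module, class = "flag_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
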