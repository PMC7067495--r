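## Synthetic-data generators: fluorescence-like calcium traces, bulk cGMP
## dose-response datasets and constructed spike trains with known envelope
## statistics.  These emulate the structure of the experimental inputs the
## analysis operates on and double as ground-truth oracles for the
## spike-train quantification.

#' Fluorescence-like trace from a simulated calcium trajectory
#'
#' Emulates a single-cell flagellar fluorescence recording: the intensity
#' is proportional to the calcium concentration (uncalibrated probe), with
#' an additive baseline offset and Gaussian measurement noise (the default
#' noise model; a Poisson-like shot-noise option scales the Gaussian
#' standard deviation with the square root of the signal).  The generator
#' also returns the ground-truth spike list obtained from the noiseless
#' series, so detector performance can be scored.
#'
#' @param ts a `flag_ts` trajectory (or data frame with `time` and `C`).
#' @param scale proportionality factor intensity / concentration.
#' @param baseline additive offset (intensity units).
#' @param noise_sd Gaussian noise standard deviation (intensity units,
#'   >= 0).
#' @param noise one of `"gaussian"` (default) or `"poisson_like"`.
#' @param pre_window required pre-stimulus window (s, >= 1); errors if the
#'   trajectory provides less.
#' @param stimulus_time stimulus time (s).
#' @param seed RNG seed (deterministic output for a fixed seed).
#' @return data frame with columns `time`, `value`; attributes
#'   `ground_truth` (spike data frame from the noiseless trace),
#'   `noise_sd`, `scale`, `baseline`.
#' @export
make_fluorescence <- function(ts, scale = 1, baseline = 0, noise_sd = 0,
                              noise = c("gaussian", "poisson_like"),
                              pre_window = 1, stimulus_time = 0, seed = 1) {
  noise <- match.arg(noise)
  stopifnot(noise_sd >= 0)
  df <- as.data.frame(ts)
  if (!all(c("time", "C") %in% names(df)))
    stop("make_fluorescence(): trajectory must provide 'time' and 'C'")
  if (stimulus_time - min(df$time) < pre_window)
    stop("make_fluorescence(): trajectory must include at least ",
         pre_window, " s before the stimulus")
  clean <- scale * df$C + baseline
  gt <- detect_spikes(data.frame(time = df$time, value = clean),
                      stimulus_time = stimulus_time, value_col = "value")
  set.seed(seed)
  eps <- if (noise == "gaussian") stats::rnorm(length(clean), 0, noise_sd)
         else stats::rnorm(length(clean), 0,
                           noise_sd * sqrt(pmax(clean, 0) / mean(clean)))
  out <- data.frame(time = df$time, value = clean + eps)
  structure(out, ground_truth = gt$spikes, noise_sd = noise_sd,
            scale = scale, baseline = baseline)
}

#' Synthetic bulk cGMP dose-response dataset
#'
#' Bulk-population cGMP kinetics (pmol per 10^8 cells) at several SAP
#' doses, generated from the upstream receptor/cGMP model with optional
#' multiplicative noise — the structure of a stopped-flow radioimmunoassay
#' dataset.
#'
#' @param doses SAP doses (nM, > 0).
#' @param params upstream parameter set (ground truth).
#' @param times sampling times (s); the default is dense over the fast
#'   peak and sparse over the slow decay.
#' @param noise_frac multiplicative noise fraction (lognormal-free simple
#'   Gaussian factor `1 + N(0, noise_frac)`).
#' @param seed RNG seed.
#' @return data frame with columns `dose_nM`, `time_s`, `value`, `unit`,
#'   attribute `provenance = "synthetic"`.
#' @export
make_cgmp_dataset <- function(doses = c(0.25, 2.5, 25, 250),
                              params = reference_params("upstream"),
                              times = c(seq(0.05, 1, by = 0.05),
                                        seq(1.5, 10, by = 0.5),
                                        seq(12, 45, by = 3)),
                              noise_frac = 0, seed = 1) {
  stopifnot(all(doses > 0), all(times >= 0), noise_frac >= 0)
  Gb_r <- .bulk_baseline(params)
  set.seed(seed)
  out <- do.call(rbind, lapply(doses, function(dd) {
    val <- .bulk_cgmp_curve(dd, times, params, Gb_r)
    if (noise_frac > 0)
      val <- val * (1 + stats::rnorm(length(val), 0, noise_frac))
    data.frame(dose_nM = dd, time_s = times, value = val,
               unit = "pmol_per_1e8cells")
  }))
  structure(out, provenance = "synthetic")
}

#' Constructed spike train with exactly known envelope statistics
#'
#' A sum of localized bumps whose amplitudes and interspike intervals
#' follow exact linear ramps, `A_k = A_1 (1 + b_A (k - 1))` and
#' `T_k = T_1 (1 + b_T (k - 1))`, so that [spike_features()] on the
#' noiseless trace returns `(b_A, b_T)` by construction.
#'
#' @param n_spikes number of spikes (>= 1).
#' @param A1 first-spike amplitude (signal units, > 0).
#' @param T1 first interspike interval (s, > 0).
#' @param b_A,b_T linear ramp slopes; every implied amplitude and interval
#'   must stay positive.
#' @param shape bump shape: `"gaussian"` (default) or `"triangular"`.
#' @param width bump width parameter (s).
#' @param baseline additive offset.
#' @param noise_sd Gaussian noise SD.
#' @param dt sampling interval (s).
#' @param t_first time of the first spike (s, > 1 so a pre-stimulus
#'   baseline window exists with the stimulus at 0).
#' @param seed RNG seed.
#' @return data frame (`time`, `value`) with attribute `ground_truth`
#'   (data frame `t`, `A` of the constructed spikes).
#' @export
make_constructed_train <- function(n_spikes = 6, A1 = 1, T1 = 1,
                                   b_A = -0.1, b_T = 0.05,
                                   shape = c("gaussian", "triangular"),
                                   width = 0.08, baseline = 0,
                                   noise_sd = 0, dt = 0.01, t_first = 2,
                                   seed = 1) {
  shape <- match.arg(shape)
  stopifnot(n_spikes >= 1, A1 > 0, T1 > 0, width > 0, t_first > 1)
  k <- seq_len(n_spikes)
  A <- A1 * (1 + b_A * (k - 1))
  Tk <- T1 * (1 + b_T * (seq_len(max(n_spikes - 1, 1)) - 1))
  if (any(A <= 0) || any(Tk <= 0))
    stop("make_constructed_train(): slopes imply non-positive amplitude ",
         "or interval")
  t_sp <- t_first + c(0, cumsum(Tk))[k]
  t_end <- max(t_sp) + 4 * width + 1
  tt <- seq(-2, t_end, by = dt)
  vv <- rep(baseline, length(tt))
  for (i in k) {
    u <- (tt - t_sp[i]) / width
    vv <- vv + if (shape == "gaussian") A[i] * exp(-u^2)
               else A[i] * pmax(1 - abs(u), 0)
  }
  set.seed(seed)
  if (noise_sd > 0) vv <- vv + stats::rnorm(length(vv), 0, noise_sd)
  structure(data.frame(time = tt, value = vv),
            ground_truth = data.frame(t = t_sp, A = A + baseline))
}
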