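## Spike-train quantification: smoothing, spike calling, envelope statistics
## and the physiological selection criteria.

#' Detect calcium spikes in a time series
#'
#' Implements the quantification used throughout the package: the series is
#' smoothed with a cubic smoothing spline ([stats::smooth.spline()],
#' smoothing parameter chosen by generalised cross-validation unless
#' overridden), and spikes are the local maxima of the smooth curve after
#' the stimulus that exceed a detection threshold.
#'
#' The threshold is `baseline_mean + max(3 * baseline_sd,
#' rel_floor * (smooth_max - baseline_mean))`, where the baseline statistics
#' come from the raw pre-stimulus window.  For measured (noisy) traces the
#' classic three-standard-deviations rule dominates; the relative floor
#' (default 5% of the post-stimulus dynamic range) keeps the detector
#' meaningful on noiseless model output, where the baseline SD degenerates
#' to zero and sub-plateau ripples would otherwise count as spikes.  The
#' same statistic serves as a minimal topographic prominence, suppressing
#' the shoulder maxima that spline fits produce on very steep spike fronts.
#'
#' @param x a data frame with columns `time` and a signal column (see
#'   `value_col`), or a `flag_ts` trajectory.
#' @param stimulus_time time of the stimulus (s); at least 1 s of
#'   pre-stimulus samples is required for the baseline window.
#' @param value_col name of the signal column (default `"C"` falling back
#'   to `"value"`).
#' @param spar optional smoothing parameter forwarded to
#'   [stats::smooth.spline()] (GCV when `NULL`).
#' @param threshold optional explicit detection threshold overriding the
#'   baseline rule (signal units).
#' @param rel_floor relative floor of the threshold rule (default 0.05).
#' @return an object of class `spike_train`: list with `spikes` (data frame
#'   `t`, `A`; amplitudes measured on the smooth curve, relative to zero),
#'   `intervals` (`T_k = t_{k+1} - t_k`), `baseline_mean`, `baseline_sd`,
#'   `threshold` and `stimulus_time`.
#' @export
detect_spikes <- function(x, stimulus_time = 0, value_col = NULL,
                          spar = NULL, threshold = NULL, rel_floor = 0.05) {
  df <- as.data.frame(x)
  if (is.null(value_col))
    value_col <- if ("C" %in% names(df)) "C" else "value"
  if (!all(c("time", value_col) %in% names(df)))
    stop("detect_spikes(): need columns 'time' and '", value_col, "'")
  tt <- df$time
  vv <- df[[value_col]]
  pre <- tt < stimulus_time
  if (sum(pre) < 2 || (stimulus_time - min(tt)) < 1)
    stop("detect_spikes(): need at least 1 s of pre-stimulus samples")
  b_mean <- mean(vv[pre])
  b_sd <- stats::sd(vv[pre])

  ## the default knot heuristic of smooth.spline is far too coarse for
  ## densely sampled traces with sub-0.1 s spikes: cap the knot spacing at
  ## ~10 ms so the spline can represent individual spikes
  n_knots <- min(length(tt), max(100, ceiling(diff(range(tt)) / 0.01)))
  fit <- if (is.null(spar))
    stats::smooth.spline(tt, vv, nknots = n_knots)
  else stats::smooth.spline(tt, vv, spar = spar, nknots = n_knots)
  sm <- stats::predict(fit, tt)$y

  rng <- max(sm[tt >= stimulus_time]) - b_mean
  min_drop <- max(3 * b_sd, rel_floor * max(rng, 0))
  if (is.null(threshold)) threshold <- b_mean + min_drop
  ## a trace whose post-stimulus excursion is negligible against its own
  ## baseline carries no spikes; this guards against solver-level wiggles on
  ## flat trajectories being promoted to maxima (scale-invariant: both
  ## sides scale linearly with the signal)
  if (rng < 0.01 * abs(b_mean)) {
    return(structure(list(spikes = data.frame(t = numeric(0),
                                              A = numeric(0)),
                          intervals = numeric(0), baseline_mean = b_mean,
                          baseline_sd = b_sd, threshold = threshold,
                          stimulus_time = stimulus_time),
                     class = "spike_train"))
  }

  n <- length(sm)
  is_max <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] &
                     sm[2:(n - 1)] >= sm[3:n], FALSE)
  idx <- which(is_max & tt > stimulus_time & sm > threshold)
  ## spline fits of near-discontinuous spike fronts ring, producing
  ## shoulder maxima: keep only maxima whose topographic prominence (height
  ## above the deepest valley separating them from higher terrain) exceeds
  ## the same statistic that sets the threshold
  idx <- idx[.prominence(sm, idx) >= min_drop]
  spikes <- data.frame(t = tt[idx], A = sm[idx])
  structure(list(spikes = spikes,
                 intervals = if (nrow(spikes) > 1) diff(spikes$t)
                             else numeric(0),
                 baseline_mean = b_mean, baseline_sd = b_sd,
                 threshold = threshold, stimulus_time = stimulus_time),
            class = "spike_train")
}

# Topographic prominence of local maxima: for each candidate index, the
# height above the higher of the two lowest points separating it from
# higher values on either side (series boundaries count as bases).
.prominence <- function(sm, idx) {
  vapply(idx, function(p) {
    h <- sm[p]
    lbase <- h
    j <- p - 1
    vmin <- h
    while (j >= 1 && sm[j] <= h) { vmin <- min(vmin, sm[j]); j <- j - 1 }
    lbase <- vmin
    j <- p + 1
    vmin <- h
    while (j <= length(sm) && sm[j] <= h) {
      vmin <- min(vmin, sm[j]); j <- j + 1
    }
    rbase <- vmin
    h - max(lbase, rbase)
  }, numeric(1))
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes, threshold %.3g (baseline %.3g +/- %.3g)\n",
              nrow(x$spikes), x$threshold, x$baseline_mean, x$baseline_sd))
  if (nrow(x$spikes)) print(utils::head(x$spikes, 10))
  invisible(x)
}

#' Spike-train envelope features
#'
#' Summary statistics of a spike train: the mean interspike interval
#' `T_bar` and the ordinary-least-squares slopes of the relative amplitude
#' `A_k / A_1` (`b_A`) and of the relative interspike interval `T_k / T_1`
#' (`b_T`) over the spike index `k = 1, 2, ...` (the first, unit-valued
#' point is included in the regression).  `b_A` needs at least 3 spikes and
#' `b_T` at least 3 intervals; otherwise the feature is `NA`.
#'
#' @param train a `spike_train`, or a data frame with columns `t` and `A`.
#' @return named numeric vector `c(T_bar, b_A, b_T, n_spikes)`.
#' @export
spike_features <- function(train) {
  sp <- if (inherits(train, "spike_train")) train$spikes else
    as.data.frame(train)
  n <- nrow(sp)
  ols_slope <- function(y) {
    k <- seq_along(y)
    sum((k - mean(k)) * (y - mean(y))) / sum((k - mean(k))^2)
  }
  Tk <- if (n > 1) diff(sp$t) else numeric(0)
  c(T_bar = if (n > 1) mean(Tk) else NA_real_,
    b_A = if (n >= 3) ols_slope(sp$A / sp$A[1]) else NA_real_,
    b_T = if (n >= 4) ols_slope(Tk / Tk[1]) else NA_real_,
    n_spikes = n)
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' @param px,py point coordinates (vectorised).
#' @param polygon two-column matrix of vertex coordinates of a simple
#'   polygon (closed implicitly).
#' @return logical vector; boundary points count as inside.
#' @export
point_in_polygon <- function(px, py, polygon) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3 || any(!is.finite(polygon)))
    stop("point_in_polygon(): polygon must have >= 3 finite vertices")
  n <- nrow(polygon)
  xs <- polygon[, 1]; ys <- polygon[, 2]
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    inside <- FALSE
    j <- n
    for (k in seq_len(n)) {
      if (((ys[k] > y) != (ys[j] > y)) &&
          (x < (xs[j] - xs[k]) * (y - ys[k]) / (ys[j] - ys[k]) + xs[k]))
        inside <- !inside
      ## boundary: on-segment points accepted
      d <- (xs[j] - xs[k]) * (y - ys[k]) - (ys[j] - ys[k]) * (x - xs[k])
      if (abs(d) < 1e-12 &&
          x >= min(xs[k], xs[j]) - 1e-12 && x <= max(xs[k], xs[j]) + 1e-12 &&
          y >= min(ys[k], ys[j]) - 1e-12 && y <= max(ys[k], ys[j]) + 1e-12)
        return(TRUE)
      j <- k
    }
    inside
  }, logical(1))
}

#' Default envelope-coefficient acceptance region
#'
#' The experimentally most representative spike trains have decaying
#' amplitudes (`b_A < 0`) and growing interspike intervals (`b_T > 0`).
#' The exact experimental convex hull is not published, so the default
#' region is that quadrant clipped to the observed plot range:
#' `b_T` in (0, 0.5], `b_A` in [-0.25, 0).
#'
#' @return a 4 x 2 matrix of polygon vertices (columns `b_T`, `b_A`).
#' @export
default_hull <- function() {
  m <- rbind(c(1e-9, -1e-9), c(0.5, -1e-9), c(0.5, -0.25), c(1e-9, -0.25))
  colnames(m) <- c("b_T", "b_A")
  m
}

#' Physiological selection criteria for a spike train
#'
#' A parameter regime is considered coherent with the observed responses
#' when (i) the mean interspike interval lies in [0.37, 1.38] s, (ii) the
#' envelope-coefficient point `(b_T, b_A)` falls inside the acceptance
#' polygon (default: the decaying-amplitude / growing-interval quadrant,
#' see [default_hull()]), and (iii) the resting calcium concentration is
#' about 100 nM (within `resting_tol`).
#'
#' @param features output of [spike_features()] (or a `spike_train`).
#' @param resting_C resting calcium concentration of the regime (nM).
#' @param hull acceptance polygon (two columns: `b_T`, `b_A`).
#' @param interval_range admissible mean-interval range (s).
#' @param resting_target,resting_tol resting-calcium target and tolerance
#'   (nM).
#' @return logical scalar with attribute `checks` (named logical vector).
#' @export
meets_selection_criteria <- function(features, resting_C = 100,
                                     hull = default_hull(),
                                     interval_range = c(0.37, 1.38),
                                     resting_target = 100,
                                     resting_tol = 10) {
  if (inherits(features, "spike_train")) features <- spike_features(features)
  checks <- c(
    interval = is.finite(features[["T_bar"]]) &&
      features[["T_bar"]] >= interval_range[1] &&
      features[["T_bar"]] <= interval_range[2],
    envelope = is.finite(features[["b_A"]]) && is.finite(features[["b_T"]]) &&
      point_in_polygon(features[["b_T"]], features[["b_A"]], hull),
    resting = abs(resting_C - resting_target) <= resting_tol)
  structure(all(checks), checks = checks)
}

#' Read a two-column delimited time series
#'
#' Accepts comma-, tab- or whitespace-delimited files whose first two
#' columns are time (s) and signal intensity.
#'
#' @param path file path.
#' @return data frame with columns `time` and `value`.
#' @export
read_trace <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, header = grepl("[A-Za-z]", first), sep = sep)
  df <- df[, 1:2]
  names(df) <- c("time", "value")
  df
}
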