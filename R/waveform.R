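#' Construct a waveform series
#'
#' A `waveform_series` holds one cardiac cycle (or the prospectively gated,
#' diastole-truncated part of one) of paired velocity and cross-sectional
#' area samples. Units are fixed package-wide: time in ms since the R-wave
#' trigger, velocity in m/s (signed, positive away from the heart), area in
#' mm^2. Area must be strictly positive everywhere so that lnA is defined.
#'
#' @param t numeric vector of sample times \[ms\], strictly increasing.
#' @param U numeric vector of mean velocity \[m/s\], same length as `t`.
#' @param A numeric vector of lumen area \[mm^2\], strictly positive.
#' @param dt_native original sampling interval \[ms\], if known.
#' @param gated_complete_cycle logical; `FALSE` when the acquisition is
#'   prospectively gated and end-diastole is truncated.
#' @return An object of class `waveform_series`.
#' @export
#' @examples
#' t <- seq(0, 780, by = 9.6)
#' s <- waveform_series(t, U = sin(t / 200), A = 500 + 20 * sin(t / 200))
waveform_series <- function(t, U, A, dt_native = NULL,
                            gated_complete_cycle = NA) {
  if (!is.numeric(t) || !is.numeric(U) || !is.numeric(A))
    stop("t, U and A must be numeric vectors", call. = FALSE)
  n <- length(t)
  if (length(U) != n || length(A) != n)
    stop(sprintf("t, U, A must have equal length (got %d, %d, %d)",
                 n, length(U), length(A)), call. = FALSE)
  if (n < 8L)
    stop(sprintf("need at least 8 samples, got %d", n), call. = FALSE)
  if (anyNA(t) || anyNA(U) || anyNA(A) ||
      !all(is.finite(t)) || !all(is.finite(U)) || !all(is.finite(A)))
    stop("t, U, A must be finite and free of missing values", call. = FALSE)
  if (any(diff(t) <= 0))
    stop(sprintf("time must be strictly increasing (violation at sample %d)",
                 which(diff(t) <= 0)[1] + 1L), call. = FALSE)
  if (any(A <= 0))
    stop(sprintf("area must be strictly positive (A = %g at sample %d)",
                 A[which(A <= 0)[1]], which(A <= 0)[1]), call. = FALSE)
  structure(
    list(t = as.numeric(t), U = as.numeric(U), A = as.numeric(A),
         dt_native = dt_native,
         gated_complete_cycle = gated_complete_cycle),
    class = "waveform_series")
}

#' @export
print.waveform_series <- function(x, ...) {
  cat("<waveform_series> ", length(x$t), " samples, t = [",
      round(x$t[1], 2), ", ", round(x$t[length(x$t)], 2), "] ms",
      if (is_uniform(x)) sprintf(", uniform dt = %g ms", sampling_interval(x)),
      "\n", sep = "")
  cat("  U: [", round(min(x$U), 3), ", ", round(max(x$U), 3), "] m/s;  A: [",
      round(min(x$A), 1), ", ", round(max(x$A), 1), "] mm^2\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.waveform_series <- function(x, ...) {
  data.frame(time_ms = x$t, U_mps = x$U, A_mm2 = x$A)
}

# uniform-sampling check, tolerant to fp representation of the grid
is_uniform <- function(series, tol = 1e-6) {
  d <- diff(series$t)
  diff(range(d)) <= tol * max(d)
}

sampling_interval <- function(series) {
  if (!is_uniform(series))
    stop("series is not uniformly sampled", call. = FALSE)
  mean(diff(series$t))
}

#' Load velocity/area waveforms from a CSV or JSON file
#'
#' Reads the tabular output of a PC-CMR flow/area segmentation step. The file
#' must contain time, velocity and area columns; names are configurable. The
#' velocity sign convention (positive away from the heart) can be fixed with
#' `velocity_sign = -1` when the velocity-encoding direction was inverted.
#'
#' @param path file to read. `.json` is parsed as an array of records; any
#'   other extension is read as CSV with a header row.
#' @param columns named character vector mapping internal names `t`, `U`, `A`
#'   to the column names in the file.
#' @param velocity_sign `+1` or `-1`; `U` is multiplied by this.
#' @return A validated [waveform_series()].
#' @export
load_waveforms <- function(path,
                           columns = c(t = "time_ms", U = "U_mps", A = "A_mm2"),
                           velocity_sign = 1) {
  if (!file.exists(path))
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  if (!velocity_sign %in% c(-1, 1))
    stop("velocity_sign must be +1 or -1", call. = FALSE)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    read.csv(path, check.names = FALSE)
  }
  for (nm in c("t", "U", "A")) {
    if (!columns[[nm]] %in% names(df))
      stop(sprintf("missing column '%s' (expected for %s) in %s",
                   columns[[nm]], nm, path), call. = FALSE)
  }
  waveform_series(t = df[[columns[["t"]]]],
                  U = velocity_sign * df[[columns[["U"]]]],
                  A = df[[columns[["A"]]]])
}

#' Write a waveform series to CSV or JSON
#'
#' @param series a [waveform_series()].
#' @param path output file; `.json` writes an array of records, anything
#'   else a CSV with header `time_ms,U_mps,A_mm2`.
#' @return `path`, invisibly.
#' @export
write_waveforms <- function(series, path) {
  stopifnot(inherits(series, "waveform_series"))
  df <- as.data.frame(series)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, digits = NA)
  } else {
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Resample a waveform series onto a uniform grid
#'
#' Interpolates U and A onto a uniform grid of spacing `dt` starting at the
#' first sample. The default method is shape-preserving monotone cubic
#' (Fritsch-Carlson, as in PCHIP), which passes through every original sample
#' and cannot overshoot between knots; plain linear interpolation is also
#' available. Downsampling is refused: `dt` may not exceed the smallest
#' native spacing.
#'
#' @param series a [waveform_series()].
#' @param dt target sampling interval \[ms\]; default 1 ms.
#' @param method `"monotone-cubic"` (default) or `"linear"`.
#' @return A uniformly sampled [waveform_series()].
#' @export
resample_uniform <- function(series, dt = 1,
                             method = c("monotone-cubic", "linear")) {
  stopifnot(inherits(series, "waveform_series"))
  method <- match.arg(method)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a positive scalar [ms]", call. = FALSE)
  native <- min(diff(series$t))
  if (dt > native + 1e-9)
    stop(sprintf(
      "dt = %g ms exceeds the native spacing %g ms; downsampling is refused",
      dt, native), call. = FALSE)
  t0 <- series$t[1]
  tn <- series$t[length(series$t)]
  grid <- t0 + dt * seq(0L, floor((tn - t0) / dt + 1e-9))
  interp <- function(y) {
    if (method == "linear") {
      approx(series$t, y, xout = grid)$y
    } else {
      splinefun(series$t, y, method = "monoH.FC")(grid)
    }
  }
  waveform_series(t = grid, U = interp(series$U), A = interp(series$A),
                  dt_native = if (is.null(series$dt_native)) native
                              else series$dt_native,
                  gated_complete_cycle = series$gated_complete_cycle)
}

#' Savitzky-Golay smoothing of the area curve
#'
#' Replaces A by its local least-squares polynomial (Savitzky-Golay) smooth
#' of the given order and centred window. Defaults follow standard practice
#' for 1-ms-resampled aortic curves: 3rd order, 101-sample (100 ms) window.
#' The window must be odd (a centred filter); a window longer than the series
#' is shrunk to the largest valid odd size, recorded in the result's
#' `smoothing` field. Velocity is untouched unless `smooth_velocity = TRUE`
#' (same filter). Edge samples are handled by the filter's startup/ending
#' transients: the full polynomial fit over the first/last window evaluated
#' at the edge positions.
#'
#' @param series a uniformly sampled [waveform_series()].
#' @param poly_order polynomial order of the local fit; default 3.
#' @param window_samples odd window length in samples; default 101.
#' @param smooth_velocity also smooth U with the same filter; default `FALSE`.
#' @return A [waveform_series()] with smoothed A (and optionally U) and a
#'   `smoothing` record of the parameters actually used.
#' @export
smooth_area <- function(series, poly_order = 3, window_samples = 101,
                        smooth_velocity = FALSE) {
  stopifnot(inherits(series, "waveform_series"))
  if (!is_uniform(series))
    stop("smooth_area requires a uniformly sampled series; resample first",
         call. = FALSE)
  if (window_samples %% 2 == 0)
    stop(sprintf(
      "window_samples must be odd (a centred filter); got %d - use %d",
      window_samples, window_samples + 1), call. = FALSE)
  if (poly_order >= window_samples)
    stop("poly_order must be smaller than window_samples", call. = FALSE)
  n <- length(series$t)
  win <- as.integer(window_samples)
  if (win > n) {
    win <- if (n %% 2 == 1L) n else n - 1L
    if (win <= poly_order)
      stop("series too short to smooth at this polynomial order",
           call. = FALSE)
  }
  out <- series
  out$A <- signal::sgolayfilt(series$A, p = poly_order, n = win)
  if (any(out$A <= 0))
    stop("smoothing produced non-positive area; check input quality",
         call. = FALSE)
  if (smooth_velocity)
    out$U <- signal::sgolayfilt(series$U, p = poly_order, n = win)
  out$smoothing <- list(poly_order = poly_order, window_samples = win,
                        window_requested = as.integer(window_samples),
                        velocity_smoothed = smooth_velocity)
  out
}

#' Detect the systolic foot of the velocity upstroke
#'
#' The systolic foot anchors all early-systole windows. Baseline velocity is
#' the median of the first `baseline_fraction` of samples; the foot is the
#' last sample before U first exceeds
#' `baseline + threshold_fraction * (peak - baseline)` on the way up to the
#' global velocity maximum. The rule is baseline-relative, so a constant
#' velocity offset does not move the foot.
#'
#' @param series a uniformly sampled [waveform_series()].
#' @param threshold_fraction upstroke fraction defining the crossing;
#'   default 0.05 (5 percent).
#' @param baseline_fraction fraction of initial samples defining baseline;
#'   default 0.05.
#' @param min_excursion minimum peak-baseline excursion \[m/s\] below which
#'   the signal is declared flat; default 0.02.
#' @return An object of class `foot_index` with fields `index` (sample
#'   position), `time` \[ms\] and `method`.
#' @export
detect_systolic_foot <- function(series, threshold_fraction = 0.05,
                                 baseline_fraction = 0.05,
                                 min_excursion = 0.02) {
  stopifnot(inherits(series, "waveform_series"))
  if (!is_uniform(series))
    stop("detect_systolic_foot requires a uniformly sampled series",
         call. = FALSE)
  U <- series$U
  n <- length(U)
  nb <- max(3L, as.integer(ceiling(baseline_fraction * n)))
  baseline <- median(U[seq_len(nb)])
  ipk <- which.max(U)
  excursion <- U[ipk] - baseline
  if (excursion < min_excursion)
    stop(sprintf(
      "no systolic upstroke: peak - baseline = %.4g m/s is below %.4g",
      excursion, min_excursion), call. = FALSE)
  thr <- baseline + threshold_fraction * excursion
  cross <- which(U[seq_len(ipk)] > thr)[1]
  if (is.na(cross) || cross == 1L)
    stop("could not locate the systolic foot before the velocity peak",
         call. = FALSE)
  structure(list(index = cross - 1L, time = series$t[cross - 1L],
                 method = sprintf("upstroke-threshold-%g", threshold_fraction)),
            class = "foot_index")
}

#' @export
print.foot_index <- function(x, ...) {
  cat(sprintf("<foot_index> sample %d (t = %g ms), method %s\n",
              x$index, x$time, x$method))
  invisible(x)
}
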