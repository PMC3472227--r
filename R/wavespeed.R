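#' Build the U-lnA loop
#'
#' Pairs velocity with the natural log of area, sample by sample. In
#' reflection-free early systole all wavefronts are forward-travelling, so
#' the loop's early limb is a straight line whose slope is the wave speed c.
#' The additive constant in lnA (i.e. the area unit) does not affect the
#' slope.
#'
#' @param series a uniformly sampled, positive-area [waveform_series()].
#' @param foot a [detect_systolic_foot()] result anchoring early systole.
#' @return An object of class `ulna_loop` with fields `t`, `U`, `lnA`,
#'   `foot_index`, `peak_u_index`.
#' @export
build_loop <- function(series, foot = detect_systolic_foot(series)) {
  stopifnot(inherits(series, "waveform_series"),
            inherits(foot, "foot_index"))
  peak <- which.max(series$U)
  if (foot$index >= peak)
    stop("systolic foot must precede the velocity peak", call. = FALSE)
  structure(list(t = series$t, U = series$U, lnA = log(series$A),
                 foot_index = foot$index, peak_u_index = peak),
            class = "ulna_loop")
}

# r2 of the OLS fit of y on x, centred two-pass computation; -Inf when the
# abscissa has no variance (vertical loop segment) so such windows never win
.window_r2 <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sxx <- sum(xc * xc)
  syy <- sum(yc * yc)
  if (sxx <= 0 || syy <= 0) return(-Inf)
  sxy <- sum(xc * yc)
  (sxy * sxy) / (sxx * syy)
}

#' Select the most linear early-systolic portion of the loop
#'
#' Among all contiguous windows lying between the systolic foot and the
#' velocity peak and spanning at least `min_len_ms`, returns the one whose
#' ordinary-least-squares fit of U on lnA has the highest coefficient of
#' determination. Windows whose r2 lies within `r2_tol` of the maximum are
#' treated as tied; ties go to the longest window, then the earliest start.
#' The search stops at the velocity peak because reflected waves are
#' expected after early systole, where the loop relation no longer holds.
#'
#' @param loop a [build_loop()] result.
#' @param min_len_ms minimum window span \[ms\]; default 20 (prevents
#'   degenerate near-perfect two-point fits).
#' @param search_start,search_end sample indices bounding the search;
#'   default foot and velocity-peak index.
#' @param r2_tol tie tolerance on r2; default 1e-12.
#' @return A list with `start`, `end` (sample indices), `r2`, and `n_windows`
#'   examined.
#' @export
select_linear_window <- function(loop, min_len_ms = 20,
                                 search_start = loop$foot_index,
                                 search_end = loop$peak_u_index,
                                 r2_tol = 1e-12) {
  stopifnot(inherits(loop, "ulna_loop"))
  dt <- mean(diff(loop$t))
  min_pts <- as.integer(round(min_len_ms / dt)) + 1L
  if (min_pts < 3L) min_pts <- 3L
  a <- as.integer(search_start)
  b <- as.integer(search_end)
  if (a < 1L || b > length(loop$U) || b - a + 1L < min_pts)
    stop(sprintf(
      "search span [%d, %d] holds %d samples; need at least %d for a %g ms window",
      a, b, max(0L, b - a + 1L), min_pts, min_len_ms), call. = FALSE)
  x <- loop$lnA[a:b]
  y <- loop$U[a:b]
  m <- length(x)
  # screening pass: r2 for every admissible window from cumulative sums,
  # computed on region-centred data to keep the cancellation error small
  xs <- x - mean(x)
  ys <- y - mean(y)
  c1x <- cumsum(xs);        c1y <- cumsum(ys)
  c2x <- cumsum(xs * xs);   c2y <- cumsum(ys * ys)
  cxy <- cumsum(xs * ys)
  starts <- integer(0); ends <- integer(0); r2s <- numeric(0)
  for (i in seq_len(m - min_pts + 1L)) {
    j <- (i + min_pts - 1L):m
    k <- j - i + 1L
    off <- i - 1L
    sx <- c1x[j] - if (off) c1x[off] else 0
    sy <- c1y[j] - if (off) c1y[off] else 0
    sxx <- c2x[j] - if (off) c2x[off] else 0
    syy <- c2y[j] - if (off) c2y[off] else 0
    sxy <- cxy[j] - if (off) cxy[off] else 0
    vx <- sxx - sx * sx / k
    vy <- syy - sy * sy / k
    cv <- sxy - sx * sy / k
    r2 <- ifelse(vx <= 0 | vy <= 0, -Inf, (cv * cv) / (vx * vy))
    starts <- c(starts, rep.int(i, length(j)))
    ends <- c(ends, j)
    r2s <- c(r2s, r2)
  }
  if (!any(is.finite(r2s)))
    stop("no window with lnA variance found (vertical loop)", call. = FALSE)
  # refine near-maximal candidates with the exact per-window computation so
  # the tie rule operates on clean r2 values
  keep <- which(r2s >= max(r2s) - 1e-6)
  exact <- vapply(keep, function(q) {
    .window_r2(x[starts[q]:ends[q]], y[starts[q]:ends[q]])
  }, numeric(1))
  best <- max(exact)
  tied <- keep[exact >= best - r2_tol]
  len <- ends[tied] - starts[tied]
  tied <- tied[len == max(len)]
  pick <- tied[which.min(starts[tied])]
  list(start = a + starts[pick] - 1L, end = a + ends[pick] - 1L,
       r2 = .window_r2(x[starts[pick]:ends[pick]], y[starts[pick]:ends[pick]]),
       n_windows = length(r2s))
}

#' Estimate wave speed from the U-lnA loop
#'
#' Wave speed is the ordinary-least-squares slope of U on lnA over the
#' selected early-systolic window (the loop-gradient convention of the P-U
#' loop literature). Optionally converts to distensibility through the
#' Bramwell-Hill relation `D = 1 / (rho c^2)` when a blood density is given.
#'
#' @param loop a [build_loop()] result.
#' @param window a [select_linear_window()] result; selected automatically
#'   when omitted.
#' @param rho blood density \[kg/m^3\] for the optional distensibility;
#'   `NULL` to skip.
#' @param ... passed to [select_linear_window()] when `window` is missing.
#' @return An object of class `wave_speed_fit`: `c` \[m/s\], `window`
#'   (indices and times \[ms\]), `r2`, and `distensibility` \[1/Pa\] or `NA`.
#' @export
estimate_wave_speed <- function(loop, window = NULL, rho = NULL, ...) {
  stopifnot(inherits(loop, "ulna_loop"))
  if (is.null(window)) window <- select_linear_window(loop, ...)
  idx <- window$start:window$end
  x <- loop$lnA[idx]
  y <- loop$U[idx]
  xc <- x - mean(x)
  if (sum(xc * xc) <= 0)
    stop("lnA has zero variance in the selected window (vertical loop)",
         call. = FALSE)
  slope <- sum(xc * (y - mean(y))) / sum(xc * xc)
  if (!is.finite(slope) || slope <= 0)
    warning(sprintf("non-physiologic wave speed estimate: %.3g m/s", slope))
  structure(list(
    c = slope,
    window = list(start = window$start, end = window$end,
                  t_start = loop$t[window$start], t_end = loop$t[window$end]),
    r2 = .window_r2(x, y),
    distensibility = if (is.null(rho)) NA_real_ else 1 / (rho * slope^2),
    method = "U-lnA loop gradient, OLS of U on lnA"),
    class = "wave_speed_fit")
}

#' @export
print.wave_speed_fit <- function(x, ...) {
  cat(sprintf("<wave_speed_fit> c = %.3f m/s (r2 = %.4f), window %g-%g ms\n",
              x$c, x$r2, x$window$t_start, x$window$t_end))
  if (is.finite(x$distensibility))
    cat(sprintf("  distensibility = %.3e 1/Pa\n", x$distensibility))
  invisible(x)
}
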