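#' Plot a waveform series
#'
#' Two stacked panels: velocity and area against time, the standard view of
#' a PC-CMR flow/area extraction.
#'
#' @param x a [waveform_series()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.waveform_series <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(x$t, x$U, type = "l", xlab = "time [ms]", ylab = "U [m/s]", ...)
  plot(x$t, x$A, type = "l", xlab = "time [ms]", ylab = "A [mm^2]", ...)
  invisible(x)
}

#' Plot the U-lnA loop with the selected linear portion
#'
#' lnA on the abscissa, U on the ordinate; when a window (or a full
#' [estimate_wave_speed()] fit) is supplied its samples are highlighted in
#' red, the convention for showing where the wave-speed gradient was taken.
#'
#' @param x a [build_loop()] result.
#' @param window optional [select_linear_window()] result or
#'   `wave_speed_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ulna_loop <- function(x, window = NULL, ...) {
  plot(x$lnA, x$U, type = "l", xlab = "ln A", ylab = "U [m/s]", ...)
  if (!is.null(window)) {
    w <- if (inherits(window, "wave_speed_fit")) window$window else window
    idx <- w$start:w$end
    lines(x$lnA[idx], x$U[idx], col = "red", lwd = 2)
  }
  invisible(x)
}

#' Plot separated and net wave intensity
#'
#' Forward, backward and net intensity against time, with detected peaks
#' marked when supplied: the canonical FCW / BCW / FEW pattern view.
#'
#' @param x a [separated_intensity()] result.
#' @param peaks optional [find_wave_peaks()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.wave_intensity_result <- function(x, peaks = NULL, ...) {
  ylim <- range(x$dI_plus, x$dI_minus, x$dI_net)
  plot(x$t_mid, x$dI_net, type = "l", col = "grey40", ylim = ylim,
       xlab = "time [ms]", ylab = "dI [m/s]", ...)
  lines(x$t_mid, x$dI_plus, col = "blue")
  lines(x$t_mid, x$dI_minus, col = "red")
  abline(h = 0, lty = 3)
  if (!is.null(peaks)) {
    for (w in peaks[c("fcw", "bcw", "few")])
      if (!is.na(w$value)) points(w$time, w$value, pch = 19)
  }
  legend("topright", legend = c("net", "forward", "backward"),
         col = c("grey40", "blue", "red"), lty = 1, bty = "n")
  invisible(x)
}
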