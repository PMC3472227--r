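test_that("CSV round trip, sign correction and validation errors", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  set.seed(11)
  df <- data.frame(time_ms = seq(0, 390, by = 10),
                   U_mps = runif(40, -0.1, 1),
                   A_mm2 = runif(40, 480, 560))
  write.csv(df, tmp, row.names = FALSE)

  s <- load_waveforms(tmp)
  expect_s3_class(s, "waveform_series")
  expect_length(s$t, 40)
  expect_equal(s$U, df$U_mps)
  expect_equal(s$A, df$A_mm2)

  flipped <- load_waveforms(tmp, velocity_sign = -1)
  expect_equal(flipped$U, -df$U_mps)
  expect_equal(flipped$A, df$A_mm2)

  # JSON round trip through the writer
  tmpj <- withr::local_tempfile(fileext = ".json")
  write_waveforms(s, tmpj)
  expect_equal(load_waveforms(tmpj)$U, s$U)

  expect_error(load_waveforms(tmp, columns = c(t = "time_ms", U = "vel",
                                               A = "A_mm2")),
               "missing column 'vel'")

  df_bad <- df; df_bad$A_mm2[17] <- 0
  write.csv(df_bad, tmp, row.names = FALSE)
  expect_error(load_waveforms(tmp), "sample 17")

  df_bad <- df; df_bad$time_ms[5] <- df_bad$time_ms[7]
  write.csv(df_bad, tmp, row.names = FALSE)
  expect_error(load_waveforms(tmp), "strictly increasing")
})

test_that("series validation rejects short, mismatched and negative input", {
  t <- seq(0, 70, by = 10)
  expect_error(waveform_series(t[1:5], rep(0, 5), rep(1, 5)), "at least 8")
  expect_error(waveform_series(t, rep(0, 7), rep(1, 8)), "equal length")
  expect_error(waveform_series(t, rep(0, 8), c(rep(1, 4), -2, rep(1, 3))),
               "sample 5")
})

test_that("resampling reproduces linear signals and passes through knots", {
  t <- seq(0, 76.8, by = 9.6)
  s <- waveform_series(t, U = 0.01 * t - 0.2, A = 500 + 0.5 * t)
  for (m in c("linear", "monotone-cubic")) {
    r <- resample_uniform(s, dt = 1, method = m)
    expect_equal(diff(r$t), rep(1, length(r$t) - 1))
    expect_equal(r$U, 0.01 * r$t - 0.2, tolerance = 1e-12)
    expect_equal(r$A, 500 + 0.5 * r$t, tolerance = 1e-12)
  }

  # knots on the target grid are reproduced exactly (interpolation passes
  # through the data)
  t4 <- seq(0, 60, by = 4)
  set.seed(2)
  s4 <- waveform_series(t4, U = cumsum(rnorm(16, 0.02, 0.05)),
                        A = 500 + cumsum(rnorm(16, 0, 2)))
  r4 <- resample_uniform(s4, dt = 1)
  at_knots <- match(t4, r4$t)
  expect_equal(r4$U[at_knots], s4$U)
  expect_equal(r4$A[at_knots], s4$A)

  expect_error(resample_uniform(s, dt = 20), "downsampling")
})

test_that("monotone-cubic resampling does not overshoot between knots", {
  # monotone area samples: the shape-preserving interpolant must stay
  # within the bracketing knot values on every native interval
  t <- seq(0, 96, by = 9.6)
  A <- 500 + cumsum(c(0, 2, 5, 12, 20, 18, 9, 4, 2, 1, 0.5))
  s <- waveform_series(t, U = seq(0, 1, length.out = 11), A = A)
  r <- resample_uniform(s, dt = 0.5, method = "monotone-cubic")
  for (i in seq_len(length(t) - 1)) {
    in_span <- r$t >= t[i] & r$t <= t[i + 1]
    expect_true(all(r$A[in_span] >= min(A[i], A[i + 1]) - 1e-9))
    expect_true(all(r$A[in_span] <= max(A[i], A[i + 1]) + 1e-9))
  }
})

test_that("interpolation method barely affects the wave speed estimate", {
  gen <- generate_waveforms(synthetic_spec(seed = 7, noise_sd_U = 0.005,
                                           noise_sd_A = 0.3))
  c_pchip <- wia_analyze(gen$series,
                         wia_config(interp = "monotone-cubic"))$wave_speed$c
  c_lin <- wia_analyze(gen$series,
                       wia_config(interp = "linear"))$wave_speed$c
  expect_lt(abs(c_pchip - c_lin) / c_pchip, 0.02)
})

test_that("Savitzky-Golay smoothing preserves cubics and matches the
           per-window least-squares oracle", {
  t <- seq(0, 200, by = 1)
  cubic <- 500 + 0.3 * t - 2e-3 * t^2 + 4e-6 * t^3
  s <- waveform_series(t, U = rep(0.5, 201), A = cubic)
  sm <- smooth_area(s)
  expect_equal(sm$A, cubic, tolerance = 1e-10)
  expect_equal(sm$U, s$U) # velocity untouched by default

  s_const <- waveform_series(t, U = rep(0.5, 201), A = rep(512, 201))
  expect_equal(smooth_area(s_const)$A, rep(512, 201))

  # interior sample = value at centre of the degree-3 LS fit over the
  # centred 101-sample window
  set.seed(3)
  noisy <- waveform_series(t, U = rep(0.5, 201),
                           A = 520 + 30 * sin(t / 40) + rnorm(201, 0, 2))
  smn <- smooth_area(noisy)
  i <- 101L
  win <- (i - 50L):(i + 50L)
  fit <- lm(A ~ poly(tt, 3), data = data.frame(A = noisy$A[win],
                                               tt = t[win]))
  expect_equal(smn$A[i],
               unname(predict(fit, data.frame(tt = t[i]))),
               tolerance = 1e-8)

  expect_error(smooth_area(s, window_samples = 100), "odd")
})

test_that("smoothing is linear and shrinks over-long windows with a record", {
  t <- seq(0, 150, by = 1)
  set.seed(4)
  A1 <- 500 + cumsum(rnorm(151)); A2 <- 480 + 20 * sin(t / 15)
  mk <- function(A) waveform_series(t, U = rep(0, 151), A = A)
  lhs <- smooth_area(mk(0.3 * A1 + 0.7 * A2))$A
  rhs <- 0.3 * smooth_area(mk(A1))$A + 0.7 * smooth_area(mk(A2))$A
  expect_equal(lhs, rhs, tolerance = 1e-10)

  short <- waveform_series(seq(0, 49), U = rep(0, 50), A = rep(500, 50))
  sm <- smooth_area(short, window_samples = 101)
  expect_equal(sm$smoothing$window_samples, 49L)
  expect_equal(sm$smoothing$window_requested, 101L)
})

test_that("systolic foot detection follows the 5% upstroke rule", {
  # ramp from baseline 0 starting at sample 21: foot is the last sample
  # below 5% of the peak
  U <- c(rep(0, 20), seq(0, 1, length.out = 81))
  s <- waveform_series(seq_along(U) - 1, U, A = rep(500, length(U)))
  foot <- detect_systolic_foot(s)
  expect_s3_class(foot, "foot_index")
  expect_lt(foot$index, which.max(U))
  expect_true(U[foot$index] <= 0.05 && U[foot$index + 1] > 0.05)

  # baseline-relative: constant offset does not move the foot
  s2 <- s; s2$U <- s2$U + 0.4
  expect_equal(detect_systolic_foot(s2)$index, foot$index)

  flat <- waveform_series(seq_along(U) - 1, rep(0.3, length(U)),
                          rep(500, length(U)))
  expect_error(detect_systolic_foot(flat), "no systolic upstroke")
})

test_that("foot detection is robust to noise across seeded simulations", {
  hits <- 0L
  for (r in 1:100) {
    gen <- generate_waveforms(synthetic_spec(noise_sd_U = 0.005,
                                             seed = 1000 + r))
    s <- resample_uniform(gen$series, dt = 1)
    foot <- detect_systolic_foot(s)
    if (abs(foot$time - gen$truth$foot_time) <= 5) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})
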