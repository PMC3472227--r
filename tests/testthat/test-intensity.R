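test_that("net intensity is the increment product and separated intensity
           adds up", {
  inc <- make_increments(dU = c(0.075, 0, -0.02), dlnA = c(0.015, 0.5, 0.01))
  expect_equal(net_intensity(inc), c(1.125e-3, 0, -2e-4))

  # worked numbers: dU = 0.1, dlnA = 0.01, c = 5
  sep <- separate_waves(make_increments(0.1, 0.01), 5)
  wi <- separated_intensity(sep)
  expect_equal(wi$dI_plus, 0.075 * 0.015)
  expect_equal(wi$dI_minus, 0.025 * (-0.005))
  expect_equal(wi$dI_plus + wi$dI_minus, 0.1 * 0.01)
  expect_equal(wi$dI_net, 0.1 * 0.01)
})

test_that("sign laws and additivity hold for arbitrary increments and wave
           speeds", {
  set.seed(9)
  for (i in 1:50) {
    m <- sample(20:60, 1)
    sep <- separate_waves(make_increments(rnorm(m, 0, 0.05),
                                          rnorm(m, 0, 0.01)),
                          runif(1, 0.5, 15))
    wi <- separated_intensity(sep)
    expect_true(all(wi$dI_plus >= 0))
    expect_true(all(wi$dI_minus <= 0))
    expect_lt(max(abs(wi$dI_net - wi$dI_plus - wi$dI_minus)),
              1e-12 * max(abs(wi$dI_net)))
  }
})

test_that("forward-only signals have non-negative net intensity", {
  gen <- generate_waveforms(synthetic_spec(reflection_coefficient = 0,
                                           native_dt = 1))
  expect_true(all(net_intensity(differentials(gen$series)) >= -1e-15))
})

test_that("time-corrected intensity is dI/dt^2 and is sampling-rate
           invariant where raw dI is not", {
  gen1 <- generate_waveforms(synthetic_spec(native_dt = 1,
                                            reflection_coefficient = 0))
  gen2 <- generate_waveforms(synthetic_spec(native_dt = 2,
                                            reflection_coefficient = 0))
  tc1 <- time_corrected_intensity(gen1$series)
  tc2 <- time_corrected_intensity(gen2$series)
  dI1 <- net_intensity(differentials(gen1$series))
  dI2 <- net_intensity(differentials(gen2$series))
  expect_equal(tc1, dI1 / (1e-3)^2, tolerance = 1e-12)
  expect_equal(tc2, dI2 / (2e-3)^2, tolerance = 1e-12)
  expect_lt(abs(max(tc2) / max(tc1) - 1), 0.05)
  expect_lt(abs(max(dI2) / max(dI1) - 4), 4 * 0.05)

  flat <- waveform_series(0:20, rep(0.3, 21), rep(500, 21))
  expect_equal(time_corrected_intensity(flat), rep(0, 20))
})

test_that("the volunteer template yields the FCW-BCW-FEW sequence with
           programmed timing", {
  spec <- synthetic_spec(seed = 10)
  gen <- generate_waveforms(spec)
  rep <- wia_analyze(gen$series)
  pk <- rep$peaks
  expect_false(is.na(pk$fcw$value))
  expect_false(is.na(pk$bcw$value))
  expect_false(is.na(pk$few$value))
  expect_lt(abs(pk$fcw$time - gen$truth$fcw_center), 5)
  expect_lt(abs(pk$few$time - gen$truth$few_center), 5)
  expect_true(pk$fcw$time < pk$bcw$time && pk$bcw$time < pk$few$time)
  expect_gt(pk$fcw$value, pk$few$value) # programmed amplitude ordering
  expect_lt(pk$bcw$value, 0)
})

test_that("the backward intensity lobe starts at the programmed reflection
           arrival", {
  spec <- synthetic_spec(reflection_coefficient = 0.4,
                         reflection_delay = 60)
  gen <- generate_waveforms(spec)
  sep <- separate_waves(differentials(gen$series), spec$c_true)
  wi <- separated_intensity(sep)
  lobe <- which(wi$dI_minus < 0.01 * min(wi$dI_minus))
  onset <- wi$t_mid[lobe[1]]
  expect_lt(abs(onset - gen$truth$bcw_onset), spec$native_dt + 0.5)
})

test_that("no reflection means no backward compression wave", {
  gen <- generate_waveforms(synthetic_spec(reflection_coefficient = 0))
  rep <- wia_analyze(gen$series)
  expect_true(is.na(rep$peaks$bcw$value))
  expect_match(rep$peaks$bcw$reason, "noise floor|no negative")
})

test_that("peak intensities scale quadratically with waveform amplitude", {
  gen <- generate_waveforms(synthetic_spec(reflection_coefficient = 0.3,
                                           native_dt = 1))
  inc <- differentials(gen$series)
  k <- 1.7
  scaled <- make_increments(k * inc$dU, k * inc$dlnA, dt_ms = inc$dt_ms,
                            U0 = inc$U0, lnA0 = inc$lnA0)
  cc <- gen$truth$spec$c_true
  wi1 <- separated_intensity(separate_waves(inc, cc))
  wi2 <- separated_intensity(separate_waves(scaled, cc))
  expect_equal(max(wi2$dI_plus), k^2 * max(wi1$dI_plus), tolerance = 1e-10)
  expect_equal(min(wi2$dI_minus), k^2 * min(wi1$dI_minus), tolerance = 1e-10)
})

test_that("peak search demands a forward compression lobe", {
  # a purely backward wave train: dU+ vanishes identically
  dlnA <- rep(c(0.002, -0.002), 30)
  sep <- separate_waves(make_increments(dU = -6 * dlnA, dlnA = dlnA), 6)
  wi <- separated_intensity(sep)
  foot <- structure(list(index = 1L, time = 0, method = "fixed"),
                    class = "foot_index")
  expect_error(find_wave_peaks(wi, sep, foot), "no forward compression")
})
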