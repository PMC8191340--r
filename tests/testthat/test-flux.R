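# flux_analysis: calibration, buffer capacities, rates, flux recovery.

test_that("ratio traces calibrate linearly to pH", {
  cal <- data.frame(ratio = c(2, 3), ph = c(7.0, 7.5))
  tr <- ph_trace(time = 0:4, value = c(2, 2.5, 3, 2.5, 2),
                 value_kind = "ratio", calibration = cal)
  ph <- calibrate_ph(tr)
  expect_equal(attr(ph, "value_kind"), "pH")
  expect_equal(ph$value, c(7.0, 7.25, 7.5, 7.25, 7.0))

  # already in pH units: identity
  tr_ph <- ph_trace(0:2, c(7, 7.1, 7.2), "pH")
  expect_identical(calibrate_ph(tr_ph), tr_ph)

  # one-point calibration with a known slope inverts the construction
  slope <- 0.5
  true_ph <- c(7.1, 7.3, 7.2)
  ratio <- 2 + (true_ph - 7.0) / slope
  tr1 <- ph_trace(0:2, ratio, "ratio",
                  calibration = data.frame(ratio = 2, ph = 7.0))
  expect_equal(calibrate_ph(tr1, slope = slope)$value, true_ph)

  dup <- data.frame(ratio = c(2, 2), ph = c(7, 7.5))
  tr_dup <- ph_trace(0:2, c(2, 2, 2), "ratio", calibration = dup)
  expect_error(calibrate_ph(tr_dup), "degenerate")
  expect_error(ph_trace(0:2, c(2, 2, 2), "ratio"), "calibration")
  expect_error(ph_trace(c(0, 0, 1), c(7, 7, 7), "pH"), "increasing")
})

test_that("buffer capacities follow their defining formulas", {
  expect_equal(beta_intrinsic(10, 0.5), 20)
  expect_equal(beta_intrinsic(0, 0.4), 0)
  expect_error(beta_intrinsic(10, 0), "nonzero")

  expect_equal(beta_bicarbonate(10), 23)
  expect_equal(beta_bicarbonate(0), 0)
  expect_error(beta_bicarbonate(-1), ">= 0")

  # at pH_i = pH_bath, [HCO3-]_in equals the bath value: the 24 mM
  # bicarbonate bath gives beta_HCO3 = 55.2 mM/pH
  expect_equal(hco3_in(7.4, 24, 7.4), 24)
  expect_equal(beta_bicarbonate(hco3_in(7.4, 24, 7.4)), 55.2)
  expect_equal(hco3_in(7.1, 24, 7.4), 24 * 10^(-0.3))
  expect_equal(hco3_in(7.4, 0, 7.4), 0)
})

test_that("beta_intrinsic recovers the generator's value from a pulse", {
  # synthetic ammonium pulse built with beta_i = 30 mM/pH: adding
  # dNH4 = 6 mM alkalinizes by dNH4 / beta_i
  beta_true <- 30
  d_nh4 <- 6
  ph0 <- 7.0
  ph1 <- ph0 + d_nh4 / beta_true
  expect_equal(beta_intrinsic(d_nh4, ph1 - ph0), beta_true,
               tolerance = 0.01)
})

test_that("initial_rate is the OLS slope over the window", {
  t <- seq(0, 60, by = 0.5)
  tr <- ph_trace(t, 7 + 0.02 * t, "pH")
  r <- initial_rate(tr, switch_time = 0, window = 12.5)
  expect_equal(r$slope, 0.02, tolerance = 1e-12)

  flat <- ph_trace(t, rep(7.1, length(t)), "pH")
  expect_equal(initial_rate(flat, 0)$slope, 0)

  set.seed(50)
  tn <- seq(0, 14.5, by = 0.5)  # 30 samples
  noisy <- ph_trace(tn, 7 + 0.01 * tn + rnorm(30, sd = 0.005), "pH")
  rn <- initial_rate(noisy, 0, window = 14.5)
  expect_lt(abs(rn$slope - 0.01), 3 * rn$se)

  expect_error(initial_rate(tr, switch_time = 59.9, window = 0.6),
               ">= 3 samples")
})

test_that("proton_flux multiplies total buffering by the rate", {
  expect_equal(proton_flux(20, 30, 0.01), 0.5)
  expect_equal(proton_flux(20, 30, 0), 0)
  # literal [H+]-derivative variant: sign flips (H+ falls as pH rises)
  lit <- proton_flux(20, 30, 0.01, deriv = "H", ph = 7.0)
  expect_lt(lit, 0)
  expect_equal(lit, -50 * log(10) * 10^(3 - 7) * 0.01)
})

test_that("the full flux pipeline inverts the trace generator", {
  baths <- data.frame(t_start = c(0, 30), hco3_bath_mM = c(24, 24),
                      ph_bath = c(7.4, 7.4))
  tr <- simulate_ph_trace(0.05, beta_i = 20, baths = baths,
                          duration_s = 120, sampling_rate_hz = 2,
                          ph0 = 7.0, noise_sd = 0, seed = 51)
  # flux 0 -> flat trace (noise only)
  tr0 <- simulate_ph_trace(0, beta_i = 20, baths = baths,
                           duration_s = 60, noise_sd = 0, seed = 52)
  expect_true(all(tr0$value == tr0$value[1]))

  res <- estimate_flux(tr, beta_i = 20)
  expect_lt(abs(res$flux_mM_s - 0.05) / 0.05, 0.01)

  # identical seeds give identical traces
  tr_b <- simulate_ph_trace(0.05, beta_i = 20, baths = baths,
                            duration_s = 120, sampling_rate_hz = 2,
                            ph0 = 7.0, noise_sd = 0.005, seed = 53)
  tr_c <- simulate_ph_trace(0.05, beta_i = 20, baths = baths,
                            duration_s = 120, sampling_rate_hz = 2,
                            ph0 = 7.0, noise_sd = 0.005, seed = 53)
  expect_identical(tr_b$value, tr_c$value)

  # noisy recovery within 3 standard errors (30-sample window)
  resn <- estimate_flux(tr_b, beta_i = 20, window = 14.5)
  expect_lt(abs(resn$flux_mM_s - 0.05), 3 * resn$flux_se)
})

test_that("pH traces roundtrip through CSV + JSON sidecar", {
  baths <- data.frame(t_start = c(0, 30), hco3_bath_mM = c(0, 24),
                      ph_bath = c(7.4, 7.4))
  tr <- simulate_ph_trace(0.03, beta_i = 25, baths = baths,
                          duration_s = 60, noise_sd = 0.002, seed = 54)
  p <- withr::local_tempfile(fileext = ".csv")
  write_ph_trace(tr, p)
  back <- read_ph_trace(p)
  expect_equal(back$time, tr$time)
  expect_equal(back$value, tr$value)
  expect_equal(attr(back, "value_kind"), "pH")
  expect_equal(attr(back, "baths")$hco3_bath_mM, c(0, 24))
  expect_equal(attr(back, "events")$time, 30)
})
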