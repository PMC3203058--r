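test_that("volume fraction to molar conversion is the exact closed form", {
  # c / (N_A * d0^3 in litres): 0.01 at d0 = 10 nm -> ~1.66e-5 M
  expect_equal(volume_fraction_to_molar(0.01, 10),
               0.01 / (6.02214076e23 * 1e-21), tolerance = 1e-12)
  expect_equal(volume_fraction_to_molar(0, 10), 0)
  expect_error(volume_fraction_to_molar(0.01, -1), "positive")
  # round trip to 1e-12 relative
  for (cc in c(1e-4, 0.01, 0.3)) {
    expect_equal(molar_to_volume_fraction(volume_fraction_to_molar(cc, 30), 30),
                 cc, tolerance = 1e-12)
  }
  # dimensional scaling: d0 -> k d0 scales molarity by k^-3
  k <- 2.5
  expect_equal(volume_fraction_to_molar(0.02, 10 * k),
               volume_fraction_to_molar(0.02, 10) / k^3, tolerance = 1e-12)
})

test_that("time calibration is linear and scales as d0 squared", {
  cal <- physical_calibration(d0 = 30, D_real = 1e-3, D_mc = 1 / 6)
  expect_equal(cal$seconds_per_sweep, (30e-3)^2 * (1 / 6) / 1e-3)
  expect_equal(sweeps_to_seconds(0, cal), 0)
  a <- sweeps_to_seconds(1200, cal)
  b <- sweeps_to_seconds(800, cal)
  expect_equal(sweeps_to_seconds(2000, cal), a + b)     # additivity
  k <- 3
  cal_k <- physical_calibration(30 * k, 1e-3, 1 / 6)
  expect_equal(cal_k$seconds_per_sweep, cal$seconds_per_sweep * k^2)
  expect_error(physical_calibration(30, -1, 1 / 6), "positive")
})

test_that("diffusion fitting flags non-diffusive series", {
  sw <- seq(100, 10000, by = 100)
  lin <- fit_diffusion(sw, 6 * 0.25 * sw)
  expect_equal(lin$D, 0.25, tolerance = 1e-9)
  expect_true(lin$diffusive)
  frozen <- fit_diffusion(sw, rep(2.0, length(sw)))
  expect_false(frozen$diffusive)
  sub <- fit_diffusion(sw, sw^0.3)
  expect_false(sub$diffusive)
})

test_that("free molecules diffuse at the random-walk constant 1/6", {
  st <- free_molecule_state(300, 24)
  p <- model_params(n = 1, L = 24, c = 300 / 24^3, E_X = 0)
  d <- measure_model_diffusion(p, "molecules", sweeps = 4000,
                               record_every = 50, state = st, seed = 55)
  expect_true(d$diffusive)
  expect_equal(d$D, 1 / 6, tolerance = 0.15)
  # doubling the sweep count does not move the estimate beyond its error
  d2 <- measure_model_diffusion(p, "molecules", sweeps = 8000,
                                record_every = 100, state = st, seed = 56)
  expect_equal(d2$D, d$D, tolerance = 0.2)
})
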