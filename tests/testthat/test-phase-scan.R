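test_that("threshold interpolation brackets the first crossing", {
  d <- tibble::tibble(c = 1:4, P_mean = c(0, 0, 1, 1))
  th <- estimate_threshold(d, "c")
  expect_equal(th$threshold, 2.5)
  expect_equal(th$bracket_lo, 2)
  expect_equal(th$bracket_hi, 3)
  expect_true(th$crossed)

  # all below the level: an explicit no-crossing result, not an error
  th2 <- estimate_threshold(tibble::tibble(c = 1:4, P_mean = rep(0.1, 4)), "c")
  expect_false(th2$crossed)
  expect_true(is.na(th2$threshold))

  # logistic curve sampled at 8 points recovers the midpoint inside the bracket
  x <- seq(1, 5, length.out = 8)
  y <- 1 / (1 + exp(-(x - 3) / 0.3))
  th3 <- estimate_threshold(tibble::tibble(c = x, P_mean = y), "c")
  expect_true(th3$crossed)
  expect_gte(th3$threshold, th3$bracket_lo)
  expect_lte(th3$threshold, th3$bracket_hi)
  expect_equal(th3$threshold, 3, tolerance = 0.05)
})

test_that("a one-point grid aggregates replicate means with their SE", {
  p <- model_params(n = 1, L = 8, c = 0.02, E_X = 2, sweeps = 200,
                    record_every = 20)
  scan <- phase_scan(p, vary = list(c = 0.02), replicates = 3, seed = 123)
  expect_equal(nrow(scan), 1)
  reps <- tidy(scan)
  expect_equal(nrow(reps), 3)
  expect_equal(scan$P_mean, mean(reps$P))
  expect_equal(scan$P_se, sd(reps$P) / sqrt(3))
})

test_that("scans are deterministic and order-independent given the base seed", {
  p <- model_params(n = 1, L = 8, c = 0.02, E_X = 2, sweeps = 150,
                    record_every = 30)
  s1 <- phase_scan(p, vary = list(c = c(0.01, 0.03)), replicates = 2, seed = 5)
  s2 <- phase_scan(p, vary = list(c = c(0.01, 0.03)), replicates = 2, seed = 5)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  # per-point seeds differ across points and replicates and stay below 2^31
  seeds <- expand.grid(point = 1:50, rep = 1:5)
  vals <- mapply(xicsim:::point_seed, 5, seeds$point, seeds$rep)
  expect_false(any(duplicated(vals)))
  expect_true(all(vals >= 0 & vals < 2^31))
})

test_that("without binding the order parameter stays near its entropic floor", {
  p <- model_params(n = 4, L = 16, c = 0.005, E_X = 0, sweeps = 10000,
                    record_every = 200)
  scan <- phase_scan(p, vary = list(c = c(0.002, 0.01)), replicates = 2,
                     seed = 77)
  expect_true(all(scan$P_mean < 0.15))
})

test_that("unknown scan axes are rejected", {
  p <- model_params(n = 1, L = 8, c = 0.02)
  expect_error(phase_scan(p, vary = list(banana = 1:2)), "axes must be")
})
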