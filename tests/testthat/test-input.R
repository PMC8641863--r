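test_that("input calibration has the exact closed form", {
  inp <- calibrate_input(1.83, mean = 6)
  expect_equal(c(inp$a, inp$b, inp$d), c(6, 0.83, 1.83))
  expect_equal(inp$d / (inp$d - inp$b), 1.83)
  expect_equal(inp$a / (inp$d - inp$b), 6)
  # stationary %CV = 100*sqrt(fano/mean)
  expect_equal(100 * sqrt(1.83 / 6), 55.22681, tolerance = 1e-6)
  expect_error(calibrate_input(1), "super-Poissonian")
  expect_error(calibrate_input(0.5), "super-Poissonian")
})

test_that("the Fano factor is identical at every plateau mean", {
  fanos <- vapply(c(2, 3, 4, 5, 6), function(m) {
    inp <- calibrate_input(1.83, m)
    inp$d / (inp$d - inp$b)
  }, numeric(1))
  expect_equal(fanos, rep(1.83, 5))
  # while %CV decreases with the mean
  cvs <- 100 * sqrt(1.83 / c(2, 3, 4, 5, 6))
  expect_true(all(diff(cvs) < 0))
})

test_that("staircase builds the mirrored plateau sequence", {
  pr <- staircase()
  expect_equal(pr$segments$level, c(1, 2, 3, 4, 5, 6, 5, 4, 3, 2, 1))
  expect_equal(pr$segments$phase,
               c("base", rep("up", 5), rep("down", 5)))
  expect_equal(diff(pr$segments$t0), rep(20, 10))
  expect_error(staircase(levels = 6), "five")
  expect_error(staircase(levels = c(2, 3, 3, 4, 5)), "increasing")
  expect_error(staircase(duration = -1), "positive")
})

test_that("noise-scale family changes Fano but not the mean", {
  ms <- lapply(c("reduced", "default", "increased"), set_input_noise,
               mean = 6)
  expect_equal(vapply(ms, `[[`, numeric(1), "fano"), c(1.2, 1.83, 3.0))
  expect_equal(vapply(ms, function(m) m$a / (m$d - m$b), numeric(1)),
               rep(6, 3))
})
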