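test_that("cv_percent and fano_factor match closed forms", {
  expect_equal(cv_percent(4, 1), 25)
  expect_equal(cv_percent(6, 6), 100 / sqrt(6))     # Poisson
  expect_equal(cv_percent(6, 1.83 * 6), 55.22681, tolerance = 1e-6)
  expect_equal(fano_factor(10, 10), 1)
  expect_equal(fano_factor(6, 1.83 * 6), 1.83)
  # conserved binomial node: Fano = 1 - p
  expect_equal(fano_factor(10, 60 * (1 / 6) * (5 / 6)), 5 / 6)
  expect_error(cv_percent(0, 1), "positive")
  expect_error(fano_factor(-1, 1), "positive")
})

test_that("io_slope recovers linear, flat and inverted responses", {
  expect_equal(io_slope(2:6, 5 * (2:6)), 5)
  expect_equal(io_slope(2:6, rep(7, 5)), 0)
  expect_lt(io_slope(2:6, 30 - 2 * (2:6)), 0)
  expect_error(io_slope(2:6, 1:4))
  expect_error(io_slope(rep(3, 5), 1:5), "degenerate")
})

test_that("saturation guard flags pinned species and rejects empty input", {
  stats <- data.frame(level = 6, species = c("X_a", "Z_a"),
                      mean = c(30, 59.5), var = c(1, 1))
  chk <- saturation_check(stats, total = 60)
  expect_false(chk$pass)
  expect_identical(chk$violations$species, "Z_a")
  ok <- saturation_check(data.frame(level = 6, species = "X_a",
                                    mean = 30, var = 1), total = 60)
  expect_true(ok$pass)
  expect_error(saturation_check(NULL), "empty")
})

test_that("rank_models sorts by noise and reports the correlation", {
  df <- data.frame(model_id = c("a", "b", "c"),
                   cv6 = c(20, 5, 10), slope = c(0.1, 1.0, 0.6))
  rk <- rank_models(df)
  expect_identical(rk$best_cv, "b")
  expect_identical(rk$best_slope, "b")
  expect_identical(rk$table$model_id, c("b", "c", "a"))
  expect_lt(rk$correlation, 0)
})
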