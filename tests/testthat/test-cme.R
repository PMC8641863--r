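test_that("CME recovers the binomial stationary law of a two-state node", {
  crn <- input_node_crn(1.83, 2, total = 3)
  sol <- cme_stationary_small(crn, s_cap = 30, input_mean = 2)
  # unregulated node: binomial(3, 1/6)
  expect_equal(sol$mean[["X_a"]], 0.5, tolerance = 1e-6)
  expect_equal(sol$cov["X_a", "X_a"], 3 * (1 / 6) * (5 / 6),
               tolerance = 1e-6)
  # capped input matches the closed form
  expect_equal(sol$mean[["S"]], 2, tolerance = 1e-6)
  expect_equal(sol$cov["S", "S"] / sol$mean[["S"]], 1.83, tolerance = 1e-5)
  expect_lt(sol$boundary_mass, 1e-8)
})

test_that("cap too small is rejected by the boundary-mass diagnostic", {
  crn <- input_node_crn(1.83, 2, total = 3)
  sol <- cme_stationary_small(crn, s_cap = 4, input_mean = 2)
  expect_gt(sol$boundary_mass, 1e-8)
})

test_that("CME, SSA and LNA agree on a shrunken c1-OR", {
  params <- ffl_params(total = 3)
  crn <- build_model(catalog_entry("c1-OR"), params = params)
  cme <- cme_stationary_small(crn, s_cap = 30, input_mean = 2)
  expect_lt(cme$boundary_mass, 1e-8)

  ens <- ssa_ensemble(crn, constant_protocol(2, 40), n = 400, base_seed = 21)
  for (sp in c("S", "X_a", "Y_a", "Z_a")) {
    e <- ens$stats[ens$stats$species == sp, ]
    expect_lt(abs(e$mean - cme$mean[[sp]]), 3 * e$se_mean,
              label = paste("mean of", sp))
    expect_lt(abs(e$var - cme$cov[sp, sp]), 3 * e$se_var,
              label = paste("variance of", sp))
  }

  # LNA is approximate at molecule counts of a few: documented 15% band
  lna <- lna_stationary(crn, 2)
  for (sp in c("S", "X_a", "Y_a", "Z_a"))
    expect_lt(abs(lna$mean[[sp]] - cme$mean[[sp]]) / cme$mean[[sp]], 0.15)
})
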