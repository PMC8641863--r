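test_that("SSA is deterministic given a seed and conserves totals exactly", {
  crn <- c1_or()
  pr <- constant_protocol(4, 20)
  t1 <- ssa_simulate(crn, pr, seed = 11)
  t2 <- ssa_simulate(crn, pr, seed = 11)
  expect_identical(t1$state, t2$state)
  t3 <- ssa_simulate(crn, pr, seed = 12)
  expect_false(identical(t1$state, t3$state))
  expect_true(all(t1$state == round(t1$state)), info = "integer states")
  expect_true(all(t1$state >= 0))
  for (cl in conservation_laws(crn))
    expect_true(all(rowSums(t1$state[, cl$species]) == cl$total))
})

test_that("SSA reproduces closed-form moments of linear systems", {
  crn <- input_node_crn(1.83, 6)
  ens <- ssa_ensemble(crn, constant_protocol(6, 60), n = 300, base_seed = 42)
  s <- ens$stats[ens$stats$species == "S", ]
  # super-Poissonian input: mean 6, Fano 1.83, within 3 SE
  expect_lt(abs(s$mean - 6), 3 * s$se_mean)
  expect_lt(abs(s$var - 10.98), 3 * s$se_var)
  # unregulated node: binomial(60, 1/6)
  xa <- ens$stats[ens$stats$species == "X_a", ]
  expect_lt(abs(xa$mean - 10), 3 * xa$se_mean)
  expect_lt(abs(xa$var - 60 * (1 / 6) * (5 / 6)), 3 * xa$se_var)
})

test_that("near-Poissonian input recovers Fano 1 within Monte-Carlo error", {
  crn <- input_node_crn(1 + 1e-6, 6)
  ens <- ssa_ensemble(crn, constant_protocol(6, 60), n = 300, base_seed = 5)
  s <- ens$stats[ens$stats$species == "S", ]
  expect_lt(abs(s$var / s$mean - 1), 3 * s$se_var / s$mean)
})

test_that("LNA and SSA agree on the output noise of c1-OR", {
  crn <- c1_or()
  st <- lna_stationary(crn, 6)
  ens <- ssa_ensemble(crn, constant_protocol(6, 40), n = 300, base_seed = 9)
  z <- ens$stats[ens$stats$species == "Z_a", ]
  expect_lt(abs(z$mean - st$mean[["Z_a"]]), 3 * z$se_mean + 0.5)
  cv_lna <- cv_percent(st$mean[["Z_a"]], st$cov["Z_a", "Z_a"])
  cv_ssa <- cv_percent(z$mean, z$var)
  se_cv <- cv_ssa * 0.5 * z$se_var / z$var  # delta method
  expect_lt(abs(cv_lna - cv_ssa), 3 * se_cv + 0.5)
})
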