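test_that("drift, Jacobian and diffusion of the input submodel are exact", {
  crn <- input_node_crn(1.83, 6)
  x <- stats::setNames(numeric(3), crn$species$name)
  x["S"] <- 6; x["X_i"] <- 50; x["X_a"] <- 10
  f <- drift(crn, x)
  # a + bS - dS = 6 + 0.83*6 - 1.83*6 = 0 at the fixed point
  expect_equal(unname(f[1]), 0)
  # diffusion of the S coordinate: a + (b + d) S
  D <- diffusion(crn, x)
  expect_equal(D["S", "S"], 6 + (0.83 + 1.83) * 6)
  # Jacobian of the linear input: b - d = -1
  J <- lna_jacobian(crn, x)
  expect_equal(unname(J[1, 1]), -1)
})

test_that("analytic Jacobian matches finite differences on a full model", {
  crn <- build_model(catalog_entry("c1i4-mint-OR"),
                     params = ffl_params(and_factor = 0.5))
  st <- lna_stationary(crn, 3)
  x <- st$mean
  J <- lna_jacobian(crn, x)
  h <- 1e-6
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    expect_equal(J[, i], (drift(crn, xp) - drift(crn, xm)) / (2 * h),
                 tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("LNA is exact on the linear input and binomial node", {
  crn <- input_node_crn(1.83, 6)
  st <- lna_stationary(crn, 6)
  expect_equal(st$mean[["S"]], 6, tolerance = 1e-8)
  expect_equal(st$cov["S", "S"], 10.98, tolerance = 1e-6)
  expect_equal(st$cov["S", "S"] / st$mean[["S"]], 1.83, tolerance = 1e-6)
  # unregulated two-state node: binomial(60, 1/6)
  expect_equal(st$mean[["X_a"]], 10, tolerance = 1e-8)
  expect_equal(st$cov["X_a", "X_a"], 60 * (1 / 6) * (5 / 6),
               tolerance = 1e-6)
  # Poissonian limit: fano -> 1 gives variance = mean
  crn2 <- input_node_crn(1 + 1e-9, 6)
  st2 <- lna_stationary(crn2, 6)
  expect_equal(st2$cov["S", "S"] / st2$mean[["S"]], 1, tolerance = 1e-6)
})

test_that("stationary covariance is symmetric PSD with pinned conservation", {
  for (id in c("c1-OR", "c4c4-minp-OR", "c3i2-mint-OR")) {
    crn <- build_model(catalog_entry(id))
    st <- lna_stationary(crn, 6)
    expect_equal(st$cov, t(st$cov))
    ev <- eigen(st$cov, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
    for (cl in conservation_laws(crn)) {
      v <- as.numeric(crn$species$name %in% cl$species)
      expect_lt(abs(drop(v %*% st$cov %*% v)), 1e-9)
      expect_equal(sum(st$mean[cl$species]), cl$total, tolerance = 1e-7)
    }
    expect_true(st$stable)
  }
})

test_that("staircase integration reaches the stationary state on each plateau", {
  crn <- c1_or()
  res <- lna_integrate(crn, staircase())
  stats <- lna_plateau_stats(res)
  for (lv in c(2, 6)) {
    st <- lna_stationary(crn, lv)
    up <- stats[stats$level == lv & stats$phase == "up" &
                  stats$species == "Z_a", ]
    expect_equal(up$mean, st$mean[["Z_a"]], tolerance = 1e-3)
    expect_equal(up$var, st$cov["Z_a", "Z_a"], tolerance = 1e-2)
  }
  # up vs down phase at the same mean agree (no major delays)
  for (lv in c(2, 3, 4, 5)) {
    zu <- stats[stats$level == lv & stats$phase == "up" &
                  stats$species == "Z_a", ]
    zd <- stats[stats$level == lv & stats$phase == "down" &
                  stats$species == "Z_a", ]
    expect_equal(zu$mean, zd$mean, tolerance = 0.01)
  }
  # conserved sum has zero variance along the whole trajectory
  xsum_var <- vapply(res$plateaus, function(p)
    abs(sum(p$cov[c("X_i", "X_a"), c("X_i", "X_a")])), numeric(1))
  expect_true(all(xsum_var < 1e-8))
})
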