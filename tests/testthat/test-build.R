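test_that("one-step isolated model has the expected species and laws", {
  crn <- c1_or()
  expect_setequal(crn$species$name,
                  c("S", "X_i", "X_a", "Y_i", "Y_a", "Z_i", "Z_a"))
  laws <- conservation_laws(crn)
  expect_length(laws, 3L)
  expect_true(all(vapply(laws, `[[`, numeric(1), "total") == 60))
  # S belongs to no conservation law
  expect_false(any(vapply(laws, function(l) "S" %in% l$species, logical(1))))
})

test_that("conservation indicators annihilate the stoichiometry matrix", {
  ids <- c("c1-OR", "c3-AND", "chain-2", "c1c1-minp-OR", "c4i1-minp-OR",
           "i4i4-minp-uOR-lAND", "c1i4-mint-OR", "c3i2-mint-AND")
  for (id in ids) for (scheme in c("one-step", "two-step")) {
    crn <- build_model(catalog_entry(id), scheme,
                       params = ffl_params(and_factor = 0.5))
    N <- stoichiometry(crn)
    for (cl in conservation_laws(crn)) {
      v <- as.numeric(crn$species$name %in% cl$species)
      expect_identical(max(abs(drop(v %*% N))), 0)
    }
  }
})

test_that("two-step models add intermediates and keep totals", {
  crn <- build_model(catalog_entry("c1-OR"), "two-step")
  expect_true(all(c("X_m", "Y_m", "Z_m") %in% crn$species$name))
  laws <- conservation_laws(crn)
  expect_true(all(vapply(laws, function(l) length(l$species), integer(1)) == 3L))
  expect_true(all(vapply(laws, `[[`, numeric(1), "total") == 60))
  # minp model has four protein nodes hence four laws
  crn2 <- build_model(catalog_entry("c1c1-minp-OR"))
  expect_length(conservation_laws(crn2), 4L)
})

test_that("mass-action propensities follow the normalisation rules", {
  crn <- build_model(catalog_entry("c1-OR"), params = ffl_params(s_ref = 6))
  x <- stats::setNames(numeric(7), crn$species$name)
  x["S"] <- 6; x["X_i"] <- 50
  v <- propensities(crn, x)
  # S-driven activation: (kp / s_ref) * S * X_i = (10/6)*6*50
  expect_equal(unname(v["X:act<-S"]), 500)
  # at the default normalisation the same propensity is (10/18)*6*50
  vd <- propensities(c1_or(), x)
  expect_equal(unname(vd["X:act<-S"]), 10 / 18 * 6 * 50)
  x2 <- x; x2["X_a"] <- 12
  expect_equal(unname(propensities(crn, x2)["X:inact:basal"]), 60)  # ka * X_a
  expect_error(propensities(crn, x - 100), "negative")
  # stoichiometry column of a conversion
  col <- stoichiometry(crn)[, "X:act:basal"]
  expect_equal(unname(col[c("X_i", "X_a")]), c(-1, 1))
  expect_true(all(col[setdiff(names(col), c("X_i", "X_a"))] == 0))
})

test_that("AND gates multiply normalised activities with attenuation", {
  crn <- build_model(catalog_entry("c1-AND"),
                     params = ffl_params(and_factor = 0.5, p_ref = 60))
  x <- stats::setNames(numeric(7), crn$species$name)
  x["Y_a"] <- 30; x["X_a"] <- 20; x["Z_i"] <- 40
  v <- propensities(crn, x)
  and_rx <- grep("AND", names(v), value = TRUE)
  expect_length(and_rx, 1L)
  expect_equal(unname(v[and_rx]),
               0.5 * 10 * (30 / 60) * (20 / 60) * 40)
})

test_that("AND calibration matches the OR twin's mean output at input 1", {
  for (id in c("c1-AND", "i2-AND")) {
    entry <- catalog_entry(id)
    crn <- build_model(entry, params = ffl_params(and_factor = NULL))
    or_id <- sub("-AND$", "-OR", id)
    or_crn <- build_model(catalog_entry(or_id))
    zAND <- lna_stationary(crn, 1)$mean[["Z_a"]]
    zOR <- lna_stationary(or_crn, 1)$mean[["Z_a"]]
    expect_lt(abs(zAND - zOR) / zOR, 0.05)
    expect_gt(crn$and_factor, 0)
  }
})

test_that("model compilation is deterministic", {
  crn1 <- build_model(catalog_entry("c1c1-minp-uAND-lOR"),
                      params = ffl_params(and_factor = 0.5))
  crn2 <- build_model(catalog_entry("c1c1-minp-uAND-lOR"),
                      params = ffl_params(and_factor = 0.5))
  expect_identical(export_model(crn1, "json"), export_model(crn2, "json"))
})
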