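test_that("JSON export round-trips to an identical model", {
  crn <- build_model(catalog_entry("c1c1-minp-uAND-lOR"), "two-step",
                     params = ffl_params(and_factor = 0.5))
  doc <- export_model(crn, "json")
  crn2 <- import_model(doc)
  expect_identical(export_model(crn2, "json"), doc)
  expect_identical(crn2$N, crn$N)
  expect_identical(crn2$rates, crn$rates)
  expect_identical(crn2$model_id, crn$model_id)
})

test_that("SBML export is well-formed with the full species complement", {
  crn <- c1_or()
  doc <- export_model(crn, "sbml")
  x <- xml2::read_xml(doc)   # errors if not well-formed
  ns <- xml2::xml_ns(x)
  sp <- xml2::xml_find_all(x, ".//d1:species", ns)
  expect_length(sp, 7L)
  rx <- xml2::xml_find_all(x, ".//d1:reaction", ns)
  expect_length(rx, length(crn$reactions))
  # every reaction carries a kinetic law
  kl <- xml2::xml_find_all(x, ".//d1:kineticLaw", ns)
  expect_length(kl, length(crn$reactions))
})

test_that("unknown export format is rejected", {
  expect_error(export_model(c1_or(), "xlsx"))
})
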