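test_that("FFL classification is a bijection with correct coherence", {
  tab <- ffl_sign_table()
  seen <- character(0)
  for (sxy in c(1, -1)) for (syz in c(1, -1)) for (sxz in c(1, -1)) {
    cl <- classify_ffl(sxy, syz, sxz)
    expect_identical(cl$coherent, sxy * syz == sxz)
    seen <- c(seen, cl$type)
  }
  expect_setequal(seen, tab$type)
  expect_length(unique(seen), 8L)
  # anchored types
  expect_identical(classify_ffl("+", "+", "+")$type, "c1")
  expect_identical(classify_ffl("-", "-", "+")$type, "c4")
  expect_identical(classify_ffl("-", "+", "+")$type, "i4")
})

test_that("gate admissibility follows the equal-signs rule", {
  expect_setequal(gate_options(c("+", "+")), c("AND", "OR"))
  expect_identical(gate_options(c("+", "-")), "OR")
  expect_setequal(gate_options(c("+", "+", "+")), c("AND", "OR"))
  expect_identical(gate_options(c("+", "+", "-")), "OR")
  expect_error(gate_options("+"), "at least two")
})

test_that("catalog families have the published sizes", {
  expect_length(enumerate_isolated(), 12L)
  expect_length(enumerate_chains(), 4L)
  expect_length(enumerate_mint(), 26L)
  expect_length(enumerate_minp("none"), 42L)
  expect_length(enumerate_minp("s2fig"), 33L)
  # coupled models under the reconstructed exclusion rule
  expect_identical(length(enumerate_minp("s2fig")) + length(enumerate_mint()),
                   59L)
  expect_error(enumerate_minp("bogus"))
})

test_that("isolated gate variants follow Z-input signs", {
  ids <- vapply(enumerate_isolated(), `[[`, character(1), "model_id")
  expect_setequal(ids, c("c1-AND", "c1-OR", "c2-OR", "c3-AND", "c3-OR",
                         "c4-OR", "i1-OR", "i2-AND", "i2-OR", "i3-OR",
                         "i4-AND", "i4-OR"))
})

test_that("model ids are unique and match the field's naming", {
  cat_all <- enumerate_catalog(drop_rule = "none")
  ids <- names(cat_all)
  expect_identical(anyDuplicated(ids), 0L)
  expect_true(all(c("c1-OR", "chain-1", "c1c1-minp-OR", "c4c4-minp-OR",
                    "c4i1-minp-OR", "c1i4-mint-OR", "c1i4-minp-OR",
                    "c3i2-mint-OR") %in% ids))
  # branch order is canonical: no swapped duplicates
  expect_false(any(c("i4c1-mint-OR", "i1c4-minp-OR") %in% ids))
})

test_that("branch-swap canonicalisation leaves coupled entries invariant", {
  cat_all <- enumerate_catalog(families = c("minp", "mint"))
  for (e in cat_all) {
    pr <- e$branch_types
    expect_identical(pr, sort(pr))
  }
  # chains carry no gates
  for (e in enumerate_chains()) expect_length(e$gates, 0L)
})

test_that("catalog JSONL export round-trips", {
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  entries <- enumerate_catalog(families = "isolated")
  write_catalog(entries, tmp)
  back <- read_catalog(tmp)
  expect_identical(names(back), names(entries))
  expect_identical(back[["c1-OR"]]$edges, entries[["c1-OR"]]$edges)
})

test_that("s2fig reconstruction excludes only AND-with-forced-companion gates", {
  excl <- minp_s2fig_exclusions()
  expect_length(excl, 9L)
  all42 <- names(enumerate_catalog(families = "minp", drop_rule = "none"))
  expect_true(all(excl %in% all42))
  expect_true(all(grepl("uAND-lOR|uOR-lAND", excl)))
})
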