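test_that("population reference dates follow the piecewise mapping", {
  expect_identical(
    population_reference_date(2008:2017),
    c(2005L, 2010L, 2010L, 2010L, 2010L, 2010L, 2015L, 2015L, 2015L, 2020L)
  )
  expect_error(population_reference_date(2007), "study span")
  expect_error(population_reference_date(2018), "study span")
})

test_that("name normalisation collapses case, punctuation and segment order", {
  expect_identical(normalize_name("Republic of, Landia"), normalize_name("LANDIA; republic of"))
  expect_identical(normalize_name("a,  b"), normalize_name("B, a."))
  # word order *within* a segment is preserved (only comma segments sort)
  expect_false(normalize_name("of Republic Landia") == normalize_name("Landia Republic of"))
})

test_that("crosswalk resolution is exact, error-reporting, and ambiguity-checked", {
  xw <- crosswalk(tibble::tibble(
    source_name = c("Republic of Landia", "LANDIA, REPUBLIC OF", "Wheat"),
    vocabulary = c("production", "population", "production"),
    kind = c("region", "region", "product"),
    target_id = c("LA", "LA", "P1")
  ))
  expect_identical(resolve_name(xw, "republic-of landia", "production", "region"), "LA")
  # comma-segment reordering of a loaded alias resolves to the same id
  expect_identical(resolve_name(xw, "Republic of, Landia", "population", "region"), "LA")
  expect_error(resolve_name(xw, "Atlantis", "production", "region"), "nearest candidates")
  expect_error(
    crosswalk(tibble::tibble(
      source_name = c("X", "x."), vocabulary = "production",
      kind = "region", target_id = c("A", "B")
    )),
    "ambiguous"
  )
})

test_that("crosswalks of generated worlds are bijective over every vocabulary", {
  w <- tiny_world(seed = 42)
  for (v in c("production", "population", "feed")) {
    sub <- w$crosswalk[w$crosswalk$vocabulary == v & w$crosswalk$kind == "region", ]
    expect_identical(resolve_name(w$crosswalk, sub$source_name, v, "region"), sub$target_id)
  }
  for (v in c("production", "composition", "trade")) {
    sub <- w$crosswalk[w$crosswalk$vocabulary == v & w$crosswalk$kind == "product", ]
    expect_identical(resolve_name(w$crosswalk, sub$source_name, v, "product"), sub$target_id)
  }
})

test_that("registries enforce their invariants", {
  expect_error(
    region_registry(tibble::tibble(
      region_id = "C1", level = "country", continent = NA_character_
    )),
    "continent"
  )
  expect_error(
    product_registry(tibble::tibble(
      product_id = "P1", category = "milk",
      is_animal_product = FALSE, has_composition = TRUE
    )),
    "inconsistent"
  )
})

test_that("long-format tables round-trip through read and write", {
  w <- tiny_world(seed = 7)
  tmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(w$raw$production, tmp)
  tbl <- read_long_table(tmp, "production")
  expect_identical(nrow(tbl), nrow(w$raw$production))
  expect_true(all(tbl$tonnes >= 0))

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_long_table(tbl, tmp2, "production", units = c(tonnes = "tonnes"))
  tbl2 <- read_long_table(tmp2, "production")
  expect_equal(
    dplyr::arrange(tbl, region, product, year),
    dplyr::arrange(tbl2, region, product, year)
  )

  # resolving the display names recovers the generated identifiers
  ids <- resolve_name(w$crosswalk, tbl$region, "production", "region")
  expect_true(all(ids %in% w$regions$region_id))
})

test_that("malformed long tables are rejected with schema errors", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(Area = "A", Year = 2010, Element = "Production"), tmp)
  expect_error(read_long_table(tmp, "production"), "missing column")

  readr::write_csv(
    tibble::tibble(
      Area = "A", Item = "x", Element = "Production",
      Year = 2010, Unit = "tonnes", Value = -5
    ),
    tmp
  )
  expect_error(read_long_table(tmp, "production"), "negative")
})
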