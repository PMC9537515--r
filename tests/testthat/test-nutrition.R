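test_that("nutrient supplies are linear and additive over products", {
  comp <- tibble::tibble(
    product_id = c("wheat", "wheat", "beans"),
    nutrient = c("energy", "protein", "energy"),
    amount_per_kg = c(3000, 120, 3400)
  )
  one <- nutrient_supply(tibble::tibble(product_id = "wheat", kg = 2), comp)
  expect_equal(one$amount[one$nutrient == "energy"], 6000)
  expect_equal(one$amount[one$nutrient == "protein"], 240)

  empty <- nutrient_supply(tibble::tibble(product_id = character(), kg = numeric()), comp)
  expect_true(all(empty$amount == 0))
  expect_setequal(empty$nutrient, c("energy", "protein"))

  both <- nutrient_supply(
    tibble::tibble(product_id = c("wheat", "beans"), kg = c(2, 1)), comp
  )
  expect_equal(both$amount[both$nutrient == "energy"], 6000 + 3400)

  expect_warning(
    nutrient_supply(tibble::tibble(product_id = "tobacco", kg = 5), comp),
    "without composition"
  )
})

test_that("population requirements match the per-person brute force", {
  sched <- tidyr::expand_grid(
    sex = c("male", "female"), age_bin = age_bins(), nutrient = "energy"
  ) |>
    dplyr::mutate(daily_amount = 2000)
  pyr1 <- tibble::tibble(sex = "male", age_bin = "25-29", persons = 1)
  req1 <- population_requirement(pyr1, sched)
  expect_equal(req1$annual, 2000 * 365)
  expect_equal(req1$daily, 2000)

  empty <- population_requirement(
    tibble::tibble(sex = character(), age_bin = character(), persons = numeric()),
    sched
  )
  expect_equal(empty$annual, 0)

  # brute force over individual persons equals the weighted computation
  withr::with_seed(42, {
    for (i in 1:5) {
      pyr <- random_pyramid(50)
      sch <- random_schedule()
      fast <- population_requirement(pyr, sch)
      brute <- sapply(sort(unique(sch$nutrient)), function(nu) {
        tot <- 0
        for (k in seq_len(nrow(pyr))) {
          d <- sch$daily_amount[sch$sex == pyr$sex[k] & sch$age_bin == pyr$age_bin[k] & sch$nutrient == nu]
          for (person in seq_len(pyr$persons[k])) tot <- tot + d * 365
        }
        tot
      })
      expect_equal(fast$annual, unname(brute), tolerance = 1e-9)
    }
  })

  expect_error(
    population_requirement(
      tibble::tibble(sex = "male", age_bin = "banana", persons = 1), sched
    ),
    "age bins"
  )
})

test_that("sufficiency ratios are elementwise and zero-requirement flagged", {
  sup <- tibble::tibble(nutrient = c("a", "b"), amount = c(10, 4))
  req <- tibble::tibble(nutrient = c("a", "b"), annual = c(10, 2))
  sr <- sufficiency_ratio(sup, req)
  expect_equal(sr$ratio, c(1, 2))

  req0 <- tibble::tibble(nutrient = c("a", "b"), annual = c(10, 0))
  expect_warning(sr0 <- sufficiency_ratio(sup, req0), "zero requirement")
  expect_true(is.na(sr0$ratio[sr0$nutrient == "b"]))
})

test_that("ratios are invariant to common rescaling of population and supply", {
  withr::with_seed(7, {
    pyr <- random_pyramid()
    sch <- random_schedule()
    req <- population_requirement(pyr, sch)
    sup <- tibble::tibble(
      nutrient = req$nutrient, amount = req$annual * runif(nrow(req), 0.5, 2)
    )
    base <- sufficiency_ratio(sup, req)
    k <- 3.7
    scaled <- sufficiency_ratio(
      dplyr::mutate(sup, amount = amount * k),
      population_requirement(dplyr::mutate(pyr, persons = persons * k), sch)
    )
    expect_equal(scaled$ratio, base$ratio, tolerance = 1e-9)
  })
})

test_that("headcounts sum person-equivalents of unmet and surplus requirement", {
  ratios <- tibble::tibble(region_id = "C1", nutrient = "energy", ratio = 0.5)
  pops <- tibble::tibble(region_id = "C1", population = 10)
  hc <- headcount_report(ratios, pops)
  expect_equal(hc$deficit_requirement_years, 5)
  expect_equal(hc$excess_requirement_years, 0)

  even <- headcount_report(
    tibble::tibble(region_id = c("C1", "C2"), nutrient = "energy", ratio = 1),
    tibble::tibble(region_id = c("C1", "C2"), population = c(5, 9))
  )
  expect_equal(even$deficit_requirement_years, 0)
  expect_equal(even$excess_requirement_years, 0)

  # splitting a country into two with identical per-capita values is neutral
  whole <- headcount_report(
    tibble::tibble(region_id = "C1", nutrient = "energy", ratio = 1.4),
    tibble::tibble(region_id = "C1", population = 10)
  )
  split <- headcount_report(
    tibble::tibble(region_id = c("A", "B"), nutrient = "energy", ratio = 1.4),
    tibble::tibble(region_id = c("A", "B"), population = c(4, 6))
  )
  expect_equal(split$excess_requirement_years, whole$excess_requirement_years)

  expect_warning(
    headcount_report(ratios, tibble::tibble(region_id = "C9", population = 1)),
    "excluded"
  )
})

test_that("global excess minus deficit equals the signed balance identity", {
  withr::with_seed(12, {
    ratios <- tidyr::expand_grid(
      region_id = sprintf("C%02d", 1:20), nutrient = c("energy", "zinc")
    ) |>
      dplyr::mutate(ratio = runif(dplyr::n(), 0.3, 2.5))
    pops <- tibble::tibble(
      region_id = sprintf("C%02d", 1:20),
      population = runif(20, 1e4, 1e7)
    )
    hc <- headcount_report(ratios, pops)
    signed <- ratios |>
      dplyr::inner_join(pops, by = "region_id") |>
      dplyr::group_by(nutrient) |>
      dplyr::summarise(net = sum(population * (ratio - 1)))
    expect_equal(
      hc$excess_requirement_years - hc$deficit_requirement_years,
      signed$net,
      tolerance = 1e-12
    )
  })
})

test_that("population scaling preserves structure and scales requirements linearly", {
  w <- tiny_world(seed = 4)
  pyr <- w$pyramids[w$pyramids$reference_date == 2010, ]
  total <- sum(pyr$persons)
  scaled <- scale_population(pyr, 2 * total)
  expect_equal(scaled$persons, pyr$persons * 2)
  same <- scale_population(pyr, total)
  expect_equal(same$persons, pyr$persons)

  req <- population_requirement(pyr[pyr$region_id == pyr$region_id[1], ], w$requirements)
  req2 <- population_requirement(
    scaled[scaled$region_id == pyr$region_id[1], ], w$requirements
  )
  expect_equal(req2$annual, 2 * req$annual, tolerance = 1e-12)
})

test_that("category stratification conserves totals and moves with products", {
  w <- tiny_world(seed = 8)
  led <- average_ledger(world_ledger(w))
  slice <- led |>
    dplyr::group_by(product_id) |>
    dplyr::summarise(kg = sum(p4_kg))
  strat <- stratify_by_category(slice, w$composition, w$products)
  # the slice still carries the non-food products, which have no composition
  expect_warning(total <- nutrient_supply(slice, w$composition), "without composition")
  sums <- strat |>
    dplyr::group_by(nutrient) |>
    dplyr::summarise(amount = sum(amount))
  expect_equal(sums$amount, total$amount[match(sums$nutrient, total$nutrient)],
    tolerance = 1e-9
  )
  shares <- strat |>
    dplyr::filter(!is.na(share)) |>
    dplyr::group_by(nutrient) |>
    dplyr::summarise(s = sum(share))
  expect_equal(shares$s, rep(1, nrow(shares)), tolerance = 1e-9)

  # moving a product between categories moves its contribution intact
  prods2 <- w$products
  victim <- prods2$product_id[prods2$category == "cereals"][1]
  prods2$category[prods2$product_id == victim] <- "pulses"
  prods2$is_animal_product[prods2$product_id == victim] <- FALSE
  strat2 <- stratify_by_category(slice, w$composition, prods2)
  moved <- nutrient_supply(slice[slice$product_id == victim, ], w$composition)
  for (nu in c("energy", "protein")) {
    before <- strat$amount[strat$category == "cereals" & strat$nutrient == nu]
    after <- strat2$amount[strat2$category == "cereals" & strat2$nutrient == nu]
    expect_equal(before - after, moved$amount[moved$nutrient == nu], tolerance = 1e-9)
  }
})
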