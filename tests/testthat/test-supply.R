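test_that("unit conversion and trade clipping follow the accounting rules", {
  expect_identical(tonnes_to_kg(c(100, 0, 2.5)), c(100000, 0, 2500))
  expect_error(tonnes_to_kg(-1), "non-negative")
  expect_identical(net_trade_supply(10, 2, 15), 0)
  expect_identical(net_trade_supply(10, 0, 0), 10)
  expect_identical(net_trade_supply(5, 7, 3), 9)
})

test_that("weighted diets are style-proportion means and validated", {
  one <- tibble::tibble(
    animal_type = "ruminant", style_id = "s1", style_proportion = 1,
    category = "cereals", intake_kg_day = 2
  )
  expect_equal(weighted_diet(one)$intake_kg_day, 2)

  two <- tibble::tibble(
    animal_type = "ruminant", style_id = c("s1", "s2"),
    style_proportion = c(0.5, 0.5), category = "cereals",
    intake_kg_day = c(2, 4)
  )
  expect_equal(weighted_diet(two)$intake_kg_day, 3)

  three <- tibble::tibble(
    animal_type = "x", style_id = c("a", "b", "c"),
    style_proportion = c(0.2, 0.3, 0.5), category = "cereals",
    intake_kg_day = c(1, 2, 3)
  )
  expect_equal(weighted_diet(three)$intake_kg_day, 2.3)

  bad <- dplyr::mutate(two, style_proportion = c(0.5, 0.6))
  expect_error(weighted_diet(bad), "sum to 1")
})

test_that("feed fluxes annualise daily intake and are additive over animal types", {
  diets <- tibble::tibble(
    animal_type = c("ruminant", "nonruminant"), style_id = "only",
    style_proportion = 1, category = "cereals", intake_kg_day = c(2, 1)
  )
  pops <- tibble::tibble(
    region_id = "C1", year = 2010L,
    animal_type = c("ruminant", "nonruminant"), head = c(1000, 0)
  )
  ff <- feed_flux(diets, pops)
  expect_equal(ff$feed_kg, 2 * 1000 * 365)

  pops$head <- c(1000, 500)
  ff2 <- feed_flux(diets, pops)
  expect_equal(ff2$feed_kg, 2 * 1000 * 365 + 1 * 500 * 365)
})

test_that("ledger tiers follow the P1-P4 chain on hand-computed cases", {
  products <- tibble::tibble(
    product_id = c("wheat", "milk"), category = c("cereals", "milk"),
    is_animal_product = c(FALSE, TRUE), has_composition = TRUE
  )
  production <- tibble::tibble(
    region_id = "C1", year = 2010L,
    product_id = c("wheat", "milk"), tonnes = c(100, 50)
  )
  lw <- tidyr::expand_grid(
    region_group_id = "G1", category = c("cereals", "milk")
  ) |>
    dplyr::mutate(loss_fraction = c(0.1, 0), waste_fraction = c(0.3, 0))
  rg <- tibble::tibble(region_id = "C1", region_group_id = "G1")

  led <- compute_ledger(production, NULL, lw, rg, NULL, products)
  wheat <- led[led$product_id == "wheat", ]
  expect_equal(wheat$p1_kg, 100000)
  expect_equal(wheat$p2_kg, 90000)
  expect_equal(wheat$p3_kg, 63000)
  expect_equal(wheat$p4_kg, 63000)

  milk <- led[led$product_id == "milk", ]
  expect_equal(milk$p1_kg, 0)
  expect_equal(milk$livestock_kg, 50000)
  expect_equal(milk$p4_kg, 50000)

  # zero world
  led0 <- compute_ledger(
    dplyr::mutate(production, tonnes = 0), NULL, lw, rg, NULL, products
  )
  expect_true(all(as.matrix(led0[flux_cols]) == 0))
})

test_that("ledger invariants hold on generated worlds", {
  for (s in 1:3) {
    w <- tiny_world(seed = s)
    led <- world_ledger(w)
    expect_true(all(as.matrix(led[flux_cols]) >= 0))
    expect_equal(led$p2_kg,
      pmax(0, led$p1_kg - led$loss_kg + led$import_kg - led$export_kg),
      tolerance = 1e-12
    )
    expect_equal(led$p3_kg, led$p2_kg - led$waste_kg, tolerance = 1e-12)
    expect_equal(led$p4_kg,
      pmax(0, led$p3_kg + led$livestock_kg - led$feed_kg),
      tolerance = 1e-12
    )
    expect_true(all(led$waste_kg <= led$p2_kg + 1e-9))
    expect_true(all(led$p1_kg[led$category %in% animal_categories()] == 0))
    expect_true(all(led$livestock_kg[!led$category %in% animal_categories()] == 0))
  }
})

test_that("waste and exports act monotonically on downstream tiers", {
  w <- tiny_world(seed = 5)
  feed <- feed_flux(w$diets, w$animal_populations)
  led <- compute_ledger(w$production, w$trade, w$loss_waste, w$region_groups, feed, w$products)
  lw_hi <- dplyr::mutate(w$loss_waste, waste_fraction = pmin(1, waste_fraction + 0.2))
  led_hi <- compute_ledger(w$production, w$trade, lw_hi, w$region_groups, feed, w$products)
  expect_true(all(led_hi$p3_kg <= led$p3_kg + 1e-9))
  expect_true(all(led_hi$p4_kg <= led$p4_kg + 1e-9))

  tr_hi <- dplyr::mutate(w$trade, export_tonnes = export_tonnes * 2)
  led_ex <- compute_ledger(w$production, tr_hi, w$loss_waste, w$region_groups, feed, w$products)
  expect_true(all(led_ex$p2_kg <= led$p2_kg + 1e-9))
})

test_that("the ledger is homogeneous of degree one in its mass inputs", {
  w <- tiny_world(seed = 11, trade_intensity = 0) # no clipping active
  feed <- feed_flux(w$diets, w$animal_populations)
  led <- compute_ledger(w$production, NULL, w$loss_waste, w$region_groups, feed, w$products)
  lam <- 2.5
  led2 <- compute_ledger(
    dplyr::mutate(w$production, tonnes = tonnes * lam), NULL,
    w$loss_waste, w$region_groups,
    dplyr::mutate(feed, feed_kg = feed_kg * lam), w$products
  )
  expect_equal(as.matrix(led2[flux_cols]), lam * as.matrix(led[flux_cols]),
    tolerance = 1e-9
  )
})

test_that("a frictionless world collapses all plant tiers onto P1", {
  w <- tiny_world(
    seed = 9, trade_intensity = 0,
    loss_range = c(0, 0), waste_range = c(0, 0)
  )
  led <- compute_ledger(
    w$production, NULL, w$loss_waste, w$region_groups, NULL, w$products
  )
  plant <- led[!led$category %in% animal_categories(), ]
  expect_equal(plant$p2_kg, plant$p1_kg, tolerance = 1e-12)
  expect_equal(plant$p3_kg, plant$p1_kg, tolerance = 1e-12)
  expect_equal(plant$p4_kg, plant$p1_kg, tolerance = 1e-12)
})

test_that("year averaging is the arithmetic mean and order-invariant", {
  w <- tiny_world(seed = 2, years = 2010:2011)
  led <- world_ledger(w)
  avg <- average_ledger(led)
  manual <- led |>
    dplyr::group_by(region_id, product_id) |>
    dplyr::summarise(p4 = mean(p4_kg), .groups = "drop")
  expect_equal(avg$p4_kg, manual$p4, tolerance = 1e-12)
  shuffled <- led[rev(seq_len(nrow(led))), ]
  expect_equal(average_ledger(shuffled), avg)
})
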