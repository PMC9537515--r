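test_that("identical configurations generate identical worlds", {
  w1 <- tiny_world(seed = 21)
  w2 <- tiny_world(seed = 21)
  for (tab in c("production", "trade", "loss_waste", "composition", "pyramids", "environment")) {
    expect_identical(w1[[tab]], w2[[tab]])
  }
  w3 <- tiny_world(seed = 22)
  expect_false(identical(w1$production, w3$production))
})

test_that("zero trade intensity produces a tradeless world", {
  w <- tiny_world(seed = 23, trade_intensity = 0)
  expect_true(all(w$trade$import_tonnes == 0))
  expect_true(all(w$trade$export_tonnes == 0))
})

test_that("pyramids have 42 cells and energy requirements are positive everywhere", {
  w <- tiny_world(seed = 24)
  cells <- w$pyramids |>
    dplyr::count(region_id, reference_date)
  expect_true(all(cells$n == 42L))
  energy <- w$requirements[w$requirements$nutrient == "energy", ]
  expect_identical(nrow(energy), 42L)
  expect_true(all(energy$daily_amount > 0))
})

test_that("parent-child correlation approaches its closed form at large n", {
  # single-edge SEM: cor(x, y) = b / sqrt(b^2 + 1) for unit noise
  b <- 0.9
  dag <- tibble::tibble(from = "x", to = "y", coefficient = b)
  d <- simulate_sem(dag, 5000, seed = 77)
  expect_equal(cor(d$x, d$y), b / sqrt(b^2 + 1), tolerance = 0.03)
})

test_that("the SEM draws honour the configured ground-truth structure", {
  w <- generate_world(world_config(seed = 25, n_countries = 400, years = 2010))
  z <- w$ground_truth$sem_draws
  # a configured strong edge shows up as strong correlation;
  # two independent roots stay near zero
  dag <- w$ground_truth$true_dag
  e <- dag[dag$from == "ruminant_meat" & dag$to == "milk", ]
  expect_gt(abs(cor(z$ruminant_meat, z$milk)), 0.5)
  expect_lt(abs(cor(z$nuts, z$roots_tubers)), 0.2)
})

test_that("the reference ledger equals the vectorised engine on random worlds", {
  for (s in 26:28) {
    w <- tiny_world(seed = s, n_countries = 4, years = 2010:2011)
    led <- world_ledger(w)
    ref <- reference_ledger(w)
    expect_identical(led[c("region_id", "year", "product_id")], ref[c("region_id", "year", "product_id")])
    expect_equal(as.matrix(led[flux_cols]), as.matrix(ref[flux_cols]), tolerance = 1e-12)
  }
})

test_that("the reference ledger is itself homogeneous under mass scaling", {
  w <- tiny_world(seed = 29, n_countries = 3, years = 2010, trade_intensity = 0)
  ref <- reference_ledger(w)
  w2 <- w
  lam <- 3
  w2$production$tonnes <- w$production$tonnes * lam
  w2$animal_populations$head <- w$animal_populations$head * lam
  ref2 <- reference_ledger(w2)
  expect_equal(as.matrix(ref2[flux_cols]), lam * as.matrix(ref[flux_cols]),
    tolerance = 1e-9
  )
})

test_that("world configuration is validated", {
  expect_error(world_config(years = 2000:2005), "years")
  expect_error(world_config(trade_intensity = -1))
  expect_error(
    world_config(true_dag = tibble::tibble(
      from = c("cereals", "milk"), to = c("milk", "cereals"), coefficient = 1
    )),
    "acyclic"
  )
})
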