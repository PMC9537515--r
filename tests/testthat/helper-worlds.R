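# small worlds and fixtures shared across tests

tiny_world <- function(seed = 1, n_countries = 6, years = 2010:2012, ...) {
  generate_world(world_config(
    seed = seed, n_countries = n_countries, years = years,
    products_per_category = 2, ...
  ))
}

# ledger flux columns, in canonical order
flux_cols <- c(
  "p1_kg", "loss_kg", "import_kg", "export_kg", "waste_kg",
  "feed_kg", "livestock_kg", "p2_kg", "p3_kg", "p4_kg"
)

world_ledger <- function(world) {
  feed <- feed_flux(world$diets, world$animal_populations)
  compute_ledger(
    world$production, world$trade, world$loss_waste,
    world$region_groups, feed, world$products
  )
}

# uniform random pyramid over the 42 demographic cells
random_pyramid <- function(max_persons = 1000) {
  tidyr::expand_grid(sex = c("male", "female"), age_bin = age_bins()) |>
    dplyr::mutate(persons = round(runif(dplyr::n(), 0, max_persons)))
}

# random requirement schedule over a few nutrients
random_schedule <- function(nutrients = c("energy", "protein", "calcium")) {
  tidyr::expand_grid(
    sex = c("male", "female"), age_bin = age_bins(), nutrient = nutrients
  ) |>
    dplyr::mutate(daily_amount = runif(dplyr::n(), 0.5, 3))
}
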