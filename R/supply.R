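# Four-tier food-supply mass balance.
#
# P1: raw plant production (animal products excluded).
# P2: P1 minus production/postharvest/processing losses, plus net trade,
#     clipped at zero (exports bounded by domestic availability).
# P3: P2 minus post-trade waste.
# P4: P3 plus livestock products (meat, milk, eggs) minus livestock feed,
#     floored at zero per product.
#
# All masses are carried in kg internally; tonnes appear only at the I/O
# boundary.

#' Convert metric tonnes to kilograms
#'
#' @param t Numeric vector of non-negative masses in tonnes.
#' @return `1000 * t`, in kg.
#' @export
tonnes_to_kg <- function(t) {
  if (any(!is.finite(t)) || any(t < 0)) stop("tonnes must be finite and non-negative")
  1000 * t
}

#' Weighted average livestock diet per animal type
#'
#' Livestock diets are given per production style (e.g. grazing, mixed,
#' industrial) with the proportion of animals housed under each style; the
#' weighted average diet per animal type is the style-proportion-weighted
#' mean intake of each food category.
#'
#' @param diets Data frame with columns `animal_type`, `style_id`,
#'   `style_proportion`, `category`, `intake_kg_day` (kg per head per day).
#' @return Tibble with columns `animal_type`, `category`, `intake_kg_day`.
#' @export
weighted_diet <- function(diets) {
  diets <- as_tibble(diets)
  stopifnot(all(c("animal_type", "style_id", "style_proportion", "category", "intake_kg_day") %in% names(diets)))
  props <- diets |>
    distinct(.data$animal_type, .data$style_id, .data$style_proportion) |>
    group_by(.data$animal_type) |>
    summarise(total = sum(.data$style_proportion), .groups = "drop")
  off <- abs(props$total - 1) > 1e-9
  if (any(off)) {
    stop(
      "style proportions must sum to 1 within animal type: ",
      paste(props$animal_type[off], collapse = ", ")
    )
  }
  diets |>
    group_by(.data$animal_type, .data$category) |>
    summarise(intake_kg_day = sum(.data$style_proportion * .data$intake_kg_day), .groups = "drop")
}

#' Annual livestock feed consumption by food category
#'
#' Combines weighted average daily diets with animal headcounts to give the
#' total mass of each food category consumed as feed per region and year.
#' Daily intakes are annualised with a factor of 365. Regions or years with
#' no animal-population row contribute zero head (the missing-value rule).
#'
#' @param diets Style-resolved diet table (see [weighted_diet()]).
#' @param populations Data frame with columns `region_id`, `year`,
#'   `animal_type`, `head`.
#' @return Tibble with columns `region_id`, `year`, `category`, `feed_kg`.
#' @export
feed_flux <- function(diets, populations) {
  wd <- weighted_diet(diets)
  populations <- as_tibble(populations)
  stopifnot(all(c("region_id", "year", "animal_type", "head") %in% names(populations)))
  if (any(populations$head < 0)) stop("animal head counts must be non-negative")
  populations |>
    inner_join(wd, by = "animal_type", relationship = "many-to-many") |>
    group_by(.data$region_id, .data$year, .data$category) |>
    summarise(feed_kg = sum(.data$intake_kg_day * .data$head * 365), .groups = "drop")
}

#' Post-loss supply after net trade, clipped at zero
#'
#' Exports from a region are bounded by domestic production plus imports, so
#' the post-trade supply is floored at zero.
#'
#' @param post_loss_kg,import_kg,export_kg Non-negative numeric vectors (kg).
#' @return `pmax(0, post_loss_kg + import_kg - export_kg)`.
#' @export
net_trade_supply <- function(post_loss_kg, import_kg, export_kg) {
  if (any(post_loss_kg < 0) || any(import_kg < 0) || any(export_kg < 0)) {
    stop("all trade inputs must be non-negative")
  }
  pmax(0, post_loss_kg + import_kg - export_kg)
}

#' Compute the P1--P4 supply ledger
#'
#' Builds, per region x year x product, the full set of food fluxes and the
#' four supply tiers. Losses apply to raw plant production before trade;
#' waste applies after trade (`waste_kg = p2_kg * waste_fraction`); livestock
#' feed is deducted from the plant products of each food category in
#' proportion to their post-waste supply, and each product's P4 is floored
#' at zero. Livestock products enter only at P4. Missing production or trade
#' cells are treated as zero.
#'
#' @param production Data frame `region_id`, `year`, `product_id`, `tonnes`.
#' @param trade Data frame `region_id`, `year`, `product_id`,
#'   `import_tonnes`, `export_tonnes`; may be `NULL` for a no-trade world.
#' @param loss_waste Data frame `region_group_id`, `category`,
#'   `loss_fraction`, `waste_fraction` (both in `[0, 1]`).
#' @param region_groups Data frame `region_id`, `region_group_id` mapping
#'   each country to its loss/waste region group.
#' @param feed_fluxes Data frame `region_id`, `year`, `category`, `feed_kg`
#'   as returned by [feed_flux()]; may be `NULL`.
#' @param products Product registry (see [product_registry()]).
#' @return A `SupplyLedger` tibble with columns `region_id`, `year`,
#'   `product_id`, `category`, `p1_kg`, `loss_kg`, `import_kg`, `export_kg`,
#'   `waste_kg`, `feed_kg`, `livestock_kg`, `p2_kg`, `p3_kg`, `p4_kg`.
#' @export
compute_ledger <- function(production, trade = NULL, loss_waste, region_groups,
                           feed_fluxes = NULL, products) {
  products <- product_registry(products)
  production <- as_tibble(production)
  stopifnot(all(c("region_id", "year", "product_id", "tonnes") %in% names(production)))
  if (any(production$tonnes < 0)) stop("production tonnes must be non-negative")
  if (any(loss_waste$loss_fraction < 0 | loss_waste$loss_fraction > 1) ||
    any(loss_waste$waste_fraction < 0 | loss_waste$waste_fraction > 1)) {
    stop("loss and waste fractions must lie in [0, 1]")
  }
  unknown <- setdiff(production$product_id, products$product_id)
  if (length(unknown)) {
    stop("crosswalk error: unknown product_id ", paste(utils::head(unknown, 5L), collapse = ", "))
  }

  if (is.null(trade)) {
    trade <- tibble(
      region_id = character(), year = integer(), product_id = character(),
      import_tonnes = numeric(), export_tonnes = numeric()
    )
  }
  trade <- as_tibble(trade)
  if (any(trade$import_tonnes < 0) || any(trade$export_tonnes < 0)) {
    stop("trade tonnages must be non-negative")
  }

  led <- full_join(
    production,
    trade,
    by = c("region_id", "year", "product_id")
  ) |>
    mutate(
      tonnes = dplyr::coalesce(.data$tonnes, 0),
      import_tonnes = dplyr::coalesce(.data$import_tonnes, 0),
      export_tonnes = dplyr::coalesce(.data$export_tonnes, 0)
    ) |>
    left_join(select(products, "product_id", "category", "is_animal_product"), by = "product_id") |>
    left_join(as_tibble(region_groups), by = "region_id") |>
    left_join(as_tibble(loss_waste), by = c("region_group_id", "category"))

  if (anyNA(led$category)) {
    stop("crosswalk error: products missing from the registry after join")
  }
  if (anyNA(led$loss_fraction) || anyNA(led$waste_fraction)) {
    miss <- led |>
      filter(is.na(.data$loss_fraction) | is.na(.data$waste_fraction)) |>
      distinct(.data$region_id, .data$category)
    stop(
      "crosswalk error: no loss/waste row for ",
      paste(utils::head(paste0(miss$region_id, ":", miss$category), 5L), collapse = ", ")
    )
  }

  led <- led |>
    mutate(
      p1_kg = if_else(.data$is_animal_product, 0, 1000 * .data$tonnes),
      livestock_kg = if_else(.data$is_animal_product, 1000 * .data$tonnes, 0),
      loss_kg = .data$p1_kg * .data$loss_fraction,
      import_kg = 1000 * .data$import_tonnes,
      export_kg = 1000 * .data$export_tonnes,
      p2_kg = pmax(0, .data$p1_kg - .data$loss_kg + .data$import_kg - .data$export_kg),
      waste_kg = .data$p2_kg * .data$waste_fraction,
      p3_kg = .data$p2_kg - .data$waste_kg
    )

  if (is.null(feed_fluxes)) {
    feed_fluxes <- tibble(
      region_id = character(), year = integer(),
      category = character(), feed_kg = numeric()
    )
  }
  fe <- as_tibble(feed_fluxes) |> rename(feed_cat_kg = "feed_kg")

  led <- led |>
    left_join(fe, by = c("region_id", "year", "category")) |>
    mutate(feed_cat_kg = dplyr::coalesce(.data$feed_cat_kg, 0)) |>
    group_by(.data$region_id, .data$year, .data$category) |>
    mutate(
      plant_p3 = if_else(.data$is_animal_product, 0, .data$p3_kg),
      cat_plant_p3 = sum(.data$plant_p3),
      feed_kg = if_else(
        .data$is_animal_product | .data$cat_plant_p3 <= 0,
        0,
        .data$feed_cat_kg * .data$plant_p3 / .data$cat_plant_p3
      )
    ) |>
    ungroup() |>
    mutate(p4_kg = pmax(0, .data$p3_kg + .data$livestock_kg - .data$feed_kg))

  led |>
    select(
      "region_id", "year", "product_id", "category",
      "p1_kg", "loss_kg", "import_kg", "export_kg", "waste_kg",
      "feed_kg", "livestock_kg", "p2_kg", "p3_kg", "p4_kg"
    ) |>
    arrange(.data$region_id, .data$year, .data$product_id)
}

#' Average a supply ledger over its available years
#'
#' @param ledger A ledger from [compute_ledger()].
#' @return Tibble with one row per region x product and every flux column
#'   replaced by its arithmetic mean over the years present.
#' @export
average_ledger <- function(ledger) {
  flux_cols <- c(
    "p1_kg", "loss_kg", "import_kg", "export_kg", "waste_kg",
    "feed_kg", "livestock_kg", "p2_kg", "p3_kg", "p4_kg"
  )
  ledger |>
    group_by(.data$region_id, .data$product_id, .data$category) |>
    summarise(across(all_of(flux_cols), mean), n_years = dplyr::n(), .groups = "drop") |>
    arrange(.data$region_id, .data$product_id)
}
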