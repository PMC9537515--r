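# Country x variable feature matrix feeding the network analysis.
#
# One row per country; columns are per-capita food-category production
# masses, per-capita nutrient supplies (production mass times composition),
# and the four per-capita environmental variables (CH4, N2O, CO2eq, water
# withdrawal). Per-capita scaling controls for the spread of country
# population sizes. Column roles (food / nutrient / environment) drive the
# expert-knowledge blacklist: nutrient supplies are deterministic
# consequences of production, so arcs from nutrients to food categories are
# forbidden.

#' Assemble the per-capita country feature matrix
#'
#' @param ledger_avg Year-averaged supply ledger ([average_ledger()]),
#'   country level.
#' @param composition Data frame `product_id`, `nutrient`, `amount_per_kg`.
#' @param environment Data frame `region_id`, `ch4`, `n2o`, `co2eq`,
#'   `water_withdrawal`, year-averaged, country level.
#' @param populations Data frame `region_id`, `population` (persons).
#' @param products Product registry.
#' @return A `hen_features` tibble: `region_id` plus numeric columns
#'   `food_<category>`, `nutrient_<id>`, `env_<variable>`, each divided by
#'   country population. Column roles are attached as the `roles`
#'   attribute. Countries without environment rows are dropped with a
#'   warning.
#' @export
assemble_features <- function(ledger_avg, composition, environment, populations, products) {
  environment <- as_tibble(environment)
  populations <- as_tibble(populations)
  stopifnot(all(c("region_id", "ch4", "n2o", "co2eq", "water_withdrawal") %in% names(environment)))

  regions <- unique(ledger_avg$region_id)
  missing_env <- setdiff(regions, environment$region_id)
  if (length(missing_env)) {
    warning(
      "countries without environmental data excluded from the feature matrix: ",
      paste(missing_env, collapse = ", ")
    )
    regions <- setdiff(regions, missing_env)
  }

  # total production mass per category: raw plant production + livestock output
  food <- ledger_avg |>
    filter(.data$region_id %in% regions) |>
    mutate(production_kg = .data$p1_kg + .data$livestock_kg) |>
    group_by(.data$region_id, .data$category) |>
    summarise(kg = sum(.data$production_kg), .groups = "drop") |>
    filter(.data$category != "other") |>
    mutate(category = factor(.data$category, setdiff(FOOD_CATEGORIES, "other"))) |>
    tidyr::complete(region_id = regions, .data$category, fill = list(kg = 0)) |>
    mutate(column = paste0("food_", .data$category)) |>
    select("region_id", "column", value = "kg")

  nutrients <- ledger_avg |>
    filter(.data$region_id %in% regions) |>
    mutate(production_kg = .data$p1_kg + .data$livestock_kg) |>
    inner_join(as_tibble(composition), by = "product_id", relationship = "many-to-many") |>
    group_by(.data$region_id, .data$nutrient) |>
    summarise(value = sum(.data$production_kg * .data$amount_per_kg), .groups = "drop") |>
    tidyr::complete(
      region_id = regions, nutrient = sort(unique(composition$nutrient)),
      fill = list(value = 0)
    ) |>
    mutate(column = paste0("nutrient_", .data$nutrient)) |>
    select("region_id", "column", "value")

  env <- environment |>
    filter(.data$region_id %in% regions) |>
    tidyr::pivot_longer(
      all_of(c("ch4", "n2o", "co2eq", "water_withdrawal")),
      names_to = "column", values_to = "value"
    ) |>
    mutate(column = paste0("env_", .data$column)) |>
    select("region_id", "column", "value")

  wide <- bind_rows(food, nutrients, env) |>
    inner_join(populations, by = "region_id") |>
    mutate(value = .data$value / .data$population) |>
    select(-"population") |>
    tidyr::pivot_wider(names_from = "column", values_from = "value") |>
    arrange(.data$region_id)

  if (anyNA(wide)) stop("feature matrix has missing cells after assembly")
  cols <- setdiff(names(wide), "region_id")
  roles <- dplyr::case_when(
    startsWith(cols, "food_") ~ "food",
    startsWith(cols, "nutrient_") ~ "nutrient",
    TRUE ~ "environment"
  )
  names(roles) <- cols
  structure(wide, roles = roles, class = c("hen_features", class(wide)))
}

#' Role-based arc blacklist for structure learning
#'
#' Every ordered pair from a column with the first role to a column with the
#' second role is forbidden. The default forbids nutrient -> food arcs:
#' production can drive nutrient supplies, never the reverse.
#'
#' @param features A `hen_features` tibble (or any data frame plus an
#'   explicit `roles` named vector).
#' @param from_role,to_role Roles defining the forbidden direction.
#' @param roles Optional named character vector column -> role overriding
#'   the attribute.
#' @return A tibble `from`, `to` of forbidden arcs.
#' @export
role_blacklist <- function(features, from_role = "nutrient", to_role = "food", roles = NULL) {
  roles <- roles %||% attr(features, "roles")
  if (is.null(roles)) stop("no column roles available; supply `roles`")
  tidyr::expand_grid(
    from = names(roles)[roles == from_role],
    to = names(roles)[roles == to_role]
  )
}

#' Numeric matrix view of a feature table
#'
#' @param features A `hen_features` tibble.
#' @return Numeric matrix with countries as rownames.
#' @export
feature_matrix <- function(features) {
  m <- as.matrix(features[setdiff(names(features), "region_id")])
  rownames(m) <- features$region_id
  m
}
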