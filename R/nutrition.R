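# Nutrient supplies, population requirements, sufficiency and headcounts.
#
# Supplies (kg of product) map to nutrients through per-kg composition;
# requirements come from age/sex daily schedules weighted by population
# pyramids; sufficiency is supply over annual requirement; headcounts count
# person-equivalents of unmet (or surplus) requirement, aggregated over
# countries. Supplies are availability, not consumption.

#' Map product supplies to nutrient supplies
#'
#' @param supply Data frame with columns `product_id`, `kg` (one slice of a
#'   supply ledger, e.g. P4 for one region).
#' @param composition Data frame with columns `product_id`, `nutrient`,
#'   `amount_per_kg`. The nutrient key set of the composition table defines
#'   the keys of the result; nutrients a slice does not supply appear with
#'   amount 0.
#' @return Tibble `nutrient`, `amount`, one row per nutrient key. Products
#'   absent from the composition table contribute nothing and trigger one
#'   warning listing them.
#' @export
nutrient_supply <- function(supply, composition) {
  supply <- as_tibble(supply)
  composition <- as_tibble(composition)
  stopifnot(all(c("product_id", "kg") %in% names(supply)))
  stopifnot(all(c("product_id", "nutrient", "amount_per_kg") %in% names(composition)))
  nutrients <- sort(unique(composition$nutrient))
  uncovered <- setdiff(unique(supply$product_id), unique(composition$product_id))
  if (length(uncovered)) {
    warning(
      "products without composition excluded from nutrient mapping: ",
      paste(uncovered, collapse = ", ")
    )
  }
  supply |>
    inner_join(composition, by = "product_id", relationship = "many-to-many") |>
    group_by(.data$nutrient) |>
    summarise(amount = sum(.data$kg * .data$amount_per_kg), .groups = "drop") |>
    tidyr::complete(nutrient = nutrients, fill = list(amount = 0)) |>
    arrange(.data$nutrient)
}

#' Annual nutrient requirement of a population
#'
#' Weights an age/sex daily requirement schedule by a population pyramid:
#' annual requirement = sum over the 42 (sex, age bin) cells of
#' persons x daily requirement x 365. The per-day column (`daily`, the
#' annual value divided back by 365) is exposed for sense checks against the
#' original requirement schedules.
#'
#' @param pyramid Data frame `sex`, `age_bin`, `persons` (one region, one
#'   reference date).
#' @param schedule Data frame `sex`, `age_bin`, `nutrient`, `daily_amount`
#'   (per-person daily requirement).
#' @return Tibble `nutrient`, `annual`, `daily`.
#' @export
population_requirement <- function(pyramid, schedule) {
  pyramid <- as_tibble(pyramid)
  schedule <- as_tibble(schedule)
  stopifnot(all(c("sex", "age_bin", "persons") %in% names(pyramid)))
  stopifnot(all(c("sex", "age_bin", "nutrient", "daily_amount") %in% names(schedule)))
  bad_bins <- setdiff(unique(pyramid$age_bin), AGE_BINS)
  if (length(bad_bins)) {
    stop("schema error: unknown age bins ", paste(bad_bins, collapse = ", "))
  }
  sched_cells <- distinct(schedule, .data$sex, .data$age_bin)
  missing_cells <- dplyr::anti_join(
    distinct(pyramid, .data$sex, .data$age_bin), sched_cells,
    by = c("sex", "age_bin")
  )
  if (nrow(missing_cells)) {
    stop(
      "schema error: requirement schedule lacks cell(s) ",
      paste(utils::head(paste0(missing_cells$sex, ":", missing_cells$age_bin), 5L), collapse = ", ")
    )
  }
  nutrients <- sort(unique(schedule$nutrient))
  pyramid |>
    inner_join(schedule, by = c("sex", "age_bin"), relationship = "many-to-many") |>
    group_by(.data$nutrient) |>
    summarise(annual = sum(.data$persons * .data$daily_amount * 365), .groups = "drop") |>
    tidyr::complete(nutrient = nutrients, fill = list(annual = 0)) |>
    mutate(daily = .data$annual / 365) |>
    arrange(.data$nutrient)
}

#' Sufficiency ratios of supply to requirement
#'
#' @param supply Tibble `nutrient`, `amount` (annual supply, from
#'   [nutrient_supply()]).
#' @param requirement Tibble `nutrient`, `annual` (from
#'   [population_requirement()]).
#' @return Tibble `nutrient`, `supply`, `requirement`, `ratio`. Nutrients
#'   with zero requirement get `ratio = NA` and are flagged with one
#'   warning; they are reported as supplies only.
#' @export
sufficiency_ratio <- function(supply, requirement) {
  out <- full_join(
    rename(as_tibble(supply), supply = "amount"),
    rename(select(as_tibble(requirement), "nutrient", "annual"), requirement = "annual"),
    by = "nutrient"
  ) |>
    mutate(
      supply = dplyr::coalesce(.data$supply, 0),
      requirement = dplyr::coalesce(.data$requirement, 0),
      ratio = if_else(.data$requirement > 0, .data$supply / .data$requirement, NA_real_)
    ) |>
    arrange(.data$nutrient)
  undef <- out$requirement <= 0 & out$supply > 0
  if (any(undef)) {
    warning(
      "nutrients with zero requirement reported as supply only: ",
      paste(out$nutrient[undef], collapse = ", ")
    )
  }
  out
}

#' Excess and deficit nutrient requirement-years across countries
#'
#' For each country and nutrient, the requirement-year balance is
#' `population * (ratio - 1)`: person-equivalents of surplus (positive) or
#' unmet (negative) annual requirement when supplies are scaled to the
#' country's own population requirement. Deficits and excesses are summed
#' separately over countries.
#'
#' @param ratios Data frame `region_id`, `nutrient`, `ratio` of country-level
#'   sufficiency ratios.
#' @param populations Data frame `region_id`, `population`.
#' @return Tibble `nutrient`, `deficit_requirement_years`,
#'   `excess_requirement_years`. Countries missing a population row are
#'   excluded with a warning.
#' @export
headcount_report <- function(ratios, populations) {
  ratios <- as_tibble(ratios)
  populations <- as_tibble(populations)
  stopifnot(all(c("region_id", "nutrient", "ratio") %in% names(ratios)))
  stopifnot(all(c("region_id", "population") %in% names(populations)))
  missing_pop <- setdiff(unique(ratios$region_id), populations$region_id)
  if (length(missing_pop)) {
    warning(
      "countries without population excluded from headcounts: ",
      paste(missing_pop, collapse = ", ")
    )
  }
  ratios |>
    inner_join(populations, by = "region_id") |>
    filter(!is.na(.data$ratio)) |>
    mutate(balance = .data$population * (.data$ratio - 1)) |>
    group_by(.data$nutrient) |>
    summarise(
      deficit_requirement_years = sum(pmax(0, -.data$balance)),
      excess_requirement_years = sum(pmax(0, .data$balance)),
      .groups = "drop"
    ) |>
    arrange(.data$nutrient)
}

#' Scale population pyramids to a target global total
#'
#' Multiplies every pyramid cell by `target_total / current_global_total`,
#' preserving the age-sex structure and the relative size of every region.
#' Used for the 10-billion-person scenario.
#'
#' @param pyramids Data frame `region_id`, `sex`, `age_bin`, `persons`
#'   (optionally more columns, preserved).
#' @param target_total Target global population, `> 0`.
#' @return The pyramids with `persons` rescaled.
#' @export
scale_population <- function(pyramids, target_total) {
  stopifnot(target_total > 0)
  total <- sum(pyramids$persons)
  if (total <= 0) stop("current global population is zero; cannot scale")
  mutate(as_tibble(pyramids), persons = .data$persons * (target_total / total))
}

#' Nutrient supplies stratified by food category
#'
#' @param supply Data frame `product_id`, `kg`.
#' @param composition Data frame `product_id`, `nutrient`, `amount_per_kg`.
#' @param products Product registry (maps products to categories).
#' @return Tibble `category`, `nutrient`, `amount`, `share` where `share` is
#'   the category's fraction of the total supply of that nutrient (`NA` when
#'   the total is zero). Per nutrient, amounts sum to the unstratified
#'   [nutrient_supply()] total and shares sum to 1.
#' @export
stratify_by_category <- function(supply, composition, products) {
  products <- as_tibble(products)
  per_cat <- as_tibble(supply) |>
    inner_join(as_tibble(composition), by = "product_id", relationship = "many-to-many") |>
    left_join(select(products, "product_id", "category"), by = "product_id") |>
    group_by(.data$category, .data$nutrient) |>
    summarise(amount = sum(.data$kg * .data$amount_per_kg), .groups = "drop")
  per_cat |>
    group_by(.data$nutrient) |>
    mutate(
      total = sum(.data$amount),
      share = if_else(.data$total > 0, .data$amount / .data$total, NA_real_)
    ) |>
    ungroup() |>
    select("category", "nutrient", "amount", "share") |>
    arrange(.data$nutrient, .data$category)
}
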