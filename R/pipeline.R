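# End-to-end pipeline: mass balance -> nutrition -> network, with tidy
# CSV/JSON/DOT outputs and a machine-readable run manifest.

#' Year-weighted country nutrient requirements
#'
#' Annual nutrient requirement per country, averaged over the year span with
#' each population-pyramid reference date weighted by the number of calendar
#' years mapping to it (see [population_reference_date()]).
#'
#' @param pyramids Data frame `region_id`, `reference_date`, `sex`,
#'   `age_bin`, `persons`.
#' @param schedule Requirement schedule `sex`, `age_bin`, `nutrient`,
#'   `daily_amount`.
#' @param years Calendar years of the analysis span.
#' @return Tibble `region_id`, `nutrient`, `annual`.
#' @export
country_requirements <- function(pyramids, schedule, years) {
  ref <- population_reference_date(years)
  w <- table(ref) / length(ref)
  as_tibble(pyramids) |>
    filter(.data$reference_date %in% as.integer(names(w))) |>
    inner_join(as_tibble(schedule), by = c("sex", "age_bin"), relationship = "many-to-many") |>
    group_by(.data$region_id, .data$reference_date, .data$nutrient) |>
    summarise(annual = sum(.data$persons * .data$daily_amount * 365), .groups = "drop") |>
    mutate(weight = as.numeric(w[as.character(.data$reference_date)])) |>
    group_by(.data$region_id, .data$nutrient) |>
    summarise(annual = sum(.data$annual * .data$weight), .groups = "drop")
}

#' Year-weighted country populations
#'
#' @param populations Data frame `region_id`, `year`, `population`.
#' @return Tibble `region_id`, `population` (mean over years).
#' @export
country_populations <- function(populations) {
  as_tibble(populations) |>
    group_by(.data$region_id) |>
    summarise(population = mean(.data$population), .groups = "drop")
}

#' Country nutrient supplies from a year-averaged ledger
#'
#' @param ledger_avg Year-averaged ledger ([average_ledger()]).
#' @param composition Composition table.
#' @param representation Supply tier: `"p1"`, `"p2"`, `"p3"` or `"p4"`.
#' @return Tibble `region_id`, `nutrient`, `amount`.
#' @export
country_nutrient_supplies <- function(ledger_avg, composition, representation = "p4") {
  col <- match.arg(representation, c("p1", "p2", "p3", "p4"))
  col <- paste0(col, "_kg")
  regions <- unique(ledger_avg$region_id)
  nutrients <- sort(unique(composition$nutrient))
  ledger_avg |>
    mutate(kg = .data[[col]]) |>
    inner_join(as_tibble(composition), by = "product_id", relationship = "many-to-many") |>
    group_by(.data$region_id, .data$nutrient) |>
    summarise(amount = sum(.data$kg * .data$amount_per_kg), .groups = "drop") |>
    tidyr::complete(region_id = regions, nutrient = nutrients, fill = list(amount = 0))
}

#' Run the full analysis pipeline on a synthetic world
#'
#' Sequences the stages end to end: livestock feed fluxes, the P1--P4
#' ledger, year averaging, country and global nutrient sufficiency (plus an
#' optional scaled-population scenario), excess/deficit requirement-year
#' headcounts, the global category breakdown, per-capita feature assembly,
#' bootstrap-averaged network learning with the nutrient-to-food blacklist,
#' and local linear models. When `out_dir` is given, writes
#' `sufficiency.csv`, `headcount.csv`, `category_breakdown.csv`,
#' `network_edges.csv`, `network_local_models.csv`, `network.dot`,
#' `network_summary.json`, `manifest.json` and `run.log`. Identical world,
#' configuration and seed reproduce identical outputs byte for byte.
#'
#' @param world A `hen_world` from [generate_world()].
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @param representation Supply tier used for sufficiency (default `"p4"`).
#' @param n_boot Bootstrap replicates for arc strengths.
#' @param threshold Arc-strength retention cutoff.
#' @param seed Seed for the bootstrap resampling.
#' @param scenario_population Optional target global population (e.g.
#'   `1e10`); adds scenario sufficiency columns.
#' @return A list of result objects (ledger, sufficiency tables, headcounts,
#'   features, arc strengths, network, local fits, manifest), invisibly
#'   self-describing via its `manifest` element.
#' @export
run_pipeline <- function(world, out_dir = NULL, representation = "p4",
                         n_boot = 200, threshold = 0.6, seed = 1,
                         scenario_population = NULL) {
  stopifnot(inherits(world, "hen_world"))
  representation <- match.arg(representation, c("p1", "p2", "p3", "p4"))
  stopifnot(threshold >= 0, threshold <= 1)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  collected <- withCallingHandlers(
    {
      years <- world$config$years
      feed <- feed_flux(world$diets, world$animal_populations)
      ledger <- compute_ledger(
        world$production, world$trade, world$loss_waste,
        world$region_groups, feed, world$products
      )
      ledger_avg <- average_ledger(ledger)
      note("ledger: ", nrow(ledger), " rows, ", nrow(ledger_avg), " averaged")

      supplies <- country_nutrient_supplies(ledger_avg, world$composition, representation)
      requirements <- country_requirements(world$pyramids, world$requirements, years)
      pops <- country_populations(world$populations)

      ratios <- supplies |>
        inner_join(rename(requirements, requirement = "annual"),
          by = c("region_id", "nutrient")
        ) |>
        mutate(ratio = if_else(.data$requirement > 0,
          .data$amount / .data$requirement, NA_real_
        ))

      global_suff <- sufficiency_ratio(
        supplies |> group_by(nutrient = .data$nutrient) |>
          summarise(amount = sum(.data$amount), .groups = "drop"),
        requirements |> group_by(nutrient = .data$nutrient) |>
          summarise(annual = sum(.data$annual), .groups = "drop")
      )

      if (!is.null(scenario_population)) {
        scaled <- scale_population(world$pyramids, scenario_population)
        scen_req <- country_requirements(scaled, world$requirements, years) |>
          group_by(.data$nutrient) |>
          summarise(annual = sum(.data$annual), .groups = "drop")
        global_suff <- global_suff |>
          left_join(rename(scen_req, scenario_requirement = "annual"), by = "nutrient") |>
          mutate(scenario_ratio = if_else(.data$scenario_requirement > 0,
            .data$supply / .data$scenario_requirement, NA_real_
          ))
      }

      headcount <- headcount_report(
        select(ratios, "region_id", "nutrient", "ratio"), pops
      )

      global_slice <- ledger_avg |>
        mutate(kg = .data[[paste0(representation, "_kg")]]) |>
        group_by(.data$product_id) |>
        summarise(kg = sum(.data$kg), .groups = "drop")
      breakdown <- stratify_by_category(global_slice, world$composition, world$products)

      env_avg <- world$environment |>
        group_by(.data$region_id) |>
        summarise(across(all_of(c("ch4", "n2o", "co2eq", "water_withdrawal")), mean),
          .groups = "drop"
        )
      features <- assemble_features(
        ledger_avg, world$composition, env_avg, pops, world$products
      )
      blacklist <- role_blacklist(features)
      arcs <- bootstrap_arcs(
        feature_matrix(features),
        blacklist = blacklist, n_boot = n_boot, seed = seed
      )
      network <- threshold_network(arcs, min_strength = threshold)
      local_fits <- fit_local_models(network, feature_matrix(features))
      note(
        "network: ", nrow(network$arcs), " arcs over ",
        length(network$nodes), " nodes at strength > ", threshold
      )

      manifest <- list(
        package = "hennet",
        version = as.character(utils::packageVersion("hennet")),
        seed = seed,
        representation = representation,
        n_boot = n_boot,
        threshold = threshold,
        scenario_population = scenario_population,
        years = years,
        n_countries = world$config$n_countries,
        world_config_hash = rlang::hash(world$config)
      )

      list(
        ledger = ledger, ledger_avg = ledger_avg,
        supplies = supplies, requirements = requirements,
        country_ratios = ratios, sufficiency = global_suff,
        headcount = headcount, breakdown = breakdown,
        features = features, arc_strengths = arcs, network = network,
        local_fits = local_fits, manifest = manifest
      )
    },
    warning = function(w) note("warning: ", conditionMessage(w))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    pth <- function(f) file.path(out_dir, f)
    readr::write_csv(collected$sufficiency, pth("sufficiency.csv"))
    readr::write_csv(collected$headcount, pth("headcount.csv"))
    readr::write_csv(collected$breakdown, pth("category_breakdown.csv"))
    readr::write_csv(as_tibble(collected$arc_strengths) |>
      dplyr::semi_join(collected$network$arcs, by = c("from", "to")),
    pth("network_edges.csv")
    )
    readr::write_csv(as_tibble(collected$local_fits), pth("network_local_models.csv"))
    write_dot(collected$network, pth("network.dot"))
    jsonlite::write_json(
      c(
        as.list(glance(collected$network)),
        list(min_strength = collected$network$min_strength)
      ),
      pth("network_summary.json"),
      auto_unbox = TRUE, digits = 10
    )
    jsonlite::write_json(collected$manifest, pth("manifest.json"),
      auto_unbox = TRUE, digits = 10, null = "null"
    )
    writeLines(log_lines, pth("run.log"))
    collected$paths <- vapply(
      c(
        "sufficiency.csv", "headcount.csv", "category_breakdown.csv",
        "network_edges.csv", "network_local_models.csv", "network.dot",
        "network_summary.json", "manifest.json", "run.log"
      ),
      pth, character(1)
    )
  }
  invisible(collected)
}
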