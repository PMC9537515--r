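# Synthetic-world generator: every input table the pipeline consumes, with
# known ground truth.
#
# Per-capita food-category outputs (and the four environmental variables)
# are drawn from a linear-Gaussian structural equation model over a known
# acyclic graph, so the network stage has a recoverable ground truth that is
# blacklist-consistent by construction: nutrient supplies are derived from
# production via composition, never free variables. Magnitudes are loosely
# food-system-like (kg per person per year) but no attempt is made to match
# real-world country data.

DEFAULT_NUTRIENTS <- c(
  "energy", "protein",
  "lysine", "methionine", "phenylalanine", "histidine", "cysteine",
  "threonine", "tryptophan",
  "dha_epa", "arachidonic_acid", "linoleic_acid", "alpha_linolenic_acid",
  "vitamin_a", "thiamin", "riboflavin", "niacin", "vitamin_b6", "folate",
  "choline", "vitamin_b12", "vitamin_c", "vitamin_d", "vitamin_e", "vitamin_k",
  "calcium", "potassium", "iron", "zinc", "copper", "phosphorus"
)

#' Default nutrient key set
#'
#' Energy, protein, seven indicator amino acids, four fatty-acid keys (DHA
#' and EPA combined as one key), twelve vitamins and six minerals.
#'
#' @return Character vector of nutrient keys.
#' @export
default_nutrients <- function() DEFAULT_NUTRIENTS

# per-capita production base, kg/person/year
BASE_MASS <- c(
  cereals = 300, sweeteners = 60, pulses = 30, nuts = 10, oilseeds = 80,
  vegetables = 150, fruits = 100, berries = 5, roots_tubers = 120,
  ruminant_meat = 25, nonruminant_meat = 40, milk = 150, eggs = 12,
  other = 8
)

# per-capita environmental bases (CO2eq-mass kg / m3 per person-year)
BASE_ENV <- c(ch4 = 900, n2o = 500, co2eq = 2500, water_withdrawal = 800)

#' Default ground-truth dependency structure
#'
#' A linear-Gaussian DAG over the 13 food categories and the four
#' environmental variables: an oilseed-driven cascade of crop and livestock
#' production, greenhouse-gas variables as children of ruminant meat and
#' milk (with an inverse berry association), nitrous oxide driven by
#' cereals, and water withdrawal driven by vegetables and fruits. Nuts and
#' roots/tubers are independent of the cascade.
#'
#' @return Tibble `from`, `to`, `coefficient`.
#' @export
default_true_dag <- function() {
  tibble::tribble(
    ~from, ~to, ~coefficient,
    "oilseeds", "cereals", 0.8,
    "oilseeds", "sweeteners", 0.7,
    "oilseeds", "nonruminant_meat", 0.6,
    "oilseeds", "vegetables", 0.6,
    "oilseeds", "ruminant_meat", 0.5,
    "cereals", "eggs", 0.6,
    "cereals", "pulses", 0.5,
    "vegetables", "fruits", 0.8,
    "ruminant_meat", "milk", 0.9,
    "ruminant_meat", "ch4", 0.9,
    "milk", "ch4", 0.6,
    "ruminant_meat", "co2eq", 0.8,
    "milk", "co2eq", 0.5,
    "berries", "co2eq", -0.4,
    "cereals", "n2o", 0.8,
    "vegetables", "water_withdrawal", 0.9,
    "fruits", "water_withdrawal", 0.5
  )
}

#' Fixed ten-node benchmark structure for recovery studies
#'
#' A fixed linear-Gaussian DAG used to benchmark structure recovery: an
#' exogenous hub driving a cascade with two colliders, one inverse edge and
#' one secondary root, echoing the production-cascade motif of
#' [default_true_dag()] but with strong coefficients (magnitudes 0.8--1.2)
#' and unit noise so the skeleton is identifiable at moderate sample sizes.
#' The companion blacklist forbids every arc into the hub, the analogue of
#' the nutrient-to-food constraint of the country analysis.
#'
#' @return Tibble `from`, `to`, `coefficient` with attribute `nodes`;
#'   `benchmark_blacklist()` returns the matching `from`/`to` constraint
#'   table.
#' @export
benchmark_dag <- function() {
  dag <- tibble::tribble(
    ~from, ~to, ~coefficient,
    "n01", "n02", 0.9,
    "n01", "n03", 0.8,
    "n01", "n04", -0.8,
    "n02", "n05", 1.0,
    "n02", "n06", 0.85,
    "n03", "n06", -0.9,
    "n04", "n07", 1.1,
    "n05", "n08", 0.8,
    "n07", "n08", 0.9,
    "n08", "n09", 1.2,
    "n10", "n09", -0.85
  )
  attr(dag, "nodes") <- sprintf("n%02d", 1:10)
  dag
}

#' @rdname benchmark_dag
#' @export
benchmark_blacklist <- function() {
  tibble(from = sprintf("n%02d", 2:10), to = "n01")
}

#' Configuration of a synthetic world
#'
#' @param seed Integer seed; the whole world is a deterministic function of
#'   the configuration.
#' @param n_countries Number of countries (default 120).
#' @param years Calendar years covered (default 2008--2017).
#' @param trade_intensity Upper bound of the uniform import/export
#'   fractions; 0 disables trade.
#' @param loss_range,waste_range Ranges the per-group, per-category loss and
#'   waste fractions are drawn from.
#' @param n_region_groups Number of loss/waste region groups.
#' @param products_per_category Candidate counts of products per category.
#' @param nutrients Nutrient key set.
#' @param true_dag Ground-truth SEM edges (`from`, `to`, `coefficient`) over
#'   food categories and environmental variables.
#' @param noise_sd Exogenous noise standard deviation of the SEM.
#' @return A validated `hen_world_config` list.
#' @export
world_config <- function(seed = 1, n_countries = 120, years = 2008:2017,
                         trade_intensity = 0.2,
                         loss_range = c(0.02, 0.15), waste_range = c(0.05, 0.3),
                         n_region_groups = 3, products_per_category = 2:4,
                         nutrients = default_nutrients(),
                         true_dag = default_true_dag(), noise_sd = 1) {
  stopifnot(
    n_countries >= 2, length(years) >= 1,
    all(years >= 2008 & years <= 2017),
    trade_intensity >= 0, n_region_groups >= 1,
    all(loss_range >= 0 & loss_range <= 1), all(waste_range >= 0 & waste_range <= 1),
    all(products_per_category >= 1), length(nutrients) >= 1
  )
  sem_nodes <- c(setdiff(FOOD_CATEGORIES, "other"), names(BASE_ENV))
  stopifnot(all(true_dag$from %in% sem_nodes), all(true_dag$to %in% sem_nodes))
  # ground truth is blacklist-consistent by construction (nutrients are never
  # SEM nodes); acyclicity still needs checking
  if (is.null(topo_order_or_null(true_dag, sem_nodes))) {
    stop("true_dag must be acyclic")
  }
  structure(
    list(
      seed = as.integer(seed), n_countries = as.integer(n_countries),
      years = as.integer(years), trade_intensity = trade_intensity,
      loss_range = loss_range, waste_range = waste_range,
      n_region_groups = as.integer(n_region_groups),
      products_per_category = as.integer(products_per_category),
      nutrients = nutrients, true_dag = as_tibble(true_dag),
      noise_sd = noise_sd, sem_nodes = sem_nodes
    ),
    class = "hen_world_config"
  )
}

topo_order_or_null <- function(edges, nodes) {
  order <- character()
  remaining <- nodes
  edges <- as.data.frame(edges)
  repeat {
    free <- remaining[vapply(remaining, function(v) {
      !any(edges$to == v & edges$from %in% remaining)
    }, logical(1))]
    if (!length(free)) break
    order <- c(order, free)
    remaining <- setdiff(remaining, free)
  }
  if (length(remaining)) NULL else order
}

#' Simulate data from a linear-Gaussian structural equation model
#'
#' Each node is the coefficient-weighted sum of its parents plus Gaussian
#' noise, generated in topological order.
#'
#' @param dag Tibble `from`, `to`, `coefficient`.
#' @param n Number of observations.
#' @param nodes Node set (defaults to the nodes appearing in `dag`).
#' @param noise_sd Noise standard deviation.
#' @param seed Optional seed.
#' @return Tibble of `n` rows, one column per node.
#' @export
simulate_sem <- function(dag, n, nodes = NULL, noise_sd = 1, seed = NULL) {
  dag <- as_tibble(dag)
  nodes <- nodes %||% attr(dag, "nodes") %||% unique(c(dag$from, dag$to))
  ord <- topo_order_or_null(dag, nodes)
  if (is.null(ord)) stop("dag contains a cycle")
  gen <- function() {
    x <- matrix(0, n, length(nodes), dimnames = list(NULL, nodes))
    for (v in ord) {
      pa <- dag[dag$to == v, ]
      mu <- if (nrow(pa)) x[, pa$from, drop = FALSE] %*% pa$coefficient else 0
      x[, v] <- mu + rnorm(n, sd = noise_sd)
    }
    as_tibble(x)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Draw a random DAG with strong coefficients
#'
#' Edges are placed independently with probability `edge_prob` respecting a
#' random topological order; coefficient magnitudes are uniform on
#' `coef_range` with random signs.
#'
#' @param n_nodes Number of nodes.
#' @param edge_prob Probability of each forward edge.
#' @param coef_range Range of absolute coefficients.
#' @param seed Optional seed.
#' @return Tibble `from`, `to`, `coefficient` with a `nodes` attribute.
#' @export
random_dag <- function(n_nodes, edge_prob = 0.25, coef_range = c(0.8, 1.2), seed = NULL) {
  gen <- function() {
    nodes <- sprintf("v%02d", seq_len(n_nodes))
    ord <- sample(nodes)
    edges <- list()
    for (i in seq_len(n_nodes - 1)) {
      for (j in (i + 1):n_nodes) {
        if (runif(1) < edge_prob) {
          coefficient <- runif(1, coef_range[1], coef_range[2]) * sample(c(-1, 1), 1)
          edges[[length(edges) + 1]] <- tibble(
            from = ord[i], to = ord[j], coefficient = coefficient
          )
        }
      }
    }
    out <- if (length(edges)) bind_rows(edges) else {
      tibble(from = character(), to = character(), coefficient = numeric())
    }
    attr(out, "nodes") <- nodes
    out
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# deterministic display-name variants exercising the crosswalk mismatch
# classes: case, punctuation, and comma-segment order
region_names <- function(base) {
  tibble(
    production = paste("Republic of", base),
    population = paste0(toupper(base), ", REPUBLIC OF"),
    feed = paste0("republic.of, ", tolower(base))
  )
}

product_names <- function(base) {
  tibble(
    production = base,
    composition = gsub(" ", "-", toupper(base)),
    trade = {
      parts <- strsplit(base, " ", fixed = TRUE)
      vapply(parts, function(p) paste(rev(p), collapse = ", "), character(1))
    }
  )
}

#' Generate a complete synthetic world
#'
#' Emits every input table the pipeline consumes -- production, trade,
#' loss/waste fractions, livestock diets and populations, composition,
#' requirement schedule, population pyramids, environmental tables,
#' registries and name crosswalks (with deliberate spelling perturbations
#' across vocabularies) -- plus the ground truth (SEM draws and the true
#' DAG). Identical configurations produce identical worlds.
#'
#' @param config A [world_config()].
#' @return A `hen_world` list of tibbles (see Details in the vignette).
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "hen_world_config"))
  withr::with_seed(config$seed, generate_world_impl(config))
}

generate_world_impl <- function(config) {
  n <- config$n_countries
  years <- config$years
  cats <- setdiff(FOOD_CATEGORIES, "other")
  continents <- c("Aurelia", "Borealis", "Cimmeria", "Doggerland", "Elysia", "Fennoria")

  ## regions -----------------------------------------------------------------
  country_ids <- sprintf("C%03d", seq_len(n))
  country_base <- sprintf("Landia %03d", seq_len(n))
  continent_of <- sample(continents, n, replace = TRUE)
  regions <- bind_rows(
    tibble(
      region_id = country_ids, level = "country", continent = continent_of
    ),
    tibble(region_id = continents, level = "continent", continent = NA_character_),
    tibble(region_id = "WORLD", level = "global", continent = NA_character_)
  ) |> region_registry()

  rnames <- region_names(country_base)
  region_xwalk <- bind_rows(lapply(c("production", "population", "feed"), function(v) {
    tibble(
      source_name = rnames[[v]], vocabulary = v, kind = "region",
      target_id = country_ids
    )
  }))

  ## products ----------------------------------------------------------------
  ppc <- config$products_per_category
  n_per_cat <- if (length(ppc) == 1L) {
    rep(ppc, length(cats))
  } else {
    sample(ppc, length(cats), replace = TRUE)
  }
  products <- purrr::map2_dfr(cats, n_per_cat, function(cat, k) {
    tibble(
      product_id = sprintf("P_%s_%02d", cat, seq_len(k)),
      category = cat,
      base_name = sprintf("%s crop %02d", gsub("_", " ", cat), seq_len(k))
    )
  }) |>
    bind_rows(tibble(
      product_id = c("P_other_01", "P_other_02"), category = "other",
      base_name = c("fibre crop 01", "tobacco crop 01")
    )) |>
    mutate(
      is_animal_product = .data$category %in% ANIMAL_CATEGORIES,
      has_composition = .data$category != "other"
    )
  products <- product_registry(products |> select(
    "product_id", "category", "is_animal_product", "has_composition", "base_name"
  ))

  pnames <- product_names(products$base_name)
  product_xwalk <- bind_rows(lapply(c("production", "composition", "trade"), function(v) {
    tibble(
      source_name = pnames[[v]], vocabulary = v, kind = "product",
      target_id = products$product_id
    )
  }))
  xwalk <- crosswalk(bind_rows(region_xwalk, product_xwalk))

  ## structural model draws --------------------------------------------------
  z <- simulate_sem(config$true_dag, n, nodes = config$sem_nodes, noise_sd = config$noise_sd)
  percap_food <- purrr::map_dfc(cats, function(cat) {
    tibble(!!cat := pmax(0.05 * BASE_MASS[[cat]], BASE_MASS[[cat]] * (1 + 0.15 * z[[cat]])))
  })
  percap_food$other <- BASE_MASS[["other"]] * runif(n, 0.5, 1.5)
  percap_env <- purrr::map_dfc(names(BASE_ENV), function(v) {
    tibble(!!v := pmax(0.05 * BASE_ENV[[v]], BASE_ENV[[v]] * (1 + 0.2 * z[[v]])))
  })

  ## pyramids and populations ------------------------------------------------
  ref_dates <- c(2005L, 2010L, 2015L, 2020L)
  base_pop <- exp(rnorm(n, 16, 1.2))
  age_mid <- c(seq(2, 97, 5), 102)
  age_w <- exp(-0.028 * age_mid)
  age_w <- age_w / sum(age_w)
  sex_share <- c(male = 0.505, female = 0.495)
  pyramids <- tidyr::expand_grid(
    region_id = country_ids, reference_date = ref_dates,
    sex = SEXES, age_bin = AGE_BINS
  ) |>
    mutate(
      persons = round(
        base_pop[match(.data$region_id, country_ids)] *
          1.01^(.data$reference_date - 2010) *
          sex_share[.data$sex] * age_w[match(.data$age_bin, AGE_BINS)]
      )
    )
  populations <- tidyr::expand_grid(region_id = country_ids, year = years) |>
    mutate(reference_date = population_reference_date(.data$year)) |>
    left_join(
      pyramids |>
        group_by(.data$region_id, .data$reference_date) |>
        summarise(population = sum(.data$persons), .groups = "drop"),
      by = c("region_id", "reference_date")
    ) |>
    select("region_id", "year", "population")

  ## production --------------------------------------------------------------
  share <- products |>
    group_by(.data$category) |>
    mutate(share = {
      u <- runif(dplyr::n(), 0.5, 1.5)
      u / sum(u)
    }) |>
    ungroup() |>
    select("product_id", "category", "share")
  percap_long <- percap_food |>
    mutate(region_id = country_ids) |>
    tidyr::pivot_longer(-"region_id", names_to = "category", values_to = "percap_kg")
  production <- tidyr::expand_grid(region_id = country_ids, year = years) |>
    left_join(populations, by = c("region_id", "year")) |>
    left_join(percap_long, by = "region_id", relationship = "many-to-many") |>
    left_join(share, by = "category", relationship = "many-to-many") |>
    mutate(
      tonnes = pmax(
        0,
        .data$percap_kg * .data$population * .data$share *
          (1 + 0.05 * rnorm(dplyr::n())) / 1000
      )
    ) |>
    select("region_id", "year", "product_id", "tonnes")

  ## trade -------------------------------------------------------------------
  mean_tonnes <- production |>
    group_by(.data$product_id) |>
    summarise(mean_tonnes = mean(.data$tonnes), .groups = "drop")
  trade <- production |>
    left_join(mean_tonnes, by = "product_id") |>
    mutate(
      import_tonnes = runif(dplyr::n(), 0, config$trade_intensity) * .data$mean_tonnes,
      export_tonnes = runif(dplyr::n(), 0, config$trade_intensity) * .data$tonnes
    ) |>
    select("region_id", "year", "product_id", "import_tonnes", "export_tonnes")

  ## loss / waste ------------------------------------------------------------
  group_ids <- sprintf("G%02d", seq_len(config$n_region_groups))
  region_groups <- tibble(
    region_id = country_ids,
    region_group_id = sample(group_ids, n, replace = TRUE)
  )
  loss_waste <- tidyr::expand_grid(
    region_group_id = group_ids, category = FOOD_CATEGORIES
  ) |>
    mutate(
      loss_fraction = runif(dplyr::n(), config$loss_range[1], config$loss_range[2]),
      waste_fraction = runif(dplyr::n(), config$waste_range[1], config$waste_range[2])
    )

  ## livestock diets and populations -----------------------------------------
  diets <- tibble::tribble(
    ~animal_type, ~style_id, ~style_proportion, ~category, ~intake_kg_day,
    "ruminant", "grazing", 0.35, "cereals", 0.5,
    "ruminant", "grazing", 0.35, "oilseeds", 0.3,
    "ruminant", "mixed", 0.65, "cereals", 3.0,
    "ruminant", "mixed", 0.65, "oilseeds", 1.0,
    "ruminant", "mixed", 0.65, "pulses", 0.5,
    "nonruminant", "industrial", 0.70, "cereals", 1.8,
    "nonruminant", "industrial", 0.70, "oilseeds", 0.7,
    "nonruminant", "backyard", 0.30, "cereals", 0.6,
    "nonruminant", "backyard", 0.30, "roots_tubers", 0.4
  )
  head_rate <- tibble(
    region_id = country_ids,
    ruminant = runif(n, 0.01, 0.04),
    nonruminant = runif(n, 0.05, 0.2)
  ) |>
    tidyr::pivot_longer(-"region_id", names_to = "animal_type", values_to = "rate")
  animal_populations <- tidyr::expand_grid(region_id = country_ids, year = years) |>
    left_join(populations, by = c("region_id", "year")) |>
    left_join(head_rate, by = "region_id", relationship = "many-to-many") |>
    mutate(head = round(.data$population * .data$rate)) |>
    select("region_id", "year", "animal_type", "head")

  ## composition and requirements --------------------------------------------
  nutr <- config$nutrients
  nutrient_base <- setNames(10^runif(length(nutr), -2, 1), nutr)
  nutrient_base["energy"] <- 3000 # kcal/kg scale
  affinity <- tidyr::expand_grid(nutrient = nutr, category = cats) |>
    mutate(
      a = stats::rexp(dplyr::n()) * stats::rbinom(dplyr::n(), 1, 0.7),
      a = if_else(.data$nutrient == "energy", pmax(.data$a, 0.3), .data$a)
    )
  composition <- products |>
    filter(.data$has_composition) |>
    select("product_id", "category") |>
    tidyr::expand_grid(nutrient = nutr) |>
    left_join(affinity, by = c("nutrient", "category")) |>
    mutate(amount_per_kg = nutrient_base[.data$nutrient] * .data$a * runif(dplyr::n(), 0.7, 1.3)) |>
    select("product_id", "nutrient", "amount_per_kg")

  # requirement bases calibrated to the world's own per-capita supply scale,
  # jittered so sufficiency ratios spread around 1
  mean_comp <- composition |>
    left_join(select(products, "product_id", "category"), by = "product_id") |>
    left_join(share, by = c("product_id", "category")) |>
    group_by(.data$category, .data$nutrient) |>
    summarise(per_kg = sum(.data$amount_per_kg * .data$share), .groups = "drop")
  implied_daily <- mean_comp |>
    mutate(percap_year = BASE_MASS[.data$category] * .data$per_kg) |>
    group_by(.data$nutrient) |>
    summarise(daily = sum(.data$percap_year) / 365, .groups = "drop")
  req_base <- setNames(
    implied_daily$daily * runif(nrow(implied_daily), 0.4, 1.4),
    implied_daily$nutrient
  )
  age_mult <- setNames(0.4 + 0.6 * pmin(age_mid, 25) / 25, AGE_BINS)
  sex_mult <- c(male = 1.1, female = 0.95)
  requirements <- tidyr::expand_grid(sex = SEXES, age_bin = AGE_BINS, nutrient = nutr) |>
    mutate(
      daily_amount = req_base[.data$nutrient] * age_mult[.data$age_bin] * sex_mult[.data$sex]
    )

  ## environment -------------------------------------------------------------
  environment <- tidyr::expand_grid(region_id = country_ids, year = years) |>
    left_join(populations, by = c("region_id", "year")) |>
    left_join(
      percap_env |> mutate(region_id = country_ids),
      by = "region_id"
    ) |>
    mutate(across(
      all_of(names(BASE_ENV)),
      ~ pmax(0, .x * .data$population * (1 + 0.03 * rnorm(dplyr::n())))
    )) |>
    select("region_id", "year", all_of(names(BASE_ENV)))

  ## raw (display-name) views ------------------------------------------------
  region_disp <- setNames(rnames$production, country_ids)
  product_disp <- setNames(pnames$production, products$product_id)
  product_disp_trade <- setNames(pnames$trade, products$product_id)
  raw <- list(
    production = tibble(
      Area = region_disp[production$region_id],
      Item = product_disp[production$product_id],
      Element = "Production", Year = production$year,
      Unit = "tonnes", Value = production$tonnes
    ),
    trade = bind_rows(
      tibble(
        Area = region_disp[trade$region_id],
        Item = product_disp_trade[trade$product_id],
        Element = "Import Quantity", Year = trade$year,
        Unit = "tonnes", Value = trade$import_tonnes
      ),
      tibble(
        Area = region_disp[trade$region_id],
        Item = product_disp_trade[trade$product_id],
        Element = "Export Quantity", Year = trade$year,
        Unit = "tonnes", Value = trade$export_tonnes
      )
    )
  )

  structure(
    list(
      config = config,
      regions = regions,
      products = select(products, -"base_name"),
      region_groups = region_groups,
      crosswalk = xwalk,
      production = production,
      trade = trade,
      loss_waste = loss_waste,
      diets = diets,
      animal_populations = animal_populations,
      composition = composition,
      requirements = requirements,
      pyramids = pyramids,
      populations = populations,
      environment = environment,
      raw = raw,
      ground_truth = list(
        true_dag = config$true_dag,
        sem_draws = z |> mutate(region_id = country_ids, .before = 1),
        percap_food = percap_food |> mutate(region_id = country_ids, .before = 1)
      )
    ),
    class = "hen_world"
  )
}

#' @export
print.hen_world <- function(x, ...) {
  cat(
    "<hen_world> ", x$config$n_countries, " countries, ",
    length(x$config$years), " years, ",
    nrow(x$products), " products, ",
    length(x$config$nutrients), " nutrients\n",
    sep = ""
  )
  invisible(x)
}

#' Reference supply ledger (independent oracle)
#'
#' Recomputes the P1--P4 ledger with a deliberately plain per-row loop that
#' shares no code with [compute_ledger()]; used to validate the vectorised
#' engine on generated worlds.
#'
#' @param world A `hen_world`.
#' @return A ledger tibble with the same columns and ordering as
#'   [compute_ledger()].
#' @export
reference_ledger <- function(world) {
  prod_tab <- as.data.frame(world$production)
  trade_tab <- as.data.frame(world$trade)
  products <- as.data.frame(world$products)
  lw <- as.data.frame(world$loss_waste)
  rg <- as.data.frame(world$region_groups)
  diets <- as.data.frame(world$diets)
  heads <- as.data.frame(world$animal_populations)

  # weighted diets, the slow way
  wd <- list()
  for (at in unique(diets$animal_type)) {
    d <- diets[diets$animal_type == at, ]
    intake <- list()
    for (k in seq_len(nrow(d))) {
      cat_k <- d$category[k]
      add <- d$style_proportion[k] * d$intake_kg_day[k]
      intake[[cat_k]] <- (if (is.null(intake[[cat_k]])) 0 else intake[[cat_k]]) + add
    }
    wd[[at]] <- intake
  }

  keys <- unique(rbind(
    prod_tab[c("region_id", "year", "product_id")],
    trade_tab[c("region_id", "year", "product_id")]
  ))
  keys <- keys[order(keys$region_id, keys$year, keys$product_id), ]

  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    r <- keys$region_id[i]
    y <- keys$year[i]
    p <- keys$product_id[i]
    pr <- products[products$product_id == p, ]
    g <- rg$region_group_id[rg$region_id == r]
    fr <- lw[lw$region_group_id == g & lw$category == pr$category, ]

    tn <- prod_tab$tonnes[prod_tab$region_id == r & prod_tab$year == y & prod_tab$product_id == p]
    tn <- if (length(tn)) tn else 0
    im <- trade_tab$import_tonnes[trade_tab$region_id == r & trade_tab$year == y & trade_tab$product_id == p]
    im <- if (length(im)) im else 0
    ex <- trade_tab$export_tonnes[trade_tab$region_id == r & trade_tab$year == y & trade_tab$product_id == p]
    ex <- if (length(ex)) ex else 0

    p1 <- if (pr$is_animal_product) 0 else 1000 * tn
    livestock <- if (pr$is_animal_product) 1000 * tn else 0
    loss <- p1 * fr$loss_fraction
    p2 <- max(0, p1 - loss + 1000 * im - 1000 * ex)
    waste <- p2 * fr$waste_fraction
    p3 <- p2 - waste
    rows[[i]] <- data.frame(
      region_id = r, year = y, product_id = p, category = pr$category,
      is_animal = pr$is_animal_product,
      p1_kg = p1, loss_kg = loss, import_kg = 1000 * im, export_kg = 1000 * ex,
      waste_kg = waste, livestock_kg = livestock, p2_kg = p2, p3_kg = p3
    )
  }
  led <- do.call(rbind, rows)

  # category feed totals per region-year, then proportional allocation
  led$feed_kg <- 0
  for (r in unique(led$region_id)) {
    for (y in unique(led$year[led$region_id == r])) {
      feed_cat <- list()
      for (at in names(wd)) {
        hd <- heads$head[heads$region_id == r & heads$year == y & heads$animal_type == at]
        hd <- if (length(hd)) hd else 0
        for (cat_k in names(wd[[at]])) {
          add <- wd[[at]][[cat_k]] * hd * 365
          feed_cat[[cat_k]] <- (if (is.null(feed_cat[[cat_k]])) 0 else feed_cat[[cat_k]]) + add
        }
      }
      for (cat_k in names(feed_cat)) {
        sel <- led$region_id == r & led$year == y & led$category == cat_k & !led$is_animal
        denom <- sum(led$p3_kg[sel])
        if (denom > 0) {
          led$feed_kg[sel] <- feed_cat[[cat_k]] * led$p3_kg[sel] / denom
        }
      }
    }
  }
  led$p4_kg <- pmax(0, led$p3_kg + led$livestock_kg - led$feed_kg)

  as_tibble(led[c(
    "region_id", "year", "product_id", "category",
    "p1_kg", "loss_kg", "import_kg", "export_kg", "waste_kg",
    "feed_kg", "livestock_kg", "p2_kg", "p3_kg", "p4_kg"
  )]) |> arrange(.data$region_id, .data$year, .data$product_id)
}
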