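# Name crosswalks between data vocabularies and the population-year rule.
#
# The source datasets the pipeline emulates (production, population, feed)
# spell region and product names differently: different case, punctuation,
# or word order within comma-separated segments ("Republic of X" vs
# "X, Republic of").  A crosswalk maps every (display name, vocabulary) to an
# opaque identifier; lookups are robust to those mismatch classes via a
# documented normalisation and nothing fuzzier.

#' Normalise a display name for crosswalk lookup
#'
#' Lower-cases, splits on commas, strips punctuation and collapses whitespace
#' within each segment, sorts the segments, and rejoins them with single
#' spaces. Two names that differ only in case, punctuation, or the order of
#' comma-separated segments therefore normalise identically.
#'
#' @param x Character vector of display names.
#' @return Character vector of normalised keys.
#' @export
#' @examples
#' normalize_name("Republic of, Landia") == normalize_name("LANDIA; republic of")
normalize_name <- function(x) {
  vapply(as.character(x), function(nm) {
    segs <- strsplit(tolower(nm), ",", fixed = TRUE)[[1]]
    segs <- gsub("[^a-z0-9 ]+", " ", segs)
    segs <- gsub("[[:space:]]+", " ", segs)
    segs <- trimws(segs)
    segs <- segs[nzchar(segs)]
    paste(sort(segs), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Build a name crosswalk
#'
#' @param entries A data frame with columns `source_name`, `vocabulary`,
#'   `kind` (`"region"` or `"product"`), and `target_id`.
#' @return A tibble of class `hen_crosswalk` with a precomputed normalised
#'   lookup key.
#' @export
crosswalk <- function(entries) {
  stopifnot(is.data.frame(entries))
  need <- c("source_name", "vocabulary", "kind", "target_id")
  missing_cols <- setdiff(need, names(entries))
  if (length(missing_cols)) {
    stop("crosswalk entries missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- as_tibble(entries[need])
  out$norm_key <- normalize_name(out$source_name)
  dup <- out |>
    dplyr::distinct(.data$norm_key, .data$vocabulary, .data$kind, .data$target_id) |>
    dplyr::count(.data$norm_key, .data$vocabulary, .data$kind) |>
    filter(.data$n > 1L)
  if (nrow(dup)) {
    stop(
      "ambiguous crosswalk: ", nrow(dup), " normalised name(s) map to ",
      "multiple identifiers, e.g. '", dup$norm_key[1], "' in vocabulary '",
      dup$vocabulary[1], "'"
    )
  }
  class(out) <- c("hen_crosswalk", class(out))
  out
}

#' Resolve display names to identifiers
#'
#' Case-, punctuation- and segment-order-insensitive lookup of display names
#' in one vocabulary of a loaded crosswalk (see [normalize_name()]).
#'
#' @param xwalk A crosswalk built by [crosswalk()].
#' @param name Character vector of display names to resolve.
#' @param vocabulary Vocabulary the names come from (e.g. `"production"`,
#'   `"population"`, `"feed"`, `"composition"`, `"trade"`).
#' @param kind `"region"` or `"product"`.
#' @return Character vector of identifiers, same length as `name`.
#' @export
resolve_name <- function(xwalk, name, vocabulary, kind = c("region", "product")) {
  kind <- match.arg(kind)
  stopifnot(inherits(xwalk, "hen_crosswalk"))
  sub <- xwalk[xwalk$vocabulary == vocabulary & xwalk$kind == kind, ]
  if (!nrow(sub)) {
    stop("crosswalk has no entries for vocabulary '", vocabulary, "', kind '", kind, "'")
  }
  keys <- normalize_name(name)
  idx <- match(keys, sub$norm_key)
  if (anyNA(idx)) {
    bad <- unique(name[is.na(idx)])
    near <- utils::adist(normalize_name(bad[1]), sub$norm_key)
    cand <- sub$source_name[order(near)][seq_len(min(3L, nrow(sub)))]
    stop(
      "unknown ", kind, " name(s) in vocabulary '", vocabulary, "': ",
      paste(utils::head(bad, 5L), collapse = ", "),
      "; nearest candidates for '", bad[1], "': ",
      paste(cand, collapse = ", ")
    )
  }
  sub$target_id[idx]
}

#' Map a calendar year to its population-pyramid reference date
#'
#' Population pyramids exist only at reference dates 2005, 2010, 2015 and
#' 2020; calendar years of the study span map onto them piecewise: 2008 uses
#' 2005, 2009--2013 use 2010, 2014--2016 use 2015, and 2017 uses 2020.
#'
#' @param year Integer vector of calendar years in 2008--2017.
#' @return Integer vector of reference dates.
#' @export
#' @examples
#' population_reference_date(2008:2017)
population_reference_date <- function(year) {
  year <- as.integer(year)
  if (anyNA(year) || any(year < 2008L | year > 2017L)) {
    stop("year must lie within the study span 2008-2017")
  }
  dplyr::case_when(
    year == 2008L ~ 2005L,
    year <= 2013L ~ 2010L,
    year <= 2016L ~ 2015L,
    TRUE ~ 2020L
  )
}

#' Region and product registries
#'
#' Constructors validating the two registry tables the pipeline keys on.
#' Regions carry a level (`country`, `continent`, `global`) and, for
#' countries, a continent; products carry a food category, an animal-product
#' flag consistent with the category, and a flag for products lacking food
#' composition (e.g. fibre and tobacco products), which are excluded from
#' nutrient mapping.
#'
#' @param regions Data frame with columns `region_id`, `level`, `continent`.
#' @param products Data frame with columns `product_id`, `category`,
#'   `is_animal_product`, `has_composition`.
#' @return A validated tibble.
#' @export
region_registry <- function(regions) {
  regions <- as_tibble(regions)
  stopifnot(all(c("region_id", "level", "continent") %in% names(regions)))
  if (anyDuplicated(regions$region_id)) stop("region_id must be unique")
  if (!all(regions$level %in% c("country", "continent", "global"))) {
    stop("level must be one of country, continent, global")
  }
  no_cont <- regions$level == "country" & (is.na(regions$continent) | !nzchar(regions$continent))
  if (any(no_cont)) {
    stop("every country needs a continent: ", paste(regions$region_id[no_cont], collapse = ", "))
  }
  regions
}

#' @rdname region_registry
#' @export
product_registry <- function(products) {
  products <- as_tibble(products)
  stopifnot(all(c("product_id", "category", "is_animal_product", "has_composition") %in% names(products)))
  if (anyDuplicated(products$product_id)) stop("product_id must be unique")
  bad_cat <- !products$category %in% FOOD_CATEGORIES
  if (any(bad_cat)) {
    stop("unknown categories: ", paste(unique(products$category[bad_cat]), collapse = ", "))
  }
  mismatch <- xor(products$is_animal_product, products$category %in% ANIMAL_CATEGORIES)
  if (any(mismatch)) {
    stop(
      "is_animal_product inconsistent with category for: ",
      paste(products$product_id[mismatch], collapse = ", ")
    )
  }
  products
}
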