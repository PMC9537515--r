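# Readers and writers for the long-format input tables.
#
# Production, trade and environmental tables travel in the long export style
# of agricultural statistics portals (Area, Item, Element, Year, Unit, Value);
# the remaining tables (loss/waste fractions, livestock diets and
# populations, composition, requirements, pyramids, crosswalks) are tidy CSV.

TABLE_SCHEMAS <- list(
  production = list(
    cols = c(region = "Area", product = "Item", year = "Year", unit = "Unit", value = "Value"),
    elements = c(tonnes = "Production"),
    nonneg = "tonnes"
  ),
  trade = list(
    cols = c(region = "Area", product = "Item", year = "Year", unit = "Unit", value = "Value"),
    elements = c(import_tonnes = "Import Quantity", export_tonnes = "Export Quantity"),
    nonneg = c("import_tonnes", "export_tonnes")
  ),
  environment = list(
    cols = c(region = "Area", year = "Year", unit = "Unit", value = "Value"),
    elements = c(
      ch4 = "Emissions (CH4)", n2o = "Emissions (N2O)",
      co2eq = "Emissions (CO2eq)", water_withdrawal = "Water withdrawal"
    ),
    nonneg = c("ch4", "n2o", "co2eq", "water_withdrawal")
  )
)

#' Read a long-format input table
#'
#' Reads one of the long-format (`Area`/`Item`/`Element`/`Year`/`Value`)
#' input tables and pivots it to a typed tidy table. Schema violations
#' (missing columns, negative quantities, duplicate keys) raise errors that
#' report the offending rows.
#'
#' @param path Path to a CSV file.
#' @param schema One of `"production"`, `"trade"`, `"environment"`.
#' @return A tidy tibble; e.g. `production` has columns
#'   `region`, `product`, `year`, `tonnes` (names, not yet crosswalked).
#' @export
read_long_table <- function(path, schema = c("production", "trade", "environment")) {
  schema <- match.arg(schema)
  sch <- TABLE_SCHEMAS[[schema]]
  raw <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(c(unname(sch$cols), "Element"), names(raw))
  missing_cols <- setdiff(missing_cols, "Unit")
  if (length(missing_cols)) {
    stop("schema error reading ", path, ": missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(unique(raw$Element), unname(sch$elements))
  if (length(unknown)) {
    stop("schema error reading ", path, ": unknown Element value(s) ", paste(unknown, collapse = ", "))
  }
  bad <- which(!is.finite(raw$Value) | raw$Value < 0)
  if (length(bad)) {
    stop(
      "validation error reading ", path, ": negative or non-finite Value at data row(s) ",
      paste(utils::head(bad, 5L), collapse = ", ")
    )
  }
  long <- tibble(
    region = as.character(raw[[sch$cols[["region"]]]]),
    year = as.integer(raw[[sch$cols[["year"]]]]),
    element = names(sch$elements)[match(raw$Element, sch$elements)],
    value = as.numeric(raw$Value)
  )
  if ("product" %in% names(sch$cols)) {
    long$product <- as.character(raw[[sch$cols[["product"]]]])
  }
  keys <- intersect(c("region", "product", "year", "element"), names(long))
  if (anyDuplicated(long[keys])) {
    stop("validation error reading ", path, ": duplicate (region, product, year, element) rows")
  }
  out <- tidyr::pivot_wider(
    long,
    names_from = "element", values_from = "value",
    values_fill = 0
  )
  for (el in names(sch$elements)) if (!el %in% names(out)) out[[el]] <- 0
  dplyr::relocate(out, dplyr::any_of(c("region", "product", "year")))
}

#' Write a typed table back to its long format
#'
#' Inverse of [read_long_table()]; `write_long_table()` followed by
#' [read_long_table()] round-trips losslessly.
#'
#' @param tbl A tidy table as returned by [read_long_table()].
#' @param path Output CSV path.
#' @param schema One of `"production"`, `"trade"`, `"environment"`.
#' @param units Named character vector mapping element column to its unit
#'   string (written to the `Unit` column).
#' @return `path`, invisibly.
#' @export
write_long_table <- function(tbl, path, schema = c("production", "trade", "environment"),
                             units = NULL) {
  schema <- match.arg(schema)
  sch <- TABLE_SCHEMAS[[schema]]
  long <- tidyr::pivot_longer(
    tbl,
    cols = all_of(names(sch$elements)),
    names_to = "element", values_to = "Value"
  )
  out <- tibble(
    Area = long$region,
    Year = long$year,
    Element = unname(sch$elements[long$element]),
    Unit = if (is.null(units)) "unit" else unname(units[long$element]),
    Value = long$Value
  )
  if ("product" %in% names(long)) out <- mutate(out, Item = long$product, .after = "Area")
  readr::write_csv(out, path)
  invisible(path)
}

#' Read or write a tidy CSV table with schema validation
#'
#' Plain tidy-CSV transport for the tables that do not use the long
#' statistical-portal layout; validates that
#' the named columns are present and that quantity columns are non-negative.
#'
#' @param path CSV path.
#' @param required Character vector of required column names.
#' @param nonneg Columns that must be finite and `>= 0`.
#' @return A tibble.
#' @export
read_tidy_table <- function(path, required = character(), nonneg = character()) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols)) {
    stop("schema error reading ", path, ": missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  for (cc in nonneg) {
    bad <- which(!is.finite(tbl[[cc]]) | tbl[[cc]] < 0)
    if (length(bad)) {
      stop(
        "validation error reading ", path, ": negative or non-finite '", cc,
        "' at row(s) ", paste(utils::head(bad, 5L), collapse = ", ")
      )
    }
  }
  tbl
}
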