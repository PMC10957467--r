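#' Default column schema for a smoking panel CSV
#'
#' Maps the canonical field names used throughout the package to the column
#' names expected in an input CSV. Exports of country-year smoking estimates
#' vary in their headers, so every reader takes a schema argument; override
#' individual entries to adapt to a particular file.
#'
#' @param ... Named overrides, e.g. `smokers = "val_current"`.
#'
#' @return Named character vector with entries `country`, `year`, `age_band`,
#'   `smokers`, `population`, `former`, `ever`.
#' @export
#' @examples
#' default_panel_schema(smokers = "n_current")
default_panel_schema <- function(...) {
  schema <- c(
    country = "country", year = "year", age_band = "age_band",
    smokers = "smokers", population = "population",
    former = "former", ever = "ever"
  )
  overrides <- c(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(schema))
    if (length(bad)) {
      stop("unknown schema field(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    schema[names(overrides)] <- overrides
  }
  schema
}

#' Age bands used in the analysis
#'
#' The panel carries two age bands: 10-24 (initiation ages, the current-smoker
#' outcomes) and 45-59 (cessation ages, the quit-ratio outcome).
#' @keywords internal
age_bands <- function() c("10-24", "45-59")

#' Read and validate a country-year smoking panel
#'
#' Reads a long-format CSV with one row per (country, year, age band) holding
#' counts of current smokers and population, plus former and ever smokers for
#' the cessation band. All rows are validated against the panel invariants;
#' violations are reported with the offending row numbers.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Column map, see [default_panel_schema()].
#'
#' @return A tibble with columns `country_id`, `year`, `age_band`,
#'   `current_smokers`, `population`, `former_smokers`, `ever_smokers`.
#' @export
read_panel <- function(path, schema = default_panel_schema()) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(unname(schema), names(raw))
  if (length(missing)) {
    stop("panel is missing required column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  panel <- tibble::tibble(
    country_id = as.character(raw[[schema[["country"]]]]),
    year = as.integer(raw[[schema[["year"]]]]),
    age_band = as.character(raw[[schema[["age_band"]]]]),
    current_smokers = as.numeric(raw[[schema[["smokers"]]]]),
    population = as.numeric(raw[[schema[["population"]]]]),
    former_smokers = as.numeric(raw[[schema[["former"]]]]),
    ever_smokers = as.numeric(raw[[schema[["ever"]]]])
  )
  validate_panel(panel)
}

#' Validate panel invariants
#'
#' Checks non-negative counts, smokers within population, former within ever,
#' and uniqueness of (country, year, age band). Violations raise an error
#' naming the rule and the offending row numbers.
#'
#' @param panel A panel tibble as returned by [read_panel()].
#' @return The panel, invisibly validated (returned unchanged).
#' @export
validate_panel <- function(panel) {
  required <- c(
    "country_id", "year", "age_band", "current_smokers", "population",
    "former_smokers", "ever_smokers"
  )
  missing <- setdiff(required, names(panel))
  if (length(missing)) {
    stop("panel is missing required column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  fail <- function(rule, rows) {
    stop(
      sprintf(
        "panel validation failed [%s] at row(s): %s", rule,
        paste(utils::head(rows, 20), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  counts <- c("current_smokers", "population", "former_smokers", "ever_smokers")
  for (col in counts) {
    bad <- which(!is.na(panel[[col]]) & panel[[col]] < 0)
    if (length(bad)) fail(paste0("negative ", col), bad)
  }
  bad <- which(panel$current_smokers > panel$population)
  if (length(bad)) fail("current_smokers > population", bad)
  bad <- which(!is.na(panel$former_smokers) & !is.na(panel$ever_smokers) &
    panel$former_smokers > panel$ever_smokers)
  if (length(bad)) fail("former_smokers > ever_smokers", bad)
  key <- paste(panel$country_id, panel$year, panel$age_band, sep = "\r")
  bad <- which(duplicated(key))
  if (length(bad)) fail("duplicated (country, year, age_band)", bad)
  tibble::as_tibble(panel)
}

#' Write a validated panel to CSV
#'
#' Inverse of [read_panel()] under the default schema: writing then reading
#' reproduces the records exactly.
#'
#' @param panel Panel tibble.
#' @param path Output CSV path.
#' @param schema Column map used for the output header.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, schema = default_panel_schema()) {
  out <- panel
  names(out) <- c(
    schema[["country"]], schema[["year"]], schema[["age_band"]],
    schema[["smokers"]], schema[["population"]], schema[["former"]],
    schema[["ever"]]
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a country metadata table
#'
#' One row per country: ratification year, World Bank income group, tobacco
#' tax share of the most-sold brand in 2008 and its 2008-2012 change in
#' percentage points, and the number of survey years available 1990-2020
#' (used as a data-quality flag). Missing ratification or tax fields are
#' allowed and handled downstream.
#'
#' @param path Path to a CSV with columns `country`, `ratification_year`,
#'   `income_group`, `tax_share_2008`, `tax_change_pp`, `survey_years_count`
#'   (the last four optional).
#' @return A tibble with canonical column names.
#' @export
read_country_meta <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"country" %in% names(raw)) {
    stop("meta table is missing required column: country", call. = FALSE)
  }
  n <- nrow(raw)
  grab <- function(col, default, as = as.numeric) {
    if (col %in% names(raw)) as(raw[[col]]) else rep(default, n)
  }
  meta <- tibble::tibble(
    country_id = as.character(raw$country),
    ratification_year = grab("ratification_year", NA_integer_, as.integer),
    income_group = grab("income_group", NA_character_, as.character),
    tax_share_2008 = grab("tax_share_2008", NA_real_),
    tax_change_pp = grab("tax_change_pp", NA_real_),
    survey_years_count = grab("survey_years_count", NA_integer_, as.integer)
  )
  validate_country_meta(meta)
}

income_groups <- function() c("high", "upper-middle", "lower-middle", "low")

validate_country_meta <- function(meta) {
  bad <- which(!is.na(meta$income_group) &
    !meta$income_group %in% income_groups())
  if (length(bad)) {
    stop(
      "income_group must be one of ", paste(income_groups(), collapse = ", "),
      "; offending row(s): ", paste(utils::head(bad, 20), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(meta$country_id)) {
    stop("duplicated country_id in meta table", call. = FALSE)
  }
  tibble::as_tibble(meta)
}

#' Classify countries by tobacco tax change
#'
#' A country is a high-tax-change country when the total tax share of the
#' retail price of its most-sold cigarette brand rose by 10 or more
#' percentage points between 2008 and 2012; low otherwise (including
#' decreases); unclassified when tax data are absent.
#'
#' @param meta Country metadata tibble with a `tax_change_pp` column.
#' @return `meta` with an added `tax_group` column, one of
#'   `"high"`, `"low"`, `"unclassified"`.
#' @export
#' @examples
#' meta <- tibble::tibble(country_id = c("A", "B", "C"),
#'                        tax_change_pp = c(10, -3, NA))
#' classify_tax_change(meta)$tax_group
classify_tax_change <- function(meta) {
  dplyr::mutate(
    meta,
    tax_group = dplyr::case_when(
      is.na(.data$tax_change_pp) ~ "unclassified",
      .data$tax_change_pp >= 10 ~ "high",
      TRUE ~ "low"
    )
  )
}

#' Filter countries by survey coverage
#'
#' Keeps countries with strictly more than `min_surveys` survey years in the
#' covered period — the high-quality-data flag (more than ten surveys in
#' 1990-2020 under the defaults).
#'
#' @param meta Country metadata tibble.
#' @param min_surveys Strict lower bound on `survey_years_count` (default 10).
#' @return The qualifying rows of `meta`.
#' @export
filter_quality <- function(meta, min_surveys = 10) {
  stopifnot(min_surveys >= 0)
  dplyr::filter(
    meta,
    !is.na(.data$survey_years_count), .data$survey_years_count > min_surveys
  )
}

#' Build a country grouping scheme
#'
#' Assigns countries to analysis groups. Schemes: `"world"` (one group,
#' excluding the configured countries, by default China), `"income"` (four
#' World Bank income groups), `"tax"` (high vs low tax change among countries
#' with tax data), `"country"` (each country its own group). Countries without
#' a ratification year, and countries ratifying too late for a full post
#' window (`ratification_year > last_data_year - post_window`), are excluded
#' with a recorded reason; group membership is then fixed across all event
#' times.
#'
#' @param meta Country metadata tibble.
#' @param scheme One of `"world"`, `"income"`, `"tax"`, `"country"`.
#' @param exclude Country ids excluded from the `world` scheme
#'   (default `"CHN"`; analyzed separately with `scheme = "country"`).
#' @param last_data_year Final calendar year available in the panel.
#' @param post_window Post-ratification years required (default 10).
#' @return A tibble with columns `group`, `country_id`; excluded countries are
#'   attached as a tibble in `attr(, "exclusions")` with columns `country_id`,
#'   `reason`.
#' @export
build_grouping <- function(meta, scheme = c("world", "income", "tax", "country"),
                           exclude = "CHN", last_data_year = 2020,
                           post_window = 10) {
  scheme <- match.arg(scheme)
  excl <- tibble::tibble(country_id = character(), reason = character())
  note <- function(ids, reason) {
    if (length(ids)) {
      excl <<- dplyr::bind_rows(excl, tibble::tibble(country_id = ids, reason = reason))
    }
  }

  m <- meta
  ids <- m$country_id[is.na(m$ratification_year)]
  note(ids, "no ratification year")
  m <- dplyr::filter(m, !is.na(.data$ratification_year))

  late <- m$country_id[m$ratification_year > last_data_year - post_window]
  note(late, sprintf("ratified after %d (incomplete post window)", last_data_year - post_window))
  m <- dplyr::filter(m, .data$ratification_year <= last_data_year - post_window)

  if (scheme == "world") {
    note(intersect(exclude, m$country_id), "configured world exclusion")
    m <- dplyr::filter(m, !.data$country_id %in% exclude)
    members <- tibble::tibble(group = "world", country_id = m$country_id)
  } else if (scheme == "income") {
    note(intersect(exclude, m$country_id), "configured exclusion")
    m <- dplyr::filter(m, !.data$country_id %in% exclude)
    ids <- m$country_id[is.na(m$income_group)]
    note(ids, "no income group")
    m <- dplyr::filter(m, !is.na(.data$income_group))
    members <- tibble::tibble(group = m$income_group, country_id = m$country_id)
  } else if (scheme == "tax") {
    note(intersect(exclude, m$country_id), "configured exclusion")
    m <- dplyr::filter(m, !.data$country_id %in% exclude)
    m <- classify_tax_change(m)
    ids <- m$country_id[m$tax_group == "unclassified"]
    note(ids, "no tax data")
    m <- dplyr::filter(m, .data$tax_group != "unclassified")
    members <- tibble::tibble(
      group = paste0(m$tax_group, "-tax-change"), country_id = m$country_id
    )
  } else {
    members <- tibble::tibble(group = m$country_id, country_id = m$country_id)
  }

  if (nrow(members) == 0 ||
    any(tapply(members$country_id, members$group, length) == 0)) {
    stop("grouping scheme '", scheme, "' produced an empty group", call. = FALSE)
  }
  members <- dplyr::arrange(members, .data$group, .data$country_id)
  attr(members, "exclusions") <- excl
  attr(members, "scheme") <- scheme
  members
}
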