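#' Category fractions over a set of deaths
#'
#' The fraction of deaths assigned to each category — cause-specific
#' mortality fractions (CSMFs) when applied to causes, the COMCAT
#' distribution when applied to circumstance categories. The categories in
#' `category` form a complete partition (derived categories such as
#' `"multiple"` and `"indeterminate"` included), so the fractions sum to 1.
#'
#' @param outputs A data frame of per-death outputs (e.g. `va_results`).
#' @param category Name of the category column (default `"comcat"`).
#' @return A tibble `category`, `n`, `fraction`, ordered by first
#'   appearance of each category.
#' @export
category_fractions <- function(outputs, category = "comcat") {
  outputs <- tibble::as_tibble(outputs)
  if (nrow(outputs) == 0L) abort("no deaths: cannot compute fractions")
  if (!category %in% names(outputs)) {
    abort(paste0("column '", category, "' not found"))
  }
  outputs |>
    dplyr::count(category = .data[[category]], name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
}

#' Sex composition within each category
#'
#' Within each assigned category, the fraction of deaths of the given sex.
#' Deaths of unknown sex are excluded from the denominator (their count is
#' reported in the `n_unknown` column); categories with no deaths of known
#' sex are omitted.
#'
#' @param outputs A data frame of per-death outputs with a `sex` column.
#' @param category Name of the category column.
#' @param sex_value Sex whose share is reported (default `"male"`).
#' @return A tibble `category`, `n`, `n_unknown`, `fraction`.
#' @export
sex_fraction_by_category <- function(outputs, category = "comcat",
                                     sex_value = "male") {
  outputs <- tibble::as_tibble(outputs)
  outputs |>
    dplyr::group_by(category = .data[[category]]) |>
    dplyr::summarise(
      n = sum(.data$sex %in% c("female", "male")),
      n_unknown = sum(!.data$sex %in% c("female", "male")),
      fraction = sum(.data$sex == sex_value) / n,
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n > 0L)
}

#' Read person-year denominators from CSV
#'
#' @param path CSV with columns `age_band`, `sex`, `year` (or `"all"`) and
#'   `person_years`.
#' @return A tibble with those columns; `year` kept as character so the
#'   `"all"` stratum is representable.
#' @export
read_person_years <- function(path) {
  py <- readr::read_csv(path, col_types = readr::cols(
    age_band = "c", sex = "c", year = "c", person_years = "d"
  ), progress = FALSE)
  if (any(py$person_years < 0, na.rm = TRUE)) abort("negative person-years")
  py
}

#' Stratum-specific mortality rates
#'
#' Deaths per `per` person-years in each (stratum, category) cell:
#' `rate = per * deaths / person_years`. Strata are whatever key columns
#' `counts` and `person_years` share (typically `age_band`, `sex` and
#' optionally `year`). Cells with deaths but no (or zero) exposure are a
#' hard error naming the stratum; strata with exposure but no deaths get
#' rate 0.
#'
#' @param counts Data frame with stratum columns, a `category` column and a
#'   death count column `n`.
#' @param person_years Data frame with the same stratum columns and a
#'   `person_years` column.
#' @param per Rate scale (default 1000 person-years).
#' @return A tibble: stratum columns, `category`, `n`, `person_years`,
#'   `rate`.
#' @export
stratum_rates <- function(counts, person_years, per = 1000) {
  counts <- tibble::as_tibble(counts)
  person_years <- tibble::as_tibble(person_years)
  keys <- intersect(setdiff(names(counts), c("category", "n")),
                    setdiff(names(person_years), "person_years"))
  if (length(keys) == 0L) abort("counts and person_years share no stratum columns")
  joined <- dplyr::full_join(
    counts,
    dplyr::summarise(dplyr::group_by(person_years,
                                     dplyr::across(dplyr::all_of(keys))),
                     person_years = sum(.data$person_years), .groups = "drop"),
    by = keys
  )
  joined$n[is.na(joined$n)] <- 0L
  bad <- joined$n > 0 & (is.na(joined$person_years) | joined$person_years <= 0)
  if (any(bad)) {
    b <- joined[bad, keys, drop = FALSE][1L, ]
    abort(paste0("deaths in a stratum with no exposure: ",
                 paste(names(b), unlist(lapply(b, as.character)),
                       sep = "=", collapse = ", ")))
  }
  joined |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::mutate(rate = per * .data$n / .data$person_years)
}

#' Directly standardised rates
#'
#' Direct standardisation: each category's standardised rate is the
#' weighted sum of its stratum-specific rates, \eqn{\sum_s w_s r_{s}},
#' with weights over the age/sex strata summing to 1. With
#' `weights = NULL` the rates are *internally* standardised: the weights
#' are the whole dataset's own person-year distribution across the strata
#' (or its death-count distribution with `internal = "deaths"`). Strata
#' present in the weights but missing a rate for some category contribute
#' rate 0 with a warning. Being a convex combination, every standardised
#' rate lies between the minimum and maximum stratum rate of its category.
#'
#' @param rates Output of [stratum_rates()].
#' @param weights Optional data frame: stratum columns plus `weight`
#'   (non-negative, summing to 1).
#' @param internal `"person_years"` (default) or `"deaths"`: which internal
#'   distribution supplies the weights when `weights` is `NULL`.
#' @return A tibble `category`, `std_rate`.
#' @export
standardize_rates <- function(rates, weights = NULL,
                              internal = c("person_years", "deaths")) {
  internal <- match.arg(internal)
  rates <- tibble::as_tibble(rates)
  keys <- setdiff(names(rates), c("category", "n", "person_years", "rate"))
  if (is.null(weights)) {
    if (internal == "person_years") {
      w <- rates |>
        dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
        dplyr::summarise(person_years = .data$person_years[1L],
                         .groups = "drop")
      w$weight <- w$person_years / sum(w$person_years)
    } else {
      w <- rates |>
        dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
        dplyr::summarise(weight = sum(.data$n), .groups = "drop")
      w$weight <- w$weight / sum(w$weight)
    }
    weights <- w[, c(keys, "weight")]
  } else {
    weights <- tibble::as_tibble(weights)
    if (any(weights$weight < 0)) abort("negative standard weight")
    if (abs(sum(weights$weight) - 1) > 1e-9) {
      abort("standard weights must sum to 1")
    }
  }
  wkeys <- setdiff(names(weights), "weight")
  grid <- tidyr::expand_grid(
    weights,
    category = unique(rates$category)
  )
  joined <- dplyr::left_join(grid, rates[, c(wkeys, "category", "rate")],
                             by = c(wkeys, "category"))
  if (anyNA(joined$rate)) {
    warn(paste0(sum(is.na(joined$rate)),
                " weighted stratum-category cell(s) lack a rate; treated as 0"))
    joined$rate[is.na(joined$rate)] <- 0
  }
  joined |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(std_rate = sum(.data$weight * .data$rate),
                     .groups = "drop")
}

#' Map fine cause labels to broad groups
#'
#' Deterministic lookup of each cause label in a user-editable grouping
#' table (broad groups such as infections, cancer, cardiovascular, other
#' NCD, injuries, pregnancy/neonatal, indeterminate). Labels absent from
#' the table map to `"ungrouped"` with a warning.
#'
#' @param cause_label Character vector of cause labels.
#' @param grouping_table Data frame with columns `cause_label`,
#'   `broad_group`; see [read_broad_cause_groups()].
#' @return Character vector of broad group tokens, same length as input.
#' @export
broad_cause_grouping <- function(cause_label, grouping_table) {
  grouping_table <- tibble::as_tibble(grouping_table)
  hit <- match(cause_label, grouping_table$cause_label)
  out <- grouping_table$broad_group[hit]
  n_miss <- sum(is.na(hit) & !is.na(cause_label))
  if (n_miss > 0L) {
    warn(paste0(n_miss, " cause label(s) not in grouping table; mapped to 'ungrouped'"))
  }
  out[is.na(hit) & !is.na(cause_label)] <- "ungrouped"
  out
}

#' Read a cause grouping table
#'
#' @param path CSV with columns `cause_label`, `broad_group`. The packaged
#'   illustrative table is at
#'   `system.file("extdata", "broad_cause_groups.csv", package = "vacomcat")`.
#' @return A tibble `cause_label`, `broad_group`.
#' @export
read_broad_cause_groups <- function(path) {
  readr::read_csv(path, col_types = readr::cols(cause_label = "c",
                                                broad_group = "c"),
                  progress = FALSE)
}

#' COMCATs ranked within each broad cause group
#'
#' For each broad cause-of-death group, the assigned COMCATs in descending
#' order of death count, with proportions within the group. Count ties are
#' broken by the canonical COMCAT order ([comcat_categories()], then
#' `"multiple"`).
#'
#' @param outputs Per-death outputs carrying both a broad-cause column and
#'   a COMCAT column.
#' @param cause_col Name of the broad-cause column (default `"broad_cause"`).
#' @param comcat_col Name of the COMCAT column (default `"comcat"`).
#' @return A tibble `broad_cause`, `comcat`, `n`, `proportion`, `rank`,
#'   ranked within group.
#' @export
comcat_by_cause_ranking <- function(outputs, cause_col = "broad_cause",
                                    comcat_col = "comcat") {
  outputs <- tibble::as_tibble(outputs)
  canon <- c(comcat_categories(), "multiple")
  outputs |>
    dplyr::count(broad_cause = .data[[cause_col]],
                 comcat = .data[[comcat_col]]) |>
    dplyr::group_by(.data$broad_cause) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$n), match(.data$comcat, canon),
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}
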