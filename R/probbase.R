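#' The six assignable COMCAT labels
#'
#' Circumstances Of Mortality CATegories, in canonical order: traditions,
#' emergencies, recognition, resources, health systems, inevitability.
#' The seventh category, `"multiple"`, is a derived output of the dominance
#' rule (no single category predominated), never a probbase column. The
#' labels use the revised terms "traditions" and "recognition" (formerly
#' "culture" and "knowledge").
#'
#' @return Character vector of six labels.
#' @export
comcat_categories <- function() {
  c("traditions", "emergencies", "recognition", "resources",
    "health_systems", "inevitability")
}

#' Construct a probability base
#'
#' A probbase links indicator responses to categories: a prior probability
#' per category and, for each (indicator, substantive response) pair, the
#' conditional probability of that response given each category. A probbase
#' may omit the `no` row of an indicator, in which case `no` responses to it
#' are non-informative (skipped, like missing).
#'
#' @param categories Character vector of category labels (unique, non-empty).
#' @param prior Numeric prior over categories, in `[0,1]`; normalised to sum
#'   to 1 (the pre-normalisation sum is kept in the load report).
#' @param cond Tibble with columns `indicator`, `response` (`"yes"`/`"no"`),
#'   `category`, `prob` in `[0,1]`; every (indicator, response) pair present
#'   for one category must be present for all (rectangularity).
#' @param set_name Token naming the category set (e.g. `"comcats"`).
#' @return An object of class `va_probbase`.
#' @export
probbase <- function(categories, prior, cond, set_name = "categories") {
  categories <- as.character(categories)
  if (length(categories) == 0L) abort("empty category set")
  if (anyDuplicated(categories) || any(categories == "")) {
    abort("category labels must be unique and non-empty")
  }
  if (is.null(names(prior))) names(prior) <- categories
  prior <- prior[categories]
  if (anyNA(prior) || any(prior < 0 | prior > 1)) {
    abort("prior probabilities must all lie in [0,1]")
  }
  raw_sum <- sum(prior)
  if (raw_sum <= 0) abort("prior has zero total mass")
  prior <- prior / raw_sum

  cond <- tibble::as_tibble(cond)
  stopifnot(all(c("indicator", "response", "category", "prob") %in% names(cond)))
  if (!all(cond$response %in% c("yes", "no"))) {
    abort("cond responses must be 'yes' or 'no'")
  }
  if (!all(cond$category %in% categories)) {
    bad <- setdiff(unique(cond$category), categories)
    abort(paste0("cond references unknown categories: ", paste(bad, collapse = ", ")))
  }
  if (anyNA(cond$prob) || any(cond$prob < 0 | cond$prob > 1)) {
    i <- which(is.na(cond$prob) | cond$prob < 0 | cond$prob > 1)[1L]
    abort(sprintf("probability out of range at (%s, %s, %s)",
                  cond$indicator[i], cond$response[i], cond$category[i]))
  }
  counts <- dplyr::count(cond, .data$indicator, .data$response)
  if (any(counts$n != length(categories))) {
    bad <- counts[counts$n != length(categories), ]
    abort(sprintf("ragged probbase: (%s, %s) has %d of %d categories",
                  bad$indicator[1L], bad$response[1L], bad$n[1L],
                  length(categories)))
  }
  if (anyDuplicated(cond[, c("indicator", "response", "category")])) {
    abort("duplicate (indicator, response, category) cell in probbase")
  }
  cond <- dplyr::arrange(cond, .data$indicator, .data$response,
                         match(.data$category, categories))
  cond <- tibble::tibble(indicator = as.character(cond$indicator),
                         response = as.character(cond$response),
                         category = as.character(cond$category),
                         prob = as.numeric(cond$prob))
  structure(
    list(set_name = set_name, categories = categories, prior = prior,
         cond = cond, prior_raw_sum = raw_sum, symbol_cells = 0L),
    class = "va_probbase"
  )
}

#' @export
print.va_probbase <- function(x, ...) {
  cat(sprintf("<va_probbase '%s': %d categories, %d indicator rows>\n",
              x$set_name, length(x$categories),
              nrow(dplyr::distinct(x$cond, .data$indicator, .data$response))))
  invisible(x)
}

#' Read a probbase from CSV
#'
#' Expected layout: header `indicator,response,<cat1>,...,<catK>`; one row
#' with the reserved indicator token `_prior` holding the category priors;
#' one row per (indicator, response) pair. Cells are numerals in `[0,1]` or
#' grade symbols resolved through `symbol_table`. No default symbol table is
#' assumed: probbases authored with letter grades must supply one.
#'
#' @param path Path to the probbase CSV.
#' @param symbol_table Optional named numeric vector (or two-column data
#'   frame `symbol`, `value`) mapping grade symbols to probabilities.
#' @param set_name Name for the category set.
#' @return A `va_probbase`; the count of symbol-resolved cells is available
#'   as `$symbol_cells`, the pre-normalisation prior sum as `$prior_raw_sum`.
#' @export
read_probbase <- function(path, symbol_table = NULL, set_name = "categories") {
  if (!file.exists(path)) abort(paste0("probbase file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("indicator", "response") %in% names(raw))) {
    abort("probbase CSV must start with 'indicator,response' columns")
  }
  categories <- setdiff(names(raw), c("indicator", "response"))
  if (length(categories) == 0L) abort("probbase CSV has no category columns")
  if (anyNA(raw[categories])) abort("ragged probbase CSV: empty cell found")

  if (is.data.frame(symbol_table)) {
    symbol_table <- setNames(as.numeric(symbol_table$value),
                             as.character(symbol_table$symbol))
  }
  n_symbols <- 0L
  resolve <- function(cells, where) {
    num <- suppressWarnings(as.numeric(cells))
    sym <- is.na(num)
    if (any(sym)) {
      if (is.null(symbol_table)) {
        abort(paste0("symbol '", cells[sym][1L], "' in ", where,
                     " but no symbol table supplied"))
      }
      hit <- match(cells[sym], names(symbol_table))
      if (anyNA(hit)) {
        abort(paste0("unresolvable symbol '", cells[sym][is.na(hit)][1L],
                     "' in ", where))
      }
      num[sym] <- unname(symbol_table[hit])
      n_symbols <<- n_symbols + sum(sym)
    }
    num
  }

  is_prior <- raw$indicator == "_prior"
  if (sum(is_prior) != 1L) abort("probbase must contain exactly one '_prior' row")
  prior <- resolve(unlist(raw[is_prior, categories]), "'_prior' row")
  if (any(prior < 0 | prior > 1)) {
    j <- which(prior < 0 | prior > 1)[1L]
    abort(sprintf("probability out of range at (_prior, %s)", categories[j]))
  }
  names(prior) <- categories

  body <- raw[!is_prior, , drop = FALSE]
  cond <- tidyr::pivot_longer(body, dplyr::all_of(categories),
                              names_to = "category", values_to = "cell")
  cond$response <- tolower(trimws(cond$response))
  cond$prob <- resolve(cond$cell, "probbase body")
  bad <- which(cond$prob < 0 | cond$prob > 1)
  if (length(bad) > 0L) {
    i <- bad[1L]
    abort(sprintf("probability out of range at (%s, %s, %s)",
                  cond$indicator[i], cond$response[i], cond$category[i]))
  }
  pb <- probbase(categories, prior,
                 cond[, c("indicator", "response", "category", "prob")],
                 set_name = set_name)
  pb$symbol_cells <- n_symbols
  pb
}

#' Write a probbase to CSV
#'
#' Inverse of [read_probbase()]: reading the written file reconstructs an
#' identical probbase (priors are written already normalised).
#'
#' @param pb A `va_probbase`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_probbase <- function(pb, path) {
  wide <- tidyr::pivot_wider(pb$cond, names_from = "category",
                             values_from = "prob")
  prior_row <- tibble::as_tibble(c(list(indicator = "_prior", response = ""),
                                   as.list(pb$prior)))
  readr::write_csv(dplyr::bind_rows(prior_row, wide), path)
  invisible(path)
}

#' Cross-validate a probbase against an indicator dictionary
#'
#' Reporting only, never an error: lists indicators present on one side
#' only, categories no response supports (unreachable: every conditional
#' probability zero) and non-discriminative rows (identical value for every
#' category, so the row can never move the posterior).
#'
#' @param pb A `va_probbase`.
#' @param dictionary A `va_dictionary`.
#' @return A list with `indicators_not_in_dictionary`,
#'   `indicators_not_in_probbase`, `unreachable_categories`,
#'   `constant_rows` (tibble `indicator`, `response`), and `ok` (TRUE when
#'   all four are empty).
#' @export
validate_probbase <- function(pb, dictionary) {
  pb_ind <- unique(pb$cond$indicator)
  only_pb <- setdiff(pb_ind, dictionary$id)
  only_dict <- setdiff(dictionary$id, pb_ind)
  col_max <- dplyr::summarise(dplyr::group_by(pb$cond, .data$category),
                              m = max(.data$prob), .groups = "drop")
  unreachable <- col_max$category[col_max$m == 0]
  rows <- dplyr::summarise(
    dplyr::group_by(pb$cond, .data$indicator, .data$response),
    constant = max(.data$prob) == min(.data$prob), .groups = "drop")
  constant_rows <- rows[rows$constant, c("indicator", "response")]
  list(
    indicators_not_in_dictionary = only_pb,
    indicators_not_in_probbase = only_dict,
    unreachable_categories = unreachable,
    constant_rows = constant_rows,
    ok = length(only_pb) == 0L && length(only_dict) == 0L &&
      length(unreachable) == 0L && nrow(constant_rows) == 0L
  )
}

#' Read a symbol table CSV
#'
#' @param path CSV with columns `symbol`, `value`.
#' @return Named numeric vector for use with [read_probbase()].
#' @export
read_symbol_table <- function(path) {
  st <- readr::read_csv(path, col_types = readr::cols(symbol = "c", value = "d"),
                        progress = FALSE)
  setNames(st$value, st$symbol)
}
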