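#' Default response token map
#'
#' Tokens are matched case-insensitively after trimming whitespace. Anything
#' not listed under `yes`, `no` or `missing` is coerced to `"missing"` and
#' counted in the ingest report: the engine consumes only substantive
#' responses, so "don't know" and "refused" are treated as missing.
#'
#' @return A named list with character vectors `yes`, `no`, `missing`.
#' @export
default_token_map <- function() {
  list(
    yes     = c("y", "yes", "1", "true"),
    no      = c("n", "no", "0", "false"),
    missing = c("", ".", "ref", "refused", "dk", "doesn't know", "nk", "na")
  )
}

#' Default age bands
#'
#' The five bands used for age/sex standardisation: under 5, 5--19, 20--49,
#' 50--69 and 70-plus years.
#'
#' @return Character vector of band labels.
#' @export
default_age_bands <- function() {
  c("<5", "5-19", "20-49", "50-69", "70+")
}

classify_token <- function(tok, token_map) {
  tok <- tolower(trimws(tok))
  tok[is.na(tok)] <- ""
  out <- rep(NA_character_, length(tok))
  out[tok %in% tolower(token_map$yes)] <- "yes"
  out[tok %in% tolower(token_map$no)] <- "no"
  out[tok %in% tolower(token_map$missing)] <- "missing"
  out
}

#' Read verbal autopsy records from a wide CSV
#'
#' The CSV must have a `record_id` column and one column per indicator id;
#' `age_group`, `sex` and `year` columns are used when present. Parsing is
#' total: every cell maps to exactly one of `"yes"`, `"no"`, `"missing"`.
#' Unrecognised tokens are coerced to missing and counted; unknown columns
#' (not in the dictionary, not demographic) are ignored with a warning;
#' rows repeating an earlier `record_id` are rejected. The ingest report is
#' attached as an attribute and retrieved with [va_ingest_report()].
#'
#' @param path Path to the records CSV.
#' @param dictionary A `va_dictionary`; only its indicator columns are read.
#' @param token_map Response token map, see [default_token_map()].
#' @param id_col Name of the record-id column (default `"record_id"`).
#' @return A tibble of class `va_records`: `record_id`, `age_group`, `sex`,
#'   `year`, then one character column per dictionary indicator present in
#'   the file, values in `{"yes","no","missing"}`.
#' @export
read_va_csv <- function(path, dictionary, token_map = default_token_map(),
                        id_col = "record_id") {
  if (!file.exists(path)) abort(paste0("records file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!id_col %in% names(raw)) {
    abort(paste0("records CSV lacks the record-id column '", id_col, "'"))
  }
  demo_cols <- c("age_group", "sex", "year")
  ind_cols <- intersect(dictionary$id, names(raw))
  unknown_cols <- setdiff(names(raw), c(id_col, demo_cols, dictionary$id))
  if (length(unknown_cols) > 0L) {
    warn(paste0("ignoring ", length(unknown_cols), " unknown column(s): ",
                paste(head(unknown_cols, 5L), collapse = ", ")))
  }

  ids <- trimws(raw[[id_col]])
  dup_mask <- duplicated(ids) | ids == "" | is.na(ids)
  rejected_ids <- ids[dup_mask]
  kept <- raw[!dup_mask, , drop = FALSE]
  if (nrow(kept) == 0L) abort("zero parseable rows in records CSV")

  coercions <- 0L
  resp <- lapply(ind_cols, function(col) {
    cls <- classify_token(kept[[col]], token_map)
    coercions <<- coercions + sum(is.na(cls))
    cls[is.na(cls)] <- "missing"
    cls
  })
  names(resp) <- ind_cols

  out <- tibble::tibble(
    record_id = trimws(kept[[id_col]]),
    age_group = if ("age_group" %in% names(kept)) trimws(kept$age_group) else NA_character_,
    sex = if ("sex" %in% names(kept)) tolower(trimws(kept$sex)) else "unknown",
    year = if ("year" %in% names(kept)) suppressWarnings(as.integer(kept$year)) else NA_integer_
  )
  out$sex[!out$sex %in% c("female", "male")] <- "unknown"
  out <- dplyr::bind_cols(out, tibble::as_tibble(resp))

  report <- list(
    n_rows = nrow(raw),
    n_kept = nrow(out),
    n_rejected = length(rejected_ids),
    rejected_ids = rejected_ids,
    unknown_columns = unknown_cols,
    coercion_count = coercions,
    indicators_read = ind_cols
  )
  structure(out, class = c("va_records", class(out)), ingest_report = report)
}

#' Ingest report of a records table
#'
#' @param records A `va_records` tibble from [read_va_csv()] or
#'   [generate_records()].
#' @return A list: rows seen/kept/rejected, rejected ids, ignored columns,
#'   count of tokens coerced to missing.
#' @export
va_ingest_report <- function(records) {
  attr(records, "ingest_report")
}

#' Write per-death results to CSV
#'
#' One row per death: identifiers and demographics, the assigned COMCAT and
#' the six COMCAT likelihoods, then (when causes were processed) the ranked
#' causes with their likelihoods and the indeterminate residual. Numeric
#' columns survive a write/read round trip well beyond six decimal places.
#'
#' @param results A `va_results` tibble from [va_process()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  readr::write_csv(tibble::as_tibble(results), path, na = "")
  invisible(path)
}

#' Read a per-death results CSV back into a results tibble
#'
#' @param path Path to a CSV written by [write_results_csv()].
#' @return A `va_results` tibble.
#' @export
read_results_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("results file not found: ", path))
  out <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  for (nm in names(out)) {
    if (grepl("^comcat_lik_|_lik$|^indeterminate$", nm)) {
      out[[nm]] <- as.numeric(out[[nm]])
    } else if (nm == "year" || grepl("_updates$", nm)) {
      out[[nm]] <- as.integer(out[[nm]])
    } else if (grepl("_degenerate$", nm)) {
      out[[nm]] <- as.logical(out[[nm]])
    }
  }
  structure(out, class = c("va_results", class(out)))
}
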