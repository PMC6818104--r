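#' The ten circumstantial indicators of the WHO-2016 instrument
#'
#' Returns the indicator dictionary for the ten social and health-systems
#' circumstance items of the WHO-2016 verbal autopsy instrument
#' (`Id10450`--`Id10459`): travel to a facility, motorised transport,
#' problems at admission / with treatment / obtaining medications or tests,
#' distance over two hours, doubts that care was needed, use of traditional
#' medicine, use of a telephone to call for help, and prohibitive costs of
#' care. The `note` column records which substantive response carries the
#' circumstantial signal for each item.
#'
#' @return A tibble of class `va_dictionary` with columns `id`, `text`,
#'   `note`, one row per indicator, in instrument order.
#' @export
#' @examples
#' comcat_dictionary()
comcat_dictionary <- function() {
  dict <- tibble::tribble(
    ~id, ~text, ~note,
    "Id10450", "In the final days before death, did she/he travel to a hospital or health facility?",
    "'no' indicates no contact with hospital-level services in the days before death",
    "Id10451", "Did she/he use motorised transport to get to the hospital or health facility?",
    "'no' indicates no motorised transport to a facility during the final illness",
    "Id10452", "Were there any problems during admission to the hospital or health facility?",
    "'yes' indicates problems on arrival (delays, paperwork, queues, no staff)",
    "Id10453", "Were there any problems with the way she/he was treated in the hospital or health facility?",
    "'yes' indicates problems with medical treatment, procedures, attitudes, respect or dignity",
    "Id10454", "Were there any problems getting medications, or diagnostic tests in the hospital or health facility?",
    "'yes' indicates problems obtaining drugs, blood products or diagnostic tests",
    "Id10455", "Does it take more than 2 hours to get to the nearest hospital or health facility from the deceased's household?",
    "'yes' indicates the nearest 24-hour facility is over two hours away by available transport",
    "Id10456", "In the final days before death, were there any doubts about whether medical care was needed?",
    "'yes' indicates doubts among those assisting about whether facility care was needed",
    "Id10457", "In the final days before death, was traditional medicine used?",
    "'yes' indicates a major part of treatment came from a traditional or alternative practitioner",
    "Id10458", "In the final days before death, did anyone use a telephone or cell phone to call for help?",
    "'no' indicates no telephone of any kind was used to call for help or arrange transport",
    "Id10459", "Over the course of illness, did the total costs of care and treatment prohibit other household payments?",
    "'yes' indicates costs of the final illness crowded out other household expenses or caused debt"
  )
  new_va_dictionary(dict, dialect = "who2016")
}

new_va_dictionary <- function(x, dialect = "custom") {
  structure(x, class = c("va_dictionary", class(tibble::tibble())),
            dialect = dialect)
}

#' Read an indicator dictionary from CSV
#'
#' The dictionary CSV has columns `id`, `text` and optionally `note`. Under
#' the `"who2016"` dialect the ten circumstantial items `Id10450`--`Id10459`
#' must all be present; the `"custom"` dialect accepts any indicator set.
#'
#' @param path Path to a dictionary CSV.
#' @param dialect `"who2016"` or `"custom"`.
#' @return A `va_dictionary` tibble (columns `id`, `text`, `note`).
#' @export
read_dictionary <- function(path, dialect = c("who2016", "custom")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("dictionary file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0L) abort("no indicators: dictionary file is empty")
  if (!"id" %in% names(raw)) abort("dictionary CSV must have an 'id' column")
  if (!"text" %in% names(raw)) raw$text <- NA_character_
  if (!"note" %in% names(raw)) raw$note <- NA_character_
  raw$id <- trimws(raw$id)
  if (any(raw$id == "" | is.na(raw$id))) abort("dictionary contains empty indicator ids")
  dup <- unique(raw$id[duplicated(raw$id)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate indicator id(s) in dictionary: ",
                 paste(dup, collapse = ", ")))
  }
  dict <- dplyr::select(raw, "id", "text", "note")
  if (dialect == "who2016") {
    need <- comcat_dictionary()$id
    missing <- setdiff(need, dict$id)
    if (length(missing) > 0L) {
      abort(paste0("who2016 dialect requires circumstantial items; missing: ",
                   paste(missing, collapse = ", ")))
    }
  }
  new_va_dictionary(tibble::as_tibble(dict), dialect = dialect)
}

#' Write an indicator dictionary to CSV
#'
#' @param dictionary A `va_dictionary` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dictionary, path) {
  readr::write_csv(tibble::as_tibble(dictionary)[, c("id", "text", "note")], path)
  invisible(path)
}
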