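#' Tidy per-death results into a long posterior table
#'
#' @param x A `va_results` object from [va_process()].
#' @param ... Unused.
#' @return A tibble, one row per (death, COMCAT): `record_id`, `category`,
#'   `likelihood`, `degenerate`, `updates`, plus the assigned `comcat`.
#' @method tidy va_results
#' @export
tidy.va_results <- function(x, ...) {
  post <- attr(x, "comcat_posterior")
  if (is.null(post)) {
    post <- tibble::as_tibble(x) |>
      dplyr::select("record_id", dplyr::starts_with("comcat_lik_")) |>
      tidyr::pivot_longer(-"record_id", names_to = "category",
                          names_prefix = "comcat_lik_",
                          values_to = "likelihood")
  }
  dplyr::left_join(tibble::as_tibble(post),
                   tibble::as_tibble(x)[, c("record_id", "comcat")],
                   by = "record_id")
}

#' One-row summary of a processed dataset
#'
#' @param x A `va_results` object.
#' @param ... Unused.
#' @return A tibble with `n_deaths`, `n_multiple`, `multiple_rate`,
#'   `n_degenerate`, `mean_updates`, `max_likelihood_mean`.
#' @method glance va_results
#' @export
glance.va_results <- function(x, ...) {
  lik <- as.matrix(tibble::as_tibble(x)[, grep("^comcat_lik_", names(x))])
  tibble::tibble(
    n_deaths = nrow(x),
    n_multiple = sum(x$comcat == "multiple"),
    multiple_rate = mean(x$comcat == "multiple"),
    n_degenerate = sum(x$comcat_degenerate),
    mean_updates = mean(x$comcat_updates),
    max_likelihood_mean = mean(apply(lik, 1L, max))
  )
}

#' Tidy a recovery evaluation into a long confusion table
#'
#' @param x A `va_recovery` object from [evaluate_recovery()].
#' @param ... Unused.
#' @return A tibble `true_category`, `assigned`, `n`.
#' @method tidy va_recovery
#' @export
tidy.va_recovery <- function(x, ...) {
  tidyr::pivot_longer(x$confusion, -"true_category",
                      names_to = "assigned", values_to = "n")
}

#' One-row summary of a recovery evaluation
#'
#' @param x A `va_recovery` object.
#' @param ... Unused.
#' @return A tibble with `n`, `accuracy`, `multiple_rate`.
#' @method glance va_recovery
#' @export
glance.va_recovery <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy,
                 multiple_rate = x$multiple_rate)
}
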