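#' Per-death posterior likelihoods over a category set
#'
#' The naive-Bayes update at the heart of InterVA-style interpretation.
#' For each death and each category \eqn{c}, the unnormalised mass is
#' \deqn{m(c) = \pi(c) \prod_r P(r \mid c)}
#' where \eqn{\pi} is the probbase prior and the product runs over the
#' record's substantive responses \eqn{r} for which the probbase carries a
#' matching (indicator, response) row. Missing responses contribute no
#' factor, as do responses to indicators absent from the probbase and `no`
#' responses to indicators whose probbase omits a `no` row. Masses are
#' normalised to likelihoods at the end; products are accumulated in log
#' space so that hundreds of small factors cannot underflow. A record whose
#' total mass is zero is flagged degenerate, with all likelihoods zero.
#'
#' @param records A `va_records` tibble (one row per death, one character
#'   column per indicator with values `"yes"`/`"no"`/`"missing"`).
#' @param pb A `va_probbase`.
#' @return A tibble of class `va_posterior`, one row per (record, category):
#'   `record_id`, `category`, `likelihood`, `degenerate`, `updates` (count
#'   of substantive responses consumed). Non-degenerate likelihoods sum to
#'   1 per record.
#' @export
compute_posterior <- function(records, pb) {
  stopifnot(inherits(pb, "va_probbase"))
  records <- tibble::as_tibble(records)
  cats <- pb$categories
  K <- length(cats)

  pairs <- dplyr::distinct(pb$cond[, c("indicator", "response")])
  logM <- matrix(log(pb$cond$prob), ncol = K, byrow = TRUE)
  rownames(logM) <- paste(pairs$indicator, pairs$response)
  log_prior <- log(pb$prior)

  ind_cols <- intersect(unique(pairs$indicator), names(records))
  n <- nrow(records)
  lik <- matrix(0, nrow = n, ncol = K, dimnames = list(NULL, cats))
  degenerate <- logical(n)
  updates <- integer(n)

  if (n > 0L) {
    resp <- as.matrix(records[, ind_cols, drop = FALSE])
    for (i in seq_len(n)) {
      subst <- resp[i, ] %in% c("yes", "no")
      keys <- paste(ind_cols[subst], resp[i, subst])
      keys <- keys[keys %in% rownames(logM)]
      updates[i] <- length(keys)
      ll <- log_prior
      if (length(keys) > 0L) {
        ll <- ll + colSums(logM[keys, , drop = FALSE])
      }
      top <- max(ll)
      if (top == -Inf) {
        degenerate[i] <- TRUE
      } else {
        w <- exp(ll - top)
        lik[i, ] <- w / sum(w)
      }
    }
  }

  out <- tibble::tibble(
    record_id = rep(records$record_id, each = K),
    category = rep(cats, times = n),
    likelihood = as.vector(t(lik)),
    degenerate = rep(degenerate, each = K),
    updates = rep(updates, each = K)
  )
  structure(out, class = c("va_posterior", class(out)),
            categories = cats, set_name = pb$set_name)
}

#' Assign a COMCAT by the dominance rule
#'
#' A single category is assigned to a death only when its likelihood
#' strictly exceeds the threshold (default 50%); otherwise the derived
#' `"multiple"` category applies — no single circumstance predominated.
#' Exact ties at the threshold and degenerate (all-zero) distributions also
#' yield `"multiple"`. Two categories can never both exceed 50%, so the
#' assigned argmax is unambiguous.
#'
#' @param posterior A `va_posterior` tibble over the COMCAT set.
#' @param threshold Dominance threshold, strictly between 0 and 1.
#' @return A tibble, one row per death: `record_id`, `comcat` (a category
#'   label or `"multiple"`), `max_category`, `max_likelihood`, `degenerate`.
#' @export
assign_comcat <- function(posterior, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    abort("threshold must lie strictly between 0 and 1")
  }
  cats <- attr(posterior, "categories") %||% unique(posterior$category)
  posterior |>
    dplyr::mutate(category = factor(.data$category, levels = cats)) |>
    dplyr::arrange(.data$category) |>
    dplyr::group_by(.data$record_id) |>
    dplyr::summarise(
      max_category = as.character(.data$category[which.max(.data$likelihood)]),
      max_likelihood = max(.data$likelihood),
      degenerate = .data$degenerate[1L],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      comcat = dplyr::if_else(!.data$degenerate & .data$max_likelihood > threshold,
                              .data$max_category, "multiple"),
      .before = "max_category"
    )
}

#' Rank causes of death with an indeterminate residual
#'
#' Causes are taken in descending likelihood (ties broken by probbase
#' category order) while the likelihood stays at or above
#' `report_threshold` and at most `max_causes` are reported; all remaining
#' posterior mass is the indeterminate residual. Ranked likelihoods plus
#' the residual sum to 1; a degenerate distribution is fully indeterminate.
#'
#' @param posterior A `va_posterior` tibble over the cause set.
#' @param max_causes Maximum number of reported causes (at least 1).
#' @param report_threshold Minimum likelihood for a cause to be reported.
#' @return A tibble, one row per death: `record_id`, `cause_1`,
#'   `cause_1_lik`, ... up to `max_causes`, `indeterminate`, `degenerate`.
#'   Unused cause slots are `NA`.
#' @export
assign_causes <- function(posterior, max_causes = 3, report_threshold = 0.1) {
  if (!is.numeric(max_causes) || max_causes < 1) {
    abort("max_causes must be at least 1")
  }
  max_causes <- as.integer(max_causes)
  cats <- attr(posterior, "categories") %||% unique(posterior$category)

  per_record <- function(df) {
    ord <- order(-df$likelihood, match(df$category, cats))
    take <- df[ord, ][seq_len(min(max_causes, nrow(df))), ]
    take <- take[!df$degenerate[1L] & take$likelihood >= report_threshold, ]
    # a lower-ranked cause can only pass the threshold if all above it did
    row <- setNames(
      rep(list(NA), 2L * max_causes),
      as.vector(rbind(paste0("cause_", seq_len(max_causes)),
                      paste0("cause_", seq_len(max_causes), "_lik")))
    )
    k <- nrow(take)
    if (k > 0L) {
      row[paste0("cause_", seq_len(k))] <- as.list(take$category)
      row[paste0("cause_", seq_len(k), "_lik")] <- as.list(take$likelihood)
    }
    row$indeterminate <- 1 - sum(take$likelihood)
    row$degenerate <- df$degenerate[1L]
    tibble::as_tibble(row)
  }

  posterior |>
    dplyr::group_by(.data$record_id) |>
    dplyr::group_modify(~ per_record(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(dplyr::across(dplyr::matches("^cause_[0-9]+$"), as.character),
                  dplyr::across(dplyr::matches("_lik$"), as.numeric))
}

#' Process a verbal autopsy dataset end to end
#'
#' Runs the Bayesian engine once per death: always the COMCAT sub-model
#' (posterior over the six circumstance categories plus the dominance
#' rule), and in parallel — sharing no state — the cause-of-death model
#' when a cause probbase is supplied. Processing is deterministic and
#' stateless: the same inputs always yield the same outputs, and record
#' order only permutes rows.
#'
#' @param records A `va_records` tibble.
#' @param comcat_pb COMCAT probbase (`va_probbase`).
#' @param cause_pb Optional cause-of-death probbase.
#' @param threshold Dominance threshold for [assign_comcat()].
#' @param max_causes,report_threshold Reporting rule for [assign_causes()].
#' @return A tibble of class `va_results`, one row per death: demographics,
#'   `comcat`, six `comcat_lik_*` columns, `comcat_degenerate`,
#'   `comcat_updates`, and when causes were processed the ranked
#'   `cause_k`/`cause_k_lik` columns with `indeterminate` residual. The
#'   COMCAT posterior is attached for [tidy()].
#' @export
va_process <- function(records, comcat_pb, cause_pb = NULL, threshold = 0.5,
                       max_causes = 3, report_threshold = 0.1) {
  records <- tibble::as_tibble(records)
  demo <- records[, intersect(c("record_id", "age_group", "sex", "year"),
                              names(records)), drop = FALSE]

  post <- compute_posterior(records, comcat_pb)
  assign <- assign_comcat(post, threshold = threshold)
  lik_wide <- post |>
    dplyr::mutate(category = paste0("comcat_lik_", .data$category)) |>
    tidyr::pivot_wider(id_cols = "record_id", names_from = "category",
                       values_from = "likelihood")
  upd <- dplyr::distinct(post, .data$record_id, comcat_updates = .data$updates)

  out <- demo |>
    dplyr::left_join(assign[, c("record_id", "comcat", "degenerate")],
                     by = "record_id") |>
    dplyr::rename(comcat_degenerate = "degenerate") |>
    dplyr::left_join(lik_wide, by = "record_id") |>
    dplyr::left_join(upd, by = "record_id")

  if (!is.null(cause_pb)) {
    cpost <- compute_posterior(records, cause_pb)
    causes <- assign_causes(cpost, max_causes = max_causes,
                            report_threshold = report_threshold) |>
      dplyr::rename(cause_degenerate = "degenerate")
    cupd <- dplyr::distinct(cpost, .data$record_id, cause_updates = .data$updates)
    out <- out |>
      dplyr::left_join(causes, by = "record_id") |>
      dplyr::left_join(cupd, by = "record_id")
  }
  structure(out, class = c("va_results", class(out)), comcat_posterior = post)
}

#' @export
print.va_results <- function(x, ...) {
  cat(sprintf("<va_results: %d deaths, %d assigned 'multiple', %d degenerate>\n",
              nrow(x), sum(x$comcat == "multiple"), sum(x$comcat_degenerate)))
  NextMethod()
}
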