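#' Specify a synthetic verbal-autopsy scenario
#'
#' A scenario fixes everything the generator needs: the category mixture
#' deaths are drawn from, the number of records, how discriminative the
#' generated probbase is (`sharpness`), the per-response missingness, a
#' demographics mixture and a seed. Identical scenarios generate
#' byte-identical datasets.
#'
#' `sharpness` multiplies the yes-odds of a category's *signature*
#' indicators relative to the baseline yes-probability: at `sharpness = 1`
#' every category column is identical (a non-discriminative probbase, under
#' which assignment collapses to the prior and hence to `"multiple"`);
#' larger values make each category's signature indicators increasingly
#' diagnostic.
#'
#' @param categories Category labels (default the six COMCATs).
#' @param category_mixture Named probabilities summing to 1 (default
#'   uniform) from which each death's true category is drawn.
#' @param n_records Number of deaths to simulate.
#' @param sharpness Discriminativeness of the generated probbase, `>= 1`.
#' @param missingness Probability that any single response is masked to
#'   missing, in `[0,1]` (default 0.1).
#' @param baseline_yes Baseline yes-probability of every indicator under
#'   non-signature categories (default 0.2).
#' @param demographics Optional data frame `age_group`, `sex`, `year`,
#'   `prob` (summing to 1); default uniform over the five standard age
#'   bands, two sexes and years 2012--2016.
#' @param seed Integer seed; the single pseudo-random stream for the
#'   scenario.
#' @return A list of class `va_scenario`.
#' @export
scenario_spec <- function(categories = comcat_categories(),
                          category_mixture = NULL,
                          n_records = 500,
                          sharpness = 20,
                          missingness = 0.1,
                          baseline_yes = 0.2,
                          demographics = NULL,
                          seed = 1L) {
  categories <- as.character(categories)
  if (is.null(category_mixture)) {
    category_mixture <- setNames(rep(1 / length(categories),
                                     length(categories)), categories)
  }
  category_mixture <- category_mixture[categories]
  if (anyNA(category_mixture) || any(category_mixture < 0)) {
    abort("category_mixture must cover every category with probabilities in [0,1]")
  }
  if (abs(sum(category_mixture) - 1) > 1e-9) {
    abort("category_mixture must sum to 1")
  }
  if (sharpness < 1) abort("sharpness must be >= 1")
  if (missingness < 0 || missingness > 1) abort("missingness must lie in [0,1]")
  if (baseline_yes <= 0 || baseline_yes >= 1) {
    abort("baseline_yes must lie strictly between 0 and 1")
  }
  if (is.null(demographics)) {
    demographics <- tidyr::expand_grid(age_group = default_age_bands(),
                                       sex = c("female", "male"),
                                       year = 2012:2016)
    demographics$prob <- 1 / nrow(demographics)
  }
  demographics <- tibble::as_tibble(demographics)
  if (abs(sum(demographics$prob) - 1) > 1e-9) {
    abort("demographics mixture must sum to 1")
  }
  structure(
    list(categories = categories, category_mixture = category_mixture,
         n_records = as.integer(n_records), sharpness = sharpness,
         missingness = missingness, baseline_yes = baseline_yes,
         demographics = demographics, seed = as.integer(seed)),
    class = "va_scenario"
  )
}

#' Generate a probbase with known signature structure
#'
#' Indicators are assigned to categories round-robin, so each category owns
#' an (almost) equal signature subset. A signature indicator's
#' yes-probability under its own category has odds `sharpness` times the
#' baseline odds; under every other category it keeps the baseline
#' yes-probability. Both `yes` and `no` rows are emitted
#' (`P(no) = 1 - P(yes)`), so negative responses are informative too. With
#' `sharpness = 1` all category columns are identical. The prior is
#' uniform. Deterministic: the construction involves no random draws.
#'
#' @param spec A `va_scenario`.
#' @param n_indicators Number of indicators to generate (`>= 1`), named
#'   `S01`, `S02`, ...; alternatively a character vector of indicator ids
#'   to use verbatim (e.g. `comcat_dictionary()$id`).
#' @return A `va_probbase` over the scenario's categories.
#' @export
generate_probbase <- function(spec, n_indicators = 30) {
  stopifnot(inherits(spec, "va_scenario"))
  if (is.character(n_indicators)) {
    ids <- n_indicators
  } else {
    if (n_indicators < 1) abort("n_indicators must be >= 1")
    ids <- sprintf("S%02d", seq_len(n_indicators))
  }
  cats <- spec$categories
  K <- length(cats)
  p0 <- spec$baseline_yes
  odds0 <- p0 / (1 - p0)
  p_sig <- (spec$sharpness * odds0) / (1 + spec$sharpness * odds0)
  owner <- cats[((seq_along(ids) - 1L) %% K) + 1L]

  yes <- tidyr::expand_grid(indicator = ids, category = cats)
  yes$response <- "yes"
  yes$prob <- ifelse(yes$category == rep(owner, each = K), p_sig, p0)
  no <- yes
  no$response <- "no"
  no$prob <- 1 - yes$prob
  cond <- dplyr::bind_rows(yes, no)[, c("indicator", "response",
                                        "category", "prob")]
  probbase(cats, setNames(rep(1 / K, K), cats), cond, set_name = "comcats")
}

#' Generate verbal-autopsy records from a probbase
#'
#' For each death: draw the true category from the scenario mixture; draw
#' each indicator response `yes` with the probbase's
#' `P(yes | indicator, true category)`, else `no`; independently mask each
#' response to `missing` with probability `missingness`; attach
#' demographics drawn from the demographics mixture. Responses are
#' conditionally independent given the category — exactly the naive-Bayes
#' assumption the engine makes — so recovery experiments measure the
#' engine, not model misspecification. Deterministic given the scenario
#' seed.
#'
#' @param spec A `va_scenario`.
#' @param pb A `va_probbase` (typically from [generate_probbase()]).
#' @param dictionary Optional `va_dictionary`; defaults to a dictionary
#'   built from the probbase's indicators.
#' @return A list: `records` (a `va_records` tibble) and `truth` (tibble
#'   `record_id`, `true_category`).
#' @export
generate_records <- function(spec, pb, dictionary = NULL) {
  stopifnot(inherits(spec, "va_scenario"), inherits(pb, "va_probbase"))
  ids <- unique(pb$cond$indicator)
  if (!is.null(dictionary)) {
    missing_ids <- setdiff(ids, dictionary$id)
    if (length(missing_ids) > 0L) {
      abort(paste0("probbase indicators absent from dictionary: ",
                   paste(missing_ids, collapse = ", ")))
    }
    ids <- intersect(dictionary$id, ids)
  }
  n <- spec$n_records
  rid <- sprintf("R%05d", seq_len(n))
  yes_tab <- pb$cond[pb$cond$response == "yes", ]
  p_yes <- matrix(yes_tab$prob[order(match(yes_tab$indicator, ids),
                                     match(yes_tab$category, pb$categories))],
                  nrow = length(ids), byrow = TRUE,
                  dimnames = list(ids, pb$categories))

  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
    code
  }

  withr_seed({
    truth <- sample(spec$categories, n, replace = TRUE,
                    prob = spec$category_mixture)
    demo_idx <- sample.int(nrow(spec$demographics), n, replace = TRUE,
                           prob = spec$demographics$prob)
    resp <- matrix("no", nrow = n, ncol = length(ids),
                   dimnames = list(NULL, ids))
    if (n > 0L) {
      pmat <- t(p_yes[, truth, drop = FALSE])
      draw <- matrix(runif(n * length(ids)), nrow = n)
      resp[draw < pmat] <- "yes"
      miss <- matrix(runif(n * length(ids)), nrow = n) < spec$missingness
      resp[miss] <- "missing"
    }
  })

  demo <- spec$demographics[demo_idx, c("age_group", "sex", "year"), drop = FALSE]
  records <- dplyr::bind_cols(
    tibble::tibble(record_id = rid),
    tibble::as_tibble(demo),
    tibble::as_tibble(resp)
  )
  records <- structure(records, class = c("va_records", class(records)))
  list(records = records,
       truth = tibble::tibble(record_id = rid, true_category = truth))
}

#' Evaluate recovery of generating categories
#'
#' Cross-tabulates generating (true) categories against assigned COMCATs —
#' a truth-by-assigned confusion matrix including the derived `"multiple"`
#' column — and summarises accuracy over the non-`"multiple"` assignments
#' plus the fraction assigned `"multiple"`. When every death is assigned
#' `"multiple"`, accuracy is undefined and reported as `NA`.
#'
#' @param outputs Per-death outputs with `record_id` and a `comcat` column
#'   (e.g. `va_results`).
#' @param truth Tibble `record_id`, `true_category` from
#'   [generate_records()].
#' @return A list of class `va_recovery`: `confusion` (tibble
#'   `true_category` x assigned counts), `accuracy`, `multiple_rate`, `n`.
#' @export
evaluate_recovery <- function(outputs, truth) {
  outputs <- tibble::as_tibble(outputs)
  truth <- tibble::as_tibble(truth)
  if (!setequal(outputs$record_id, truth$record_id) ||
      nrow(outputs) != nrow(truth)) {
    abort("outputs and truth must carry the same record ids")
  }
  joined <- dplyr::inner_join(truth, outputs[, c("record_id", "comcat")],
                              by = "record_id")
  cats <- unique(truth$true_category)
  assigned_levels <- c(union(cats, unique(joined$comcat)), "multiple")
  assigned_levels <- unique(assigned_levels)
  confusion <- joined |>
    dplyr::count(.data$true_category,
                 assigned = factor(.data$comcat, levels = assigned_levels),
                 .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "assigned", values_from = "n",
                       values_fill = 0L)
  non_multiple <- joined[joined$comcat != "multiple", ]
  accuracy <- if (nrow(non_multiple) > 0L) {
    mean(non_multiple$comcat == non_multiple$true_category)
  } else {
    NA_real_
  }
  structure(
    list(confusion = confusion,
         accuracy = accuracy,
         multiple_rate = mean(joined$comcat == "multiple"),
         n = nrow(joined)),
    class = "va_recovery"
  )
}

#' @export
print.va_recovery <- function(x, ...) {
  cat(sprintf("<va_recovery: n=%d, accuracy=%s, multiple_rate=%.3f>\n",
              x$n,
              if (is.na(x$accuracy)) "n/a" else sprintf("%.3f", x$accuracy),
              x$multiple_rate))
  print(x$confusion)
  invisible(x)
}

#' Write a full synthetic bundle to disk
#'
#' Materialises a scenario as four files in `dir`: `records.csv`,
#' `probbase.csv`, `truth.csv` and `scenario.yaml`. Identical scenarios
#' produce byte-identical bundles.
#'
#' @param spec A `va_scenario`.
#' @param dir Output directory (created if needed).
#' @param n_indicators Passed to [generate_probbase()].
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_scenario_bundle <- function(spec, dir, n_indicators = 30) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pb <- generate_probbase(spec, n_indicators)
  gen <- generate_records(spec, pb)
  paths <- c(records = file.path(dir, "records.csv"),
             probbase = file.path(dir, "probbase.csv"),
             truth = file.path(dir, "truth.csv"),
             scenario = file.path(dir, "scenario.yaml"))
  readr::write_csv(tibble::as_tibble(gen$records), paths["records"])
  write_probbase(pb, paths["probbase"])
  readr::write_csv(gen$truth, paths["truth"])
  scen <- list(categories = spec$categories,
               category_mixture = as.list(spec$category_mixture),
               n_records = spec$n_records, sharpness = spec$sharpness,
               missingness = spec$missingness,
               baseline_yes = spec$baseline_yes, seed = spec$seed)
  writeLines(yaml::as.yaml(scen, precision = 15L), paths["scenario"])
  invisible(paths)
}

#' Read a scenario back from YAML
#'
#' @param path Path to a `scenario.yaml` written by
#'   [write_scenario_bundle()].
#' @return A `va_scenario`.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  scenario_spec(categories = unlist(y$categories),
                category_mixture = unlist(y$category_mixture),
                n_records = y$n_records, sharpness = y$sharpness,
                missingness = y$missingness, baseline_yes = y$baseline_yes,
                seed = y$seed)
}
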