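# Independent brute-force Bayes oracle: enumerates the prior x likelihood
# product cell by cell with plain linear-space arithmetic and data-frame
# subsetting. Shares no code path with compute_posterior (which works in
# log space on a precomputed matrix).
oracle_posterior <- function(record_row, pb) {
  cats <- pb$categories
  cond <- as.data.frame(pb$cond)
  mass <- vapply(cats, function(cc) {
    m <- unname(pb$prior[[cc]])
    for (ind in unique(cond$indicator)) {
      if (!ind %in% names(record_row)) next
      r <- record_row[[ind]]
      if (!r %in% c("yes", "no")) next
      hit <- cond[cond$indicator == ind & cond$response == r &
                    cond$category == cc, "prob"]
      if (length(hit) == 1L) m <- m * hit
    }
    m
  }, numeric(1))
  total <- sum(mass)
  if (total == 0) setNames(rep(0, length(cats)), cats) else mass / total
}

# Random small probbase for property tests: optional exact-zero cells and
# optional dropped 'no' rows (making NO non-informative for that indicator).
random_probbase <- function(n_cat, n_ind, p_zero = 0.05, p_drop_no = 0.3) {
  cats <- paste0("cat", seq_len(n_cat))
  ids <- sprintf("I%02d", seq_len(n_ind))
  grid <- expand.grid(indicator = ids, response = c("yes", "no"),
                      category = cats, stringsAsFactors = FALSE)
  grid$prob <- runif(nrow(grid))
  grid$prob[runif(nrow(grid)) < p_zero] <- 0
  drop <- ids[runif(n_ind) < p_drop_no]
  grid <- grid[!(grid$response == "no" & grid$indicator %in% drop), ]
  prior <- runif(n_cat, 0.1, 1)
  probbase(cats, setNames(prior, cats), grid, set_name = "test")
}

random_record <- function(ids, id = "X1") {
  resp <- sample(c("yes", "no", "missing"), length(ids), replace = TRUE)
  rec <- c(list(record_id = id, age_group = "20-49", sex = "female",
                year = 2014L), setNames(as.list(resp), ids))
  structure(tibble::as_tibble(rec),
            class = c("va_records", class(tibble::tibble())))
}

# Likelihood matrix (records x categories) from a long posterior tibble.
posterior_matrix <- function(post) {
  wide <- tidyr::pivot_wider(post, id_cols = "record_id",
                             names_from = "category",
                             values_from = "likelihood")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$record_id
  m
}

write_tmp_csv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "tmp.csv")
  readr::write_csv(df, path, na = "")
  path
}
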