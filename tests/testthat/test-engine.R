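two_cat_pb <- function() {
  probbase(c("cat1", "cat2"), c(cat1 = 0.5, cat2 = 0.5), tibble::tibble(
    indicator = rep("I01", 2), response = "yes",
    category = c("cat1", "cat2"), prob = c(0.8, 0.2)))
}

one_record <- function(...) {
  rec <- c(list(record_id = "X1", age_group = "20-49", sex = "female",
                year = 2014L), list(...))
  tibble::as_tibble(rec)
}

test_that("posterior matches the closed-form Bayes update", {
  # priors 0.5/0.5, one YES with cond 0.8/0.2 -> posterior 0.8/0.2
  post <- compute_posterior(one_record(I01 = "yes"), two_cat_pb())
  expect_equal(post$likelihood, c(0.8, 0.2), tolerance = 1e-12)
  expect_equal(post$updates[1], 1L)

  # all-missing record: empty product, posterior equals the prior
  post0 <- compute_posterior(one_record(I01 = "missing"), two_cat_pb())
  expect_equal(post0$likelihood, c(0.5, 0.5))
  expect_equal(post0$updates[1], 0L)

  # NO response with no 'no' row in the probbase is non-informative
  postno <- compute_posterior(one_record(I01 = "no"), two_cat_pb())
  expect_equal(postno$likelihood, c(0.5, 0.5))
  expect_equal(postno$updates[1], 0L)
})

test_that("zero conditionals annihilate categories; all-zero mass is degenerate", {
  pb <- probbase(c("a", "b"), c(a = 0.5, b = 0.5), tibble::tibble(
    indicator = "I01", response = "yes", category = c("a", "b"),
    prob = c(0, 0.4)))
  post <- compute_posterior(one_record(I01 = "yes"), pb)
  expect_equal(post$likelihood, c(0, 1))
  expect_false(post$degenerate[1])

  pb0 <- probbase(c("a", "b"), c(a = 0.5, b = 0.5), tibble::tibble(
    indicator = "I01", response = "yes", category = c("a", "b"), prob = 0))
  post0 <- compute_posterior(one_record(I01 = "yes"), pb0)
  expect_true(all(post0$degenerate))
  expect_equal(post0$likelihood, c(0, 0))
})

test_that("posterior equals the brute-force oracle on random instances", {
  set.seed(2024)
  for (trial in 1:250) {
    pb <- random_probbase(sample(2:5, 1), sample(1:8, 1))
    rec <- random_record(unique(pb$cond$indicator))
    post <- compute_posterior(rec, pb)
    expect_equal(setNames(post$likelihood, post$category),
                 oracle_posterior(rec, pb), tolerance = 1e-9)
    if (!post$degenerate[1]) {
      expect_equal(sum(post$likelihood), 1, tolerance = 1e-9)
    }
  }
})

test_that("posterior is invariant to response order and to row scaling", {
  set.seed(31)
  for (trial in 1:20) {
    pb <- random_probbase(4, 8, p_zero = 0)
    ids <- unique(pb$cond$indicator)
    rec <- random_record(ids)
    base <- compute_posterior(rec, pb)$likelihood

    # shuffle the indicator columns of the record
    shuffled <- rec[, c("record_id", "age_group", "sex", "year", sample(ids))]
    expect_equal(compute_posterior(shuffled, pb)$likelihood, base)

    # scale every category's cond for one (indicator, response) row by k>0
    k <- 0.37
    pbs <- pb
    i <- sample(nrow(pbs$cond), 1)
    pick <- pbs$cond$indicator == pbs$cond$indicator[i] &
      pbs$cond$response == pbs$cond$response[i]
    pbs$cond$prob[pick] <- pbs$cond$prob[pick] * k
    expect_equal(compute_posterior(rec, pbs)$likelihood, base,
                 tolerance = 1e-12)
  }
})

test_that("a favourable YES never decreases the favoured category's likelihood", {
  set.seed(77)
  for (trial in 1:20) {
    pb <- random_probbase(4, 6, p_zero = 0, p_drop_no = 0)
    ids <- unique(pb$cond$indicator)
    rec <- random_record(ids)
    base <- compute_posterior(rec, pb)$likelihood

    # add an extra indicator whose YES strictly favours cat1
    extra <- tibble::tibble(indicator = "IEX", response = "yes",
                            category = pb$categories,
                            prob = c(0.9, runif(3, 0.05, 0.5)))
    pb2 <- probbase(pb$categories, pb$prior,
                    dplyr::bind_rows(pb$cond, extra))
    rec2 <- dplyr::mutate(rec, IEX = "yes")
    expect_gte(compute_posterior(rec2, pb2)$likelihood[1], base[1])
  }
})

test_that("dominance rule is strict at the threshold", {
  cats <- comcat_categories()
  mk_post <- function(lik, degenerate = FALSE) {
    structure(tibble::tibble(record_id = "X1", category = cats,
                             likelihood = lik, degenerate = degenerate,
                             updates = 5L),
              categories = cats)
  }
  a <- assign_comcat(mk_post(c(0.10, 0.60, 0.10, 0.10, 0.05, 0.05)))
  expect_equal(a$comcat, "emergencies")

  # exactly 0.5 does not dominate ("exceeds" is strict)
  tie <- assign_comcat(mk_post(c(0.50, 0.30, 0.10, 0.05, 0.03, 0.02)))
  expect_equal(tie$comcat, "multiple")

  flat <- assign_comcat(mk_post(c(0.30, 0.30, 0.20, 0.10, 0.05, 0.05)))
  expect_equal(flat$comcat, "multiple")

  degen <- assign_comcat(mk_post(rep(0, 6), degenerate = TRUE))
  expect_equal(degen$comcat, "multiple")

  # custom threshold still strict; invalid thresholds rejected
  expect_equal(assign_comcat(mk_post(c(0.45, 0.2, 0.15, 0.1, 0.05, 0.05)),
                             threshold = 0.45)$comcat, "multiple")
  expect_error(assign_comcat(mk_post(rep(1 / 6, 6)), threshold = 0), "threshold")
  expect_error(assign_comcat(mk_post(rep(1 / 6, 6)), threshold = 1), "threshold")
})

test_that("cause ranking truncates at threshold and leaves the rest indeterminate", {
  cats <- paste0("c", 1:5)
  mk_post <- function(lik, degenerate = FALSE) {
    structure(tibble::tibble(record_id = "X1", category = cats,
                             likelihood = lik, degenerate = degenerate,
                             updates = 5L),
              categories = cats)
  }
  one <- assign_causes(mk_post(c(0.9, 0.04, 0.03, 0.02, 0.01)),
                       max_causes = 3, report_threshold = 0.1)
  expect_equal(one$cause_1, "c1")
  expect_equal(one$cause_1_lik, 0.9)
  expect_true(is.na(one$cause_2))
  expect_equal(one$indeterminate, 0.1)

  # sub-threshold everywhere: fully indeterminate
  unif <- assign_causes(mk_post(rep(0.2, 5)), max_causes = 3,
                        report_threshold = 0.25)
  expect_true(is.na(unif$cause_1))
  expect_equal(unif$indeterminate, 1)

  # matches an independent sort-and-truncate oracle on a crafted case
  lik <- c(0.35, 0.30, 0.15, 0.12, 0.08)
  got <- assign_causes(mk_post(lik), max_causes = 3, report_threshold = 0.1)
  ord <- order(-lik)
  keep <- ord[lik[ord] >= 0.1][1:3]
  expect_equal(unlist(got[paste0("cause_", 1:3)], use.names = FALSE),
               cats[keep])
  expect_equal(got$indeterminate, 1 - sum(lik[keep]))
  expect_equal(sum(unlist(got[paste0("cause_", 1:3, "_lik")])) +
                 got$indeterminate, 1, tolerance = 1e-9)

  degen <- assign_causes(mk_post(rep(0, 5), degenerate = TRUE))
  expect_equal(degen$indeterminate, 1)
  expect_error(assign_causes(mk_post(rep(0.2, 5)), max_causes = 0),
               "max_causes")
})

test_that("dataset processing is parallel, independent and stateless", {
  spec <- scenario_spec(n_records = 10, seed = 5)
  comcat_pb <- generate_probbase(spec, 12)
  cause_spec <- scenario_spec(categories = paste0("cause", 1:8),
                              n_records = 10, seed = 6)
  cause_pb <- generate_probbase(cause_spec, 12)
  gen <- generate_records(spec, comcat_pb)

  only_comcat <- va_process(gen$records, comcat_pb)
  expect_equal(nrow(only_comcat), 10L)
  expect_false("cause_1" %in% names(only_comcat))

  both <- va_process(gen$records, comcat_pb, cause_pb = cause_pb)
  expect_true(all(paste0("cause_", 1:3) %in% names(both)))
  # adding the cause model does not perturb the COMCAT output
  expect_equal(both$comcat, only_comcat$comcat)
  expect_equal(both$comcat_lik_traditions, only_comcat$comcat_lik_traditions)

  # permuting records permutes outputs identically
  perm <- sample(nrow(gen$records))
  shuffled <- va_process(gen$records[perm, ], comcat_pb, cause_pb = cause_pb)
  expect_equal(tibble::as_tibble(shuffled),
               tibble::as_tibble(both)[perm, ], ignore_attr = TRUE)
})
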