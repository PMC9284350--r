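test_that("percentage rounds half-up to one decimal and matches a long-division oracle", {
  expect_equal(percentage(2332, 5114), 45.6)
  expect_equal(percentage(0, 257), 0.0)
  expect_error(percentage(1, 0), "positive")
  expect_error(percentage(-1, 10), "nonnegative")
  # independent oracle: integer long division with explicit remainder check
  oracle <- function(n, d) {
    q <- (1000 * n) %/% d
    r <- (1000 * n) %% d
    (q + (2 * r >= d)) / 10
  }
  set.seed(77)
  n <- sample(0:100000, 10000, replace = TRUE)
  d <- sample(1:100000, 10000, replace = TRUE)
  expect_equal(percentage(n, d), mapply(oracle, n, d))
})

fake_records <- function(outcome_sets, exposure = "POSSIBLE", term = FALSE,
                         bw = FALSE, ages = NA_integer_) {
  n <- length(outcome_sets)
  exposures <- data.frame(user_id = sprintf("u%d", seq_len(n)),
                          pregnancy_index = 1L, canonical = "atenolol",
                          exposure_class = rep_len(exposure, n), evidence = "p",
                          stringsAsFactors = FALSE)
  outcomes <- lapply(outcome_sets, function(kinds) {
    list(reports = data.frame(kind = kinds,
                              ga_days = rep(NA_integer_, length(kinds)),
                              weight_oz = rep(NA_integer_, length(kinds)),
                              evidence_post_id = rep("p", length(kinds)),
                              stringsAsFactors = FALSE),
         term_ga_evidence = term, normal_bw_evidence = bw)
  })
  names(outcomes) <- paste(exposures$user_id, 1L)
  covariates <- lapply(rep_len(ages, n), function(a) {
    list(maternal_age = a, indications = character())
  })
  names(covariates) <- names(outcomes)
  build_cohort(exposures, outcomes, covariates)
}

test_that("composite adverse counts each pregnancy once (set-union semantics)", {
  rec <- fake_records(list(c("PRETERM", "NICU"), "LOW_BIRTH_WEIGHT",
                           character(), character()))
  s <- summarize_cohort(rec)
  expect_equal(s$outcomes$count[s$outcomes$outcome == "COMPOSITE"], 2L)
  expect_equal(sum(s$outcomes$count[s$outcomes$outcome != "COMPOSITE"]), 3L)
  expect_equal(s$reporting_bias$n_nonadverse, 2L)
})

test_that("composite <= sum of individual counts, equal iff outcome sets are disjoint", {
  kinds <- c("PRETERM", "NICU", "LOW_BIRTH_WEIGHT", "BIRTH_DEFECT", "MISCARRIAGE")
  set.seed(31)
  for (i in 1:40) {
    sets <- lapply(seq_len(sample(1:8, 1)), function(j) {
      sample(kinds, sample(0:3, 1))
    })
    rec <- fake_records(sets)
    s <- summarize_cohort(rec)
    comp <- s$outcomes$count[s$outcomes$outcome == "COMPOSITE"]
    indiv <- sum(s$outcomes$count[s$outcomes$outcome != "COMPOSITE"])
    expect_lte(comp, indiv)
    multi <- any(vapply(sets, length, 0L) >= 2L)
    if (multi) expect_lt(comp, indiv) else expect_equal(comp, indiv)
  }
})

test_that("cohort assembly keeps exposed pregnancies, excludes others, and joins totally", {
  exposures <- data.frame(user_id = c("a", "b", "c"), pregnancy_index = 1L,
                          canonical = "atenolol",
                          exposure_class = c("EXPLICIT_DURING", "NOT_DURING", "POSSIBLE"),
                          evidence = "p", stringsAsFactors = FALSE)
  rec <- build_cohort(exposures, outcomes = NULL, covariates = NULL)
  expect_equal(nrow(rec), 2L)
  expect_equal(attr(rec, "n_excluded"), 1L)
  expect_true(all(is.na(rec$maternal_age)))
  expect_false(any(rec$composite_adverse))
  expect_error(build_cohort(rbind(exposures, exposures[1, ])), "duplicate")
  empty <- build_cohort(exposures[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("evidence flags are forced consistent with contradicting adverse outcomes", {
  rec <- fake_records(list("PRETERM"), term = TRUE, bw = TRUE)
  expect_false(rec$term_ga_evidence)   # preterm pregnancy cannot carry term evidence
  expect_true(rec$normal_bw_evidence)
  rec <- fake_records(list("LOW_BIRTH_WEIGHT"), term = TRUE, bw = TRUE)
  expect_true(rec$term_ga_evidence)
  expect_false(rec$normal_bw_evidence)
})

test_that("summaries are permutation-invariant and reporting-bias rates use non-adverse denominators", {
  rec <- fake_records(list("PRETERM", character(), character(), character()),
                      term = TRUE, bw = FALSE, ages = c(25L, 30L, NA, 35L))
  s1 <- summarize_cohort(rec)
  s2 <- summarize_cohort(rec[c(3, 1, 4, 2), ])
  expect_equal(s1$outcomes$count, s2$outcomes$count)
  expect_equal(s1$reporting_bias, s2$reporting_bias)
  expect_equal(s1$reporting_bias$n_nonadverse, 3L)
  expect_equal(s1$reporting_bias$term_ga_pct, percentage(3, 3))
  rec_allclear <- fake_records(list(character(), character()))
  s <- summarize_cohort(rec_allclear)
  expect_equal(s$outcomes$count[s$outcomes$outcome == "COMPOSITE"], 0L)
  expect_equal(s$reporting_bias$n_nonadverse, 2L)
})
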