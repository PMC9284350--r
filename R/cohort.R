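.adverse_kinds <- c("PRETERM", "NICU", "LOW_BIRTH_WEIGHT", "BIRTH_DEFECT",
                    "MISCARRIAGE", "STILLBIRTH")

#' One-decimal percentage with half-up rounding
#'
#' `100 * numerator / denominator` rounded *half-up* to one decimal place
#' (base `round()` rounds half-even). Computed in exact integer arithmetic:
#' `floor((2000 n + d) / (2 d)) / 10`. This is the convention that
#' reproduces every percentage printed in the source cohort tables.
#'
#' @param numerator,denominator Nonnegative counts; the denominator must be
#'   positive. Vectorised.
#' @return Numeric percentage(s) with one decimal.
#' @examples
#' percentage(2332, 5114)  # 45.6
#' percentage(198, 219)    # 90.4
#' @export
percentage <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (any(numerator < 0)) stop("numerator must be nonnegative")
  (2000 * numerator + denominator) %/% (2 * denominator) / 10
}

#' Assemble per-pregnancy cohort records
#'
#' Joins exposure assessments, outcome reports and covariates into one
#' record per pregnancy, keeping pregnancies whose drug exposure is
#' `EXPLICIT_DURING`, `INFERRED_DURING` or `POSSIBLE` (the "took or may have
#' taken during pregnancy" cohort). Joins are total: missing extractor
#' output yields empty/missing fields, never a dropped record. The composite
#' adverse flag is TRUE iff at least one adverse outcome
#' (preterm birth, NICU admission, low birth weight, birth defect,
#' miscarriage, stillbirth) is present; term-gestational-age and
#' normal-birth-weight evidence are forced FALSE when contradicted by a
#' preterm or low-weight outcome.
#'
#' @param exposures Data.frame of per-pregnancy assessments
#'   ([classify_exposure()]).
#' @param outcomes Named list (key `"user pregnancy_index"`) of
#'   [extract_outcomes()] results, or `NULL`.
#' @param covariates Named list (same keys) of
#'   `list(maternal_age =, indications =)`, or `NULL`.
#' @return A data.frame of class `cohort_records`: one row per exposed
#'   pregnancy with logical outcome columns, `composite_adverse`,
#'   `term_ga_evidence`, `normal_bw_evidence`, `maternal_age`,
#'   `indications`. The number of pregnancies excluded for non-exposure is
#'   kept in the `n_excluded` attribute.
#' @export
build_cohort <- function(exposures, outcomes = NULL, covariates = NULL) {
  key <- paste(exposures$user_id, exposures$pregnancy_index)
  if (anyDuplicated(key)) stop("duplicate (user, pregnancy index) in exposures")
  exposed <- exposures$exposure_class %in% c("EXPLICIT_DURING", "INFERRED_DURING", "POSSIBLE")
  kept <- exposures[exposed, , drop = FALSE]
  kept_key <- key[exposed]

  n <- nrow(kept)
  rec <- data.frame(user_id = kept$user_id,
                    pregnancy_index = kept$pregnancy_index,
                    exposure_class = kept$exposure_class,
                    stringsAsFactors = FALSE)
  for (k in .adverse_kinds) rec[[k]] <- logical(n)
  rec$ga_days <- rep(NA_integer_, n)
  rec$weight_oz <- rep(NA_integer_, n)
  rec$term_ga_evidence <- logical(n)
  rec$normal_bw_evidence <- logical(n)
  rec$maternal_age <- rep(NA_integer_, n)
  rec$indications <- character(n)

  for (i in seq_len(n)) {
    oc <- outcomes[[kept_key[i]]]
    if (!is.null(oc)) {
      kinds <- oc$reports$kind
      for (k in .adverse_kinds) rec[[k]][i] <- k %in% kinds
      ga <- oc$reports$ga_days[!is.na(oc$reports$ga_days)]
      if (length(ga)) rec$ga_days[i] <- ga[1]
      wt <- oc$reports$weight_oz[!is.na(oc$reports$weight_oz)]
      if (length(wt)) rec$weight_oz[i] <- wt[1]
      rec$term_ga_evidence[i] <- isTRUE(oc$term_ga_evidence) && !rec$PRETERM[i] &&
        !rec$MISCARRIAGE[i] && !rec$STILLBIRTH[i]
      rec$normal_bw_evidence[i] <- isTRUE(oc$normal_bw_evidence) &&
        !rec$LOW_BIRTH_WEIGHT[i] && !rec$MISCARRIAGE[i] && !rec$STILLBIRTH[i]
    }
    cv <- covariates[[kept_key[i]]]
    if (!is.null(cv)) {
      rec$maternal_age[i] <- cv$maternal_age %||% NA_integer_
      rec$indications[i] <- paste(cv$indications %||% character(), collapse = ";")
    }
  }
  rec$composite_adverse <- Reduce(`|`, lapply(.adverse_kinds, function(k) rec[[k]]),
                                  logical(n))
  attr(rec, "n_excluded") <- sum(!exposed)
  class(rec) <- c("cohort_records", "data.frame")
  rec
}

#' Summarise a cohort
#'
#' Counts and one-decimal percentages of each adverse outcome over the
#' exposed denominator, the composite adverse outcome (a pregnancy with at
#' least one adverse outcome, counted once — so the composite count is at
#' most the sum of the individual counts), mean maternal age per outcome
#' (arithmetic mean of non-missing ages, rounded half-up to the nearest
#' year; missing ages reduce n), and the reporting-bias fractions among
#' non-adverse pregnancies (how often term gestational age and normal birth
#' weight were actually posted).
#'
#' @param records A `cohort_records` data.frame ([build_cohort()]).
#' @return An object of class `cohort_summary`.
#' @export
summarize_cohort <- function(records) {
  n <- nrow(records)
  mean_age <- function(sel) {
    a <- records$maternal_age[sel]
    a <- a[!is.na(a)]
    list(mean = if (length(a)) as.integer(round_half_up(mean(a))) else NA_integer_,
         n = length(a))
  }
  rows <- lapply(.adverse_kinds, function(k) {
    sel <- records[[k]]
    ag <- mean_age(sel)
    data.frame(outcome = k, count = sum(sel),
               pct = if (n > 0) percentage(sum(sel), n) else NA_real_,
               mean_age = ag$mean, age_n = ag$n, stringsAsFactors = FALSE)
  })
  comp_sel <- records$composite_adverse
  ag <- mean_age(comp_sel)
  rows[[length(rows) + 1L]] <- data.frame(
    outcome = "COMPOSITE", count = sum(comp_sel),
    pct = if (n > 0) percentage(sum(comp_sel), n) else NA_real_,
    mean_age = ag$mean, age_n = ag$n, stringsAsFactors = FALSE)
  tab <- do.call(rbind, rows)

  nonadv <- !records$composite_adverse
  n_na <- sum(nonadv)
  bias <- list(
    n_nonadverse = n_na,
    term_ga_count = sum(records$term_ga_evidence[nonadv]),
    term_ga_pct = if (n_na > 0) percentage(sum(records$term_ga_evidence[nonadv]), n_na) else NA_real_,
    normal_bw_count = sum(records$normal_bw_evidence[nonadv]),
    normal_bw_pct = if (n_na > 0) percentage(sum(records$normal_bw_evidence[nonadv]), n_na) else NA_real_)

  age_known <- sum(!is.na(records$maternal_age))
  ind_known <- sum(nzchar(records$indications))
  structure(list(n = n, outcomes = tab, reporting_bias = bias,
                 maternal_age_known = age_known,
                 maternal_age_known_pct = if (n > 0) percentage(age_known, n) else NA_real_,
                 indication_known = ind_known,
                 indication_known_pct = if (n > 0) percentage(ind_known, n) else NA_real_),
            class = "cohort_summary")
}

#' @export
summary.cohort_records <- function(object, ...) summarize_cohort(object)

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Self-reported pregnancy outcomes among exposed pregnancies (N=",
      x$n, ")\n", sep = "")
  for (i in seq_len(nrow(x$outcomes))) {
    r <- x$outcomes[i, ]
    age <- if (is.na(r$mean_age)) "N/A" else sprintf("%d (n=%d)", r$mean_age, r$age_n)
    cat(sprintf("  %-18s %4d (%.1f%%)   mean age %s\n",
                r$outcome, r$count, r$pct, age))
  }
  b <- x$reporting_bias
  cat("Reporting-bias check among non-adverse pregnancies (N=", b$n_nonadverse, ")\n", sep = "")
  if (b$n_nonadverse > 0) {
    cat(sprintf("  term gestational age reported:  %d (%.1f%%)\n",
                b$term_ga_count, b$term_ga_pct))
    cat(sprintf("  normal birth weight reported:   %d (%.1f%%)\n",
                b$normal_bw_count, b$normal_bw_pct))
  }
  cat(sprintf("Maternal age known: %d; indication known: %d\n",
              x$maternal_age_known, x$indication_known))
  invisible(x)
}

#' Convert a cohort summary to plain lists for JSON output
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return A nested list mirroring the summary fields.
#' @export
as.list.cohort_summary <- function(x, ...) {
  list(n = x$n,
       outcomes = lapply(seq_len(nrow(x$outcomes)), function(i) as.list(x$outcomes[i, ])),
       reporting_bias = x$reporting_bias,
       maternal_age_known = x$maternal_age_known,
       maternal_age_known_pct = x$maternal_age_known_pct,
       indication_known = x$indication_known,
       indication_known_pct = x$indication_known_pct)
}
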