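# Clinical thresholds used throughout: preterm birth is gestational age
# < 37 completed weeks (259 days); low birth weight is < 5 lb 8 oz (88 oz).
# Weight comparisons are done in integer ounces so the boundary is exact.

#' Parse a birth weight in pounds and ounces
#'
#' Recognises the dialects "Xlbs Yoz", "X lb Y oz", "X pounds and Y ounces",
#' "X pounds Y ounces", and a pounds-only form. Metric weights ("3.1 kg")
#' are outside the supported dialects and rejected with a diagnostic, as are
#' ounce values of 16 or more.
#'
#' @param text Post text.
#' @return A list with `pounds`, `ounces`, `total_ounces`, or `NULL` if no
#'   weight is found (rejections explain themselves via a `message()`).
#' @examples
#' parse_birth_weight("born April 2nd, 2020. 4lbs 12oz, 18 inches")$total_ounces  # 76
#' @export
parse_birth_weight <- function(text) {
  t <- normalise_text(text)
  if (grepl("\\b\\d+(?:\\.\\d+)?\\s*(?:kg|kilo(?:gram)?s?|grams?)\\b", t, perl = TRUE)) {
    message("metric birth weight not supported; ignored")
    return(NULL)
  }
  m <- regexec("\\b(\\d{1,2})\\s*(?:lbs?|pounds?)\\.?,?\\s*(?:and\\s+)?(\\d{1,2})\\s*(?:oz|ounces?)\\b",
               t, perl = TRUE)
  g <- regmatches(t, m)[[1]]
  if (length(g)) {
    lb <- as.integer(g[2]); oz <- as.integer(g[3])
  } else {
    m <- regexec("\\b(\\d{1,2})\\s*(?:lbs?|pounds?)\\b(?!\\s*(?:and|\\d))", t, perl = TRUE)
    g <- regmatches(t, m)[[1]]
    if (!length(g)) return(NULL)
    lb <- as.integer(g[2]); oz <- 0L
  }
  if (oz >= 16L) {
    message(sprintf("rejected birth weight '%s': ounces >= 16", g[1]))
    return(NULL)
  }
  total <- 16L * lb + oz
  if (total <= 0L) {
    message("rejected zero birth weight")
    return(NULL)
  }
  list(pounds = lb, ounces = oz, total_ounces = total)
}

#' Format a birth weight back to its canonical dialect
#' @param weight A list with `pounds` and `ounces` ([parse_birth_weight()]).
#' @return A string like `"4lbs 12oz"`.
#' @export
format_birth_weight <- function(weight) {
  sprintf("%dlbs %doz", weight$pounds, weight$ounces)
}

#' Detect a birth announcement in a post
#'
#' Birth announcement patterns: "born <date>" (month-name or ISO date with a
#' four-digit year), "introducing ...", and "came/arrived at N weeks". The
#' stated birth date is preferred; otherwise the post date stands in. An
#' attached pounds/ounces weight is parsed when present. Plain "happy
#' birthday" chatter does not trigger.
#'
#' @param post A single-row posts data.frame.
#' @return `NULL`, or a list with `post_id`, `date`, `weight` (possibly
#'   `NULL`) and `came_weeks` (stated gestational weeks, or `NA`).
#' @export
detect_birth_event <- function(post) {
  stopifnot(nrow(post) == 1L)
  t <- normalise_text(post$text)

  stated <- as.Date(NA)
  m <- regexec(paste0("\\bborn\\b[^.!?]{0,25}?(", textual_date_pattern(), "|",
                      iso_date_pattern(), ")"), t, perl = TRUE)
  g <- regmatches(t, m)[[1]]
  born_date <- length(g) > 0
  if (born_date) stated <- find_date_in_text(g[2])

  came <- NA_integer_
  m <- regexec("\\b(?:came|arrived|born) at (\\d{1,2}) weeks\\b", t, perl = TRUE)
  g <- regmatches(t, m)[[1]]
  if (length(g)) came <- as.integer(g[2])

  introducing <- grepl("\\bintroducing\\b", t, perl = TRUE)
  if (!born_date && !introducing && is.na(came)) return(NULL)

  list(post_id = post$post_id,
       date = if (!is.na(stated)) stated else post$post_date,
       weight = parse_birth_weight(post$text),
       came_weeks = came)
}

#' Classify gestational age at birth
#'
#' `PRETERM` if the gestational age at birth is below `term_threshold_days`
#' (default 259 = 37 weeks exactly), else `TERM_GA`. Exactly 37 weeks is
#' term.
#'
#' @param timeline A timeline row or `Date` pregnancy start.
#' @param birth_date Calendar date of birth (must not precede the start).
#' @param term_threshold_days Term boundary in days.
#' @return A list with `kind` and `ga_days`.
#' @examples
#' classify_ga_outcome(as.Date("2019-07-29"), as.Date("2020-04-02"))  # PRETERM, 248
#' @export
classify_ga_outcome <- function(timeline, birth_date, term_threshold_days = 259L) {
  ga <- gestational_age(timeline, birth_date)
  if (ga$days < 0L) stop("birth date precedes pregnancy start")
  list(kind = if (ga$days < term_threshold_days) "PRETERM" else "TERM_GA",
       ga_days = ga$days)
}

#' Classify a birth weight
#'
#' `LOW_BIRTH_WEIGHT` below `lbw_threshold_oz` ounces (default 88 =
#' 5 lb 8 oz), else `NORMAL_BW`. Exactly 5 lb 8 oz is normal.
#'
#' @param weight A list with `total_ounces` ([parse_birth_weight()]) or a
#'   number of ounces.
#' @param lbw_threshold_oz Low-birth-weight boundary in ounces.
#' @return `"LOW_BIRTH_WEIGHT"` or `"NORMAL_BW"`.
#' @export
classify_weight_outcome <- function(weight, lbw_threshold_oz = 88L) {
  oz <- if (is.list(weight)) weight$total_ounces else as.integer(weight)
  stopifnot(oz > 0L)
  if (oz < lbw_threshold_oz) "LOW_BIRTH_WEIGHT" else "NORMAL_BW"
}

#' Outcome keyword vocabularies
#'
#' Keyword lists driving [detect_outcome_keywords()], shipped as editable
#' plain-text data files (the field's trained outcome classifiers are
#' external models; these transparent lists stand in their place at the same
#' pipeline interface).
#'
#' @return A named list of character vectors: `NICU`, `MISCARRIAGE`,
#'   `STILLBIRTH`, `PRETERM`, `BIRTH_DEFECT`.
#' @export
outcome_terms <- function() {
  list(NICU = c("nicu"),
       MISCARRIAGE = c("miscarriage", "miscarried", "miscarry", "babyloss"),
       STILLBIRTH = c("stillbirth", "stillborn"),
       PRETERM = c("premature", "preemie", "preterm"),
       BIRTH_DEFECT = read_term_file(extdata("birth_defect_terms.txt")))
}

term_set_pattern <- function(terms) {
  paste0("(?<!\\p{L})(?:",
         paste(vapply(terms, term_pattern, ""), collapse = "|"),
         ")(?!\\p{L})")
}

#' Detect outcome keywords in a post
#'
#' Whole-token keyword rules for NICU admission, miscarriage, stillbirth,
#' preterm cues ("premature", "preemie", and "came/born at N weeks" with
#' N < 37) and birth defects (packaged defect-term list).
#'
#' @param post A single-row posts data.frame.
#' @param terms Keyword vocabularies ([outcome_terms()]).
#' @param term_threshold_days Term boundary, for the "came at N weeks" rule.
#' @return Character vector of detected outcome kinds (possibly empty).
#' @export
detect_outcome_keywords <- function(post, terms = outcome_terms(),
                                    term_threshold_days = 259L) {
  stopifnot(nrow(post) == 1L)
  t <- normalise_text(post$text)
  kinds <- names(terms)[vapply(terms, function(v) {
    grepl(term_set_pattern(v), t, perl = TRUE)
  }, TRUE)]
  m <- regexec("\\b(?:came|arrived|born) at (\\d{1,2}) weeks\\b", t, perl = TRUE)
  g <- regmatches(t, m)[[1]]
  if (length(g) && 7L * as.integer(g[2]) < term_threshold_days) {
    kinds <- union(kinds, "PRETERM")
  }
  unique(kinds)
}

#' Evidence that a pregnancy reached term
#'
#' TRUE if some pregnancy-referring post — a weeks anchor, "still pregnant",
#' or due-date talk — is dated at gestational age of at least
#' `term_threshold_days`, or a weeks anchor states at least 37 weeks.
#' Used for the reporting-bias check: posting at term rules out miscarriage
#' and preterm birth.
#'
#' @param timeline A timeline row.
#' @param posts The user's posts.
#' @param term_threshold_days Term boundary in days.
#' @return Logical scalar.
#' @export
detect_term_evidence <- function(timeline, posts, term_threshold_days = 259L) {
  posts <- as_posts(posts)
  anchors <- extract_anchors(posts)
  if (nrow(anchors)) {
    wk <- anchors[anchors$kind %in% c("WEEKS_PREGNANT", "WEEKS_HASHTAG"), , drop = FALSE]
    stated_weeks <- as.integer((wk$post_date - wk$implied_start) / 7)
    if (any(7L * stated_weeks >= term_threshold_days)) return(TRUE)
    ga <- gestational_age(timeline, anchors$post_date)
    if (any(ga$days >= term_threshold_days &
            abs(as.integer(anchors$implied_start - as.Date(timeline$start))) <= 28L)) {
      return(TRUE)
    }
  }
  t <- normalise_text(posts$text)
  refs <- grepl("\\bstill pregnant\\b|\\bdue date\\b|\\bweeks? pregnant\\b", t, perl = TRUE)
  ga <- gestational_age(timeline, posts$post_date)
  any(refs & ga$days >= term_threshold_days & ga$days <= 300L)
}

#' Extract all outcome reports for one pregnancy
#'
#' Orchestrates birth-event detection, gestational-age and birth-weight
#' classification, outcome keyword rules and term evidence over one user's
#' posts, assigning events to the given prenatal window. Timeline-based
#' gestational age wins over a stated "came at N weeks" when both exist.
#'
#' @param timeline A one-row timeline.
#' @param posts The user's posts.
#' @param term_threshold_days,lbw_threshold_oz Clinical thresholds.
#' @param terms Outcome keyword vocabularies.
#' @return A list with `reports` (data.frame: `kind`, `ga_days`, `weight_oz`,
#'   `evidence_post_id`), `term_ga_evidence`, `normal_bw_evidence`.
#' @export
extract_outcomes <- function(timeline, posts, term_threshold_days = 259L,
                             lbw_threshold_oz = 88L, terms = outcome_terms()) {
  posts <- as_posts(posts)
  rows <- list()
  add <- function(kind, post_id, ga_days = NA_integer_, weight_oz = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, ga_days = as.integer(ga_days),
      weight_oz = as.integer(weight_oz), evidence_post_id = post_id,
      stringsAsFactors = FALSE)
  }
  window_end <- as.Date(timeline$end) + 42L   # events up to 6 weeks past due

  for (i in seq_len(nrow(posts))) {
    post <- posts[i, , drop = FALSE]
    ev <- detect_birth_event(post)
    if (!is.null(ev) && ev$date >= as.Date(timeline$start) && ev$date <= window_end) {
      ga <- classify_ga_outcome(timeline, ev$date, term_threshold_days)
      add(ga$kind, post$post_id, ga_days = ga$ga_days)
      if (!is.null(ev$weight)) {
        add(classify_weight_outcome(ev$weight, lbw_threshold_oz), post$post_id,
            weight_oz = ev$weight$total_ounces)
      }
    } else if (!is.null(ev) && !is.na(ev$came_weeks)) {
      # no timeline-consistent date: fall back on the stated weeks
      ga_days <- 7L * ev$came_weeks
      add(if (ga_days < term_threshold_days) "PRETERM" else "TERM_GA",
          post$post_id, ga_days = ga_days)
    }
    for (k in detect_outcome_keywords(post, terms, term_threshold_days)) {
      add(k, post$post_id)
    }
  }
  reports <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(), ga_days = integer(), weight_oz = integer(),
               evidence_post_id = character(), stringsAsFactors = FALSE)
  reports <- unique(reports)
  rownames(reports) <- NULL
  term_ev <- "TERM_GA" %in% reports$kind ||
    detect_term_evidence(timeline, posts, term_threshold_days)
  list(reports = reports,
       term_ga_evidence = term_ev,
       normal_bw_evidence = "NORMAL_BW" %in% reports$kind)
}
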