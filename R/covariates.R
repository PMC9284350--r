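#' Extract self-reported age statements
#'
#' First-person exact-age patterns ("I'm 27", "I am 27 years old", "just
#' turned 30"). Ages outside the plausible maternal range \[13, 55\] are
#' rejected with a diagnostic; third-person ages ("my son is 4") never
#' match.
#'
#' @param posts A posts data.frame.
#' @param age_min,age_max Accepted age bounds in years.
#' @return A data.frame with columns `post_id`, `post_date`, `age_years`
#'   (and a `diagnostics` attribute for rejected values).
#' @export
extract_age <- function(posts, age_min = 13L, age_max = 55L) {
  posts <- as_posts(posts)
  norm <- normalise_text(posts$text)
  pats <- c(
    "\\b(?:i'm|i am) (\\d{1,2})(?!\\d)(?: ?(?:years?|yrs?) old| ?yo\\b)?(?! ?(?:weeks?|wks?|months?|days?|minutes?|hours?))",
    "\\b(?:just )?turned (\\d{1,2})\\b(?! ?(?:weeks?|wks?|months?|days?))"
  )
  rows <- list()
  diags <- character()
  for (i in seq_along(norm)) {
    for (p in pats) {
      m <- regexec(p, norm[i], perl = TRUE)
      g <- regmatches(norm[i], m)[[1]]
      if (length(g)) {
        age <- as.integer(g[2])
        if (age < age_min || age > age_max) {
          diags <- c(diags, sprintf("post %s: age %d outside [%d, %d]; rejected",
                                    posts$post_id[i], age, age_min, age_max))
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            post_id = posts$post_id[i], post_date = posts$post_date[i],
            age_years = age, stringsAsFactors = FALSE)
        }
        break
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(post_id = character(), post_date = as.Date(character()),
               age_years = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "diagnostics") <- diags
  out
}

#' Maternal age during a pregnancy
#'
#' The reference date is the prenatal window midpoint (`start +
#' midpoint_days`, default 140). Using the age report posted nearest the
#' midpoint, age at midpoint = reported age + floor((midpoint - post date) /
#' 365.25). Conflicting reports (implied birth years more than one year
#' apart) or an out-of-range result give `NA` with a diagnostic rather than
#' a guess.
#'
#' @param age_reports Output of [extract_age()] for the user.
#' @param timeline A one-row timeline.
#' @param midpoint_days Offset of the reference date from the start.
#' @return Integer age in years, or `NA`.
#' @export
age_during_pregnancy <- function(age_reports, timeline, midpoint_days = 140L) {
  if (!nrow(age_reports)) return(NA_integer_)
  birth_year <- as.integer(format(age_reports$post_date, "%Y")) - age_reports$age_years
  if (diff(range(birth_year)) > 1L) {
    return(add_diagnostic(NA_integer_,
                          "conflicting age reports (implied birth years differ by > 1); age set missing"))
  }
  midpoint <- as.Date(timeline$start) + midpoint_days
  nearest <- which.min(abs(as.integer(midpoint - age_reports$post_date)))
  age <- age_reports$age_years[nearest] +
    floor(as.integer(midpoint - age_reports$post_date[nearest]) / 365.25)
  age <- as.integer(age)
  if (age < 13L || age > 56L) {
    return(add_diagnostic(NA_integer_, sprintf("computed age %d implausible; set missing", age)))
  }
  age
}

#' Indication vocabulary
#'
#' Conditions beta-blockers are commonly taken for (tachycardia,
#' hypertension, anxiety, migraines, cardiomyopathy, ...), shipped as an
#' editable one-term-per-line data file.
#'
#' @return Character vector of indication terms.
#' @export
indication_terms <- function() {
  read_term_file(extdata("indication_terms.txt"))
}

#' Extract indications for drug use
#'
#' Case-insensitive whole-token vocabulary matches in the posts reporting
#' intake (the indication is the condition the drug was taken for — an
#' important confounder in drug-safety studies).
#'
#' @param intake_posts Posts that report intake for the pregnancy.
#' @param vocabulary Indication terms ([indication_terms()]).
#' @return Character vector of matched indication terms (possibly empty).
#' @export
extract_indication <- function(intake_posts, vocabulary = indication_terms()) {
  if (!nrow(intake_posts)) return(character())
  intake_posts <- as_posts(intake_posts)
  norm <- normalise_text(intake_posts$text)
  hits <- vocabulary[vapply(vocabulary, function(v) {
    any(grepl(term_set_pattern(v), norm, perl = TRUE))
  }, TRUE)]
  unique(unname(hits))
}
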