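#' Exposure classes, from strongest to weakest evidence
#'
#' `EXPLICIT_DURING` (the post itself says intake was during pregnancy) >
#' `INFERRED_DURING` (intake post timestamped inside the prenatal window) >
#' `POSSIBLE` (intake reported outside the window with no evidence of
#' stopping before or starting after pregnancy) > `NOT_DURING` (evidence of
#' stopping before the start or starting after the end) > `UNKNOWN` (no
#' intake reports).
#'
#' @format Character vector, strongest first.
#' @export
exposure_levels <- c("EXPLICIT_DURING", "INFERRED_DURING", "POSSIBLE",
                     "NOT_DURING", "UNKNOWN")

exposure_rank <- function(class) {
  r <- match(class, rev(exposure_levels))
  if (anyNA(r)) stop("unknown exposure class: ",
                     paste(class[is.na(r)], collapse = ", "))
  r
}

# grade a single intake report against a prenatal window
grade_report <- function(cue, date, start, end) {
  if (cue == "EXPLICIT_DURING_PREGNANCY") return("EXPLICIT_DURING")
  if (cue == "STOPPED_BEFORE" && date < start) return("NOT_DURING")
  if (cue == "STARTED_AFTER" && date > end) return("NOT_DURING")
  if (cue == "NONE" && date >= start && date <= end) return("INFERRED_DURING")
  # cue NONE outside the window, or a stop/start cue whose timestamp sits on
  # the other side of the window: no evidence excluding pregnancy-time intake
  "POSSIBLE"
}

#' Classify per-pregnancy drug exposure
#'
#' Each intake report is graded against the prenatal window — explicit
#' "during pregnancy" wording beats timestamp inference, which beats
#' possible (out-of-window) intake, which beats evidence of stopping
#' before/starting after pregnancy — and the pregnancy's exposure class is
#' the maximum grade over its reports ([exposure_levels()] order). With no
#' reports the class is `UNKNOWN`. A single stop/start report never vetoes
#' stronger evidence from other reports.
#'
#' @param timeline A one-row timeline ([estimate_timeline()]).
#' @param reports Data.frame of intake reports with columns `post_id`,
#'   `post_date`, `temporal_cue`, and optionally `user_id` (checked against
#'   the timeline) and `canonical`.
#' @return A one-row data.frame: `user_id`, `pregnancy_index`, `canonical`,
#'   `exposure_class`, `evidence` (semicolon-joined post ids).
#' @export
classify_exposure <- function(timeline, reports) {
  stopifnot(nrow(timeline) == 1L)
  if (!is.null(reports$user_id) && nrow(reports) &&
      any(reports$user_id != timeline$user_id)) {
    stop("intake report from a different user than the timeline")
  }
  if (!nrow(reports)) {
    return(data.frame(user_id = timeline$user_id,
                      pregnancy_index = timeline$pregnancy_index,
                      canonical = NA_character_, exposure_class = "UNKNOWN",
                      evidence = "", stringsAsFactors = FALSE))
  }
  grades <- vapply(seq_len(nrow(reports)), function(i) {
    grade_report(reports$temporal_cue[i], reports$post_date[i],
                 timeline$start, timeline$end)
  }, "")
  best <- grades[which.max(exposure_rank(grades))]
  data.frame(user_id = timeline$user_id,
             pregnancy_index = timeline$pregnancy_index,
             canonical = paste(sort(unique(reports$canonical %||% NA_character_)),
                               collapse = ";"),
             exposure_class = best,
             evidence = paste(reports$post_id, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Assign a user's intake reports to that user's pregnancies
#'
#' Reports timestamped inside one pregnancy's window belong to that pregnancy
#' only; explicit "during pregnancy" reports outside any window go to the
#' nearest window; remaining out-of-window reports are candidates for every
#' pregnancy (graded `POSSIBLE`/`NOT_DURING` there by [classify_exposure()]).
#'
#' @param timelines Timeline rows for a single user.
#' @param reports Intake reports (with `post_date`, `temporal_cue`) for the
#'   same user.
#' @return List of report data.frames, one per timeline row.
#' @export
assign_reports <- function(timelines, reports) {
  n <- nrow(timelines)
  out <- replicate(n, reports[0, , drop = FALSE], simplify = FALSE)
  for (i in seq_len(nrow(reports))) {
    d <- reports$post_date[i]
    inside <- which(d >= timelines$start & d <= timelines$end)
    if (length(inside)) {
      k <- inside[1]
      out[[k]] <- rbind(out[[k]], reports[i, , drop = FALSE])
    } else if (reports$temporal_cue[i] == "EXPLICIT_DURING_PREGNANCY") {
      dist <- pmin(abs(as.integer(d - timelines$start)),
                   abs(as.integer(d - timelines$end)))
      k <- which.min(dist)
      out[[k]] <- rbind(out[[k]], reports[i, , drop = FALSE])
    } else {
      for (k in seq_len(n)) out[[k]] <- rbind(out[[k]], reports[i, , drop = FALSE])
    }
  }
  out
}

#' Tabulate exposure classes over pregnancies
#'
#' Counts and one-decimal percentages of pregnancies per exposure class,
#' plus the derived rows `TAKEN` (explicit + timestamp-inferred) and
#' `TAKEN_OR_MAY_HAVE` (taken + possible). Both interpretations of "taken"
#' are preserved so either can be reported.
#'
#' @param assessments Data.frame of per-pregnancy assessments
#'   ([classify_exposure()] rows); duplicate (user, index) pairs are an
#'   error.
#' @return Data.frame with columns `class`, `count`, `pct`.
#' @export
exposure_tabulate <- function(assessments) {
  key <- paste(assessments$user_id, assessments$pregnancy_index)
  if (anyDuplicated(key)) stop("duplicate pregnancy in assessments")
  n <- nrow(assessments)
  counts <- vapply(exposure_levels, function(cl) {
    sum(assessments$exposure_class == cl)
  }, 0L)
  taken <- counts[["EXPLICIT_DURING"]] + counts[["INFERRED_DURING"]]
  may <- taken + counts[["POSSIBLE"]]
  out <- data.frame(
    class = c(exposure_levels, "TAKEN", "TAKEN_OR_MAY_HAVE"),
    count = c(unname(counts), taken, may),
    stringsAsFactors = FALSE)
  out$pct <- if (n > 0) percentage(out$count, n) else NA_real_
  out
}
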