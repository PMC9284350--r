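#' Extract pregnancy anchors from posts
#'
#' A pregnancy *anchor* is a post whose text plus timestamp imply the
#' pregnancy start date, under a fixed term gestation of `gestation_days`
#' (default 280 days = 40 weeks). Recognised anchor kinds:
#'
#' * `DUE_DATE_COUNTDOWN` — "N days til/until my due date":
#'   `implied_start = post_date + N - gestation_days`
#' * `WEEKS_PREGNANT` — "N weeks pregnant": `implied_start = post_date - 7N`
#' * `WEEKS_HASHTAG` — "#Nweekspregnant": as above
#' * `DUE_DATE_EXPLICIT` — "due <date>" (month-name or ISO date, four-digit
#'   year required): `implied_start = stated_date - gestation_days`
#'
#' Anchors violating plausibility (implied start after the post, or more
#' than 310 days before it) are dropped with a diagnostic; unparsable
#' numerals are skipped.
#'
#' @param posts A posts data.frame ([as_posts()]).
#' @param gestation_days Term gestation length in days.
#' @return A data.frame with columns `user_id`, `post_id`, `kind`,
#'   `implied_start` (`Date`), `post_date`; a `diagnostics` attribute lists
#'   dropped anchors.
#' @examples
#' p <- as_posts(data.frame(user_id = "u1", post_id = "p1",
#'                          created_at = "2020-01-25T00:00:00Z",
#'                          text = "exactly 100 days til my due date!"))
#' extract_anchors(p)$implied_start   # 2019-07-29
#' @export
extract_anchors <- function(posts, gestation_days = 280L) {
  posts <- as_posts(posts)
  norm <- normalise_text(posts$text)
  rows <- list()
  diags <- character()

  grab <- function(pattern, text) {
    m <- regexec(pattern, text, perl = TRUE)
    regmatches(text, m)[[1]]
  }

  for (i in seq_len(nrow(posts))) {
    text <- norm[i]
    d <- posts$post_date[i]
    found <- list()

    g <- grab("\\b(?:exactly )?(\\d{1,3}) (?:more )?days? (?:till?|until|'til) (?:my |our |the )?due date", text)
    if (length(g)) {
      n <- suppressWarnings(as.integer(g[2]))
      if (!is.na(n)) found$DUE_DATE_COUNTDOWN <- d + n - gestation_days
    }

    g <- grab("#(\\d{1,2}) ?weeks?pregnant", text)
    if (length(g)) {
      n <- suppressWarnings(as.integer(g[2]))
      if (!is.na(n)) found$WEEKS_HASHTAG <- d - 7L * n
    }

    g <- grab("\\b(\\d{1,2}) weeks? pregnant\\b", text)
    if (length(g)) {
      n <- suppressWarnings(as.integer(g[2]))
      if (!is.na(n)) found$WEEKS_PREGNANT <- d - 7L * n
    }

    g <- grab(paste0("\\bdue\\b (?:on |date (?:is|was) )?(",
                     textual_date_pattern(), "|", iso_date_pattern(), ")"), text)
    if (length(g)) {
      stated <- find_date_in_text(g[2])
      if (!is.na(stated)) found$DUE_DATE_EXPLICIT <- stated - gestation_days
    }

    for (kind in names(found)) {
      s <- found[[kind]]
      if (s > d || as.integer(d - s) > 310L) {
        diags <- c(diags, sprintf("post %s: implausible %s anchor (implied start %s) dropped",
                                  posts$post_id[i], kind, format(s)))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        user_id = posts$user_id[i], post_id = posts$post_id[i], kind = kind,
        implied_start = s, post_date = d, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(user_id = character(), post_id = character(), kind = character(),
               implied_start = as.Date(character()), post_date = as.Date(character()),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "diagnostics") <- diags
  out
}

#' Segment a user's anchors into candidate pregnancies
#'
#' One user's posting history may span several years and several pregnancies.
#' Anchors are sorted by implied start date and split at gaps of at least
#' `pregnancy_gap_days` (default 180) into candidate pregnancies. A candidate
#' whose implied starts span more than `cluster_tolerance_days` (default 28)
#' is internally inconsistent: it is rejected with a diagnostic rather than
#' guessed at, and contributes no timeline.
#'
#' @param anchors Anchor data.frame for a single user ([extract_anchors()]).
#' @param cluster_tolerance_days Maximum spread of implied starts within one
#'   pregnancy.
#' @param pregnancy_gap_days Minimum gap between implied starts of distinct
#'   pregnancies.
#' @return A list of clusters, each `list(anchors = <data.frame>,
#'   accepted = <logical>, reason = <character>)`.
#' @export
segment_pregnancies <- function(anchors, cluster_tolerance_days = 28L,
                                pregnancy_gap_days = 180L) {
  if (!nrow(anchors)) return(list())
  if (length(unique(anchors$user_id)) > 1L) {
    stop("segment_pregnancies() expects anchors from a single user")
  }
  anchors <- anchors[order(anchors$implied_start, anchors$post_date), , drop = FALSE]
  gaps <- as.integer(diff(anchors$implied_start))
  cluster_id <- cumsum(c(1L, as.integer(gaps >= pregnancy_gap_days)))
  lapply(split(anchors, cluster_id), function(cl) {
    span <- as.integer(max(cl$implied_start) - min(cl$implied_start))
    if (span > cluster_tolerance_days) {
      list(anchors = cl, accepted = FALSE,
           reason = sprintf("conflicting anchors: implied starts span %d days (> %d tolerance, < %d pregnancy gap)",
                            span, cluster_tolerance_days, pregnancy_gap_days))
    } else {
      list(anchors = cl, accepted = TRUE, reason = NA_character_)
    }
  })
}

#' Estimate a prenatal window from an accepted anchor cluster
#'
#' The pregnancy start is the median of the cluster's implied start dates
#' (lower median for even counts, so ties resolve to the earliest); the end
#' is `start + gestation_days`. No anchor kind is privileged over another.
#'
#' @param cluster An accepted cluster from [segment_pregnancies()], or its
#'   anchor data.frame.
#' @param index Ordinal of this pregnancy within the user.
#' @param gestation_days Term gestation length in days.
#' @return One-row data.frame: `user_id`, `pregnancy_index`, `start`, `end`,
#'   `n_anchors`.
#' @export
estimate_timeline <- function(cluster, index = 1L, gestation_days = 280L) {
  anchors <- if (is.data.frame(cluster)) cluster else cluster$anchors
  if (is.null(anchors) || !nrow(anchors)) stop("empty anchor cluster")
  s <- sort(anchors$implied_start)
  start <- s[ceiling(length(s) / 2)]   # lower median: ties toward earliest
  data.frame(user_id = anchors$user_id[1], pregnancy_index = as.integer(index),
             start = start, end = start + gestation_days,
             n_anchors = nrow(anchors), stringsAsFactors = FALSE)
}

#' Estimate all prenatal windows in a corpus
#'
#' Convenience wrapper: runs [segment_pregnancies()] and [estimate_timeline()]
#' per user over an anchor table.
#'
#' @inheritParams segment_pregnancies
#' @inheritParams estimate_timeline
#' @return A data.frame of timelines (`user_id`, `pregnancy_index`, `start`,
#'   `end`, `n_anchors`), with a `rejected` attribute holding rejected
#'   clusters and an `anchors_by_timeline` attribute (list of anchor
#'   data.frames, aligned with rows).
#' @export
estimate_timelines <- function(anchors, gestation_days = 280L,
                               cluster_tolerance_days = 28L,
                               pregnancy_gap_days = 180L) {
  empty <- data.frame(user_id = character(), pregnancy_index = integer(),
                      start = as.Date(character()), end = as.Date(character()),
                      n_anchors = integer(), stringsAsFactors = FALSE)
  if (!nrow(anchors)) {
    attr(empty, "rejected") <- list()
    attr(empty, "anchors_by_timeline") <- list()
    return(empty)
  }
  rows <- list()
  kept_anchors <- list()
  rejected <- list()
  for (u in unique(anchors$user_id)) {
    clusters <- segment_pregnancies(anchors[anchors$user_id == u, , drop = FALSE],
                                    cluster_tolerance_days, pregnancy_gap_days)
    idx <- 0L
    for (cl in clusters) {
      if (!cl$accepted) {
        rejected[[length(rejected) + 1L]] <- cl
        next
      }
      idx <- idx + 1L
      rows[[length(rows) + 1L]] <- estimate_timeline(cl, idx, gestation_days)
      kept_anchors[[length(kept_anchors) + 1L]] <- cl$anchors
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  attr(out, "anchors_by_timeline") <- kept_anchors
  out
}

#' Gestational age at a date
#'
#' Days elapsed since the pregnancy start (negative before the start) and
#' completed weeks (floor of days / 7; a birth "between 35 and 36 weeks
#' gestation" is 35 completed weeks).
#'
#' @param timeline A timeline row (anything with a `start` field) or a `Date`
#'   start.
#' @param date Calendar date(s) at which to evaluate.
#' @return A data.frame with columns `days` and `weeks`.
#' @examples
#' gestational_age(as.Date("2019-07-29"), as.Date("2020-04-02"))  # 248 d, 35 wk
#' @export
gestational_age <- function(timeline, date) {
  start <- if (inherits(timeline, "Date")) timeline else as.Date(timeline$start)
  days <- as.integer(as.Date(date) - start)
  data.frame(days = days, weeks = as.integer(floor(days / 7)))
}
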