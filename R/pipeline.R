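#' Pipeline configuration
#'
#' Tunable constants of the cohort pipeline, with the defaults used
#' throughout: a 280-day (40-week) term gestation, a 28-day anchor cluster
#' tolerance, a 180-day gap separating distinct pregnancies, a 259-day
#' (37-week) term threshold, an 88-oz (5 lb 8 oz) low-birth-weight
#' threshold, and the window midpoint (start + 140 days) as the maternal-age
#' reference date.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(gestation_days = 280L, cluster_tolerance_days = 28L,
              pregnancy_gap_days = 180L, term_threshold_days = 259L,
              lbw_threshold_oz = 88L, midpoint_days = 140L,
              age_min = 13L, age_max = 55L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- lapply(over, as.integer)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Path to a YAML file with a subset of the config keys.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals %||% list())
}

#' Run the full cohort pipeline on a post corpus
#'
#' Executes mention detection, intake classification, anchor extraction and
#' timeline estimation, per-pregnancy exposure classification, outcome and
#' covariate extraction, and cohort assembly.
#'
#' @param posts A posts data.frame or path to a JSON-lines corpus.
#' @param lexicon A `drug_lexicon`.
#' @param config A `pipeline_config`.
#' @return A list of class `pregnancy_pipeline` with elements `mentions`,
#'   `intake` (mentions with intake flags), `anchors`, `timelines`,
#'   `exposures` (one row per pregnancy with a timeline), `outcomes`,
#'   `covariates`, `records` ([build_cohort()] output) and `summary`.
#' @export
run_pipeline <- function(posts, lexicon = default_lexicon(),
                         config = pipeline_config()) {
  if (is.character(posts) && length(posts) == 1) posts <- read_posts(posts)
  posts <- as_posts(posts)

  mentions <- find_mentions(posts, lexicon)
  intake <- classify_intake(posts, mentions)

  anchors <- extract_anchors(posts, config$gestation_days)
  timelines <- estimate_timelines(anchors, config$gestation_days,
                                  config$cluster_tolerance_days,
                                  config$pregnancy_gap_days)

  intake_reports <- intake[intake$is_intake, , drop = FALSE]
  if (nrow(intake_reports)) {
    pidx <- match(intake_reports$post_id, posts$post_id)
    intake_reports$user_id <- posts$user_id[pidx]
    intake_reports$post_date <- posts$post_date[pidx]
  } else {
    intake_reports$user_id <- character()
    intake_reports$post_date <- as.Date(character())
  }

  exposures <- list()
  outcomes <- list()
  covariates <- list()
  for (u in unique(timelines$user_id)) {
    tl_u <- timelines[timelines$user_id == u, , drop = FALSE]
    rep_u <- intake_reports[intake_reports$user_id == u, , drop = FALSE]
    posts_u <- posts[posts$user_id == u, , drop = FALSE]
    ages_u <- extract_age(posts_u, config$age_min, config$age_max)
    by_preg <- assign_reports(tl_u, rep_u)
    for (j in seq_len(nrow(tl_u))) {
      tl <- tl_u[j, , drop = FALSE]
      key <- paste(tl$user_id, tl$pregnancy_index)
      exposures[[key]] <- classify_exposure(tl, by_preg[[j]])
      outcomes[[key]] <- extract_outcomes(tl, posts_u,
                                          config$term_threshold_days,
                                          config$lbw_threshold_oz)
      ipost <- posts_u[posts_u$post_id %in% by_preg[[j]]$post_id, , drop = FALSE]
      covariates[[key]] <- list(
        maternal_age = age_during_pregnancy(ages_u, tl, config$midpoint_days),
        indications = extract_indication(ipost))
    }
  }
  exposures_df <- if (length(exposures)) do.call(rbind, c(exposures, make.row.names = FALSE)) else
    data.frame(user_id = character(), pregnancy_index = integer(),
               canonical = character(), exposure_class = character(),
               evidence = character(), stringsAsFactors = FALSE)

  records <- build_cohort(exposures_df, outcomes, covariates)
  structure(list(posts = posts, mentions = mentions, intake = intake,
                 anchors = anchors, timelines = timelines,
                 exposures = exposures_df, outcomes = outcomes,
                 covariates = covariates, records = records,
                 summary = summarize_cohort(records), config = config),
            class = "pregnancy_pipeline")
}

#' @export
print.pregnancy_pipeline <- function(x, ...) {
  cat("<pregnancy_pipeline>\n")
  cat("  posts:      ", nrow(x$posts), " from ", length(unique(x$posts$user_id)),
      " user(s)\n", sep = "")
  cat("  mentions:   ", nrow(x$mentions), " (", sum(x$intake$is_intake),
      " intake reports)\n", sep = "")
  cat("  timelines:  ", nrow(x$timelines), "\n", sep = "")
  cat("  cohort:     ", nrow(x$records), " exposed pregnancies (",
      attr(x$records, "n_excluded"), " excluded)\n", sep = "")
  invisible(x)
}

#' Packaged worked-example fixtures
#'
#' Two small post corpora with hand-checked expected cohort records,
#' packaged as JSON-lines plus an expected-values CSV. `load_fixture()`
#' returns the posts and expectations; `run_fixture()` pushes the posts
#' through the full pipeline and diffs the resulting record against the
#' expectation field by field.
#'
#' @param name Fixture name: `"user1"` or `"user2"`.
#' @return `load_fixture()`: a list with `posts` and `expected`.
#'   `run_fixture()`: a list with `pass` (logical), `diffs` (character
#'   vector of mismatches), `record` (the computed cohort row) and
#'   `pipeline`.
#' @examples
#' run_fixture("user1")$pass
#' @export
load_fixture <- function(name) {
  posts <- read_posts(extdata("fixtures", paste0(name, ".jsonl")))
  exp_all <- utils::read.csv(extdata("fixtures", "expected_cohort.csv"),
                             stringsAsFactors = FALSE, colClasses = "character")
  expected <- exp_all[exp_all$fixture == name, , drop = FALSE]
  list(posts = posts, expected = expected)
}

#' @rdname load_fixture
#' @export
run_fixture <- function(name) {
  fx <- load_fixture(name)
  pl <- run_pipeline(fx$posts)
  diffs <- character()
  if (nrow(fx$expected) == 0 && nrow(fx$posts) == 0) {
    return(list(pass = nrow(pl$records) == 0, diffs = diffs,
                record = pl$records, pipeline = pl))
  }
  if (nrow(pl$records) != nrow(fx$expected)) {
    return(list(pass = FALSE,
                diffs = sprintf("expected %d cohort record(s), got %d",
                                nrow(fx$expected), nrow(pl$records)),
                record = pl$records, pipeline = pl))
  }
  expect_one <- function(field, got, want) {
    if (!identical(as.character(got), want)) {
      diffs <<- c(diffs, sprintf("%s: expected '%s', got '%s'", field, want, got))
    }
  }
  for (i in seq_len(nrow(fx$expected))) {
    e <- fx$expected[i, ]
    r <- pl$records[pl$records$user_id == e$user_id &
                    pl$records$pregnancy_index == as.integer(e$pregnancy_index), ,
                    drop = FALSE]
    if (nrow(r) != 1) {
      diffs <- c(diffs, sprintf("no unique record for user %s pregnancy %s",
                                e$user_id, e$pregnancy_index))
      next
    }
    tl <- pl$timelines[pl$timelines$user_id == e$user_id, , drop = FALSE]
    expect_one("start", format(tl$start[1]), e$start)
    expect_one("end", format(tl$end[1]), e$end)
    expect_one("exposure_class", r$exposure_class, e$exposure_class)
    got_adverse <- paste(sort(.adverse_kinds[vapply(.adverse_kinds,
                                                    function(k) r[[k]], TRUE)]),
                         collapse = ";")
    want_adverse <- paste(sort(strsplit(e$adverse_outcomes, ";")[[1]]), collapse = ";")
    expect_one("adverse_outcomes", got_adverse, want_adverse)
    expect_one("ga_days", r$ga_days, e$ga_days)
    expect_one("weight_oz", r$weight_oz, e$weight_oz)
    expect_one("term_ga_evidence", r$term_ga_evidence, e$term_ga_evidence)
    expect_one("normal_bw_evidence", r$normal_bw_evidence, e$normal_bw_evidence)
    expect_one("indications", r$indications, e$indications)
  }
  list(pass = !length(diffs), diffs = diffs, record = pl$records, pipeline = pl)
}
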