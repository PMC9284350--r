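test_that("single-report grading follows the window rules", {
  tl <- tiny_timeline("2019-07-29")   # window ends 2020-05-04
  cls <- function(cue, date) {
    classify_exposure(tl, intake_report(cue, date))$exposure_class
  }
  expect_equal(cls("EXPLICIT_DURING_PREGNANCY", "2020-04-16"), "EXPLICIT_DURING")
  expect_equal(cls("NONE", "2020-03-26"), "INFERRED_DURING")
  expect_equal(cls("NONE", as.Date("2020-05-04") + 100), "POSSIBLE")
  expect_equal(cls("NONE", "2019-01-01"), "POSSIBLE")
  expect_equal(cls("STOPPED_BEFORE", "2019-05-01"), "NOT_DURING")
  expect_equal(cls("STARTED_AFTER", "2020-08-01"), "NOT_DURING")
  expect_equal(classify_exposure(tl, intake_report("NONE", "2020-01-01")[0, ])$exposure_class,
               "UNKNOWN")
  expect_error(classify_exposure(tl, intake_report("NONE", "2020-01-01", user_id = "someone_else")),
               "different user")
})

test_that("window boundary dates count as inferred-during", {
  tl <- tiny_timeline("2019-07-29")
  r <- classify_exposure(tl, intake_report("NONE", "2019-07-29"))
  expect_equal(r$exposure_class, "INFERRED_DURING")
  r <- classify_exposure(tl, intake_report("NONE", "2020-05-04"))
  expect_equal(r$exposure_class, "INFERRED_DURING")
})

test_that("class is the maximum over reports: brute-force oracle on report sets of size <= 5", {
  # independent oracle: grade each report by the written rules, then walk the
  # ordering from strongest to weakest and take the first grade present
  oracle_grade <- function(cue, date, start, end) {
    if (cue == "EXPLICIT_DURING_PREGNANCY") return("EXPLICIT_DURING")
    if (cue == "NONE") {
      return(if (date >= start && date <= end) "INFERRED_DURING" else "POSSIBLE")
    }
    stopped <- cue == "STOPPED_BEFORE" && date < start
    started <- cue == "STARTED_AFTER" && date > end
    if (stopped || started) "NOT_DURING" else "POSSIBLE"
  }
  oracle_class <- function(reports, tl) {
    if (!nrow(reports)) return("UNKNOWN")
    grades <- mapply(oracle_grade, reports$temporal_cue,
                     as.list(reports$post_date),
                     MoreArgs = list(start = tl$start, end = tl$end))
    for (cl in c("EXPLICIT_DURING", "INFERRED_DURING", "POSSIBLE", "NOT_DURING")) {
      if (cl %in% grades) return(cl)
    }
    "UNKNOWN"
  }
  tl <- tiny_timeline("2019-07-29")
  cues <- c("NONE", "EXPLICIT_DURING_PREGNANCY", "STOPPED_BEFORE", "STARTED_AFTER")
  set.seed(402)
  for (i in 1:300) {
    n <- sample(0:5, 1)
    reports <- data.frame(
      user_id = rep("u1", n), post_id = sprintf("p%d", seq_len(n)),
      canonical = rep("atenolol", n),
      post_date = tl$start + sample(-400:500, n, replace = TRUE),
      temporal_cue = sample(cues, n, replace = TRUE),
      stringsAsFactors = FALSE)
    expect_equal(classify_exposure(tl, reports)$exposure_class,
                 oracle_class(reports, tl))
  }
})

test_that("the class maximum is monotone and permutation-invariant", {
  tl <- tiny_timeline("2019-07-29")
  explicit <- intake_report("EXPLICIT_DURING_PREGNANCY", "2020-04-16", post_id = "pe")
  weak <- intake_report("NONE", "2021-01-01", post_id = "pw")   # POSSIBLE grade
  both <- rbind(explicit, weak)
  expect_equal(classify_exposure(tl, explicit)$exposure_class, "EXPLICIT_DURING")
  expect_equal(classify_exposure(tl, both)$exposure_class, "EXPLICIT_DURING")
  expect_equal(classify_exposure(tl, both[2:1, ])$exposure_class, "EXPLICIT_DURING")
})

test_that("report assignment respects windows of multiple pregnancies", {
  tls <- rbind(tiny_timeline("2018-01-01", index = 1L),
               tiny_timeline("2020-01-01", index = 2L))
  reports <- rbind(
    intake_report("NONE", "2018-03-01", post_id = "in_first"),
    intake_report("NONE", "2020-03-01", post_id = "in_second"),
    intake_report("NONE", "2019-06-01", post_id = "between"),
    intake_report("EXPLICIT_DURING_PREGNANCY", "2019-11-20", post_id = "explicit_near_2nd"))
  by_preg <- assign_reports(tls, reports)
  expect_equal(by_preg[[1]]$post_id, c("in_first", "between"))
  expect_equal(by_preg[[2]]$post_id, c("in_second", "between", "explicit_near_2nd"))
})

test_that("exposure tabulation reproduces the taken / taken-or-may-have split", {
  mk <- function(class, n, offset = 0) {
    data.frame(user_id = sprintf("u%d", offset + seq_len(n)), pregnancy_index = 1L,
               canonical = "atenolol", exposure_class = class, evidence = "p",
               stringsAsFactors = FALSE)
  }
  assess <- rbind(mk("EXPLICIT_DURING", 30), mk("INFERRED_DURING", 28, 100),
                  mk("POSSIBLE", 199, 200), mk("NOT_DURING", 60, 500),
                  mk("UNKNOWN", 39, 600))
  tab <- exposure_tabulate(assess)
  expect_equal(tab$count[tab$class == "TAKEN"], 58)
  expect_equal(tab$pct[tab$class == "TAKEN"], 16.3)
  expect_equal(tab$pct[tab$class == "POSSIBLE"], 55.9)
  expect_equal(tab$count[tab$class == "TAKEN_OR_MAY_HAVE"], 257)
  expect_equal(tab$pct[tab$class == "TAKEN_OR_MAY_HAVE"], 72.2)

  dup <- rbind(mk("POSSIBLE", 1), mk("POSSIBLE", 1))
  expect_error(exposure_tabulate(dup), "duplicate")

  one <- mk("EXPLICIT_DURING", 1)
  expect_equal(exposure_tabulate(one)$pct[1], 100.0)
  unk <- mk("UNKNOWN", 4)
  tab <- exposure_tabulate(unk)
  expect_true(all(tab$pct[tab$class %in% c("TAKEN", "TAKEN_OR_MAY_HAVE")] == 0))
})
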