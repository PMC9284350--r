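test_that("birth weights parse across dialects and reject bad values", {
  expect_equal(parse_birth_weight("4lbs 12oz, 18 inches")$total_ounces, 76L)
  expect_equal(parse_birth_weight("7lbs 5oz 20 inches long")$total_ounces, 117L)
  expect_equal(parse_birth_weight("5 pounds and 8 ounces")$total_ounces, 88L)
  expect_equal(parse_birth_weight("6 pounds 2 ounces")$total_ounces, 98L)
  expect_equal(parse_birth_weight("8 lb 1 oz of joy")$total_ounces, 129L)
  w <- parse_birth_weight("she weighed 7lbs")
  expect_equal(c(w$pounds, w$ounces), c(7L, 0L))
  expect_null(parse_birth_weight("no weight mentioned"))
  expect_message(bad <- parse_birth_weight("5lbs 17oz"), "ounces >= 16")
  expect_null(bad)
  expect_message(metric <- parse_birth_weight("3.2 kg at birth"), "metric")
  expect_null(metric)
})

test_that("birth weight formatting round-trips through the parser", {
  set.seed(5)
  for (i in 1:30) {
    w <- list(pounds = sample(1:12, 1), ounces = sample(0:15, 1))
    re <- parse_birth_weight(format_birth_weight(w))
    expect_equal(re$pounds, w$pounds)
    expect_equal(re$ounces, w$ounces)
    expect_equal(re$total_ounces, 16L * w$pounds + w$ounces)
  }
})

test_that("birth events are detected with stated-date preference", {
  ev <- detect_birth_event(one_post(
    "Officially introducing [name], born April 2nd, 2020. 4lbs 12oz, 18 inches",
    "2020-04-03"))
  expect_equal(ev$date, as.Date("2020-04-02"))
  expect_equal(ev$weight$total_ounces, 76L)

  ev <- detect_birth_event(one_post("Introducing [name] 7lbs 5oz 20 inches long", "2020-06-11"))
  expect_equal(ev$date, as.Date("2020-06-11"))   # no stated date: post date stands in

  ev <- detect_birth_event(one_post("she came at 35 weeks, tiny and perfect", "2020-04-10"))
  expect_equal(ev$came_weeks, 35L)

  expect_null(detect_birth_event(one_post("happy birthday to my mom")))
})

test_that("gestational-age and weight dichotomies are exhaustive, exclusive and boundary-exact", {
  S <- as.Date("2019-07-29")
  r <- classify_ga_outcome(S, as.Date("2020-04-02"))
  expect_equal(r$kind, "PRETERM")
  expect_equal(r$ga_days, 248L)
  expect_equal(classify_ga_outcome(as.Date("2019-09-16"), as.Date("2020-06-11"))$kind, "TERM_GA")
  expect_equal(classify_ga_outcome(S, S + 259)$kind, "TERM_GA")   # exactly 37 weeks
  expect_equal(classify_ga_outcome(S, S + 258)$kind, "PRETERM")
  expect_error(classify_ga_outcome(S, S - 1), "precedes")

  expect_equal(classify_weight_outcome(76L), "LOW_BIRTH_WEIGHT")
  expect_equal(classify_weight_outcome(117L), "NORMAL_BW")
  expect_equal(classify_weight_outcome(88L), "NORMAL_BW")
  expect_equal(classify_weight_outcome(87L), "LOW_BIRTH_WEIGHT")
  for (ga in c(100L, 258L, 259L, 300L)) {
    expect_length(intersect(classify_ga_outcome(S, S + ga)$kind, c("PRETERM", "TERM_GA")), 1L)
  }
})

test_that("the term threshold shifts classifications monotonically", {
  S <- as.Date("2020-01-01")
  kinds_at <- function(thr) {
    vapply(250:270, function(d) classify_ga_outcome(S, S + d, thr)$kind, "")
  }
  strict <- kinds_at(266L)   # 38-week threshold
  std <- kinds_at(259L)
  expect_true(all(which(std == "PRETERM") %in% which(strict == "PRETERM")))
})

test_that("outcome keywords cover the published examples", {
  expect_setequal(detect_outcome_keywords(one_post("She's in NICU due to being premature")),
                  c("NICU", "PRETERM"))
  expect_setequal(detect_outcome_keywords(one_post("One of the worst parts of #miscarriage")),
                  "MISCARRIAGE")
  expect_setequal(detect_outcome_keywords(one_post("born with Craniosynostosis (Sagittal)")),
                  "BIRTH_DEFECT")
  expect_setequal(detect_outcome_keywords(one_post("[name] came at 35 weeks. My baby is small, even for a preemie.")),
                  "PRETERM")
  expect_length(detect_outcome_keywords(one_post("came at 38 weeks, right on time")), 0L)
  expect_length(detect_outcome_keywords(one_post("lovely day at the park")), 0L)
})

test_that("term evidence requires a pregnancy-referring post at term gestation", {
  tl <- tiny_timeline("2019-09-16")
  expect_true(detect_term_evidence(tl, one_post("#37weekspregnant", "2020-06-01")))
  expect_true(detect_term_evidence(tl, one_post("still pregnant! so done", format(as.Date("2019-09-16") + 260))))
  expect_false(detect_term_evidence(tl, one_post("20 weeks pregnant", format(as.Date("2019-09-16") + 140))))
  expect_false(detect_term_evidence(tl, one_post("what a day", format(as.Date("2019-09-16") + 260))))
})

test_that("per-pregnancy outcome extraction assembles reports and evidence flags", {
  tl <- tiny_timeline("2019-07-29")
  posts <- make_posts(
    c("exactly 100 days til my due date!",
      "Officially introducing [name], born April 2nd, 2020. 4lbs 12oz. She's in NICU due to being premature"),
    c("2020-01-25", "2020-04-03"))
  oc <- extract_outcomes(tl, posts)
  expect_setequal(unique(oc$reports$kind), c("PRETERM", "NICU", "LOW_BIRTH_WEIGHT"))
  expect_equal(oc$reports$ga_days[oc$reports$kind == "PRETERM" & !is.na(oc$reports$ga_days)], 248L)
  expect_false(oc$term_ga_evidence)
  expect_false(oc$normal_bw_evidence)

  tl2 <- tiny_timeline("2019-09-16")
  posts2 <- make_posts(c("#37weekspregnant", "Introducing [name] 7lbs 5oz"),
                       c("2020-06-01", "2020-06-11"))
  oc2 <- extract_outcomes(tl2, posts2)
  expect_setequal(unique(oc2$reports$kind), c("TERM_GA", "NORMAL_BW"))
  expect_true(oc2$term_ga_evidence)
  expect_true(oc2$normal_bw_evidence)
})
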