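#' Synthetic-corpus configuration
#'
#' Parameters of the synthetic post-corpus generator. The defaults are the
#' rates of the study conditions the package targets: 45.6% of drug-mention
#' posts are true intake reports, 27.9% of intake users have an estimable
#' prenatal timeline, exposure splits 58/199/99 over taken / possibly taken
#' / not-during among 356 pregnancies, per-outcome rates 8.9% preterm, 4.7%
#' NICU, 3.5% low birth weight, 1.6% birth defect, 0.4% miscarriage, 0%
#' stillbirth, and reporting rates of 90.4% (term gestational age) and
#' 22.8% (normal birth weight) among non-adverse pregnancies; maternal age
#' is identifiable for 86.4% and an indication for 76.7%.
#'
#' @param n_users Number of users to simulate.
#' @param posts_per_user Mean number of posts per user (structural posts are
#'   generated as needed; distractors fill up to this mean).
#' @param intake_rate Probability that a drug-mention post is a true intake
#'   report.
#' @param timeline_rate Probability that an intake user has an estimable
#'   timeline.
#' @param exposure_split Probabilities over taken / possible / neither.
#' @param explicit_share Among "taken", share reported explicitly ("during
#'   my pregnancy") rather than inferred from the timestamp.
#' @param outcome_rates Named per-outcome probabilities, sampled
#'   independently per exposed pregnancy.
#' @param report_term_ga,report_normal_bw Probability that a non-adverse
#'   pregnancy posts term-gestational-age / normal-birth-weight evidence.
#' @param age_rate,indication_rate Probability that a timeline user posts an
#'   exact age / that an intake post names an indication.
#' @param seed Integer seed; a fixed seed gives byte-identical corpora, and
#'   per-user substreams keep early users stable when `n_users` grows.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_users = 500L, posts_per_user = 8,
                       intake_rate = 0.456, timeline_rate = 0.279,
                       exposure_split = c(taken = 58, possible = 199, neither = 99) / 356,
                       explicit_share = 0.5,
                       outcome_rates = c(PRETERM = 0.089, NICU = 0.047,
                                         LOW_BIRTH_WEIGHT = 0.035,
                                         BIRTH_DEFECT = 0.016,
                                         MISCARRIAGE = 0.004, STILLBIRTH = 0),
                       report_term_ga = 0.904, report_normal_bw = 0.228,
                       age_rate = 0.864, indication_rate = 0.767, seed = 1L) {
  cfg <- list(n_users = as.integer(n_users), posts_per_user = posts_per_user,
              intake_rate = intake_rate, timeline_rate = timeline_rate,
              exposure_split = exposure_split, explicit_share = explicit_share,
              outcome_rates = outcome_rates, report_term_ga = report_term_ga,
              report_normal_bw = report_normal_bw, age_rate = age_rate,
              indication_rate = indication_rate, seed = as.integer(seed))
  probs <- c(cfg$intake_rate, cfg$timeline_rate, cfg$explicit_share,
             cfg$outcome_rates, cfg$report_term_ga, cfg$report_normal_bw,
             cfg$age_rate, cfg$indication_rate, cfg$exposure_split)
  if (any(probs < 0 | probs > 1) || anyNA(probs)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (abs(sum(cfg$exposure_split) - 1) > 1e-8) stop("exposure_split must sum to 1")
  if (cfg$report_normal_bw > cfg$report_term_ga) {
    stop("report_normal_bw cannot exceed report_term_ga: a posted term birth weight implies term-gestational-age evidence")
  }
  if (length(cfg$exposure_split) != 3) stop("exposure_split needs 3 components")
  if (cfg$n_users < 1L) stop("n_users must be positive")
  structure(cfg, class = "sim_config")
}

format_sim_date <- function(d) {
  sprintf("%s %d, %s", month.name[as.integer(format(d, "%m"))],
          as.integer(format(d, "%d")), format(d, "%Y"))
}

.sim_distractors <- c(
  "what a gorgeous sunset over the lake tonight",
  "coffee first, questions later",
  "traffic on the bridge was unbelievable today",
  "weekend hike with the dog was exactly what i needed",
  "finally finished that puzzle, 1000 pieces",
  "new season of my favourite show dropped, see you never",
  "the garden tomatoes are finally turning red")

.sim_nonintake <- c(
  "my mom takes %s for her heart and swears by it",
  "reading about %s side effects online, wild stuff",
  "the pharmacy was out of %s again this month")

.sim_indications <- c("tachycardia", "hypertension", "anxiety", "migraines",
                      "cardiomyopathy", "palpitations")

.sim_defects <- c("craniosynostosis", "spina bifida", "cleft lip", "gastroschisis")

#' Generate a synthetic post corpus with ground-truth labels
#'
#' Builds per-user post timelines from templated text — pregnancy anchors
#' (due-date countdowns, weeks-pregnant statements, week hashtags), intake
#' posts with or without "during my pregnancy", birth announcements with
#' pounds/ounces weights, outcome posts, age statements, and distractor
#' posts including non-intake drug mentions. Every template is parseable by
#' the corresponding extractor, and all anchor posts are dated to imply the
#' true start exactly, so on these noise-free corpora the pipeline should
#' recover the truth perfectly. Outcomes are sampled independently per
#' pregnancy; when several co-occur each gets its own post.
#'
#' @param config A [sim_config()].
#' @param lexicon Drug lexicon supplying mention surfaces.
#' @return A list with `posts` (a posts data.frame) and `truth`, itself a
#'   list of data.frames: `posts` (post-level mention/intake labels),
#'   `users` (mention/intake/timeline flags) and `pregnancies` (true window,
#'   exposure class, outcome flags, reporting-evidence flags, age,
#'   indication).
#' @export
simulate_corpus <- function(config = sim_config(), lexicon = default_lexicon()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  user_seeds <- sample.int(.Machine$integer.max - 1L, config$n_users)
  drugs <- names(lexicon$entries)
  drugs <- setdiff(drugs, "beta blocker")   # keep single-token surfaces in templates

  acc <- list(user_id = list(), post_id = list(), created_at = list(),
              text = list(), is_mention = list(), is_intake = list())
  preg <- list()

  for (u in seq_len(config$n_users)) {
    set.seed(user_seeds[u])
    uid <- sprintf("su%05d", u)
    texts <- character(); dates <- as.Date(character())
    ment <- logical(); intk <- logical()
    push <- function(text, date, mention = FALSE, intake = FALSE) {
      texts <<- c(texts, text); dates <<- c(dates, date)
      ment <<- c(ment, mention); intk <<- c(intk, intake)
    }
    anytime <- function() as.Date("2019-01-01") + sample.int(730L, 1L) - 1L

    n_m <- 1L + rpois(1L, 1L)
    intake_flags <- runif(n_m) < config$intake_rate
    has_intake <- any(intake_flags)
    has_tl <- has_intake && runif(1) < config$timeline_rate
    drug <- sample(drugs, 1L)
    ind <- if (runif(1) < config$indication_rate) sample(.sim_indications, 1L) else NA_character_

    if (!has_tl) {
      for (k in seq_len(n_m)) {
        if (intake_flags[k]) {
          suffix <- if (!is.na(ind) && k == 1L) paste0(" for my ", ind) else ""
          push(sprintf("I take %s every morning%s", drug, suffix), anytime(),
               mention = TRUE, intake = TRUE)
        } else {
          push(sprintf(sample(.sim_nonintake, 1L), drug), anytime(), mention = TRUE)
        }
      }
    } else {
      start <- as.Date("2019-01-01") + sample.int(365L, 1L) - 1L
      end <- start + 280L
      category <- sample(c("taken", "possible", "neither"), 1L,
                         prob = config$exposure_split)
      explicit <- category == "taken" && runif(1) < config$explicit_share

      # anchors: 1-3, each implying `start` exactly
      for (a in seq_len(sample.int(3L, 1L))) {
        kind <- sample(c("countdown", "weeks", "hashtag"), 1L)
        if (kind == "countdown") {
          nd <- sample(30:150, 1L)
          push(sprintf("exactly %d days til my due date!", nd), end - nd)
        } else if (kind == "weeks") {
          w <- sample(8:36, 1L)
          push(sprintf("%d weeks pregnant and feeling good", w), start + 7L * w)
        } else {
          w <- sample(20:36, 1L)
          push(sprintf("so ready to meet you #%dweekspregnant", w), start + 7L * w)
        }
      }

      intake_date <- switch(category,
        taken = start + sample(20:250, 1L),
        possible = if (runif(1) < 0.5) start - sample(30:200, 1L) else end + sample(30:200, 1L),
        neither = start - sample(30:200, 1L))
      suffix <- if (!is.na(ind)) paste0(" for my ", ind) else ""
      n_int <- max(1L, sum(intake_flags))
      for (k in seq_len(n_int)) {
        if (category == "taken" && explicit) {
          push(sprintf("I was on %s during my pregnancy%s", drug, suffix),
               intake_date, mention = TRUE, intake = TRUE)
        } else if (category == "neither") {
          if (runif(1) < 0.5) {
            push(sprintf("I stopped taking %s before getting pregnant", drug),
                 start - sample(30:200, 1L), mention = TRUE, intake = TRUE)
          } else {
            push(sprintf("I started %s after my pregnancy ended", drug),
                 end + sample(10:120, 1L), mention = TRUE, intake = TRUE)
          }
        } else {
          push(sprintf("I was put on %s last week%s", drug, suffix),
               intake_date, mention = TRUE, intake = TRUE)
        }
      }
      for (k in seq_len(n_m - sum(intake_flags))) {
        push(sprintf(sample(.sim_nonintake, 1L), drug), anytime(), mention = TRUE)
      }

      exposure_class <- if (category == "neither") "NOT_DURING" else
        if (explicit) "EXPLICIT_DURING" else
        if (category == "taken") "INFERRED_DURING" else "POSSIBLE"
      exposed <- category %in% c("taken", "possible")

      oc <- if (exposed) runif(length(config$outcome_rates)) < config$outcome_rates
            else rep(FALSE, length(config$outcome_rates))
      names(oc) <- names(config$outcome_rates)
      nonadverse <- exposed && !any(oc)
      term_report <- nonadverse && runif(1) < config$report_term_ga
      # a posted term birth weight is itself term-GA evidence, so weight
      # reporters are nested within term reporters; the conditional rate
      # preserves both marginal rates
      bw_report <- term_report && runif(1) <
        config$report_normal_bw / max(config$report_term_ga, 1e-12)

      ga_birth <- if (oc[["PRETERM"]]) sample(238:258, 1L) else sample(259:287, 1L)
      birth_date <- start + ga_birth
      weight_oz <- NA_integer_
      need_birth_post <- oc[["PRETERM"]] || oc[["LOW_BIRTH_WEIGHT"]] || bw_report
      if (need_birth_post) {
        weight_oz <- if (oc[["LOW_BIRTH_WEIGHT"]]) sample(60:87, 1L)
                     else if (bw_report) sample(88:150, 1L) else NA_integer_
        wtxt <- if (is.na(weight_oz)) "we are so in love" else
          sprintf("%dlbs %doz and doing great", weight_oz %/% 16L, weight_oz %% 16L)
        push(sprintf("Officially introducing [name], born %s. %s",
                     format_sim_date(birth_date), wtxt),
             birth_date + sample(0:3, 1L))
      }
      if (oc[["NICU"]]) {
        push("our sweet girl has been in the nicu these past few days",
             birth_date + sample(1:5, 1L))
      }
      if (oc[["BIRTH_DEFECT"]]) {
        push(sprintf("my baby was born with %s", sample(.sim_defects, 1L)),
             birth_date + sample(5:40, 1L))
      }
      if (oc[["MISCARRIAGE"]]) {
        push("one of the hardest days of my life #miscarriage",
             start + sample(40:90, 1L))
      }
      if (term_report) {
        w <- sample(37:39, 1L)
        push(sprintf("still here, still waiting #%dweekspregnant", w), start + 7L * w)
      }

      age <- NA_integer_
      if (runif(1) < config$age_rate) {
        age <- as.integer(pmin(45, pmax(18, round(rnorm(1, 28, 5)))))
        push(sprintf("I'm %d years old and this year keeps surprising me", age),
             start + 140L)
      }

      preg[[length(preg) + 1L]] <- data.frame(
        user_id = uid, pregnancy_index = 1L, start = start, end = end,
        exposure_class = exposure_class,
        PRETERM = unname(oc[["PRETERM"]] & exposed),
        NICU = unname(oc[["NICU"]] & exposed),
        LOW_BIRTH_WEIGHT = unname(oc[["LOW_BIRTH_WEIGHT"]] & exposed),
        BIRTH_DEFECT = unname(oc[["BIRTH_DEFECT"]] & exposed),
        MISCARRIAGE = unname(oc[["MISCARRIAGE"]] & exposed),
        STILLBIRTH = unname(oc[["STILLBIRTH"]] & exposed),
        term_ga_evidence = term_report || (need_birth_post && ga_birth >= 259L &&
                                           !oc[["MISCARRIAGE"]]),
        normal_bw_evidence = !is.na(weight_oz) && weight_oz >= 88L,
        maternal_age = age,
        indication = if (exposed || category == "neither") ind else NA_character_,
        stringsAsFactors = FALSE)
    }

    n_d <- rpois(1L, max(0, config$posts_per_user - length(texts)))
    for (k in seq_len(n_d)) push(sample(.sim_distractors, 1L), anytime())

    ord <- order(dates, seq_along(dates))
    acc$user_id[[u]] <- rep(uid, length(texts))
    acc$post_id[[u]] <- sprintf("%s-p%02d", uid, seq_along(texts))
    acc$created_at[[u]] <- paste0(format(dates[ord]), "T12:00:00Z")
    acc$text[[u]] <- texts[ord]
    acc$is_mention[[u]] <- ment[ord]
    acc$is_intake[[u]] <- intk[ord]
  }

  posts <- as_posts(data.frame(
    user_id = unlist(acc$user_id), post_id = unlist(acc$post_id),
    created_at = unlist(acc$created_at), text = unlist(acc$text),
    stringsAsFactors = FALSE))
  truth_posts <- data.frame(post_id = unlist(acc$post_id),
                            user_id = unlist(acc$user_id),
                            is_mention = unlist(acc$is_mention),
                            is_intake = unlist(acc$is_intake),
                            stringsAsFactors = FALSE)
  pregnancies <- if (length(preg)) do.call(rbind, preg) else
    data.frame(user_id = character(), pregnancy_index = integer(),
               start = as.Date(character()), end = as.Date(character()),
               exposure_class = character(), PRETERM = logical(),
               NICU = logical(), LOW_BIRTH_WEIGHT = logical(),
               BIRTH_DEFECT = logical(), MISCARRIAGE = logical(),
               STILLBIRTH = logical(), term_ga_evidence = logical(),
               normal_bw_evidence = logical(), maternal_age = integer(),
               indication = character(), stringsAsFactors = FALSE)
  rownames(pregnancies) <- NULL
  agg <- tapply(truth_posts$is_intake, truth_posts$user_id, any)
  users <- data.frame(user_id = names(agg),
                      has_intake = as.logical(agg),
                      has_timeline = names(agg) %in% pregnancies$user_id,
                      stringsAsFactors = FALSE)
  list(posts = posts,
       truth = list(posts = truth_posts, users = users, pregnancies = pregnancies),
       config = config)
}

stage_metrics <- function(stage, predicted, truth) {
  tp <- length(intersect(predicted, truth))
  data.frame(stage = stage, tp = tp,
             n_pred = length(predicted), n_truth = length(truth),
             precision = if (length(predicted)) tp / length(predicted) else NA_real_,
             recall = if (length(truth)) tp / length(truth) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Score pipeline output against synthetic ground truth
#'
#' Per-stage precision and recall (drug mentions, intake reports, timelines,
#' exposure classes, adverse outcomes, maternal age, indications) plus the
#' distribution of absolute timeline start-date errors. Stages with no true
#' or no predicted positives report `NA` for the undefined metric.
#'
#' @param pipeline A `pregnancy_pipeline` ([run_pipeline()]) run on the
#'   simulated posts.
#' @param truth The `truth` element of [simulate_corpus()] output.
#' @return A list of class `recovery_evaluation` with `stages` (data.frame)
#'   and `start_date_error_days` (integer vector over matched timelines).
#' @export
evaluate_recovery <- function(pipeline, truth) {
  if (!setequal(pipeline$posts$post_id, truth$posts$post_id)) {
    stop("pipeline output and truth labels cover different corpora")
  }
  tp <- truth$posts
  stages <- list()

  stages[[1]] <- stage_metrics("mentions",
    unique(pipeline$mentions$post_id), tp$post_id[tp$is_mention])
  stages[[2]] <- stage_metrics("intake",
    unique(pipeline$intake$post_id[pipeline$intake$is_intake]),
    tp$post_id[tp$is_intake])

  tl <- pipeline$timelines
  tr <- truth$pregnancies
  stages[[3]] <- stage_metrics("timeline", unique(tl$user_id), unique(tr$user_id))
  common <- intersect(tl$user_id, tr$user_id)
  err <- abs(as.integer(tl$start[match(common, tl$user_id)] -
                        tr$start[match(common, tr$user_id)]))

  exposed_classes <- c("EXPLICIT_DURING", "INFERRED_DURING", "POSSIBLE")
  pred_exp <- pipeline$exposures[pipeline$exposures$exposure_class %in% exposed_classes, ]
  truth_exp <- tr[tr$exposure_class %in% exposed_classes, ]
  stages[[4]] <- stage_metrics("exposure",
    paste(pred_exp$user_id, pred_exp$exposure_class),
    paste(truth_exp$user_id, truth_exp$exposure_class))

  rec <- pipeline$records
  pred_out <- unlist(lapply(.adverse_kinds, function(k) {
    paste(rec$user_id[rec[[k]]], k)
  }))
  truth_out <- unlist(lapply(.adverse_kinds, function(k) {
    paste(tr$user_id[tr[[k]]], k)
  }))
  stages[[5]] <- stage_metrics("outcomes", pred_out, truth_out)

  age_truth <- tr[!is.na(tr$maternal_age), ]
  age_pred <- rec[!is.na(rec$maternal_age), ]
  stages[[6]] <- stage_metrics("maternal_age",
    paste(age_pred$user_id, age_pred$maternal_age),
    paste(age_truth$user_id[age_truth$user_id %in% rec$user_id],
          age_truth$maternal_age[age_truth$user_id %in% rec$user_id]))

  ind_truth <- tr[!is.na(tr$indication) & tr$user_id %in% rec$user_id, ]
  ind_pred <- rec[nzchar(rec$indications), ]
  stages[[7]] <- stage_metrics("indication",
    paste(ind_pred$user_id, ind_pred$indications),
    paste(ind_truth$user_id, ind_truth$indication))

  structure(list(stages = do.call(rbind, stages), start_date_error_days = err),
            class = "recovery_evaluation")
}

#' @export
print.recovery_evaluation <- function(x, ...) {
  cat("Pipeline recovery against synthetic ground truth\n")
  print(x$stages, row.names = FALSE)
  if (length(x$start_date_error_days)) {
    cat(sprintf("start-date abs error (days): mean %.2f, max %d over %d timelines\n",
                mean(x$start_date_error_days), max(x$start_date_error_days),
                length(x$start_date_error_days)))
  }
  invisible(x)
}
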