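---
title: "Building pregnancy drug-safety cohorts from timestamped posts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building pregnancy drug-safety cohorts from timestamped posts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pregcohort)
```

## The problem

For most medications there is no registry, trial or claims cohort from which
fetal risk can be estimated, yet medication is taken in the large majority
of pregnancies. People do, however, narrate their pregnancies on social
media: they count down to due dates, tag gestational weeks, mention the
drugs they take, and announce births with dates and weights. `pregcohort`
assembles those fragments into the unit a cohort study needs — one record
per pregnancy carrying drug exposure, outcomes and covariates — using
β-blockers (the most common cardiac medication in pregnancy) as the packaged
example.

Everything in the package is rule-based and inspectable. Where production
systems would use trained classifiers for intake detection, outcome
detection or age extraction, this package ships editable pattern and keyword
files that play the same role at the same interface. The point is a
transparent, reproducible reference implementation, not state-of-the-art
text classification; no precision/recall against human annotation is
claimed for the rules themselves.

## The model of a pregnancy

A pregnancy is represented by its **prenatal window** $[S, S + G]$ with
term gestation fixed at $G = 280$ days (40 weeks). Anchors imply $S$
exactly:

* countdown: "$N$ days til my due date" posted on day $D$ implies
  $S = D + N - G$;
* weeks: "$N$ weeks pregnant" or `#Nweekspregnant` posted on $D$ implies
  $S = D - 7N$;
* explicit due date: $S = \text{due} - G$.

Gestational age at date $t$ is $t - S$ days, and **completed weeks** is
$\lfloor (t-S)/7 \rfloor$ — so a birth "between 35 and 36 weeks" is 35
completed weeks, and the preterm boundary sits exactly at
$37 \times 7 = 259$ days.

Anchors are plausibility-filtered (implied start after the post date, or
more than 310 days before it, is discarded — 310 allows a countdown posted
a month before term plus slack for post-term talk). Within a user, anchors
whose implied starts sit within 28 days of each other form one candidate
pregnancy; implied starts at least 180 days apart are distinct pregnancies;
a candidate whose implied starts spread across an intermediate gap is
internally contradictory and is *rejected with a diagnostic* rather than
guessed at. The start estimate is the median implied start (lower median on
even counts, so ties resolve to the earliest date); no anchor kind is
privileged over another because no precedence is defensible a priori.

## Exposure semantics

Each intake report is graded against the window:

| grade | condition |
|---|---|
| `EXPLICIT_DURING` | the post itself says intake was during pregnancy |
| `INFERRED_DURING` | no temporal cue, post timestamp inside the window |
| `POSSIBLE` | no cue, timestamp outside the window |
| `NOT_DURING` | stopped-before cue posted before the start, or started-after cue posted after the end |

The pregnancy's class is the *maximum* grade over its reports, so one
stop/start report never vetoes stronger evidence. `POSSIBLE` embodies the
study's core conservative assumption: intake reported at any time, with no
evidence of stopping before or starting after pregnancy, may have continued
into the window. A deliberate edge decision: a stop/start cue whose
timestamp falls on the *wrong* side of the window (e.g. "stopped before
pregnancy" posted mid-window) degrades to `POSSIBLE`, not `NOT_DURING` —
the date no longer corroborates the cue, and possible exposure is the
conservative default. The exposure tabulation keeps "taken"
(explicit + inferred) separate from "taken or may have" (+ possible) so
either denominator can be reported.

For users with several pregnancies, in-window reports attach only to the
containing pregnancy; explicit reports outside every window attach to the
nearest one; other out-of-window reports are candidates for every pregnancy
(where they can only grade `POSSIBLE`/`NOT_DURING`).

## Outcomes, thresholds and numerical choices

* **Preterm birth**: gestational age at birth $< 259$ days; exactly 37
  weeks is term. The threshold is configurable and classifications shift
  monotonically with it.
* **Low birth weight**: $< 88$ oz ($5$ lb $8$ oz); exactly 88 oz is normal.
  All weight arithmetic is in integer ounces — no floating point at the
  boundary. Metric weights are outside the supported dialects and rejected
  with a diagnostic rather than converted.
* Birth dates are taken from the announcement text when stated
  ("born April 2nd, 2020"; month-name or ISO, four-digit years only —
  two-digit years are too ambiguous) and from the post timestamp otherwise.
  Birth events are accepted up to 42 days past the estimated due date.
* "Came at $N$ weeks" supplies $7N$ days when no timeline-based gestational
  age exists; the timeline-based value wins when both exist.
* **Percentages** are computed as $\lfloor (2000n + d) / (2d) \rfloor / 10$
  — exact integer arithmetic for half-up rounding to one decimal, the
  convention that reproduces standard cohort-table presentation (base R's
  `round()` is half-even and would not).
* Mean ages are arithmetic means of non-missing values rounded half-up to
  whole years; missing ages reduce $n$ and never contribute zero.
* Degenerate inputs are contracts, not crashes: an empty corpus yields an
  empty cohort; an empty anchor cluster is an error; a birth before the
  estimated start is an error; conflicting age reports (implied birth years
  more than one apart) yield a missing age with a diagnostic.

The **reporting-bias check** asks, among pregnancies with *no* adverse
outcome, how often normal outcomes were actually posted: term-gestational-age
evidence (a weeks anchor of ≥ 37 weeks, or pregnancy-referring talk dated at
GA ≥ 259 days) and normal-birth-weight evidence (a parsed weight ≥ 88 oz).
Cohort records force these flags consistent with contradicting outcomes
(a preterm or miscarried pregnancy cannot carry term evidence).

## Text matching

Matching operates on lowercased text with Greek β mapped to "beta" and
typographic quotes straightened (length-preserving except for β, so mention
offsets are raw-text offsets for ASCII posts). Lexicon matching is
whole-token with boundaries at non-letter characters: hashtag-internal
mentions (`#propranolol`) count — hashtags are how pregnancy is narrated on
these platforms — while embedded substrings ("betablocked") do not. Hyphen
and single space are interchangeable inside multi-word terms, covering both
"beta blocker" and "beta-blocker" dialects, and the longest candidate wins
at a shared start. Intake patterns are first-person templates
(`I was/am … on <drug>`, `I take/took/stopped … <drug>`, `put me on
<drug>`, `my <drug>`) shipped in `inst/extdata/intake_patterns.txt`;
third-person reports ("my mom takes atenolol") fail them by construction.

## The synthetic generator

`simulate_corpus()` emulates the statistical skeleton of a mention-to-cohort
study: per-user post timelines containing anchors, intake statements,
birth announcements, outcome posts, age statements and distractors, every
one generated from a template its extractor can parse, with anchors dated to
imply the true start *exactly*. Its defaults are the study conditions the
package targets (intake rate 0.456 per mention post; timeline rate 0.279
among intake users; exposure split 58/199/99 over taken/possible/neither;
outcome rates 0.089, 0.047, 0.035, 0.016, 0.004, 0 for preterm, NICU, low
birth weight, defect, miscarriage, stillbirth; term-evidence and
normal-weight reporting rates 0.904 and 0.228 among non-adverse
pregnancies; age identified at 0.864, indication at 0.767).

Generator-specific choices:

* One pregnancy per timeline user (the target ratio is 356 pregnancies per
  334 users ≈ 1.07; multi-pregnancy segmentation is exercised by direct
  unit tests instead).
* Outcomes are sampled independently per pregnancy — only marginal rates
  are specified — so the composite-adverse rate has the closed form
  $1 - \prod_k (1 - p_k)$, which the tests verify at scale. When outcomes
  co-occur, each gets its own post; the narrative may be redundant but the
  labels stay exact.
* A posted term birth weight is itself term-gestational-age evidence, so
  normal-weight reporters are nested within term reporters with conditional
  probability $0.228/0.904$; both marginal rates are then honoured exactly
  (this is also why `report_normal_bw` may not exceed `report_term_ga`).
* Age posts are dated at the window midpoint, so the projected age equals
  the stated age; anchors are uniform over role-specific gestational
  ranges; birth posts fall within 3 days after the birth.
* One seed drives everything; per-user seeds are drawn first, so the first
  $k$ users are identical whatever `n_users` is.

What the generator does **not** emulate: real tweet language (paraphrase,
sarcasm, slang), misspellings beyond the packaged variant list, adversarial
negation ("never took propranolol"), twins, timeline-less outcome talk, or
correlation between outcomes. Perfect recovery on these corpora therefore
demonstrates internal consistency of generator and extractors — that the
pipeline's logic is sound end to end — not field performance on real posts.

## Validation strategy and problem sizes

The test suite checks each extractor against hand-computed examples
(including the two packaged worked fixtures, which reproduce their published
windows, gestational ages and outcome sets exactly), property-style
invariants under fixed seeds (exposure class equals a brute-force maximum
over report sets of size ≤ 5; composite ≤ sum of individual counts with
equality iff outcomes are disjoint; anchor→timeline→anchor round trips;
percentage against a long-division oracle on 10,000 random pairs), and
end-to-end recovery on simulated corpora. The simulation sizes used — 500
users for exact recovery, 10,000 users for rate calibration within three
binomial standard errors — keep the whole suite under a minute of
simulation work while leaving the binomial checks well-powered.

## Known limitations

* Rule-based intake/outcome/age detection trades recall for auditability;
  real-data performance is unmeasured here by design.
* Timeline estimation requires anchors; pregnancies narrated only through a
  birth announcement are not reconstructed, and the 28/180-day clustering
  constants, though configurable, are declared conventions rather than
  fitted quantities.
* Miscarriage and stillbirth are detectable only if self-reported, and
  selection effects (announcing a pregnancy only after the first trimester)
  bias those rates downward in any such cohort.
* The package tabulates exposure and outcomes; it deliberately computes no
  association or relative-risk statistics, and does no deidentification —
  input corpora are assumed to be already compliant with the platform's
  terms and applicable ethics review.
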