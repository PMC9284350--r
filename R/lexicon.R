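#' Load a drug keyword/variant lexicon
#'
#' The lexicon is a long-format table with columns `keyword` and `variant`
#' (one row per lexical variant — typically misspellings collected from real
#' posts; a keyword with no variants has a single row with an empty or
#' `"N/A"` variant cell). All strings are case-folded for matching. A variant
#' identical to its own keyword is dropped; a variant colliding with a
#' *different* entry's keyword is an error, as is a duplicated keyword set.
#'
#' @param x A data.frame with columns `keyword`, `variant`, or the path to a
#'   CSV file with those columns.
#' @return An object of class `drug_lexicon`: a named list mapping each
#'   canonical (case-folded) keyword to its character vector of variants.
#' @examples
#' lex <- default_lexicon()
#' length(lex$entries)   # 17 beta-blocker keywords
#' @export
load_lexicon <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- utils::read.csv(x, stringsAsFactors = FALSE, colClasses = "character")
  }
  if (!all(c("keyword", "variant") %in% names(x))) {
    stop("lexicon needs columns 'keyword' and 'variant'")
  }
  kw <- fold_term(trimws(x$keyword))
  vr <- trimws(ifelse(is.na(x$variant), "", x$variant))
  vr <- fold_term(vr)
  vr[vr %in% c("", "n/a", "na")] <- NA_character_
  if (any(!nzchar(kw))) stop("empty keyword in lexicon")

  canon <- unique(kw)
  entries <- lapply(canon, function(k) {
    v <- unique(vr[kw == k & !is.na(vr)])
    setdiff(v, k)
  })
  names(entries) <- canon

  all_variants <- unlist(entries, use.names = FALSE)
  for (k in canon) {
    clash <- intersect(entries[[k]], setdiff(canon, k))
    if (length(clash)) {
      stop("variant of '", k, "' duplicates another keyword: ",
           paste(clash, collapse = ", "))
    }
  }
  dup <- all_variants[duplicated(all_variants)]
  dup <- dup[vapply(dup, function(v) {
    sum(vapply(entries, function(e) v %in% e, TRUE)) > 1
  }, TRUE)]
  if (length(dup)) {
    stop("variant assigned to more than one keyword: ", paste(unique(dup), collapse = ", "))
  }
  structure(list(entries = entries), class = "drug_lexicon")
}

#' @rdname load_lexicon
#' @export
default_lexicon <- function() {
  load_lexicon(extdata("beta_blocker_lexicon.csv"))
}

#' @export
print.drug_lexicon <- function(x, ...) {
  nv <- vapply(x$entries, length, 0L)
  cat("<drug_lexicon> ", length(x$entries), " keywords, ",
      sum(nv), " lexical variants\n", sep = "")
  for (k in names(x$entries)) {
    cat("  ", format(k, width = 14), " ", nv[[k]], " variant(s)\n", sep = "")
  }
  invisible(x)
}

# one compiled matcher per lexicon: alternation ordered longest-first so the
# longest term wins at a shared start; boundaries at non-letter characters
# (hashtag-internal matches are intentional)
lexicon_matcher <- function(lexicon) {
  stopifnot(inherits(lexicon, "drug_lexicon"))
  terms <- unlist(lapply(names(lexicon$entries), function(k) {
    setNames(rep(k, length(lexicon$entries[[k]]) + 1L),
             c(k, lexicon$entries[[k]]))
  }))
  if (!length(terms)) return(list(pattern = NULL, canon_of = character()))
  surfaces <- names(terms)
  ord <- order(-nchar(surfaces))
  pattern <- paste0("(?<!\\p{L})(?:",
                    paste(vapply(surfaces[ord], term_pattern, ""), collapse = "|"),
                    ")(?!\\p{L})")
  list(pattern = pattern, canon_of = terms)
}

#' Find drug mentions in posts
#'
#' Scans post text for whole-token, case-insensitive occurrences of any
#' lexicon keyword or variant. Hyphen and single space are interchangeable
#' inside multi-word terms ("beta blocker" matches "beta-blocker"); token
#' boundaries fall at non-letter characters, so hashtag-internal mentions
#' ("#propranolol") are found while embedded substrings ("betablocked") are
#' not. Overlapping candidates resolve to the longest match. Character spans
#' are 0-based half-open offsets into the normalised post text (see
#' [as_posts()]; identical to the raw text for ASCII posts).
#'
#' @param posts A posts data.frame ([as_posts()]), or a single-row subset.
#' @param lexicon A `drug_lexicon` from [load_lexicon()].
#' @return A data.frame with columns `post_id`, `canonical`, `surface`,
#'   `span_start`, `span_end` (zero rows when nothing matches).
#' @examples
#' p <- as_posts(data.frame(user_id = "u1", post_id = "p1",
#'                          created_at = "2020-04-16T12:00:00Z",
#'                          text = "I was on Propranolol during my pregnancy"))
#' find_mentions(p, default_lexicon())
#' @export
find_mentions <- function(posts, lexicon = default_lexicon()) {
  posts <- as_posts(posts)
  matcher <- lexicon_matcher(lexicon)
  out <- list()
  if (nrow(posts) && !is.null(matcher$pattern)) {
    norm <- normalise_text(posts$text)
    hits <- gregexpr(matcher$pattern, norm, perl = TRUE)
    for (i in seq_len(nrow(posts))) {
      st <- hits[[i]]
      if (st[1] == -1L) next
      len <- attr(st, "match.length")
      surf <- substring(norm[i], st, st + len - 1L)
      out[[length(out) + 1L]] <- data.frame(
        post_id = posts$post_id[i],
        canonical = unname(matcher$canon_of[gsub("-", " ", surf, fixed = TRUE)]),
        surface = surf,
        span_start = as.integer(st) - 1L,
        span_end = as.integer(st) + len - 1L,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(post_id = character(), canonical = character(),
                      surface = character(), span_start = integer(),
                      span_end = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' First-person intake pattern rules
#'
#' The patterns that decide whether a drug mention is a self-reported intake
#' are shipped as an editable data file (one regex template per line;
#' `{DRUG}` is replaced by the matched drug surface). They are a transparent,
#' rule-based stand-in for human annotation of "did the poster actually take
#' the drug"; no precision/recall against human judgment is claimed.
#'
#' @return Character vector of regex templates.
#' @export
intake_patterns <- function() {
  read_term_file(extdata("intake_patterns.txt"))
}

.cue_patterns <- list(
  EXPLICIT_DURING_PREGNANCY = paste0(
    "\\bduring (?:my |the |this )?pregnan",
    "|\\bwhile (?:i was |i'm |i am )?pregnant",
    "|\\bwhen i was pregnant"),
  STOPPED_BEFORE = "\\bstop\\w*\\b[^.!?]{0,60}?\\bbefore\\b[^.!?]{0,60}?\\b(?:pregnan|conceiv|expecting)",
  STARTED_AFTER = "\\bstart\\w*\\b[^.!?]{0,60}?\\bafter\\b[^.!?]{0,60}?\\b(?:pregnan|birth|deliver|baby)"
)

#' Classify drug mentions as self-reported intake
#'
#' Applies the first-person intake rules ([intake_patterns()]) to each drug
#' mention and, for intake reports, looks for an explicit temporal cue:
#' "during my pregnancy" (`EXPLICIT_DURING_PREGNANCY`), stopping before
#' pregnancy (`STOPPED_BEFORE`) or starting after it (`STARTED_AFTER`);
#' otherwise `NONE`. A post with several distinct mentions yields one report
#' per mention. Deterministic: identical text gives identical reports.
#'
#' @param posts A posts data.frame covering the mentioned posts.
#' @param mentions Output of [find_mentions()] on those posts.
#' @param patterns Intake regex templates; defaults to the packaged set.
#' @return `mentions` with added logical `is_intake` and character
#'   `temporal_cue` columns (`temporal_cue` is `"NONE"` unless `is_intake`).
#' @export
classify_intake <- function(posts, mentions, patterns = intake_patterns()) {
  posts <- as_posts(posts)
  if (!all(mentions$post_id %in% posts$post_id)) {
    stop("mentions refer to post_ids absent from posts")
  }
  norm <- setNames(normalise_text(posts$text), posts$post_id)
  n <- nrow(mentions)
  is_intake <- logical(n)
  cue <- rep("NONE", n)
  for (i in seq_len(n)) {
    text <- norm[[mentions$post_id[i]]]
    drug_pat <- term_pattern(gsub("-", " ", mentions$surface[i], fixed = TRUE))
    hit <- any(vapply(patterns, function(p) {
      grepl(gsub("{DRUG}", drug_pat, p, fixed = TRUE), text, perl = TRUE)
    }, TRUE))
    is_intake[i] <- hit
    if (hit) {
      for (k in names(.cue_patterns)) {
        if (grepl(.cue_patterns[[k]], text, perl = TRUE)) {
          cue[i] <- k
          break
        }
      }
    }
  }
  mentions$is_intake <- is_intake
  mentions$temporal_cue <- cue
  mentions
}
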