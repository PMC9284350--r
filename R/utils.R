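# Internal helpers: text normalisation, regex escaping, date parsing,
# diagnostics plumbing. Matching throughout the package happens on
# normalise_text() output: lowercased UTF-8 with Greek beta mapped to "beta"
# and typographic quotes straightened. All substitutions except beta -> "beta"
# preserve string length, so character offsets refer to the normalised text
# (identical to the raw text for ASCII posts).

normalise_text <- function(x) {
  x <- enc2utf8(as.character(x))
  x <- gsub("β|Β", "beta", x)
  x <- chartr("‘’“”", "''\"\"", x)
  tolower(x)
}

escape_regex <- function(x) {
  gsub("([\\^$.|?*+()\\[\\]{}\\\\])", "\\\\\\1", x, perl = TRUE)
}

# hyphen and single space interchangeable inside multi-word terms
fold_term <- function(x) gsub("-", " ", normalise_text(x), fixed = TRUE)

term_pattern <- function(term) {
  gsub(" ", "[ -]", escape_regex(term), fixed = TRUE)
}

post_date <- function(created_at) as.Date(substr(as.character(created_at), 1, 10))

`%||%` <- function(a, b) if (is.null(a)) b else a

add_diagnostic <- function(x, msg) {
  attr(x, "diagnostics") <- c(attr(x, "diagnostics"), msg)
  x
}

#' @noRd
.month_names <- c("january", "february", "march", "april", "may", "june",
                  "july", "august", "september", "october", "november",
                  "december")
.month_abbr <- c("jan", "feb", "mar", "apr", "may", "jun", "jul", "aug",
                 "sep", "oct", "nov", "dec")

month_alternation <- function() {
  # full names first so "january" wins over "jan"
  paste0("(?:", paste(c(.month_names, "sept", .month_abbr), collapse = "|"), ")")
}

# "april 2nd, 2020" / "Apr 2 2020" / ISO "2020-04-02"; two-digit years rejected
textual_date_pattern <- function() {
  paste0("\\b(", month_alternation(),
         ")\\.? (\\d{1,2})(?:st|nd|rd|th)?,? (\\d{4})\\b")
}

iso_date_pattern <- function() "\\b(\\d{4})-(\\d{2})-(\\d{2})\\b"

month_number <- function(m) {
  m <- sub("^sept$", "sep", m)
  i <- match(m, .month_names)
  ifelse(is.na(i), match(substr(m, 1, 3), .month_abbr), i)
}

# first parsable calendar date in (normalised) text, or NA
find_date_in_text <- function(text) {
  m <- regexec(textual_date_pattern(), text, perl = TRUE)
  g <- regmatches(text, m)[[1]]
  if (length(g)) {
    mn <- month_number(g[2])
    d <- suppressWarnings(as.Date(sprintf("%s-%02d-%02d",
                                          g[4], mn, as.integer(g[3]))))
    if (!is.na(d)) return(d)
  }
  m <- regexec(iso_date_pattern(), text, perl = TRUE)
  g <- regmatches(text, m)[[1]]
  if (length(g)) {
    d <- suppressWarnings(as.Date(sprintf("%s-%s-%s", g[2], g[3], g[4])))
    if (!is.na(d)) return(d)
  }
  as.Date(NA)
}

# round half-up to the nearest integer (base round() is half-even)
round_half_up <- function(x) floor(x + 0.5)

# read a one-term-per-line vocabulary file, '#' comments allowed
read_term_file <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  x[nzchar(x)]
}

extdata <- function(...) {
  p <- system.file("extdata", ..., package = "pregcohort", mustWork = FALSE)
  if (!nzchar(p)) stop("packaged data file not found: ", file.path(...))
  p
}
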