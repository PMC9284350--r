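#' Post corpora
#'
#' A post corpus is a plain `data.frame` with one row per post and columns
#' `user_id`, `post_id`, `created_at` (ISO 8601 timestamp) and `text`.
#' `as_posts()` validates those columns, de-duplicates post identifiers and
#' adds a `post_date` column (`Date`, the calendar day of `created_at`; all
#' downstream date arithmetic works at day resolution). `read_posts()` /
#' `write_posts()` handle the JSON-lines interchange format (one JSON object
#' per line).
#'
#' @param x A data.frame with columns `user_id`, `post_id`, `created_at`,
#'   `text`.
#' @return `as_posts()` and `read_posts()` return the validated posts
#'   data.frame.
#' @examples
#' as_posts(data.frame(user_id = "u1", post_id = "p1",
#'                     created_at = "2020-01-25T09:00:00Z",
#'                     text = "exactly 100 days til my due date!"))
#' @export
as_posts <- function(x) {
  need <- c("user_id", "post_id", "created_at", "text")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("posts are missing columns: ", paste(miss, collapse = ", "))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (nm in need) x[[nm]] <- as.character(x[[nm]])
  if (anyDuplicated(x$post_id)) stop("duplicate post_id values in corpus")
  x$post_date <- post_date(x$created_at)
  if (anyNA(x$post_date)) stop("unparsable created_at timestamp(s)")
  rownames(x) <- NULL
  x
}

#' @rdname as_posts
#' @param path File path to a JSON-lines post corpus.
#' @export
read_posts <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(as_posts(data.frame(user_id = character(), post_id = character(),
                               created_at = character(), text = character())))
  }
  recs <- lapply(lines, jsonlite::fromJSON)
  as_posts(data.frame(
    user_id = vapply(recs, function(r) as.character(r$user_id), ""),
    post_id = vapply(recs, function(r) as.character(r$post_id), ""),
    created_at = vapply(recs, function(r) as.character(r$created_at), ""),
    text = vapply(recs, function(r) as.character(r$text), ""),
    stringsAsFactors = FALSE
  ))
}

#' @rdname as_posts
#' @param posts A posts data.frame (see `as_posts()`).
#' @export
write_posts <- function(posts, path) {
  posts <- as_posts(posts)
  lines <- vapply(seq_len(nrow(posts)), function(i) {
    jsonlite::toJSON(list(user_id = posts$user_id[i], post_id = posts$post_id[i],
                          created_at = posts$created_at[i], text = posts$text[i]),
                     auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

empty_posts <- function() {
  as_posts(data.frame(user_id = character(), post_id = character(),
                      created_at = character(), text = character()))
}
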