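# build small post corpora in code
make_posts <- function(texts, dates, user_id = "u1",
                       post_id = sprintf("%s-p%d", user_id, seq_along(texts))) {
  as_posts(data.frame(user_id = user_id, post_id = post_id,
                      created_at = paste0(dates, "T12:00:00Z"),
                      text = texts, stringsAsFactors = FALSE))
}

one_post <- function(text, date = "2020-01-01", user_id = "u1", post_id = "p1") {
  make_posts(text, date, user_id = user_id, post_id = post_id)
}

tiny_timeline <- function(start, user_id = "u1", index = 1L, gestation = 280L) {
  data.frame(user_id = user_id, pregnancy_index = as.integer(index),
             start = as.Date(start), end = as.Date(start) + gestation,
             n_anchors = 1L, stringsAsFactors = FALSE)
}

intake_report <- function(cue, date, post_id = "p1", user_id = "u1",
                          canonical = "propranolol") {
  data.frame(user_id = user_id, post_id = post_id, canonical = canonical,
             post_date = as.Date(date), temporal_cue = cue,
             stringsAsFactors = FALSE)
}
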