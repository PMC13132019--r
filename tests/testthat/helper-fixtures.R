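# Small corpora built in code for hand-checkable tests.

# survey row with every answer defaulting to "not at all" / best health
survey_row <- function(user_id, survey_date = as.Date("2024-06-01"), ...) {
  ans <- as.list(setNames(rep(1L, 53), paste0("q", 1:53)))
  ans$q29 <- 7L
  ans$q30 <- 7L
  over <- list(...)
  for (nm in names(over)) ans[[nm]] <- as.integer(over[[nm]])
  tibble::as_tibble(c(list(user_id = user_id, survey_date = survey_date), ans))
}

# three documents, two users:
#   d1 (u1) "pain was bad"          d2 (u1) "no pain at all today"
#   d3 (u2) "I am so worried!"
# u1 reports pain (q9 = 3); u2 reports no worry (q22 = 1)
fixture_corpus <- function(annotations = NULL, flags = NULL, coverage = NULL) {
  docs <- tibble::tibble(
    doc_id = c("d1", "d2", "d3"),
    user_id = c("u1", "u1", "u2"),
    timestamp = as.Date(c("2024-05-01", "2024-04-01", "2024-03-15")),
    doc_type = c("post", "comment", "post"),
    text = c("pain was bad", "no pain at all today", "I am so worried!")
  )
  surveys <- dplyr::bind_rows(
    survey_row("u1", q9 = 3),
    survey_row("u2")
  )
  qol_corpus(docs, annotations, flags, surveys, coverage)
}

ann_row <- function(doc_id, annotator_id, qid, start, end,
                    polarity = "positive", exact_match = FALSE) {
  tibble::tibble(doc_id = doc_id, annotator_id = annotator_id,
                 qid = as.integer(qid), start = as.integer(start),
                 end = as.integer(end), polarity = polarity,
                 exact_match = exact_match)
}

# quiet wrappers: the messages/warnings are part of the interface but
# noise in most tests
quiet_exclude <- function(corpus) suppressMessages(exclude_other_subject(corpus))
quiet_agreement <- function(...) suppressWarnings(agreement_table(...))
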