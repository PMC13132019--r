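#' Assemble and validate a forum corpus
#'
#' A corpus bundles the four tables the pipeline operates on:
#'
#' * `documents`: one row per forum post or comment (`doc_id`, `user_id`,
#'   `timestamp` as a `Date`, `doc_type` `"post"`/`"comment"`, `text`).
#' * `annotations`: one row per annotated text span (`doc_id`,
#'   `annotator_id`, `qid` 1..53, `start`, `end`, `polarity`
#'   `"positive"`/`"negative"`, `exact_match`). Offsets are 0-based,
#'   half-open `[start, end)`, counted in Unicode code points.
#' * `flags`: at most one row per document (`doc_id`, `refers_to_past`,
#'   `subject_is_self`); documents without a row default to
#'   `refers_to_past = FALSE`, `subject_is_self = TRUE`.
#' * `surveys`: one EORTC QLQ-C30+BR23 response set per user (`user_id`,
#'   `survey_date`, `q1`..`q53`, optional demographic columns).
#'
#' An optional `coverage` table (`doc_id`, `annotator_id`) records which
#' annotator read which document; when absent, every annotator is assumed to
#' have covered every document. Coverage matters for agreement computation,
#' where an unlabeled document is only evidence of disagreement if the
#' annotator actually read it.
#'
#' @param documents,annotations,flags,surveys,coverage Data frames as
#'   described above; all but `documents` may be `NULL` for an empty table.
#' @return A validated object of class `qol_corpus`.
#' @export
qol_corpus <- function(documents, annotations = NULL, flags = NULL,
                       surveys = NULL, coverage = NULL) {
  empty_ann <- tibble(doc_id = character(), annotator_id = character(),
                      qid = integer(), start = integer(), end = integer(),
                      polarity = character(), exact_match = logical())
  empty_flags <- tibble(doc_id = character(), refers_to_past = logical(),
                        subject_is_self = logical())
  empty_surv <- tibble(user_id = character(), survey_date = as.Date(character()))
  x <- structure(
    list(
      documents = as_tibble(documents),
      annotations = if (is.null(annotations) || nrow(annotations) == 0) empty_ann else as_tibble(annotations),
      flags = if (is.null(flags) || nrow(flags) == 0) empty_flags else as_tibble(flags),
      surveys = if (is.null(surveys) || nrow(surveys) == 0) empty_surv else as_tibble(surveys),
      coverage = if (is.null(coverage)) NULL else as_tibble(coverage)
    ),
    class = "qol_corpus"
  )
  validate_corpus(x)
}

validate_corpus <- function(x) {
  docs <- x$documents
  ann <- x$annotations
  flags <- x$flags
  surv <- x$surveys

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stopf("%s table is missing column(s): %s.", what,
                            paste(miss, collapse = ", "))
  }
  need(docs, c("doc_id", "user_id", "timestamp", "doc_type", "text"), "documents")
  need(ann, c("doc_id", "annotator_id", "qid", "start", "end"), "annotations")
  need(flags, c("doc_id"), "flags")
  need(surv, c("user_id", "survey_date"), "surveys")

  if (anyDuplicated(docs$doc_id)) {
    stopf("Duplicate doc_id in documents: %s.",
          docs$doc_id[duplicated(docs$doc_id)][1])
  }
  if (!is_date(docs$timestamp)) {
    x$documents$timestamp <- docs$timestamp <- as.Date(docs$timestamp)
  }
  if (any(is.na(docs$timestamp))) stopf("Unparseable document timestamp.")
  if (any(!nzchar(docs$text) | is.na(docs$text))) {
    stopf("Empty text in document %s.",
          docs$doc_id[which(!nzchar(docs$text) | is.na(docs$text))[1]])
  }
  if (any(!docs$doc_type %in% c("post", "comment"))) {
    stopf("doc_type must be 'post' or 'comment'.")
  }

  # annotation defaults: unmarked polarity denotes reported presence
  if (!"polarity" %in% names(ann)) ann$polarity <- "positive"
  ann$polarity[is.na(ann$polarity)] <- "positive"
  if (!"exact_match" %in% names(ann)) ann$exact_match <- FALSE
  ann$exact_match[is.na(ann$exact_match)] <- FALSE
  if (nrow(ann)) {
    if (any(!ann$polarity %in% c("positive", "negative"))) {
      stopf("Annotation polarity must be 'positive' or 'negative'.")
    }
    bad_qid <- which(is.na(ann$qid) | ann$qid < 1 | ann$qid > 53 |
                       ann$qid != floor(ann$qid))
    if (length(bad_qid)) {
      stopf("Annotation %d has invalid qid %s (must be 1..53).",
            bad_qid[1], format(ann$qid[bad_qid[1]]))
    }
    ann$qid <- as.integer(ann$qid)
    dangling <- setdiff(ann$doc_id, docs$doc_id)
    if (length(dangling)) {
      stopf("Annotation refers to unknown doc_id '%s'.", dangling[1])
    }
    len <- setNames(stringr::str_length(docs$text), docs$doc_id)
    bad <- which(is.na(ann$start) | is.na(ann$end) | ann$start < 0 |
                   ann$end <= ann$start | ann$end > len[ann$doc_id])
    if (length(bad)) {
      i <- bad[1]
      stopf(paste0("Annotation %d on doc '%s' has invalid span [%s, %s) ",
                   "(text length %d; offsets are 0-based half-open)."),
            i, ann$doc_id[i], format(ann$start[i]), format(ann$end[i]),
            len[ann$doc_id[i]])
    }
    ann$start <- as.integer(ann$start)
    ann$end <- as.integer(ann$end)
  }
  x$annotations <- ann

  if (nrow(flags)) {
    if (!"refers_to_past" %in% names(flags)) flags$refers_to_past <- FALSE
    if (!"subject_is_self" %in% names(flags)) flags$subject_is_self <- TRUE
    flags$refers_to_past[is.na(flags$refers_to_past)] <- FALSE
    flags$subject_is_self[is.na(flags$subject_is_self)] <- TRUE
    if (anyDuplicated(flags$doc_id)) {
      stopf("Duplicate flags record for doc_id '%s'.",
            flags$doc_id[duplicated(flags$doc_id)][1])
    }
    dangling <- setdiff(flags$doc_id, docs$doc_id)
    if (length(dangling)) stopf("Flags refer to unknown doc_id '%s'.", dangling[1])
    x$flags <- flags
  }

  if (nrow(surv)) {
    if (!is_date(surv$survey_date)) {
      surv$survey_date <- as.Date(surv$survey_date)
    }
    if (any(is.na(surv$survey_date))) stopf("Unparseable survey_date.")
    if (anyDuplicated(surv$user_id)) {
      stopf("More than one survey record for user '%s'.",
            surv$user_id[duplicated(surv$user_id)][1])
    }
    qcols <- intersect(paste0("q", 1:53), names(surv))
    n_levels <- eortc_catalog()$n_levels
    for (col in qcols) {
      qid <- as.integer(sub("^q", "", col))
      v <- surv[[col]]
      bad <- which(!is.na(v) & (v < 1 | v > n_levels[qid] | v != floor(v)))
      if (length(bad)) {
        stopf("Survey answer out of range: user '%s', %s = %s (levels 1..%d).",
              surv$user_id[bad[1]], col, format(v[bad[1]]), n_levels[qid])
      }
      surv[[col]] <- as.integer(v)
    }
    x$surveys <- surv
  }

  if (!is.null(x$coverage)) {
    need(x$coverage, c("doc_id", "annotator_id"), "coverage")
    dangling <- setdiff(x$coverage$doc_id, docs$doc_id)
    if (length(dangling)) stopf("Coverage refers to unknown doc_id '%s'.", dangling[1])
  }
  x
}

#' @export
print.qol_corpus <- function(x, ...) {
  cat(sprintf(
    "<qol_corpus>  %d documents (%d users), %d annotations (%d annotators), %d surveys\n",
    nrow(x$documents), length(unique(x$documents$user_id)),
    nrow(x$annotations), length(unique(x$annotations$annotator_id)),
    nrow(x$surveys)))
  invisible(x)
}

#' @export
format.qol_corpus <- function(x, ...) {
  sprintf("<qol_corpus: %d docs / %d annotations / %d surveys>",
          nrow(x$documents), nrow(x$annotations), nrow(x$surveys))
}

# flags joined onto documents with the documented defaults
document_flags <- function(corpus) {
  corpus$documents |>
    select("doc_id") |>
    left_join(corpus$flags, by = "doc_id") |>
    mutate(
      refers_to_past = dplyr::coalesce(.data$refers_to_past, FALSE),
      subject_is_self = dplyr::coalesce(.data$subject_is_self, TRUE)
    )
}

# restrict a corpus to a set of doc_ids, dropping dependent rows
restrict_docs <- function(corpus, keep_ids) {
  corpus$documents <- filter(corpus$documents, .data$doc_id %in% keep_ids)
  corpus$annotations <- filter(corpus$annotations, .data$doc_id %in% keep_ids)
  corpus$flags <- filter(corpus$flags, .data$doc_id %in% keep_ids)
  if (!is.null(corpus$coverage)) {
    corpus$coverage <- filter(corpus$coverage, .data$doc_id %in% keep_ids)
  }
  corpus
}

#' Drop documents whose subject is someone other than the posting user
#'
#' Posts carrying QoL information about another person (a relative, another
#' patient) are annotated but must not enter any statistic that compares
#' annotations with the posting user's own survey. This returns the
#' statistics-facing view with those documents (and their annotations)
#' removed.
#'
#' @param corpus A [qol_corpus()].
#' @return A `qol_corpus` with the other-subject documents removed; the
#'   number removed is attached as attribute `n_excluded_other` and
#'   reported via a message.
#' @export
exclude_other_subject <- function(corpus) {
  fl <- document_flags(corpus)
  drop_ids <- fl$doc_id[!fl$subject_is_self]
  out <- restrict_docs(corpus, setdiff(fl$doc_id, drop_ids))
  if (length(drop_ids)) {
    inform(sprintf("Excluded %d document(s) about a subject other than the posting user.",
                   length(drop_ids)))
  }
  if (nrow(out$documents) == 0) {
    warn("All documents were excluded as other-subject; statistics view is empty.")
  }
  attr(out, "n_excluded_other") <- length(drop_ids)
  out
}

#' Restrict a corpus to each user's pre-survey time window
#'
#' Keeps documents with `survey_date - months <= timestamp <= survey_date`,
#' the window being anchored on each posting user's own survey date (month
#' arithmetic at day resolution). Optionally also drops documents flagged as
#' referring to past events, which aligns forum content with the
#' questionnaire's short recall window.
#'
#' @param corpus A [qol_corpus()].
#' @param months Window length in months (e.g. 6 or 24).
#' @param exclude_past_refs Drop documents with `refers_to_past = TRUE`?
#' @return A `qol_corpus` restricted to the window, with attributes
#'   `n_dropped_window`, `n_dropped_past` and `n_dropped_no_survey`.
#' @export
filter_window <- function(corpus, months, exclude_past_refs = FALSE) {
  if (!is.numeric(months) || length(months) != 1 || months < 1) {
    stopf("`months` must be a positive number of months.")
  }
  docs <- corpus$documents |>
    left_join(select(corpus$surveys, "user_id", "survey_date"), by = "user_id")
  no_survey <- unique(docs$user_id[is.na(docs$survey_date)])
  if (length(no_survey)) {
    annotated_users <- unique(
      corpus$documents$user_id[corpus$documents$doc_id %in% corpus$annotations$doc_id])
    offending <- intersect(no_survey, annotated_users)
    if (length(offending)) {
      stopf("User '%s' has annotated documents but no survey record; cannot anchor the time window.",
            offending[1])
    }
  }
  docs <- filter(docs, !is.na(.data$survey_date))
  lower <- add_months(docs$survey_date, -as.integer(months))
  in_window <- docs$timestamp >= lower & docs$timestamp <= docs$survey_date
  keep <- docs$doc_id[in_window]
  n_window <- sum(!in_window)
  n_past <- 0L
  if (exclude_past_refs) {
    fl <- document_flags(corpus)
    past_ids <- fl$doc_id[fl$refers_to_past]
    n_past <- sum(keep %in% past_ids)
    keep <- setdiff(keep, past_ids)
  }
  out <- restrict_docs(corpus, keep)
  attr(out, "n_dropped_window") <- n_window
  attr(out, "n_dropped_past") <- n_past
  attr(out, "n_dropped_no_survey") <- sum(corpus$documents$user_id %in% no_survey)
  attr(out, "window_months") <- months
  out
}
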