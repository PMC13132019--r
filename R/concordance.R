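#' Binarize EORTC answers
#'
#' Collapses ordinal questionnaire answers to the two-valued scheme used for
#' the annotation-survey comparison. For 4-level items, "not at all" (1) is
#' `"negative"` and "a little" / "quite a bit" / "very much" (2--4) are
#' `"positive"` (issue present). For the 7-level global items (qids 29, 30)
#' a score at or below `seven_level_threshold` (default 4, the midpoint)
#' counts as `"positive"`, i.e. impaired global health.
#'
#' @param qid Integer vector of question ids.
#' @param value Integer vector of answers (recycled against `qid`).
#' @param seven_level_threshold Largest 7-level answer still classified as
#'   positive/impaired.
#' @return Character vector of `"positive"` / `"negative"`.
#' @examples
#' binarize_answer(22, 2) # "a little" worry -> positive
#' binarize_answer(9, 1)  # no pain -> negative
#' @export
binarize_answer <- function(qid, value, seven_level_threshold = 4) {
  n <- max(length(qid), length(value))
  qid <- rep_len(as.integer(qid), n)
  value <- rep_len(value, n)
  if (any(qid < 1 | qid > 53, na.rm = TRUE)) stopf("`qid` must be in 1..53.")
  n_levels <- eortc_catalog()$n_levels[qid]
  bad <- which(!is.na(value) & (value < 1 | value > n_levels | value != floor(value)))
  if (length(bad)) {
    stopf("Answer %s out of range for qid %d (levels 1..%d).",
          format(value[bad[1]]), qid[bad[1]], n_levels[bad[1]])
  }
  out <- ifelse(n_levels == 7,
                ifelse(value <= seven_level_threshold, "positive", "negative"),
                ifelse(value >= 2, "positive", "negative"))
  out[is.na(value)] <- NA_character_
  out
}

# surveys in long binarized form: user_id, qid, answer, actual
binarize_survey <- function(surveys, seven_level_threshold = 4) {
  qcols <- intersect(paste0("q", 1:53), names(surveys))
  if (length(qcols) == 0 || nrow(surveys) == 0) {
    return(tibble(user_id = character(), qid = integer(),
                  answer = integer(), actual = character()))
  }
  surveys |>
    select("user_id", dplyr::all_of(qcols)) |>
    tidyr::pivot_longer(dplyr::all_of(qcols), names_to = "qid",
                        values_to = "answer") |>
    mutate(qid = as.integer(sub("^q", "", .data$qid)),
           actual = binarize_answer(.data$qid, .data$answer,
                                    seven_level_threshold)) |>
    filter(!is.na(.data$actual))
}

#' Aggregate several annotation polarities into one user-level prediction
#'
#' The majority polarity wins; ties break to `"positive"` (the annotation
#' schema is presence-biased: the unmarked base label denotes a reported
#' presence). An empty input contributes nothing: the user-question pair is
#' skipped, mirroring the rule that a user without labeled data for a
#' question enters no confusion cell.
#'
#' @param labels Character vector of `"positive"` / `"negative"`.
#' @param tie `"positive"` (default) or `"negative"`.
#' @return A single label, or `NA_character_` for empty input.
#' @export
user_prediction <- function(labels, tie = "positive") {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) return(NA_character_)
  n_pos <- sum(labels == "positive")
  n_neg <- length(labels) - n_pos
  if (n_pos > n_neg) "positive" else if (n_neg > n_pos) "negative" else tie
}

classify_outcome <- function(predicted, actual) {
  dplyr::case_when(
    predicted == "positive" & actual == "positive" ~ "tp",
    predicted == "positive" & actual == "negative" ~ "fp",
    predicted == "negative" & actual == "negative" ~ "tn",
    predicted == "negative" & actual == "positive" ~ "fn"
  )
}

#' Pair annotations with survey answers
#'
#' Builds the comparison records underlying every concordance statistic.
#' The *predicted* label of a comparison comes from the forum annotation
#' polarity; the *actual* label is the user's binarized survey answer to the
#' same question.
#'
#' * `level = "annotation"`: one comparison per span annotation (repeated
#'   mentions by one user count separately, as in annotation-total
#'   reporting).
#' * `level = "user"`: one comparison per (user, question) pair, the
#'   prediction being [user_prediction()] over all of the user's in-view
#'   annotation polarities for that question.
#'
#' The corpus should already be the statistics-facing view (see
#' [exclude_other_subject()] and [filter_window()]).
#'
#' @param corpus A [qol_corpus()].
#' @param level `"annotation"` or `"user"`.
#' @param strict If `TRUE` (default) an annotation whose user has no survey
#'   record is an error; if `FALSE` such annotations are skipped with a
#'   warning.
#' @param seven_level_threshold Passed to [binarize_answer()].
#' @return A tibble: `user_id`, `qid`, `predicted`, `actual`, `outcome`
#'   (`"tp"`/`"fp"`/`"tn"`/`"fn"`), `level`, `n_source_annotations`, and for
#'   annotation level `doc_id`, `annotator_id`, `exact_match`.
#' @export
build_comparisons <- function(corpus, level = c("annotation", "user"),
                              strict = TRUE, seven_level_threshold = 4) {
  level <- match.arg(level)
  ann <- corpus$annotations |>
    inner_join(select(corpus$documents, "doc_id", "user_id"), by = "doc_id")
  empty <- tibble(user_id = character(), qid = integer(),
                  predicted = character(), actual = character(),
                  outcome = character(), level = character(),
                  n_source_annotations = integer())
  if (nrow(ann) == 0) return(empty)
  missing_users <- setdiff(unique(ann$user_id), unique(corpus$surveys$user_id))
  if (length(missing_users)) {
    if (strict) {
      stopf("User '%s' has annotations but no survey record.", missing_users[1])
    }
    warn(sprintf("Skipping annotations of %d user(s) without a survey record.",
                 length(missing_users)))
    ann <- filter(ann, !.data$user_id %in% missing_users)
  }
  surv <- binarize_survey(corpus$surveys, seven_level_threshold)
  if (level == "annotation") {
    out <- ann |>
      inner_join(surv, by = c("user_id", "qid")) |>
      mutate(predicted = .data$polarity,
             outcome = classify_outcome(.data$predicted, .data$actual),
             level = "annotation", n_source_annotations = 1L) |>
      select("user_id", "qid", "doc_id", "annotator_id", "exact_match",
             "predicted", "actual", "outcome", "level", "n_source_annotations")
  } else {
    out <- ann |>
      group_by(.data$user_id, .data$qid) |>
      summarise(predicted = user_prediction(.data$polarity),
                n_source_annotations = n(), .groups = "drop") |>
      inner_join(surv, by = c("user_id", "qid")) |>
      mutate(outcome = classify_outcome(.data$predicted, .data$actual),
             level = "user") |>
      select("user_id", "qid", "predicted", "actual", "outcome", "level",
             "n_source_annotations")
  }
  out
}

#' Pool comparisons into confusion counts
#'
#' Counts TP/FP/TN/FN per question, per fine group, per coarse group or
#' overall. Grouped keys micro-pool the raw counts across the group's member
#' questions, so totals are conserved under any of the three partitions.
#'
#' @param comparisons Output of [build_comparisons()].
#' @param by `"question"`, `"fine"`, `"coarse"` or `"overall"`.
#' @return A tibble: `key`, `tp`, `fp`, `tn`, `fn`, `total`,
#'   `total_annotations` (sum of source annotations behind the counts).
#' @export
confusion <- function(comparisons, by = c("question", "fine", "coarse", "overall")) {
  by <- match.arg(by)
  if (nrow(comparisons) == 0) {
    return(tibble(key = character(), tp = integer(), fp = integer(),
                  tn = integer(), fn = integer(), total = integer(),
                  total_annotations = integer()))
  }
  cat <- eortc_catalog()
  keyed <- comparisons |>
    mutate(key = switch(by,
      question = cat$text[.data$qid],
      fine = cat$fine_group[.data$qid],
      coarse = cat$coarse_group[.data$qid],
      overall = "overall"
    ))
  keyed |>
    group_by(.data$key) |>
    summarise(
      tp = sum(.data$outcome == "tp"), fp = sum(.data$outcome == "fp"),
      tn = sum(.data$outcome == "tn"), fn = sum(.data$outcome == "fn"),
      total = n(),
      total_annotations = sum(.data$n_source_annotations),
      .groups = "drop"
    ) |>
    arrange(.data$key)
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, `f1` their harmonic
#' mean. A metric whose denominator is zero is undefined and reported as
#' `NA` (and later excluded from averages); `f1` is 0 when `TP = 0` but
#' errors exist, and is computed as `2 TP / (2 TP + FP + FN)`, which equals
#' the harmonic mean whenever precision and recall are both defined.
#'
#' @param counts A tibble with columns `tp`, `fp`, `tn`, `fn` (e.g. from
#'   [confusion()]); other columns pass through.
#' @return The input with `precision`, `recall`, `f1` columns appended.
#' @examples
#' metrics(tibble::tibble(tp = 3, fp = 1, tn = 4, fn = 2))
#' @export
metrics <- function(counts) {
  counts |>
    mutate(
      precision = ifelse(.data$tp + .data$fp > 0,
                         .data$tp / (.data$tp + .data$fp), NA_real_),
      recall = ifelse(.data$tp + .data$fn > 0,
                      .data$tp / (.data$tp + .data$fn), NA_real_),
      f1 = ifelse(2 * .data$tp + .data$fp + .data$fn > 0,
                  2 * .data$tp / (2 * .data$tp + .data$fp + .data$fn),
                  NA_real_)
    )
}

#' One-call concordance analysis
#'
#' Convenience wrapper running [build_comparisons()], [confusion()] and
#' [metrics()] on an analysis-ready corpus view.
#'
#' @inheritParams build_comparisons
#' @inheritParams confusion
#' @return A tibble of class `qol_concordance` (one row per key with counts
#'   and metrics), with attributes `level`, `by` and `n_comparisons`.
#'   Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
concordance <- function(corpus, level = c("annotation", "user"),
                        by = c("question", "fine", "coarse", "overall"),
                        strict = TRUE, seven_level_threshold = 4) {
  level <- match.arg(level)
  by <- match.arg(by)
  cmp <- build_comparisons(corpus, level, strict, seven_level_threshold)
  out <- metrics(confusion(cmp, by))
  structure(out, class = c("qol_concordance", class(out)),
            level = level, by = by, n_comparisons = nrow(cmp))
}

#' Per-user accuracy of survey-answer prediction
#'
#' For user-level comparisons, a user's accuracy is the fraction of their
#' contributing questions on which the forum-derived prediction matches the
#' binarized survey answer: `(TP + TN) / total`.
#'
#' @param comparisons User-level output of [build_comparisons()].
#' @return A tibble: `user_id`, `n_questions`, `n_correct`, `accuracy`.
#' @seealso [user_accuracy_summary()]
#' @export
user_accuracy <- function(comparisons) {
  comparisons |>
    group_by(.data$user_id) |>
    summarise(
      n_questions = n(),
      n_correct = sum(.data$outcome %in% c("tp", "tn")),
      accuracy = .data$n_correct / .data$n_questions,
      .groups = "drop"
    )
}

#' Mean and SD of per-user prediction accuracy
#'
#' @inheritParams user_accuracy
#' @return A one-row tibble: `n_users`, `mean_accuracy`, `sd_accuracy`
#'   (unweighted mean and sample SD across users with at least one
#'   comparison).
#' @export
user_accuracy_summary <- function(comparisons) {
  ua <- user_accuracy(comparisons)
  tibble(n_users = nrow(ua),
         mean_accuracy = mean(ua$accuracy),
         sd_accuracy = sd(ua$accuracy))
}

#' Per-user questionnaire coverage by forum annotations
#'
#' For each user with at least one annotated document in the view, the
#' fraction of the 53 questions carrying at least one of their annotations.
#'
#' @param corpus A [qol_corpus()] (analysis view).
#' @return A tibble: `user_id`, `n_questions`, `coverage` (in \[0, 1\]).
#' @export
question_coverage <- function(corpus) {
  corpus$annotations |>
    inner_join(select(corpus$documents, "doc_id", "user_id"), by = "doc_id") |>
    distinct(.data$user_id, .data$qid) |>
    count(.data$user_id, name = "n_questions") |>
    mutate(coverage = .data$n_questions / 53)
}

#' @rdname question_coverage
#' @return `question_coverage_summary()`: a one-row tibble `n_users`,
#'   `mean_coverage`, `sd_coverage`.
#' @export
question_coverage_summary <- function(corpus) {
  qc <- question_coverage(corpus)
  tibble(n_users = nrow(qc),
         mean_coverage = mean(qc$coverage),
         sd_coverage = sd(qc$coverage))
}
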