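#' Read a corpus from plain-text files
#'
#' Reads the standoff-style on-disk layout:
#'
#' * `documents.jsonl` -- one JSON object per line with keys `doc_id`,
#'   `user_id`, `timestamp` (ISO-8601 date), `doc_type`, `text`;
#' * `annotations.jsonl` -- keys `doc_id`, `annotator_id`, `qid`, `start`,
#'   `end` (0-based half-open code-point offsets), `polarity`,
#'   `exact_match`;
#' * `flags.jsonl` -- keys `doc_id`, `refers_to_past`, `subject_is_self`;
#' * `survey.csv` -- columns `user_id`, `survey_date`, `q1`..`q53` and any
#'   demographic columns;
#' * optionally `coverage.jsonl` -- keys `doc_id`, `annotator_id`.
#'
#' Missing `annotations`/`flags`/`survey`/`coverage` files yield empty
#' tables. All validation of [qol_corpus()] applies; a violating record
#' aborts the read with the offending record named.
#'
#' @param dir Directory holding the files above.
#' @return A [qol_corpus()].
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(dir) {
  if (!dir.exists(dir)) stopf("Corpus directory '%s' does not exist.", dir)
  p <- function(f) file.path(dir, f)
  docs <- read_jsonl(p("documents.jsonl"))
  if (is.null(docs)) stopf("Required file '%s' is missing.", p("documents.jsonl"))
  docs$timestamp <- as.Date(docs$timestamp)
  ann <- read_jsonl(p("annotations.jsonl"))
  flags <- read_jsonl(p("flags.jsonl"))
  cov <- read_jsonl(p("coverage.jsonl"))
  surv <- NULL
  if (file.exists(p("survey.csv"))) {
    surv <- readr::read_csv(p("survey.csv"), show_col_types = FALSE,
                            progress = FALSE)
    surv$survey_date <- as.Date(surv$survey_date)
  }
  qol_corpus(docs, ann, flags, surv, cov)
}

read_jsonl <- function(path) {
  if (!file.exists(path)) return(NULL)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(NULL)
  rows <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) {
      stopf("Malformed JSON on line %d of '%s': %s", i, path, conditionMessage(e))
    })
    as_tibble(rec[!vapply(rec, is.null, logical(1))])
  })
  bind_rows(rows)
}

#' Write a corpus to plain-text files
#'
#' Inverse of [read_corpus()]; `read_corpus(write_corpus(corpus, dir))`
#' reproduces the corpus exactly (text byte-identical, UTF-8 throughout).
#' Empty tables are written as empty files so a directory always carries
#' the full layout.
#'
#' @param corpus A [qol_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stopf("Cannot create directory '%s'.", dir)
  p <- function(f) file.path(dir, f)
  docs <- corpus$documents
  docs$timestamp <- format(docs$timestamp, "%Y-%m-%d")
  write_jsonl(docs, p("documents.jsonl"))
  write_jsonl(corpus$annotations, p("annotations.jsonl"))
  write_jsonl(corpus$flags, p("flags.jsonl"))
  if (!is.null(corpus$coverage)) write_jsonl(corpus$coverage, p("coverage.jsonl"))
  surv <- corpus$surveys
  surv$survey_date <- format(surv$survey_date, "%Y-%m-%d")
  readr::write_csv(surv, p("survey.csv"), progress = FALSE)
  invisible(dir)
}

write_jsonl <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(df)) {
    lines <- vapply(seq_len(nrow(df)), function(i) {
      jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE, digits = NA,
                       null = "null")
    }, character(1))
    writeLines(lines, con, useBytes = TRUE)
  }
  invisible(path)
}

#' Export documents and annotations as BRAT-style standoff files
#'
#' Writes, for each document, `<doc_id>.txt` with the raw text and
#' `<doc_id>.ann` with one `T<k>` line per span
#' (`T<k>\tQ<qid>_<polarity> <start> <end>\t<covered text>`), for manual
#' inspection in standoff annotation tools. Offsets remain 0-based
#' half-open code points.
#'
#' @param corpus A [qol_corpus()].
#' @param dir Output directory.
#' @param annotator_id Optional: restrict to one annotator's spans.
#' @return `dir`, invisibly.
#' @export
export_standoff <- function(corpus, dir, annotator_id = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- corpus$annotations
  if (!is.null(annotator_id)) ann <- filter(ann, .data$annotator_id %in% !!annotator_id)
  for (i in seq_len(nrow(corpus$documents))) {
    d <- corpus$documents[i, ]
    writeLines(d$text, file.path(dir, paste0(d$doc_id, ".txt")), useBytes = FALSE)
    a <- filter(ann, .data$doc_id == d$doc_id)
    lines <- character(0)
    if (nrow(a)) {
      covered <- stringr::str_sub(d$text, a$start + 1, a$end)
      lines <- sprintf("T%d\tQ%d_%s %d %d\t%s", seq_len(nrow(a)), a$qid,
                       a$polarity, a$start, a$end, covered)
    }
    writeLines(lines, file.path(dir, paste0(d$doc_id, ".ann")))
  }
  invisible(dir)
}
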