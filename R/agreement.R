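#' Convert span annotations into a rating matrix for one question
#'
#' Fleiss kappa needs a fixed set of items, each rated by the same number of
#' raters into categories. Two granularities are supported:
#'
#' * `unit = "word"`: one item per whitespace-delimited token of every
#'   in-scope document. A rater "labels" the token if and only if one of
#'   their spans for `qid` overlaps the token's character range by at least
#'   one code point (partial-span credit).
#' * `unit = "doc"`: one item per document, labeled iff the rater placed at
#'   least one span for `qid` anywhere in it.
#'
#' Only the base question label is considered; polarity and exact-match
#' attributes are ignored. Documents not covered by the full panel (per the
#' corpus `coverage` table, when present) are excluded with a warning, since
#' Fleiss' statistic assumes a constant number of raters per item.
#'
#' @param corpus A [qol_corpus()] (already restricted to the analysis view).
#' @param qid Question id in 1..53.
#' @param panel Character vector of at least two annotator ids.
#' @param unit `"word"` or `"doc"`.
#' @return A tibble of class `unit_matrix` with columns `doc_id`, `item`,
#'   `n_labeled`, `n_unlabeled` (each row summing to `length(panel)`), and
#'   attributes `unit`, `qid`, `n_raters`, `n_excluded_uncovered`.
#' @export
unitize <- function(corpus, qid, panel, unit = c("doc", "word")) {
  unit <- match.arg(unit)
  if (length(panel) < 2) stopf("`panel` must contain at least 2 annotators.")
  if (length(qid) != 1 || qid < 1 || qid > 53) stopf("`qid` must be in 1..53.")
  docs <- corpus$documents
  n_excluded <- 0L
  if (!is.null(corpus$coverage)) {
    cov <- corpus$coverage |>
      filter(.data$annotator_id %in% panel) |>
      distinct(.data$doc_id, .data$annotator_id) |>
      count(.data$doc_id)
    covered <- cov$doc_id[cov$n == length(panel)]
    n_excluded <- nrow(docs) - sum(docs$doc_id %in% covered)
    if (n_excluded > 0) {
      warn(sprintf("Excluding %d document(s) not covered by the full panel.", n_excluded))
    }
    docs <- filter(docs, .data$doc_id %in% covered)
  }
  ann <- corpus$annotations |>
    filter(.data$qid == !!as.integer(qid), .data$annotator_id %in% panel,
           .data$doc_id %in% docs$doc_id)

  if (unit == "doc") {
    labeled <- ann |> distinct(.data$doc_id, .data$annotator_id) |> count(.data$doc_id)
    out <- docs |>
      select("doc_id") |>
      left_join(labeled, by = "doc_id") |>
      mutate(item = row_number(),
             n_labeled = as.integer(dplyr::coalesce(.data$n, 0L)),
             n_unlabeled = length(panel) - .data$n_labeled) |>
      select("doc_id", "item", "n_labeled", "n_unlabeled")
  } else {
    per_doc <- lapply(seq_len(nrow(docs)), function(i) {
      d <- docs[i, ]
      tok <- stringr::str_locate_all(d$text, "\\S+")[[1]]
      if (nrow(tok) == 0) return(NULL)
      a <- filter(ann, .data$doc_id == d$doc_id)
      n_lab <- integer(nrow(tok))
      for (r in panel) {
        sp <- filter(a, .data$annotator_id == r)
        if (nrow(sp) == 0) next
        # token [s1,e1] (1-based incl.) overlaps span [start+1, end] iff
        # s1 <= end and e1 >= start + 1
        hit <- rep(FALSE, nrow(tok))
        for (k in seq_len(nrow(sp))) {
          hit <- hit | (tok[, 1] <= sp$end[k] & tok[, 2] >= sp$start[k] + 1)
        }
        n_lab <- n_lab + as.integer(hit)
      }
      tibble(doc_id = d$doc_id, item = seq_len(nrow(tok)),
             n_labeled = n_lab, n_unlabeled = length(panel) - n_lab)
    })
    out <- bind_rows(per_doc)
    if (nrow(out)) out$item <- seq_len(nrow(out))
  }
  structure(out, class = c("unit_matrix", class(out)),
            unit = unit, qid = as.integer(qid), n_raters = length(panel),
            n_excluded_uncovered = n_excluded)
}

#' Fleiss' kappa for a two-category rating matrix
#'
#' Chance-corrected agreement among a fixed number of raters:
#' \deqn{\kappa = (\bar P - \bar P_e) / (1 - \bar P_e)} with per-item
#' agreement \eqn{P_i = [\sum_j n_{ij}(n_{ij}-1)] / [n(n-1)]} and chance
#' agreement \eqn{\bar P_e = \sum_j p_j^2},
#' \eqn{p_j = \sum_i n_{ij} / (N n)}. Values can be negative (worse than
#' chance) and are reported as computed.
#'
#' When every rating falls into a single category, \eqn{1 - \bar P_e = 0}
#' and the ratio is formally undefined; observed agreement is nevertheless
#' perfect, so `1` is returned with attribute `degenerate = TRUE`.
#'
#' @param x A `unit_matrix` from [unitize()], or a numeric matrix with one
#'   row per item and one column per category of rating counts (rows summing
#'   to the constant number of raters).
#' @return A single number `<= 1`, with attribute `degenerate`.
#' @examples
#' m <- rbind(c(3, 0), c(2, 1), c(0, 3), c(1, 2))
#' fleiss_kappa(m) # 1/3
#' @export
fleiss_kappa <- function(x) {
  if (inherits(x, "unit_matrix") || is.data.frame(x)) {
    m <- cbind(x$n_labeled, x$n_unlabeled)
  } else {
    m <- as.matrix(x)
  }
  if (is.null(dim(m)) || nrow(m) < 1 || ncol(m) < 2) {
    stopf("Rating matrix must have >= 1 item and >= 2 categories.")
  }
  n <- unique(rowSums(m))
  if (length(n) != 1) stopf("Every item must be rated by the same number of raters.")
  if (n < 2) stopf("Fleiss kappa needs at least 2 raters per item.")
  N <- nrow(m)
  P_i <- (rowSums(m^2) - n) / (n * (n - 1))
  P_bar <- mean(P_i)
  p_j <- colSums(m) / (N * n)
  P_e <- sum(p_j^2)
  if (abs(1 - P_e) < .Machine$double.eps^0.5) {
    return(structure(1, degenerate = TRUE))
  }
  structure((P_bar - P_e) / (1 - P_e), degenerate = FALSE)
}

#' Per-question agreement table
#'
#' Computes Fleiss kappa for each requested question at the given
#' granularity, together with the number of rating items and the number of
#' documents in which at least one panel member placed the label
#' (`n_labeled_docs`). Questions never labeled by anyone are degenerate
#' (all ratings "unlabeled"): they are reported with `kappa = 1` and
#' `degenerate = TRUE` rather than dropped, so the table always covers the
#' requested questions.
#'
#' @inheritParams unitize
#' @param qids Integer vector of question ids (default all 53).
#' @return A tibble of class `qol_agreement`: `qid`, `question`, `unit`,
#'   `kappa`, `degenerate`, `n_items`, `n_raters`, `n_labeled_docs`.
#' @export
agreement_table <- function(corpus, qids = 1:53, unit = c("doc", "word"),
                            panel) {
  unit <- match.arg(unit)
  if (length(panel) < 2) stopf("`panel` must contain at least 2 annotators.")
  qids <- as.integer(qids)
  n <- length(panel)
  docs <- corpus$documents
  if (!is.null(corpus$coverage)) {
    cov <- corpus$coverage |>
      filter(.data$annotator_id %in% panel) |>
      distinct(.data$doc_id, .data$annotator_id) |>
      count(.data$doc_id)
    covered <- cov$doc_id[cov$n == n]
    n_excluded <- nrow(docs) - sum(docs$doc_id %in% covered)
    if (n_excluded > 0) {
      warn(sprintf("Excluding %d document(s) not covered by the full panel.", n_excluded))
    }
    docs <- filter(docs, .data$doc_id %in% covered)
  }
  ann <- corpus$annotations |>
    filter(.data$qid %in% qids, .data$annotator_id %in% panel,
           .data$doc_id %in% docs$doc_id)
  n_labeled_docs <- ann |>
    distinct(.data$qid, .data$doc_id) |>
    count(.data$qid, name = "n_labeled_docs")

  if (unit == "doc") {
    N <- nrow(docs)
    # per (qid, doc): number of panel raters with >= 1 span
    k_tab <- ann |>
      distinct(.data$qid, .data$doc_id, .data$annotator_id) |>
      count(.data$qid, .data$doc_id, name = "k")
  } else {
    # tokenize every document once; items are (doc, token)
    tok_loc <- stringr::str_locate_all(docs$text, "\\S+")
    n_tok <- vapply(tok_loc, nrow, integer(1))
    N <- sum(n_tok)
    tok <- tibble(
      doc_id = rep(docs$doc_id, n_tok),
      tok_s = unlist(lapply(tok_loc, function(m) m[, 1])),
      tok_e = unlist(lapply(tok_loc, function(m) m[, 2]))
    )
    # any character overlap between span [start+1, end] and token marks it
    k_tab <- ann |>
      inner_join(tok, by = "doc_id", relationship = "many-to-many") |>
      filter(.data$tok_s <= .data$end, .data$tok_e >= .data$start + 1) |>
      distinct(.data$qid, .data$doc_id, .data$tok_s, .data$annotator_id) |>
      count(.data$qid, .data$doc_id, .data$tok_s, name = "k")
  }

  # Fleiss' formula from the marked items plus the (N - L) all-unlabeled ones
  per_qid <- k_tab |>
    group_by(.data$qid) |>
    summarise(
      L = n(), sum_k = sum(.data$k),
      sum_pairs = sum(.data$k * (.data$k - 1) + (n - .data$k) * (n - .data$k - 1)),
      .groups = "drop"
    )
  out <- tibble(qid = qids) |>
    left_join(per_qid, by = "qid") |>
    left_join(n_labeled_docs, by = "qid") |>
    mutate(
      L = dplyr::coalesce(.data$L, 0L),
      sum_k = dplyr::coalesce(.data$sum_k, 0L),
      sum_pairs = dplyr::coalesce(.data$sum_pairs, 0L),
      n_labeled_docs = dplyr::coalesce(.data$n_labeled_docs, 0L)
    )
  if (N >= 1) {
    P_bar <- (out$sum_pairs + (N - out$L) * n * (n - 1)) / (N * n * (n - 1))
    p1 <- out$sum_k / (N * n)
    P_e <- p1^2 + (1 - p1)^2
    degen <- abs(1 - P_e) < .Machine$double.eps^0.5
    kappa <- ifelse(degen, 1, (P_bar - P_e) / (1 - P_e))
  } else {
    kappa <- rep(NA_real_, nrow(out))
    degen <- rep(NA, nrow(out))
  }
  out <- out |>
    mutate(unit = unit, kappa = kappa, degenerate = degen,
           n_items = if (N >= 1) N else 0L, n_raters = n) |>
    select("qid", "unit", "kappa", "degenerate", "n_items", "n_raters",
           "n_labeled_docs") |>
    left_join(select(eortc_catalog(), "qid", question = "text"), by = "qid") |>
    relocate("question", .after = "qid")
  if (all(out$n_items == 0)) warn("No documents covered by the panel; agreement table is empty.")
  structure(out, class = c("qol_agreement", class(out)))
}
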