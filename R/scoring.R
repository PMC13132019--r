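#' Score one EORTC scale from item answers
#'
#' Implements the EORTC scoring-manual procedure: the raw score RS is the
#' mean of the answered items; reversed (functional) scales are scored
#' \eqn{S = (1 - (RS-1)/\mathrm{range}) \times 100}, all other scales
#' \eqn{S = ((RS-1)/\mathrm{range}) \times 100}. The score is `NA` (missing)
#' when fewer than half of the scale's items -- rounded up -- are answered.
#'
#' @param answers Named numeric vector or list mapping question ids (names
#'   `"1"`..`"53"`, or an integer-named vector) to answers; `NA` marks an
#'   unanswered item. Only the scale's items are consulted.
#' @param scale Either a scale name (a row of [eortc_scales()]) or a one-row
#'   subset of that tibble.
#' @return A single number in \eqn{[0, 100]}, or `NA_real_` under the
#'   half-items missingness rule.
#' @examples
#' # best possible physical functioning
#' scale_score(setNames(rep(1, 5), 1:5), "Physical functioning") # 100
#' # no symptoms at all
#' scale_score(setNames(c(1, 1), c(9, 19)), "Pain") # 0
#' @export
scale_score <- function(answers, scale) {
  if (is.character(scale)) {
    scales <- eortc_scales()
    if (!scale %in% scales$scale) {
      stopf("Unknown scale '%s'. Valid names: %s.", scale,
            paste(scales$scale, collapse = ", "))
    }
    scale <- scales[scales$scale == scale, ]
  }
  qids <- scale$item_qids[[1]]
  vr <- unname(scale$value_range)
  vals <- unlist(answers)[as.character(qids)]
  n_levels <- vr + 1L
  bad <- !is.na(vals) & (vals < 1 | vals > n_levels | vals != floor(vals))
  if (any(bad)) {
    stopf("Answer out of range for scale '%s': item %s has value %s (levels 1..%d).",
          scale$scale, qids[which(bad)[1]], vals[which(bad)[1]], n_levels)
  }
  k <- length(qids)
  n_ans <- sum(!is.na(vals))
  if (n_ans < ceiling(k / 2)) return(NA_real_)
  rs <- unname(mean(vals, na.rm = TRUE))
  if (isTRUE(scale$reversed)) {
    (1 - (rs - 1) / vr) * 100
  } else {
    ((rs - 1) / vr) * 100
  }
}

#' Score all EORTC scales for a survey table
#'
#' Applies [scale_score()] to every scale in [eortc_scales()] for every row
#' of a survey table (columns `q1`..`q53`, `NA` for unanswered items).
#'
#' @param surveys A data frame with a `user_id` column and answer columns
#'   `q1`..`q53`.
#' @return A tibble in long format: `user_id`, `scale`, `kind`, `score`.
#' @export
score_survey <- function(surveys) {
  scales <- eortc_scales()
  purrr::map_dfr(seq_len(nrow(surveys)), function(i) {
    ans <- as.numeric(surveys[i, paste0("q", 1:53)])
    names(ans) <- 1:53
    tibble(
      user_id = surveys$user_id[i],
      scale = scales$scale,
      kind = scales$kind,
      score = vapply(seq_len(nrow(scales)), function(j) {
        scale_score(ans, scales[j, ])
      }, numeric(1))
    )
  })
}
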