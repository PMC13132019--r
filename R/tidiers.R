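#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_hline
#'   coord_flip labs theme_minimal facet_wrap
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a concordance result
#'
#' @param x A `qol_concordance` from [concordance()].
#' @param ... Unused.
#' @return A plain tibble, one row per key, with confusion counts and
#'   precision / recall / F1.
#' @method tidy qol_concordance
#' @export
tidy.qol_concordance <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "qol_concordance")
  out
}

#' One-row summary of a concordance result
#'
#' Means and sample SDs are taken across keys with a defined value;
#' undefined (NA) metrics are excluded and counted in `n_undefined_f1`.
#'
#' @inheritParams tidy.qol_concordance
#' @return A one-row tibble: `level`, `by`, `n_keys`, `n_comparisons`,
#'   `mean_f1`, `sd_f1`, `n_undefined_f1`, `micro_f1` (F1 of the pooled
#'   counts).
#' @method glance qol_concordance
#' @export
glance.qol_concordance <- function(x, ...) {
  pooled <- metrics(tibble(tp = sum(x$tp), fp = sum(x$fp),
                           tn = sum(x$tn), fn = sum(x$fn)))
  tibble(
    level = attr(x, "level"), by = attr(x, "by"),
    n_keys = nrow(x), n_comparisons = attr(x, "n_comparisons"),
    mean_f1 = mean(x$f1, na.rm = TRUE),
    sd_f1 = sd(x$f1[!is.na(x$f1)]),
    n_undefined_f1 = sum(is.na(x$f1)),
    micro_f1 = pooled$f1
  )
}

#' Plot F1 by key for a concordance result
#'
#' @param object A `qol_concordance`.
#' @param metric Column to plot (`"f1"`, `"precision"` or `"recall"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qol_concordance
#' @export
autoplot.qol_concordance <- function(object, metric = "f1", ...) {
  df <- tidy(object)
  df <- df[!is.na(df[[metric]]), ]
  df$key <- stringr::str_trunc(df$key, 50)
  ggplot(df, aes(x = stats::reorder(.data$key, .data[[metric]]),
                 y = .data[[metric]])) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(x = NULL, y = toupper(metric),
         title = sprintf("Annotation-survey concordance (%s level, by %s)",
                         attr(object, "level"), attr(object, "by"))) +
    theme_minimal()
}

#' Tidy an agreement table
#'
#' @param x A `qol_agreement` from [agreement_table()].
#' @param ... Unused.
#' @return A plain tibble with one row per question.
#' @method tidy qol_agreement
#' @export
tidy.qol_agreement <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "qol_agreement")
  out
}

#' One-row summary of an agreement table
#'
#' Mean and sample SD of kappa across questions with at least one rating
#' item, both over all such questions and restricted to questions where at
#' least one panel member placed the label (degenerate never-labeled
#' questions report kappa 1 by convention and can distort the mean).
#'
#' @inheritParams tidy.qol_agreement
#' @return A one-row tibble: `unit`, `n_questions`, `mean_kappa`,
#'   `sd_kappa`, `n_degenerate`, `mean_kappa_labeled`, `sd_kappa_labeled`.
#' @method glance qol_agreement
#' @export
glance.qol_agreement <- function(x, ...) {
  with_items <- x[!is.na(x$kappa), ]
  labeled <- with_items[with_items$n_labeled_docs > 0, ]
  tibble(
    unit = unique(x$unit),
    n_questions = nrow(with_items),
    mean_kappa = mean(with_items$kappa),
    sd_kappa = sd(with_items$kappa),
    n_degenerate = sum(with_items$degenerate),
    mean_kappa_labeled = mean(labeled$kappa),
    sd_kappa_labeled = sd(labeled$kappa)
  )
}

#' Plot per-question agreement
#'
#' Dot plot of Fleiss kappa per question, ordered by kappa; degenerate
#' (never-labeled) questions are dropped.
#'
#' @param object A `qol_agreement`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qol_agreement
#' @export
autoplot.qol_agreement <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$kappa) & df$n_labeled_docs > 0, ]
  df$question <- stringr::str_trunc(df$question, 50)
  ggplot(df, aes(x = stats::reorder(.data$question, .data$kappa),
                 y = .data$kappa)) +
    geom_point(colour = "steelblue", size = 2) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    coord_flip() +
    labs(x = NULL, y = "Fleiss kappa",
         title = sprintf("Inter-annotator agreement (%s units)",
                         unique(df$unit))) +
    theme_minimal()
}
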