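#' Per-question label frequency table
#'
#' For each question with at least one annotation in the view: the number
#' of documents carrying the label, that count as a percentage of all
#' documents in the view, the number of distinct users with such a
#' document, and that count as a percentage of all posting users in the
#' view. Rows are ordered by document count (descending), ties by question
#' id. Percentages are rounded to one decimal place.
#'
#' @param corpus A [qol_corpus()] (analysis view).
#' @param top_n Number of rows to keep (default 10); `Inf` keeps all.
#' @return A tibble: `qid`, `question`, `n_docs`, `pct_docs`, `n_users`,
#'   `pct_users`.
#' @export
label_frequency_table <- function(corpus, top_n = 10) {
  n_docs_total <- nrow(corpus$documents)
  n_users_total <- length(unique(corpus$documents$user_id))
  ann <- corpus$annotations |>
    inner_join(select(corpus$documents, "doc_id", "user_id"), by = "doc_id")
  freq <- ann |>
    distinct(.data$qid, .data$doc_id, .data$user_id) |>
    group_by(.data$qid) |>
    summarise(n_docs = dplyr::n_distinct(.data$doc_id),
              n_users = dplyr::n_distinct(.data$user_id), .groups = "drop") |>
    mutate(pct_docs = round(100 * .data$n_docs / n_docs_total, 1),
           pct_users = round(100 * .data$n_users / n_users_total, 1)) |>
    arrange(dplyr::desc(.data$n_docs), .data$qid) |>
    left_join(select(eortc_catalog(), "qid", question = "text"), by = "qid") |>
    select("qid", "question", "n_docs", "pct_docs", "n_users", "pct_users")
  utils::head(freq, top_n)
}

#' Fraction of documents carrying at least one QoL label
#'
#' @param corpus A [qol_corpus()] (analysis view).
#' @return A single number in \[0, 1\] (0 for an empty view).
#' @export
labeled_fraction <- function(corpus) {
  if (nrow(corpus$documents) == 0) return(0)
  mean(corpus$documents$doc_id %in% corpus$annotations$doc_id)
}

#' Pipeline run configuration
#'
#' Describes one end-to-end run: the input (a [sim_config()] to simulate,
#' or a directory of corpus files to read), the analysis windows, the
#' past-reference filtering switch, the comparison level, the agreement
#' panel, and the output directory.
#'
#' `read_run_config()` loads the same structure from a YAML file with
#' top-level keys matching the arguments (a `sim:` mapping is forwarded to
#' [sim_config()]).
#'
#' @param sim A [sim_config()], or `NULL` when reading from files.
#' @param corpus_dir Directory for [read_corpus()] when `sim` is `NULL`.
#' @param window_months Integer vector of window lengths to analyse.
#' @param exclude_past_refs Drop past-referenced documents in the
#'   grouped/filtered analyses?
#' @param level Comparison level for the main concordance tables.
#' @param agreement_unit Granularities for the agreement table.
#' @param agreement_months Window (months) for the agreement table; its
#'   panel is taken from the sim config's recent panel or
#'   `agreement_panel`.
#' @param agreement_panel Annotator ids; default derived from coverage.
#' @param out_dir Output directory for the CSV bundle.
#' @param seed Overrides the sim config seed when given.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       corpus_dir = NULL,
                       window_months = c(6, 24),
                       exclude_past_refs = TRUE,
                       level = c("annotation", "user"),
                       agreement_unit = c("word", "doc"),
                       agreement_months = min(window_months),
                       agreement_panel = NULL,
                       out_dir = NULL,
                       seed = NULL) {
  level <- match.arg(level)
  if (is.null(sim) && is.null(corpus_dir)) {
    stopf("Provide either `sim` or `corpus_dir`.")
  }
  if (!is.null(corpus_dir) && !dir.exists(corpus_dir)) {
    stopf("`corpus_dir` '%s' does not exist.", corpus_dir)
  }
  if (any(window_months < 1)) stopf("`window_months` must be positive.")
  if (!is.null(seed) && !is.null(sim)) sim$seed <- as.integer(seed)
  structure(list(
    sim = sim, corpus_dir = corpus_dir,
    window_months = sort(unique(as.integer(window_months))),
    exclude_past_refs = isTRUE(exclude_past_refs),
    level = level, agreement_unit = agreement_unit,
    agreement_months = as.integer(agreement_months),
    agreement_panel = agreement_panel, out_dir = out_dir,
    seed = if (is.null(seed)) sim$seed else as.integer(seed)
  ), class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML run configuration.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$sim)) {
    sim_args <- y$sim
    if (!is.null(sim_args$survey_anchor)) {
      sim_args$survey_anchor <- as.Date(sim_args$survey_anchor)
    }
    for (tab in c("posts_bins", "annotators")) {
      if (!is.null(sim_args[[tab]])) sim_args[[tab]] <- as_tibble(sim_args[[tab]])
    }
    sim <- do.call(sim_config, sim_args)
  } else if (is.null(y$corpus_dir)) {
    sim <- sim_config()
  }
  args <- y[setdiff(names(y), "sim")]
  do.call(run_config, c(list(sim = sim), args))
}

#' Run the full analysis pipeline and write the report bundle
#'
#' Executes, in order: cohort simulation (or corpus reading), removal of
#' other-subject documents, per-window temporal filtering, cohort
#' descriptives, the per-question label frequency table, the dual-unit
#' agreement table on the short window, and concordance tables at
#' question / fine / coarse / overall granularity for every requested
#' window, plus the per-user accuracy and questionnaire-coverage summaries.
#'
#' When `config$out_dir` is set, the bundle is written as one CSV per
#' table plus a JSON `manifest.json` (configuration echo, seed, record and
#' exclusion counts). Outputs contain nothing run-dependent beyond the
#' seeded computation, so a rerun with the same configuration is
#' byte-identical.
#'
#' @param config A [run_config()] (or path to a YAML file for
#'   [read_run_config()]).
#' @return A list of class `qol_report`: `corpus` (full statistics view),
#'   `summary` (cohort descriptives), `label_frequency`, `agreement`,
#'   `concordance` (one tibble per window with key-level metrics at all
#'   granularities), `user_summary`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  if (!is.null(config$sim)) {
    sim <- config$sim
    cohort <- generate_cohort(sim)
    corpus <- cohort$corpus
  } else {
    corpus <- read_corpus(config$corpus_dir)
    sim <- NULL
  }
  n_docs_raw <- nrow(corpus$documents)
  n_ann_raw <- nrow(corpus$annotations)

  view <- suppressMessages(exclude_other_subject(corpus))
  n_other <- attr(view, "n_excluded_other")

  summary_tabs <- summarize_cohort(view)
  label_freq <- label_frequency_table(view, top_n = Inf)

  # agreement on the short-window stratum (constant panel required)
  agree_view <- filter_window(view, config$agreement_months,
                              exclude_past_refs = FALSE)
  panel <- config$agreement_panel
  if (is.null(panel)) {
    panel <- if (!is.null(agree_view$coverage) && nrow(agree_view$coverage)) {
      cov_n <- count(agree_view$coverage, .data$annotator_id)
      cov_n$annotator_id[cov_n$n == max(cov_n$n)]
    } else {
      unique(agree_view$annotations$annotator_id)
    }
  }
  agreement <- NULL
  if (length(panel) >= 2) {
    per_unit <- lapply(config$agreement_unit, function(u) {
      tab <- suppressWarnings(agreement_table(agree_view, qids = 1:53,
                                              unit = u, panel = panel))
      as_tibble(tab)
    })
    agreement <- bind_rows(per_unit) |>
      select("qid", "question", "unit", "kappa", "degenerate",
             "n_labeled_docs") |>
      tidyr::pivot_wider(names_from = "unit",
                         values_from = c("kappa", "degenerate")) |>
      arrange(.data$qid)
  }

  conc <- lapply(config$window_months, function(m) {
    w <- filter_window(view, m, exclude_past_refs = config$exclude_past_refs)
    cmp <- build_comparisons(w, level = config$level)
    granular <- lapply(c("question", "fine", "coarse", "overall"), function(g) {
      metrics(confusion(cmp, g)) |> mutate(granularity = g, .before = 1)
    })
    bind_rows(granular) |> mutate(window_months = m, .before = 1)
  })
  names(conc) <- paste0("m", config$window_months)

  user_summary <- lapply(config$window_months, function(m) {
    w <- filter_window(view, m, exclude_past_refs = config$exclude_past_refs)
    ucmp <- build_comparisons(w, level = "user")
    dplyr::bind_cols(
      tibble(window_months = m),
      user_accuracy_summary(ucmp),
      select(question_coverage_summary(w), mean_coverage = "mean_coverage",
             sd_coverage = "sd_coverage")
    )
  }) |> bind_rows()

  manifest <- list(
    package = "qolforum",
    version = as.character(utils::packageVersion("qolforum")),
    seed = config$seed,
    level = config$level,
    window_months = config$window_months,
    exclude_past_refs = config$exclude_past_refs,
    agreement_months = config$agreement_months,
    agreement_panel = panel,
    counts = list(
      documents = n_docs_raw,
      annotations = n_ann_raw,
      surveys = nrow(corpus$surveys),
      excluded_other_subject = n_other,
      documents_stats_view = nrow(view$documents),
      annotations_stats_view = nrow(view$annotations),
      labeled_fraction = labeled_fraction(view)
    )
  )
  if (!is.null(sim)) {
    manifest$sim <- list(
      n_users = sim$n_users, n_silent_users = sim$n_silent_users,
      period_months = sim$period_months, recent_months = sim$recent_months,
      consistency = sim$consistency, survey_noise = sim$survey_noise,
      seed = sim$seed
    )
  }

  out <- structure(list(
    corpus = view,
    summary = summary_tabs,
    label_frequency = label_freq,
    agreement = agreement,
    concordance = conc,
    user_summary = user_summary,
    manifest = manifest
  ), class = "qol_report")

  if (!is.null(config$out_dir)) write_report(out, config$out_dir)
  out
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  readr::write_csv(report$summary$posts_per_user, p("posts_per_user.csv"),
                   progress = FALSE)
  readr::write_csv(report$label_frequency, p("label_frequency.csv"),
                   progress = FALSE)
  if (!is.null(report$agreement)) {
    readr::write_csv(report$agreement, p("agreement.csv"), progress = FALSE)
  }
  for (nm in names(report$concordance)) {
    readr::write_csv(report$concordance[[nm]],
                     p(sprintf("concordance_%s.csv", nm)), progress = FALSE)
  }
  readr::write_csv(report$user_summary, p("user_summary.csv"), progress = FALSE)
  jsonlite::write_json(report$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.qol_report <- function(x, ...) {
  cat("<qol_report>\n")
  cat(sprintf("  corpus: %d documents, %d annotations, %d surveys\n",
              nrow(x$corpus$documents), nrow(x$corpus$annotations),
              nrow(x$corpus$surveys)))
  cat(sprintf("  labeled fraction: %.1f%%\n",
              100 * x$manifest$counts$labeled_fraction))
  for (nm in names(x$concordance)) {
    ov <- x$concordance[[nm]]
    ov <- ov[ov$granularity == "overall", ]
    if (nrow(ov)) {
      cat(sprintf("  %s overall: F1 %.2f (%d comparisons)\n",
                  nm, ov$f1, ov$total))
    }
  }
  invisible(x)
}
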