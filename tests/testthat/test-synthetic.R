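noise_free_annotators <- function(span_recall = 1) {
  tibble::tibble(
    annotator_id = c("A1", "A2", "A3"),
    span_recall = span_recall,
    false_span_rate = 0,
    polarity_flip_prob = 0,
    boundary_jitter_tokens = 0L
  )
}

test_that("generation is deterministic given the seed and leaves the RNG alone", {
  cfg <- sim_config(n_users = 15, seed = 123)
  a <- generate_cohort(cfg)
  set.seed(99)
  marker <- runif(1)
  b <- generate_cohort(cfg)
  expect_identical(a$corpus$documents, b$corpus$documents)
  expect_identical(a$corpus$annotations, b$corpus$annotations)
  expect_identical(a$corpus$surveys, b$corpus$surveys)
  expect_identical(a$truth$latent, b$truth$latent)
  set.seed(99)
  expect_identical(runif(1), marker) # caller RNG state not consumed
  # different seed, different corpus
  c2 <- generate_cohort(sim_config(n_users = 15, seed = 124))
  expect_false(identical(a$corpus$documents$text, c2$corpus$documents$text))
})

test_that("generated corpora always pass corpus validation", {
  for (sd in c(2, 3)) {
    ch <- generate_cohort(sim_config(n_users = 20, seed = sd))
    # re-validate from the raw tables; any invariant violation would abort
    expect_s3_class(
      qol_corpus(ch$corpus$documents, ch$corpus$annotations, ch$corpus$flags,
                 ch$corpus$surveys, ch$corpus$coverage),
      "qol_corpus"
    )
    # oracle mention spans resolve inside their documents
    men <- ch$truth$mentions
    txt <- setNames(ch$corpus$documents$text, ch$corpus$documents$doc_id)
    expect_true(all(men$end <= stringr::str_length(txt[men$doc_id])))
    # every mention sentence is recoverable from its offsets
    cut <- stringr::str_sub(txt[men$doc_id], men$start + 1, men$end)
    expect_true(all(stringr::str_detect(cut, "lately|recently|problem|issue")))
  }
})

test_that("the noiseless limit yields only true positives and negatives", {
  cfg <- sim_config(n_users = 20, consistency = 1, survey_noise = 0,
                    annotators = noise_free_annotators(span_recall = 0.9),
                    seed = 42)
  ch <- generate_cohort(cfg)
  w <- filter_window(quiet_exclude(ch$corpus), 24)
  cmp <- build_comparisons(w, "annotation")
  expect_gt(nrow(cmp), 0)
  expect_true(all(cmp$outcome %in% c("tp", "tn")))
})

test_that("zero mention probability produces an unlabeled corpus", {
  # false spans are annotator noise, configured separately; switch them off
  # to isolate the mention process
  cfg <- sim_config(n_users = 10, mention_prob = rep(0, 53),
                    annotators = noise_free_annotators(), seed = 8)
  ch <- generate_cohort(cfg)
  expect_equal(nrow(ch$corpus$annotations), 0)
  expect_gt(nrow(ch$corpus$documents), 0)
  w <- filter_window(quiet_exclude(ch$corpus), 24)
  expect_equal(nrow(build_comparisons(w, "annotation")), 0)
  expect_equal(labeled_fraction(ch$corpus), 0)
})

test_that("expected_accuracy has the documented closed form and guards", {
  mk <- function(c_, s) sim_config(consistency = c_, survey_noise = s,
                                   annotators = noise_free_annotators())
  expect_equal(expected_accuracy(mk(0.85, 0)), 0.85)
  expect_equal(expected_accuracy(mk(1, 0.1)), 0.9)
  # c = 0.5 is chance no matter the survey noise: 0.5(1-s) + 0.5 s = 0.5
  for (s in c(0, 0.2, 0.5)) expect_equal(expected_accuracy(mk(0.5, s)), 0.5)
  expect_error(expected_accuracy(sim_config()), "polarity_flip_prob")
})

test_that("the simulator's config validation rejects malformed inputs", {
  expect_error(sim_config(consistency = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(n_users = 0), "n_users")
  expect_error(sim_config(prevalence = rep(0.5, 10)), "length 53")
  expect_error(sim_config(panel_recent = c("A1", "Z9")), "subsets")
  expect_error(sim_config(recent_months = 40), "recent_months")
})

test_that("cohort descriptives: activity bins, label skew, labeled fraction", {
  # bin boundaries at 1 / 2-10 / 11-100 / 101-1000 / >1000 posts per user
  docs <- tibble::tibble(
    doc_id = sprintf("d%03d", 1:206),
    user_id = c("a", rep("b", 5), rep("c", 200)),
    timestamp = as.Date("2024-05-01"), doc_type = "comment", text = "x y z"
  )
  corp <- qol_corpus(docs, surveys = survey_row("a"))
  s <- summarize_cohort(corp)
  got <- setNames(s$posts_per_user$n_users, as.character(s$posts_per_user$bin))
  expect_equal(got[["1"]], 1)
  expect_equal(got[["2-10"]], 1)
  expect_equal(got[["101-1000"]], 1)
  expect_equal(got[["11-100"]], 0)
  # every doc labeled -> fraction 1; none labeled -> 0
  expect_equal(s$labeled_fraction, 0)
  ann <- tibble::tibble(doc_id = docs$doc_id, annotator_id = "A1", qid = 9L,
                        start = 0L, end = 3L, polarity = "positive",
                        exact_match = FALSE)
  expect_equal(summarize_cohort(qol_corpus(docs, ann, surveys = survey_row("a")))$labeled_fraction, 1)
  # generated cohorts keep the long-tail label skew: top question's share
  # of labeled documents exceeds the median question's share
  ch <- generate_cohort(sim_config(seed = 6))
  lf <- summarize_cohort(ch$corpus)$label_frequency
  expect_gt(max(lf$n_docs), stats::median(lf$n_docs))
  expect_identical(lf$qid[which.max(lf$n_docs)], 36L) # the fallback label dominates
  # labeled fraction lands in the one-quarter to one-third band
  frac <- labeled_fraction(quiet_exclude(ch$corpus))
  expect_gt(frac, 0.20)
  expect_lt(frac, 0.40)
})

test_that("annotator panels follow the two time strata", {
  ch <- generate_cohort(sim_config(n_users = 40, seed = 13))
  cov <- ch$corpus$coverage
  docs <- ch$corpus$documents |>
    dplyr::left_join(dplyr::select(ch$corpus$surveys, "user_id", "survey_date"),
                     by = "user_id")
  n_cov <- dplyr::count(cov, .data$doc_id)
  docs$n_annotators <- n_cov$n[match(docs$doc_id, n_cov$doc_id)]
  age_months <- as.numeric(docs$survey_date - docs$timestamp) / 30.4375
  expect_true(all(docs$n_annotators[age_months <= 6] == 3))
  expect_true(all(docs$n_annotators[age_months > 6] == 2))
  # annotations only come from covering annotators
  ann_cov <- dplyr::anti_join(ch$corpus$annotations, cov,
                              by = c("doc_id", "annotator_id"))
  expect_equal(nrow(ann_cov), 0)
})
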