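test_that("binarization follows the published answer-category mapping", {
  expect_identical(binarize_answer(22, 2), "positive") # "a little" worry
  expect_identical(binarize_answer(9, 1), "negative")  # "not at all" pain
  expect_identical(binarize_answer(9, 4), "positive")
  # 7-level global items: best health is negative, at/below midpoint positive
  expect_identical(binarize_answer(29, 7), "negative")
  expect_identical(binarize_answer(29, 4), "positive")
  expect_identical(binarize_answer(30, 5), "negative")
  # configurable threshold
  expect_identical(binarize_answer(29, 5, seven_level_threshold = 5), "positive")
  expect_error(binarize_answer(9, 5), "out of range")
  expect_error(binarize_answer(29, 8), "out of range")
})

test_that("user_prediction takes the majority with ties breaking positive", {
  expect_identical(user_prediction(c("positive", "positive", "negative")), "positive")
  expect_identical(user_prediction(c("positive", "negative")), "positive")
  expect_identical(user_prediction(c("positive", "negative"), tie = "negative"),
                   "negative")
  expect_identical(user_prediction(rep("negative", 3)), "negative")
  expect_identical(user_prediction(character(0)), NA_character_)
})

test_that("comparisons classify the four confusion outcomes as documented", {
  ann <- dplyr::bind_rows(
    ann_row("d1", "A1", 9, 0, 4),                        # u1 says pain, survey q9=3 -> TP
    ann_row("d3", "A1", 22, 0, 16),                      # u2 says worry, survey q22=1 -> FP
    ann_row("d2", "A1", 13, 0, 7, polarity = "negative") # u1 denies appetite loss, q13=1 -> TN
  )
  corp <- fixture_corpus(annotations = ann)
  cmp <- build_comparisons(corp, "annotation")
  expect_equal(nrow(cmp), 3)
  expect_identical(cmp$outcome[cmp$qid == 9], "tp")
  expect_identical(cmp$outcome[cmp$qid == 22], "fp")
  expect_identical(cmp$outcome[cmp$qid == 13], "tn")
  # negative claim against a positive survey answer -> FN
  fn_ann <- ann_row("d1", "A1", 9, 0, 4, polarity = "negative")
  cmp_fn <- build_comparisons(fixture_corpus(annotations = fn_ann), "annotation")
  expect_identical(cmp_fn$outcome, "fn")
})

test_that("user level aggregates polarities per user-question before comparing", {
  ann <- dplyr::bind_rows(
    ann_row("d1", "A1", 9, 0, 4),
    ann_row("d1", "A2", 9, 0, 4),
    ann_row("d2", "A1", 9, 3, 7, polarity = "negative")
  )
  corp <- fixture_corpus(annotations = ann)
  cmp <- build_comparisons(corp, "user")
  expect_equal(nrow(cmp), 1) # one (user, question) pair
  expect_identical(cmp$predicted, "positive") # 2 pos vs 1 neg
  expect_identical(cmp$outcome, "tp")
  expect_equal(cmp$n_source_annotations, 3L)
})

test_that("annotations of users without surveys error, or are skipped leniently", {
  docs <- tibble::tibble(doc_id = "d9", user_id = "nosurvey",
                         timestamp = as.Date("2024-05-01"),
                         doc_type = "post", text = "pain was bad")
  corp <- qol_corpus(docs, ann_row("d9", "A1", 9, 0, 4))
  expect_error(build_comparisons(corp, "annotation"), "nosurvey")
  expect_warning(cmp <- build_comparisons(corp, "annotation", strict = FALSE),
                 "Skipping")
  expect_equal(nrow(cmp), 0)
})

test_that("confusion pooling conserves totals across all partitions", {
  # 1 TP on q9 + 1 FN on q19 pool into the Pain fine group
  ann <- dplyr::bind_rows(
    ann_row("d1", "A1", 9, 0, 4),
    ann_row("d2", "A1", 19, 3, 7, polarity = "negative")
  )
  surv <- dplyr::bind_rows(survey_row("u1", q9 = 3, q19 = 2), survey_row("u2"))
  docs <- fixture_corpus()$documents
  corp <- qol_corpus(docs, ann, surveys = surv)
  cmp <- build_comparisons(corp, "annotation")
  fine <- confusion(cmp, "fine")
  expect_equal(fine$tp[fine$key == "Pain"], 1)
  expect_equal(fine$fn[fine$key == "Pain"], 1)
  coarse <- confusion(cmp, "coarse")
  expect_equal(coarse$tp[coarse$key == "SYMPTOMATIC"], 1)
  expect_equal(coarse$fn[coarse$key == "SYMPTOMATIC"], 1)
  # conservation on a generated corpus
  ch <- generate_cohort(sim_config(n_users = 30, seed = 11))
  w <- filter_window(quiet_exclude(ch$corpus), 24)
  gcmp <- build_comparisons(w, "annotation")
  tot <- function(df) colSums(df[, c("tp", "fp", "tn", "fn")])
  overall <- tot(confusion(gcmp, "overall"))
  expect_equal(tot(confusion(gcmp, "question")), overall)
  expect_equal(tot(confusion(gcmp, "fine")), overall)
  expect_equal(tot(confusion(gcmp, "coarse")), overall)
  expect_equal(sum(overall), nrow(gcmp))
  expect_equal(nrow(confusion(gcmp[0, ], "fine")), 0)
})

test_that("metrics reproduce the printed formulas on hand cases", {
  m <- metrics(tibble::tibble(tp = 3, fp = 1, tn = 4, fn = 2))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6))
  perfect <- metrics(tibble::tibble(tp = 1, fp = 0, tn = 5, fn = 0))
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))
  zero <- metrics(tibble::tibble(tp = 0, fp = 2, tn = 0, fn = 1))
  expect_equal(zero$f1, 0)
  undef <- metrics(tibble::tibble(tp = 0, fp = 0, tn = 3, fn = 0))
  expect_true(is.na(undef$precision) && is.na(undef$recall) && is.na(undef$f1))
})

test_that("metrics match brute-force recomputation on random confusion sets", {
  withr::local_seed(77)
  for (i in 1:500) {
    outcomes <- sample(c("tp", "fp", "tn", "fn"), sample(1:40, 1),
                       replace = TRUE, prob = runif(4))
    o <- oracle_metrics(outcomes)
    m <- metrics(tibble::tibble(tp = o$tp, fp = o$fp, tn = o$tn, fn = o$fn))
    expect_equal(m$precision, o$precision)
    expect_equal(m$recall, o$recall)
    expect_equal(m$f1, o$f1)
  }
})

test_that("flipping every predicted label swaps tp<->fp and tn<->fn", {
  ch <- generate_cohort(sim_config(n_users = 20, seed = 5))
  w <- filter_window(quiet_exclude(ch$corpus), 24)
  cmp <- build_comparisons(w, "annotation")
  flipped <- cmp
  flipped$predicted <- ifelse(cmp$predicted == "positive", "negative", "positive")
  flipped$outcome <- qolforum:::classify_outcome(flipped$predicted, flipped$actual)
  a <- confusion(cmp, "overall")
  b <- confusion(flipped, "overall")
  expect_equal(b$tp, a$fn)
  expect_equal(b$fn, a$tp)
  expect_equal(b$fp, a$tn)
  expect_equal(b$tn, a$fp)
})

test_that("per-user accuracy and coverage summaries follow their definitions", {
  cmp <- tibble::tibble(
    user_id = c("u1", "u1", "u1", "u2"),
    qid = c(9L, 22L, 13L, 9L),
    predicted = "positive", actual = "positive",
    outcome = c("tp", "tn", "fp", "tp"),
    level = "user", n_source_annotations = 1L
  )
  ua <- user_accuracy(cmp)
  expect_equal(ua$accuracy[ua$user_id == "u1"], 2 / 3)
  expect_equal(ua$accuracy[ua$user_id == "u2"], 1)
  s <- user_accuracy_summary(cmp)
  expect_equal(s$mean_accuracy, mean(c(2 / 3, 1)))
  expect_equal(s$sd_accuracy, sd(c(2 / 3, 1)))
  # single user all TP: mean 1, sd 0 over one user is NA-free sample sd
  s1 <- user_accuracy_summary(cmp[cmp$user_id == "u2", ])
  expect_equal(s1$mean_accuracy, 1)
  # coverage: distinct questions per user / 53
  ann <- dplyr::bind_rows(
    ann_row("d1", "A1", 9, 0, 4),
    ann_row("d1", "A2", 9, 5, 8),   # same question twice: counted once
    ann_row("d2", "A1", 13, 0, 7)
  )
  corp <- fixture_corpus(annotations = ann)
  qc <- question_coverage(corp)
  expect_equal(nrow(qc), 1) # u2 has no annotations -> excluded
  expect_equal(qc$coverage, 2 / 53)
})
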