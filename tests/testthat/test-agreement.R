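test_that("fleiss_kappa reproduces the hand-computed worked example", {
  # 4 items, 3 raters, counts (labeled, unlabeled): direct evaluation of
  # the definitional formula gives kappa = 1/3
  m <- rbind(c(3, 0), c(2, 1), c(0, 3), c(1, 2))
  expect_equal(as.numeric(fleiss_kappa(m)), 1 / 3, tolerance = 1e-12)
})

test_that("unanimous ratings across mixed categories give kappa exactly 1", {
  m <- rbind(c(3, 0), c(0, 3), c(3, 0))
  k <- fleiss_kappa(m)
  expect_identical(as.numeric(k), 1)
  expect_false(attr(k, "degenerate"))
  # single-category degenerate case: perfect observed agreement, flagged
  k2 <- fleiss_kappa(rbind(c(0, 3), c(0, 3)))
  expect_identical(as.numeric(k2), 1)
  expect_true(attr(k2, "degenerate"))
})

test_that("fleiss_kappa matches the brute-force oracle on random matrices", {
  withr::local_seed(421)
  for (i in 1:200) {
    m <- random_rating_matrix()
    expect_equal(as.numeric(fleiss_kappa(m)), oracle_fleiss(m),
                 tolerance = 1e-10)
  }
})

test_that("kappa is invariant under swapping the category columns", {
  withr::local_seed(52)
  for (i in 1:25) {
    m <- random_rating_matrix()
    expect_equal(as.numeric(fleiss_kappa(m)),
                 as.numeric(fleiss_kappa(m[, 2:1, drop = FALSE])),
                 tolerance = 1e-12)
  }
})

test_that("independent uniform raters give kappa near zero", {
  withr::local_seed(99)
  k <- rbinom(20000, 3, 0.5)
  m <- cbind(k, 3 - k)
  expect_lt(abs(as.numeric(fleiss_kappa(m))), 0.02)
})

test_that("appending unanimous unlabeled items changes kappa as the oracle says", {
  withr::local_seed(7)
  m <- random_rating_matrix()
  n <- sum(m[1, ])
  m2 <- rbind(m, c(0, n))
  expect_equal(as.numeric(fleiss_kappa(m2)), oracle_fleiss(m2), tolerance = 1e-12)
})

test_that("fleiss_kappa validates its input", {
  expect_error(fleiss_kappa(rbind(c(1, 0), c(0, 1))), "2 raters")
  expect_error(fleiss_kappa(rbind(c(2, 1), c(1, 1))), "same number of raters")
})

test_that("word-level unitization credits any character overlap", {
  # rater A spans chars [0,4) of "pain was bad", rater B spans [0,8):
  # token "pain" rated by both, token "was" by B only, "bad" by neither
  ann <- dplyr::bind_rows(
    ann_row("d1", "A1", 9, 0, 4),
    ann_row("d1", "A2", 9, 0, 8)
  )
  corp <- fixture_corpus(annotations = ann)
  m <- unitize(corp, 9, c("A1", "A2"), "word")
  d1 <- m[m$doc_id == "d1", ]
  expect_identical(d1$n_labeled, c(2L, 1L, 0L))
  # partial overlap: a span covering only part of a token still marks it
  ann2 <- ann_row("d1", "A1", 9, 2, 4) # "in" inside "pain"
  m2 <- unitize(fixture_corpus(annotations = ann2), 9, c("A1", "A2"), "word")
  expect_identical(m2$n_labeled[m2$doc_id == "d1"], c(1L, 0L, 0L))
})

test_that("doc-level unitization marks presence of any span and rows sum to the panel size", {
  ann <- dplyr::bind_rows(
    ann_row("d1", "A1", 9, 0, 4),
    ann_row("d1", "A2", 9, 5, 8),
    ann_row("d2", "A1", 9, 3, 7)
  )
  corp <- fixture_corpus(annotations = ann)
  m <- unitize(corp, 9, c("A1", "A2"), "doc")
  expect_identical(m$n_labeled[match(c("d1", "d2", "d3"), m$doc_id)],
                   c(2L, 1L, 0L))
  expect_true(all(m$n_labeled + m$n_unlabeled == 2))
  # polarity and exact-match are ignored for agreement
  ann_neg <- ann
  ann_neg$polarity <- "negative"
  ann_neg$exact_match <- TRUE
  m2 <- unitize(fixture_corpus(annotations = ann_neg), 9, c("A1", "A2"), "doc")
  expect_identical(m2$n_labeled, m$n_labeled)
})

test_that("word-level and doc-level kappa coincide on single-token documents", {
  docs <- tibble::tibble(
    doc_id = c("s1", "s2", "s3", "s4"),
    user_id = "u1",
    timestamp = as.Date("2024-05-01"),
    doc_type = "post",
    text = c("pain", "tired", "worry", "nausea")
  )
  ann <- dplyr::bind_rows(
    ann_row("s1", "A1", 9, 0, 4), ann_row("s1", "A2", 9, 0, 4),
    ann_row("s2", "A1", 9, 0, 5),
    ann_row("s4", "A2", 9, 0, 6)
  )
  corp <- qol_corpus(docs, ann, surveys = survey_row("u1"))
  kw <- fleiss_kappa(unitize(corp, 9, c("A1", "A2"), "word"))
  kd <- fleiss_kappa(unitize(corp, 9, c("A1", "A2"), "doc"))
  expect_equal(as.numeric(kw), as.numeric(kd), tolerance = 1e-12)
})

test_that("documents not covered by the full panel are excluded with a warning", {
  ann <- ann_row("d1", "A1", 9, 0, 4)
  cov <- tibble::tibble(
    doc_id = c("d1", "d1", "d2", "d2", "d3"),
    annotator_id = c("A1", "A2", "A1", "A2", "A1")
  )
  corp <- fixture_corpus(annotations = ann, coverage = cov)
  expect_warning(m <- unitize(corp, 9, c("A1", "A2"), "doc"), "not covered")
  expect_setequal(m$doc_id, c("d1", "d2"))
  expect_error(unitize(corp, 9, "A1", "doc"), "at least 2")
})

test_that("agreement_table matches the unitize + fleiss_kappa route", {
  ch <- generate_cohort(sim_config(n_users = 25, seed = 31))
  view <- quiet_exclude(ch$corpus)
  w6 <- filter_window(view, 6)
  panel <- c("A1", "A2", "A3")
  for (unit in c("word", "doc")) {
    tab <- quiet_agreement(w6, qids = 1:53, unit = unit, panel = panel)
    some <- tab$qid[!is.na(tab$kappa) & tab$n_labeled_docs > 0]
    for (q in utils::head(some, 4)) {
      m <- suppressWarnings(unitize(w6, q, panel, unit))
      expect_equal(tab$kappa[tab$qid == q], as.numeric(fleiss_kappa(m)),
                   tolerance = 1e-12)
    }
  }
})

test_that("agreement_table handles cloned, contrarian and absent annotators", {
  base <- dplyr::bind_rows(
    ann_row("d1", "A1", 9, 0, 4),
    ann_row("d2", "A1", 9, 3, 7)
  )
  clone <- base
  clone$annotator_id <- "A2"
  corp <- fixture_corpus(annotations = dplyr::bind_rows(base, clone))
  tab <- quiet_agreement(corp, qids = 9, unit = "word", panel = c("A1", "A2"))
  expect_equal(tab$kappa, 1)
  expect_equal(tab$n_labeled_docs, 2L)
  # raters disagreeing on every labeled doc: kappa <= 0
  anti <- dplyr::bind_rows(ann_row("d1", "A1", 9, 0, 4),
                           ann_row("d2", "A2", 9, 3, 7))
  tab2 <- quiet_agreement(fixture_corpus(annotations = anti), qids = 9,
                          unit = "doc", panel = c("A1", "A2"))
  expect_lte(tab2$kappa, 0)
  # a question never labeled: degenerate kappa 1 with zero labeled docs
  tab3 <- quiet_agreement(fixture_corpus(annotations = base), qids = 22,
                          unit = "doc", panel = c("A1", "A2"))
  expect_equal(tab3$kappa, 1)
  expect_true(tab3$degenerate)
  expect_equal(tab3$n_labeled_docs, 0L)
})
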