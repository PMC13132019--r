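#' Configuration of the synthetic cohort generator
#'
#' Bundles and validates every parameter of the generator. The defaults
#' emulate the observational structure the analysis assumes for a breast
#' cancer forum cohort: ~123 posting users (plus survey-only users),
#' a long-tailed posts-per-user distribution (log-uniform within activity
#' bins), a per-question mention-rate profile concentrated on a handful of
#' questions (one dominant fallback label, a few frequent symptom labels,
#' a thin tail, three questions never mentioned), a 3-annotator panel for
#' the most recent 6 months and a 2-annotator panel for older documents,
#' and a small rate of past-referenced and other-subject posts.
#'
#' The two parameters that drive the concordance analysis are
#' `consistency` (probability that what a user writes about an issue agrees
#' with their latent state) and `survey_noise` (probability that their
#' survey answer contradicts the latent state). With no annotator polarity
#' noise, annotation-level accuracy has the closed form given by
#' [expected_accuracy()].
#'
#' @param n_users Number of posting users.
#' @param n_silent_users Additional enrolled users with a survey but no
#'   posts.
#' @param period_months Length of the simulated posting period before the
#'   survey; all documents (and both annotator panels) fall in it.
#' @param recent_months Length of the most recent stratum, covered by
#'   `panel_recent`; older documents are covered by `panel_older`.
#' @param survey_anchor Date every user completed the survey
#'   (`survey_jitter_days` spreads completion dates uniformly up to that
#'   many days earlier).
#' @param survey_jitter_days See `survey_anchor`.
#' @param posts_bins Tibble `lo`, `hi`, `weight`: per-user document counts
#'   are drawn by picking a bin with probability proportional to `weight`,
#'   then log-uniformly within `[lo, hi]`.
#' @param p_post Probability a document is an initial post (vs a comment).
#' @param prevalence Length-53 vector: probability a user's latent state has
#'   issue q present.
#' @param mention_prob Length-53 vector: per-document probability that a
#'   present issue q is mentioned.
#' @param consistency Probability a mention's polarity matches the latent
#'   state.
#' @param survey_noise Probability a survey answer contradicts the latent
#'   state.
#' @param annotators Tibble `annotator_id`, `span_recall`,
#'   `false_span_rate`, `polarity_flip_prob`, `boundary_jitter_tokens`.
#' @param panel_recent,panel_older Annotator ids covering the recent /
#'   older stratum.
#' @param past_ref_prob Probability a document is flagged as referring to
#'   past events.
#' @param other_subject_prob Probability a document is about someone other
#'   than the posting user.
#' @param seven_level_threshold Binarization threshold for the 7-level
#'   global items (answers `<=` threshold count as impaired).
#' @param demographics Generate pass-through demographic columns (age, age
#'   at diagnosis, years since diagnosis)?
#' @param seed Integer seed; all randomness in [generate_cohort()] flows
#'   from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_users = 123,
                       n_silent_users = 11,
                       period_months = 24,
                       recent_months = 6,
                       survey_anchor = as.Date("2024-06-01"),
                       survey_jitter_days = 0,
                       posts_bins = default_posts_bins(),
                       p_post = 0.05,
                       prevalence = rep(0.5, 53),
                       mention_prob = default_mention_prob(),
                       consistency = 0.85,
                       survey_noise = 0.05,
                       annotators = default_annotators(),
                       panel_recent = c("A1", "A2", "A3"),
                       panel_older = c("A1", "A2"),
                       past_ref_prob = 0.10,
                       other_subject_prob = 0.005,
                       seven_level_threshold = 4,
                       demographics = TRUE,
                       seed = 1L) {
  cfg <- list(
    n_users = as.integer(n_users), n_silent_users = as.integer(n_silent_users),
    period_months = as.integer(period_months),
    recent_months = as.integer(recent_months),
    survey_anchor = as.Date(survey_anchor),
    survey_jitter_days = as.integer(survey_jitter_days),
    posts_bins = as_tibble(posts_bins), p_post = p_post,
    prevalence = prevalence, mention_prob = mention_prob,
    consistency = consistency, survey_noise = survey_noise,
    annotators = as_tibble(annotators),
    panel_recent = panel_recent, panel_older = panel_older,
    past_ref_prob = past_ref_prob, other_subject_prob = other_subject_prob,
    seven_level_threshold = as.integer(seven_level_threshold),
    demographics = isTRUE(demographics), seed = as.integer(seed)
  )
  if (cfg$n_users < 1) stopf("`n_users` must be >= 1.")
  if (cfg$n_silent_users < 0) stopf("`n_silent_users` must be >= 0.")
  if (cfg$period_months < 1) stopf("`period_months` must be >= 1.")
  if (cfg$recent_months < 1 || cfg$recent_months > cfg$period_months) {
    stopf("`recent_months` must be in 1..period_months.")
  }
  if (length(cfg$prevalence) != 53) stopf("`prevalence` must have length 53.")
  if (length(cfg$mention_prob) != 53) stopf("`mention_prob` must have length 53.")
  check_prob(cfg$prevalence, "prevalence")
  check_prob(cfg$mention_prob, "mention_prob")
  check_prob(cfg$consistency, "consistency")
  check_prob(cfg$survey_noise, "survey_noise")
  check_prob(cfg$p_post, "p_post")
  check_prob(cfg$past_ref_prob, "past_ref_prob")
  check_prob(cfg$other_subject_prob, "other_subject_prob")
  ann <- cfg$annotators
  need <- c("annotator_id", "span_recall", "false_span_rate",
            "polarity_flip_prob", "boundary_jitter_tokens")
  if (!all(need %in% names(ann))) {
    stopf("`annotators` must have columns: %s.", paste(need, collapse = ", "))
  }
  check_prob(ann$span_recall, "annotators$span_recall")
  check_prob(ann$polarity_flip_prob, "annotators$polarity_flip_prob")
  if (any(ann$false_span_rate < 0)) stopf("`false_span_rate` must be >= 0.")
  if (!all(c(cfg$panel_recent, cfg$panel_older) %in% ann$annotator_id)) {
    stopf("Panels must be subsets of `annotators$annotator_id`.")
  }
  if (length(cfg$panel_recent) < 2 || length(cfg$panel_older) < 2) {
    stopf("Both panels need at least 2 annotators.")
  }
  if (!cfg$seven_level_threshold %in% 1:6) {
    stopf("`seven_level_threshold` must be in 1..6.")
  }
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_posts_bins <- function() {
  tibble(lo = c(1, 2, 9, 31, 91), hi = c(1, 8, 30, 90, 250),
         weight = c(6, 28, 63, 22, 4))
}

#' @rdname sim_config
#' @export
default_annotators <- function() {
  tibble(
    annotator_id = c("A1", "A2", "A3"),
    span_recall = c(0.90, 0.85, 0.80),
    false_span_rate = 0.01,
    polarity_flip_prob = 0.03,
    boundary_jitter_tokens = 1L
  )
}

#' @rdname sim_config
#' @export
default_mention_prob <- function() {
  mp <- rep(0.005, 53)
  # dominant fallback label + the frequent general-discomfort questions
  mp[36] <- 0.16  # feeling ill or unwell (fallback)
  mp[22] <- 0.07  # worry
  mp[9]  <- 0.065 # pain
  mp[21] <- 0.06  # tense
  mp[6]  <- 0.055 # limited in work / daily activities
  mp[18] <- 0.04  # tired
  mp[14] <- 0.04  # nauseated
  mp[43] <- 0.03  # worried about future health
  mp[13] <- 0.024 # lacked appetite
  mp[24] <- 0.024 # depressed
  # intimate topics essentially absent from public posts
  mp[c(35, 44, 46)] <- 0
  mp
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config>  %d posting users (+%d silent), %d-month period, ",
           "consistency %.2f, survey_noise %.2f, %d annotators, seed %d\n"),
    x$n_users, x$n_silent_users, x$period_months, x$consistency,
    x$survey_noise, nrow(x$annotators), x$seed))
  invisible(x)
}

#' Closed-form annotation-level accuracy of a noise configuration
#'
#' With no annotator polarity noise, an annotation-level comparison is
#' correct exactly when the mention polarity and the binarized survey
#' answer fall on the same side of the latent state: both faithful or both
#' flipped. Hence accuracy
#' \eqn{= c (1 - s) + (1 - c) s} for consistency \eqn{c} and survey noise
#' \eqn{s}, independent of prevalence and mention rates.
#'
#' @param config A [sim_config()] with all `polarity_flip_prob = 0`.
#' @return A single number in \[0, 1\].
#' @examples
#' cfg <- sim_config(consistency = 0.85, survey_noise = 0.1,
#'   annotators = dplyr::mutate(default_annotators(), polarity_flip_prob = 0))
#' expected_accuracy(cfg)
#' @export
expected_accuracy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(config$annotators$polarity_flip_prob > 0)) {
    stopf("expected_accuracy() requires annotator polarity_flip_prob = 0; the closed form does not cover annotator polarity noise.")
  }
  c_ <- config$consistency
  s <- config$survey_noise
  c_ * (1 - s) + (1 - c_) * s
}

topic_phrases <- function() {
  c("doing strenuous activities", "taking a long walk",
    "taking a short walk outside", "staying in bed during the day",
    "needing help with washing and dressing",
    "keeping up with my work and daily activities",
    "keeping up with my hobbies", "shortness of breath", "pain",
    "needing to rest", "trouble sleeping", "feeling weak",
    "lack of appetite", "nausea", "vomiting", "constipation", "diarrhea",
    "tiredness", "pain getting in the way of my day",
    "concentrating on reading or television", "feeling tense", "worrying",
    "feeling irritable", "feeling depressed", "remembering things",
    "strain on my family life", "missing out on social activities",
    "money trouble from the treatment", "my overall health being poor",
    "my overall quality of life being low", "a dry mouth",
    "food tasting strange", "sore watery eyes", "losing my hair",
    "being upset about my hair loss", "feeling ill and unwell",
    "hot flushes", "headaches", "feeling less attractive",
    "feeling less feminine", "looking at myself in the mirror",
    "being unhappy with my body", "worry about my health down the road",
    "my interest in sex", "being sexually active", "enjoying intimacy",
    "pain in my arm and shoulder", "a swollen arm and hand",
    "raising my arm sideways", "pain around my affected breast",
    "swelling around my breast", "my breast area being oversensitive",
    "dry flaky skin around my breast")
}

filler_sentences <- function() {
  c("Hope everyone here is doing well today.",
    "Thanks so much for all the kind support in this group.",
    "My next appointment with the care team is coming up soon.",
    "Sending warm hugs to everyone reading this.",
    "The weather around here has been lovely this week.",
    "I finally got around to tidying up the garden.",
    "My family came over to visit during the weekend.",
    "Just checking in with this wonderful community again.",
    "Wishing all of you a calm and restful week ahead.",
    "It has been a busy stretch at home with the grandkids.")
}

mention_sentence <- function(qid, polarity, variant) {
  topic <- topic_phrases()[qid]
  pos <- c("I have been dealing with %s a lot lately.",
           "Lately %s has really been a problem for me.")
  neg <- c("I have had no trouble with %s at all recently.",
           "Thankfully %s has not been an issue for me lately.")
  tpl <- ifelse(polarity == "positive", pos[variant], neg[variant])
  sprintf(tpl, topic)
}

#' Generate a synthetic annotated forum cohort
#'
#' Simulates the full data-generating process the pipeline assumes:
#'
#' 1. each user gets a static latent binary QoL state over the 53 questions
#'    (Bernoulli `prevalence`);
#' 2. per-user document counts come from the long-tailed `posts_bins`
#'    distribution, timestamps uniform over the `period_months` before the
#'    user's survey date;
#' 3. each document mentions each *present* issue with probability
#'    `mention_prob[q]`; a mention's polarity agrees with the latent state
#'    with probability `consistency`. Documents are built from template
#'    sentences (fillers plus one sentence per mention), so every mention
#'    has exact character offsets;
#' 4. each panel annotator detects a mention with probability
#'    `span_recall`, flips its polarity with `polarity_flip_prob`, jitters
#'    the span boundaries by up to `boundary_jitter_tokens` tokens, and
#'    adds spurious spans at `false_span_rate` per document;
#' 5. survey answers are drawn from the latent state with contradiction
#'    probability `survey_noise` (present issues answer 2--4 on 4-level
#'    items, 1 when contradicting; 7-level items use
#'    `seven_level_threshold`);
#' 6. past-reference and other-subject flags are drawn independently per
#'    document.
#'
#' The run is fully deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `corpus` (a [qol_corpus()] including a
#'   coverage table) and `truth` (list of `latent` -- tibble `user_id`,
#'   `qid`, `present` -- and `mentions` -- the oracle spans with their
#'   polarity).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n_all <- cfg$n_users + cfg$n_silent_users
  users <- tibble(
    user_id = sprintf("U%03d", seq_len(n_all)),
    posting = seq_len(n_all) <= cfg$n_users,
    survey_date = cfg$survey_anchor -
      if (cfg$survey_jitter_days > 0)
        sample(0:cfg$survey_jitter_days, n_all, replace = TRUE) else 0L
  )

  # 1. latent states
  latent <- matrix(rbinom(n_all * 53, 1, rep(cfg$prevalence, each = n_all)) == 1,
                   nrow = n_all, ncol = 53)

  # 2. documents
  bins <- cfg$posts_bins
  bi <- sample(nrow(bins), cfg$n_users, replace = TRUE,
               prob = bins$weight / sum(bins$weight))
  n_docs_user <- pmin(pmax(round(exp(runif(
    cfg$n_users, log(bins$lo[bi]), log(bins$hi[bi])))), bins$lo[bi]), bins$hi[bi])
  period_days <- as.integer(users$survey_date[seq_len(cfg$n_users)] -
                              add_months(users$survey_date[seq_len(cfg$n_users)],
                                         -cfg$period_months))
  docs <- tibble(
    user_idx = rep(seq_len(cfg$n_users), n_docs_user),
    user_id = rep(users$user_id[seq_len(cfg$n_users)], n_docs_user),
    survey_date = rep(users$survey_date[seq_len(cfg$n_users)], n_docs_user)
  )
  n_docs <- nrow(docs)
  offset <- floor(runif(n_docs, 0, rep(period_days, n_docs_user)))
  docs <- docs |>
    mutate(
      doc_id = sprintf("D%06d", seq_len(n_docs)),
      timestamp = .data$survey_date - offset,
      doc_type = ifelse(runif(n_docs) < cfg$p_post, "post", "comment")
    )

  # 3. true mentions (only present issues are discussed)
  mention_rows <- vector("list", 53)
  for (q in seq_len(53)) {
    if (cfg$mention_prob[q] <= 0) next
    present <- latent[docs$user_idx, q]
    hit <- which(present & runif(n_docs) < cfg$mention_prob[q])
    if (length(hit)) mention_rows[[q]] <- tibble(doc_row = hit, qid = q)
  }
  mentions <- bind_rows(mention_rows)
  if (nrow(mentions) == 0) {
    mentions <- tibble(doc_row = integer(), qid = integer(),
                       polarity = character(), sentence = character())
  } else {
    mentions <- mentions |>
      arrange(.data$doc_row, .data$qid) |>
      mutate(
        polarity = ifelse(runif(n()) < cfg$consistency, "positive", "negative"),
        sentence = mention_sentence(.data$qid, .data$polarity,
                                    sample(1:2, n(), replace = TRUE))
      )
  }

  # assemble document texts; record code-point offsets of each mention
  fillers <- filler_sentences()
  n_fill <- 1L + rnbinom(n_docs, size = 2, mu = 6)
  mention_by_doc <- split(seq_len(nrow(mentions)), mentions$doc_row)
  texts <- character(n_docs)
  span_list <- vector("list", n_docs)
  for (i in seq_len(n_docs)) {
    midx <- mention_by_doc[[as.character(i)]]
    sents <- c(sample(fillers, n_fill[i], replace = TRUE),
               if (length(midx)) mentions$sentence[midx])
    kind <- c(rep(0L, n_fill[i]), if (length(midx)) midx)
    ord <- sample(length(sents))
    sents <- sents[ord]
    kind <- kind[ord]
    lens <- stringr::str_length(sents)
    starts <- cumsum(c(0L, lens[-length(lens)] + 1L)) # +1 for joining space
    texts[i] <- paste(sents, collapse = " ")
    if (any(kind > 0)) {
      w <- which(kind > 0)
      span_list[[i]] <- tibble(mention_row = kind[w],
                               start = starts[w], end = starts[w] + lens[w])
    }
  }
  spans <- bind_rows(span_list)
  if (nrow(spans)) {
    spans <- spans[order(spans$mention_row), ]
    mentions$start <- NA_integer_
    mentions$end <- NA_integer_
    mentions$start[spans$mention_row] <- as.integer(spans$start)
    mentions$end[spans$mention_row] <- as.integer(spans$end)
  }
  docs$text <- texts

  # 4. annotator panels, spans, false spans
  age_months <- as.numeric(docs$survey_date - docs$timestamp) / 30.4375
  recent <- age_months <= cfg$recent_months
  panel_of <- lapply(recent, function(r) if (r) cfg$panel_recent else cfg$panel_older)
  coverage <- tibble(
    doc_id = rep(docs$doc_id, lengths(panel_of)),
    annotator_id = unlist(panel_of)
  )
  tok_cache <- lapply(texts, function(t) stringr::str_locate_all(t, "\\S+")[[1]])

  ann_out <- vector("list", nrow(cfg$annotators))
  for (a in seq_len(nrow(cfg$annotators))) {
    aid <- cfg$annotators$annotator_id[a]
    rec <- cfg$annotators$span_recall[a]
    flip <- cfg$annotators$polarity_flip_prob[a]
    jit <- cfg$annotators$boundary_jitter_tokens[a]
    fsr <- cfg$annotators$false_span_rate[a]
    covered_docs <- which(vapply(panel_of, function(p) aid %in% p, logical(1)))
    # true-mention detections
    if (nrow(mentions)) {
      mi <- which(mentions$doc_row %in% covered_docs & runif(nrow(mentions)) < rec)
    } else mi <- integer(0)
    det <- NULL
    if (length(mi)) {
      det <- mentions[mi, c("doc_row", "qid", "start", "end", "polarity")]
      do_flip <- runif(nrow(det)) < flip
      det$polarity[do_flip] <- ifelse(det$polarity[do_flip] == "positive",
                                      "negative", "positive")
      if (jit > 0) {
        j1 <- sample(0:jit, nrow(det), replace = TRUE)
        j2 <- sample(0:jit, nrow(det), replace = TRUE)
        for (k in which(j1 + j2 > 0)) {
          tok <- tok_cache[[det$doc_row[k]]]
          first <- which(tok[, 2] >= det$start[k] + 1)[1]
          last <- max(which(tok[, 1] <= det$end[k]))
          first <- max(1L, first - j1[k])
          last <- min(nrow(tok), last + j2[k])
          det$start[k] <- tok[first, 1] - 1L
          det$end[k] <- tok[last, 2]
        }
      }
      det$exact_match <- runif(nrow(det)) < 0.5
    }
    # spurious spans on random token ranges
    n_false <- rpois(length(covered_docs), fsr)
    fs <- NULL
    if (sum(n_false) > 0) {
      fd <- rep(covered_docs, n_false)
      fs <- purrr::map_dfr(fd, function(dr) {
        tok <- tok_cache[[dr]]
        i0 <- sample(nrow(tok), 1)
        i1 <- min(nrow(tok), i0 + sample(1:4, 1) - 1L)
        tibble(doc_row = dr, qid = sample(53L, 1),
               start = tok[i0, 1] - 1L, end = tok[i1, 2],
               polarity = sample(c("positive", "negative"), 1),
               exact_match = FALSE)
      })
    }
    both <- bind_rows(det, fs)
    if (!is.null(both) && nrow(both)) {
      both$annotator_id <- aid
      ann_out[[a]] <- both
    }
  }
  annotations <- bind_rows(ann_out)
  if (nrow(annotations)) {
    annotations <- annotations |>
      mutate(doc_id = docs$doc_id[.data$doc_row],
             start = as.integer(.data$start), end = as.integer(.data$end),
             qid = as.integer(.data$qid)) |>
      select("doc_id", "annotator_id", "qid", "start", "end", "polarity",
             "exact_match") |>
      arrange(.data$doc_id, .data$annotator_id, .data$start, .data$qid)
  } else {
    annotations <- NULL
  }

  # 5. surveys
  thr <- cfg$seven_level_threshold
  answers <- matrix(NA_integer_, nrow = n_all, ncol = 53)
  for (q in seq_len(53)) {
    present <- latent[, q]
    contradict <- runif(n_all) < cfg$survey_noise
    if (q %in% c(29L, 30L)) {
      lo <- resample(seq_len(thr), n_all)       # impaired side
      hi <- resample((thr + 1):7, n_all)        # healthy side
      answers[, q] <- ifelse(xor(present, contradict), lo, hi)
    } else {
      pos <- resample(2:4, n_all)
      answers[, q] <- ifelse(xor(present, contradict), pos, 1L)
    }
  }
  surveys <- tibble(user_id = users$user_id, survey_date = users$survey_date)
  for (q in seq_len(53)) surveys[[paste0("q", q)]] <- answers[, q]
  if (cfg$demographics) {
    age <- pmin(pmax(round(rnorm(n_all, 68.2, 11.5)), 30), 95)
    since <- pmin(pmax(round(rnorm(n_all, 13.1, 9.4)), 0), age - 25)
    surveys$age <- as.integer(age)
    surveys$years_since_diagnosis <- as.integer(since)
    surveys$age_at_diagnosis <- as.integer(age - since)
  }

  # 6. document flags
  flags <- tibble(
    doc_id = docs$doc_id,
    refers_to_past = runif(n_docs) < cfg$past_ref_prob,
    subject_is_self = runif(n_docs) >= cfg$other_subject_prob
  )

  corpus <- qol_corpus(
    documents = select(docs, "doc_id", "user_id", "timestamp", "doc_type", "text"),
    annotations = annotations,
    flags = flags,
    surveys = surveys,
    coverage = coverage
  )
  latent_tb <- tibble(
    user_id = rep(users$user_id, 53),
    qid = rep(seq_len(53), each = n_all),
    present = as.vector(latent)
  )
  truth_mentions <- if (nrow(mentions)) {
    mentions |>
      mutate(doc_id = docs$doc_id[.data$doc_row],
             latent = "positive") |>
      select("doc_id", "qid", "start", "end", "polarity", "latent")
  } else {
    tibble(doc_id = character(), qid = integer(), start = integer(),
           end = integer(), polarity = character(), latent = character())
  }
  list(corpus = corpus, truth = list(latent = latent_tb, mentions = truth_mentions))
}

#' Descriptive summary of a cohort
#'
#' Reports the descriptive statistics used to characterise a forum corpus:
#' posts-per-user activity bins (1, 2--10, 11--100, 101--1000, >1000), the
#' fraction of documents carrying at least one QoL label, document length
#' in characters, and per-question label frequencies.
#'
#' @param corpus A [qol_corpus()].
#' @return A list with tibbles `posts_per_user`, `post_length`,
#'   `label_frequency` and the scalar `labeled_fraction`.
#' @export
summarize_cohort <- function(corpus) {
  per_user <- count(corpus$documents, .data$user_id)
  cuts <- cut(per_user$n, breaks = c(0, 1, 10, 100, 1000, Inf),
              labels = c("1", "2-10", "11-100", "101-1000", ">1000"))
  bins <- tibble(bin = factor(c("1", "2-10", "11-100", "101-1000", ">1000"),
                              levels = levels(cuts))) |>
    left_join(count(tibble(bin = cuts), .data$bin, name = "n_users"), by = "bin") |>
    mutate(n_users = dplyr::coalesce(.data$n_users, 0L))
  labeled_ids <- unique(corpus$annotations$doc_id)
  lens <- stringr::str_length(corpus$documents$text)
  list(
    posts_per_user = bins,
    post_length = tibble(mean_chars = mean(lens), sd_chars = sd(lens)),
    labeled_fraction = if (nrow(corpus$documents)) {
      mean(corpus$documents$doc_id %in% labeled_ids)
    } else NA_real_,
    label_frequency = corpus$annotations |>
      distinct(.data$doc_id, .data$qid) |>
      count(.data$qid, name = "n_docs") |>
      arrange(dplyr::desc(.data$n_docs), .data$qid)
  )
}
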