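#' The EORTC QLQ-C30 / QLQ-BR23 question catalog
#'
#' Static metadata for the 53 questionnaire items the pipeline works with:
#' items 1--30 come from the EORTC QLQ-C30 core questionnaire and items
#' 31--53 from the breast-cancer module QLQ-BR23. Items 29 and 30 (global
#' health / overall quality of life) use a 7-point response scale; all other
#' items use a 4-point scale ("not at all" ... "very much").
#'
#' Each question belongs to exactly one *fine* group (the 23 scales and
#' single-item measures of the EORTC scoring manual) and one *coarse* group:
#' `FUNCTIONAL` (items 1--7, 20--27, 39--46), `SYMPTOMATIC` (items 8--19, 28,
#' 31--38, 47--53) or `GLOBAL` (items 29, 30).
#'
#' The same table is shipped as a plain-text resource at
#' `system.file("extdata", "eortc_catalog.csv", package = "qolforum")`.
#'
#' @return A tibble with one row per question and columns `qid`, `text`,
#'   `instrument` (`"C30"`/`"BR23"`), `n_levels`, `fine_group`,
#'   `coarse_group`.
#' @examples
#' eortc_catalog()
#' @export
eortc_catalog <- function() {
  .catalog
}

catalog_build <- function() {
  txt <- c(
    "Do you have any trouble doing strenuous activities, like carrying a heavy shopping bag or a suitcase?",
    "Do you have any trouble taking a long walk?",
    "Do you have any trouble taking a short walk outside of the house?",
    "Do you need to stay in bed or a chair during the day?",
    "Do you need help with eating, dressing, washing yourself or using the toilet?",
    "Were you limited in doing either your work or other daily activities?",
    "Were you limited in pursuing your hobbies or other leisure time activities?",
    "Were you short of breath?",
    "Have you had pain?",
    "Did you need to rest?",
    "Have you had trouble sleeping?",
    "Have you felt weak?",
    "Have you lacked appetite?",
    "Have you felt nauseated?",
    "Have you vomited?",
    "Have you been constipated?",
    "Have you had diarrhea?",
    "Were you tired?",
    "Did pain interfere with your daily activities?",
    "Have you had difficulty in concentrating on things, like reading a newspaper or watching television?",
    "Did you feel tense?",
    "Did you worry?",
    "Did you feel irritable?",
    "Did you feel depressed?",
    "Have you had difficulty remembering things?",
    "Has your physical condition or medical treatment interfered with your family life?",
    "Has your physical condition or medical treatment interfered with your social activities?",
    "Has your physical condition or medical treatment caused you financial difficulties?",
    "How would you rate your overall health during the past week?",
    "How would you rate your overall quality of life during the past week?",
    "Did you have a dry mouth?",
    "Did food and drink taste different than usual?",
    "Were your eyes painful, irritated or watery?",
    "Have you lost any hair?",
    "Were you upset by the loss of your hair?",
    "Did you feel ill or unwell?",
    "Did you have hot flushes?",
    "Did you have headaches?",
    "Have you felt physically less attractive as a result of your disease or treatment?",
    "Have you been feeling less feminine as a result of your disease or treatment?",
    "Did you find it difficult to look at yourself naked?",
    "Have you been dissatisfied with your body?",
    "Were you worried about your health in the future?",
    "To what extent were you interested in sex?",
    "To what extent were you sexually active? (with or without intercourse)",
    "To what extent was sex enjoyable for you?",
    "Did you have any pain in your arm or shoulder?",
    "Did you have a swollen arm or hand?",
    "Was it difficult to raise your arm or to move it sideways?",
    "Have you had any pain in the area of your affected breast?",
    "Was the area of your affected breast swollen?",
    "Was the area of your affected breast oversensitive?",
    "Have you had skin problems on or in the area of your affected breast (eg, itchy, dry, flaky)?"
  )
  fine <- character(53)
  fine[1:5] <- "Physical functioning"
  fine[6:7] <- "Role functioning"
  fine[8] <- "Dyspnea"
  fine[c(9, 19)] <- "Pain"
  fine[c(10, 12, 18)] <- "Fatigue"
  fine[11] <- "Insomnia"
  fine[13] <- "Appetite loss"
  fine[14:15] <- "Nausea and vomiting"
  fine[16] <- "Constipation"
  fine[17] <- "Diarrhea"
  fine[c(20, 25)] <- "Cognitive functioning"
  fine[21:24] <- "Emotional functioning"
  fine[26:27] <- "Social functioning"
  fine[28] <- "Financial difficulties"
  fine[29:30] <- "Global health"
  fine[c(31:34, 36:38)] <- "Systemic therapy side effects"
  fine[35] <- "Upset by hair loss"
  fine[39:42] <- "Body image"
  fine[43] <- "Future perspective"
  fine[44:45] <- "Sexual functioning"
  fine[46] <- "Sexual enjoyment"
  fine[47:49] <- "Arm symptoms"
  fine[50:53] <- "Breast symptoms"
  coarse <- character(53)
  coarse[c(1:7, 20:27, 39:46)] <- "FUNCTIONAL"
  coarse[c(8:19, 28, 31:38, 47:53)] <- "SYMPTOMATIC"
  coarse[29:30] <- "GLOBAL"
  tibble::tibble(
    qid = 1:53,
    text = txt,
    instrument = ifelse(1:53 <= 30, "C30", "BR23"),
    n_levels = ifelse(1:53 %in% c(29L, 30L), 7L, 4L),
    fine_group = fine,
    coarse_group = coarse
  )
}

.catalog <- catalog_build()

#' Look up one question by id
#'
#' @param qid Integer question id in 1..53.
#' @return A one-row tibble (see [eortc_catalog()] for columns).
#' @examples
#' get_question(9) # pain item, fine group "Pain"
#' @export
get_question <- function(qid) {
  if (length(qid) != 1 || is.na(qid) || qid != as.integer(qid) ||
      qid < 1 || qid > 53) {
    stopf("`qid` must be a single integer in 1..53, got %s.",
          paste(format(qid), collapse = ", "))
  }
  .catalog[.catalog$qid == as.integer(qid), ]
}

#' Question ids belonging to a fine or coarse group
#'
#' @param group_name Group name, e.g. `"Pain"` (fine) or `"FUNCTIONAL"`
#'   (coarse).
#' @param granularity `"fine"` (23 scoring-manual groups) or `"coarse"`
#'   (FUNCTIONAL / SYMPTOMATIC / GLOBAL).
#' @return Sorted integer vector of question ids.
#' @examples
#' group_members("Breast symptoms", "fine") # 50:53
#' group_members("GLOBAL", "coarse")        # 29:30
#' @export
group_members <- function(group_name, granularity = c("fine", "coarse")) {
  granularity <- match.arg(granularity)
  col <- if (granularity == "fine") .catalog$fine_group else .catalog$coarse_group
  if (!group_name %in% col) {
    stopf("Unknown %s group '%s'. Valid names: %s.", granularity, group_name,
          paste(sort(unique(col)), collapse = ", "))
  }
  sort(.catalog$qid[col == group_name])
}

#' EORTC scale definitions
#'
#' The scales of the QLQ-C30 and QLQ-BR23 as defined in the EORTC scoring
#' manual. Scales coincide with the catalog's fine groups. `kind` is
#' `"functional"`, `"symptom"` or `"global"`; `reversed` records the scoring
#' direction: reversed scales (all functional scales except the BR23 sexual
#' functioning and sexual enjoyment scales, whose items are worded so that a
#' higher answer means better functioning) apply
#' \eqn{S = (1 - (RS - 1)/\mathrm{range}) \times 100}, all others
#' \eqn{S = ((RS - 1)/\mathrm{range}) \times 100}, where RS is the mean of
#' the answered items.
#'
#' @return A tibble with columns `scale`, `kind`, `reversed`, `value_range`
#'   and list-column `item_qids`.
#' @examples
#' eortc_scales()
#' @export
eortc_scales <- function() {
  cat <- eortc_catalog()
  groups <- unique(cat$fine_group)
  kind <- vapply(groups, function(g) {
    co <- unique(cat$coarse_group[cat$fine_group == g])
    switch(co, FUNCTIONAL = "functional", SYMPTOMATIC = "symptom", GLOBAL = "global")
  }, character(1))
  unreversed_functional <- c("Sexual functioning", "Sexual enjoyment")
  tibble(
    scale = groups,
    kind = unname(kind),
    reversed = kind == "functional" & !groups %in% unreversed_functional,
    value_range = vapply(groups, function(g) {
      unique(cat$n_levels[cat$fine_group == g]) - 1L
    }, integer(1)),
    item_qids = lapply(groups, function(g) cat$qid[cat$fine_group == g])
  )
}
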