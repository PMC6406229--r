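#' Likert response scale used by all instruments
#'
#' Four ordered categories of self-reported word familiarity, from 1
#' ("I have never seen this word and do not know its meaning") to 4
#' ("I am sure I know the word's meaning").
#'
#' @return A named integer vector of length 4 (labels as names).
#' @export
likert_scale <- function() {
  stats::setNames(1:4, c(
    "I have never seen this word and do not know its meaning.",
    "I have seen this word but do not know its meaning.",
    "I think I know the word's meaning, but I am not sure.",
    "I am sure I know the word's meaning."
  ))
}

#' Assemble a complete test instantiation
#'
#' Per frequency tier, samples `words_per_tier` true words uniformly
#' without replacement, then generates `pseudos_per_tier` pseudowords from
#' distinct template words of the same tier (templates never coincide with
#' the selected true words, so no pseudoword sits next to its visible
#' source). With the default design of 10 tiers, 5 true words and 2
#' pseudowords per tier, an instrument holds 50 true words and 20
#' pseudowords (70 items).
#'
#' True-word item weights come from the vocabulary's logistic frequency
#' weights; each pseudoword is assigned the arithmetic mean of the
#' instrument's true-word weights, and the full weight vector is then
#' normalized to sum to 1. Presentation order is a seeded shuffle.
#'
#' @param partition A `tier_partition` whose `entries` carry `weight`
#'   columns (i.e. built from [compute_item_weights()] output).
#' @param chain A `segment_chain` for pseudoword generation.
#' @param lexicon Character vector of real words pseudowords must avoid
#'   (typically the full vocabulary, plus any external word list).
#' @param words_per_tier,pseudos_per_tier Design counts (defaults 5 and 2).
#' @param seed Integer seed; the same seed reproduces the instrument
#'   exactly.
#' @param exclude Surface forms that must not appear in this instrument
#'   (used to build disjoint parallel forms).
#' @param max_attempts Per-template pseudoword search budget.
#' @return An object of class `instrument`: a list with `items` (a
#'   data.frame `item_id`, `surface`, `is_pseudoword`, `tier`, `template`,
#'   `log_z`, `weight`, in presentation order) and the design metadata.
#' @export
build_instrument <- function(partition, chain, lexicon,
                             words_per_tier = 5, pseudos_per_tier = 2,
                             seed = 1L, exclude = character(0),
                             max_attempts = 1000L) {
  stopifnot(inherits(partition, "tier_partition"),
            inherits(chain, "segment_chain"))
  entries <- partition$entries
  if (!all(c("weight", "log_z") %in% names(entries))) {
    stop("partition entries carry no item weights; run ",
         "compute_item_weights() before partition_tiers()", call. = FALSE)
  }
  lexicon <- tolower(lexicon)
  exclude <- tolower(exclude)
  withr::with_seed(seed, {
    items <- assemble_items(entries, partition$n_tiers, chain, lexicon,
                            words_per_tier, pseudos_per_tier, exclude,
                            max_attempts)
    items <- items[sample.int(nrow(items)), , drop = FALSE]
  })
  rownames(items) <- NULL
  structure(
    list(items = items, n_tiers = partition$n_tiers,
         words_per_tier = words_per_tier,
         pseudos_per_tier = pseudos_per_tier, seed = as.integer(seed)),
    class = "instrument"
  )
}

assemble_items <- function(entries, n_tiers, chain, lexicon,
                           words_per_tier, pseudos_per_tier, exclude,
                           max_attempts) {
  per_tier <- vector("list", n_tiers)
  for (tier in seq_len(n_tiers)) {
    pool <- entries[entries$tier == tier &
                      !(entries$word %in% exclude), , drop = FALSE]
    need <- words_per_tier + pseudos_per_tier
    if (nrow(pool) < need) {
      stop("tier ", tier, " holds ", nrow(pool), " eligible words; ",
           "need at least ", need, call. = FALSE)
    }
    sel <- pool[sample.int(nrow(pool), words_per_tier), , drop = FALSE]
    true_items <- data.frame(
      item_id = sprintf("t%d_%d", tier, seq_len(words_per_tier)),
      surface = sel$word, is_pseudoword = FALSE, tier = tier,
      template = NA_character_, log_z = sel$log_z, weight = sel$weight,
      stringsAsFactors = FALSE)
    templates <- pool[!(pool$word %in% sel$word), , drop = FALSE]
    per_tier[[tier]] <- list(true = true_items, templates = templates)
  }
  items <- do.call(rbind, lapply(per_tier, `[[`, "true"))
  mean_w <- mean(items$weight)

  taken <- c(items$surface, exclude)
  pseudo_rows <- vector("list", n_tiers)
  for (tier in seq_len(n_tiers)) {
    templates <- per_tier[[tier]]$templates
    tpl_order <- sample.int(nrow(templates))
    got <- 0L
    rows <- vector("list", pseudos_per_tier)
    for (ti in tpl_order) {
      if (got == pseudos_per_tier) break
      tpl <- templates$word[ti]
      pw <- tryCatch(
        generate_pseudoword(tpl, chain, c(lexicon, taken),
                            max_attempts = max_attempts),
        error = function(e) NULL)
      if (is.null(pw)) next
      got <- got + 1L
      rows[[got]] <- data.frame(
        item_id = sprintf("p%d_%d", tier, got), surface = pw,
        is_pseudoword = TRUE, tier = tier, template = tpl,
        log_z = NA_real_, weight = mean_w, stringsAsFactors = FALSE)
      taken <- c(taken, pw)
    }
    if (got < pseudos_per_tier) {
      stop("could not generate ", pseudos_per_tier,
           " pseudowords for tier ", tier, call. = FALSE)
    }
    pseudo_rows[[tier]] <- do.call(rbind, rows)
  }
  items <- rbind(items, do.call(rbind, pseudo_rows))
  items$weight <- items$weight / sum(items$weight)
  items
}

#' @export
print.instrument <- function(x, ...) {
  cat("Word-recognition instrument: ", sum(!x$items$is_pseudoword),
      " true words + ", sum(x$items$is_pseudoword), " pseudowords in ",
      x$n_tiers, " tiers (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Master key of an instrument
#'
#' The master is the idealized perfect respondent: every true word is
#' answered with the most confident category (4) and every pseudoword with
#' the lowest (1).
#'
#' @param instrument An `instrument`.
#' @return Named integer vector mapping `item_id` to category.
#' @export
master_key <- function(instrument) {
  stopifnot(inherits(instrument, "instrument"),
            nrow(instrument$items) > 0)
  stats::setNames(ifelse(instrument$items$is_pseudoword, 1L, 4L),
                  instrument$items$item_id)
}

#' Item weights of an instrument, as a named vector
#'
#' @param instrument An `instrument`.
#' @return Named numeric vector (names are item ids) summing to 1.
#' @export
item_weights <- function(instrument) {
  stats::setNames(instrument$items$weight, instrument$items$item_id)
}

#' Build two disjoint parallel forms from one corpus
#'
#' Two instruments with identical design counts are drawn from the same
#' tier partition, with entirely disjoint surface forms (no shared true
#' word or pseudoword), so that the parallel-form correlation cannot be
#' inflated by shared items. The two form seeds are derived
#' deterministically from `seed`.
#'
#' @inheritParams build_instrument
#' @return A list of two `instrument` objects, `form_a` and `form_b`.
#' @export
make_parallel_forms <- function(partition, chain, lexicon,
                                words_per_tier = 5, pseudos_per_tier = 2,
                                seed = 1L, max_attempts = 1000L) {
  seeds <- withr::with_seed(seed,
                            sample.int(.Machine$integer.max - 1L, 2L))
  form_a <- build_instrument(partition, chain, lexicon, words_per_tier,
                             pseudos_per_tier, seed = seeds[1L],
                             max_attempts = max_attempts)
  form_b <- build_instrument(partition, chain, lexicon, words_per_tier,
                             pseudos_per_tier, seed = seeds[2L],
                             exclude = form_a$items$surface,
                             max_attempts = max_attempts)
  list(form_a = form_a, form_b = form_b)
}

#' Filter response sheets with quality-control items
#'
#' Quality-control items are simple, unambiguous questions with a single
#' correct category, embedded to identify respondents gaming the test. A
#' sheet is rejected if any quality-control answer differs from the
#' required category, or if a quality-control item was left unanswered
#' (reason `"missing"`); quality-control rows are stripped from kept
#' sheets before scoring.
#'
#' @param sheets Long-format responses: data.frame `respondent_id`,
#'   `item_id`, `category`.
#' @param qc_items Named integer vector, names are quality-control item
#'   ids, values the required categories.
#' @return A list with `kept` (responses of passing respondents, QC rows
#'   removed) and `rejected` (data.frame `respondent_id`, `reason`).
#' @export
filter_responses <- function(sheets, qc_items) {
  stopifnot(is.data.frame(sheets),
            all(c("respondent_id", "item_id", "category") %in%
                  names(sheets)),
            length(qc_items) > 0, !is.null(names(qc_items)))
  ids <- unique(sheets$respondent_id)
  reasons <- character(0)
  rej_ids <- character(0)
  for (rid in ids) {
    sub <- sheets[sheets$respondent_id == rid, , drop = FALSE]
    ans <- stats::setNames(sub$category, sub$item_id)
    if (!all(names(qc_items) %in% names(ans))) {
      rej_ids <- c(rej_ids, rid); reasons <- c(reasons, "missing")
    } else if (any(ans[names(qc_items)] != qc_items)) {
      rej_ids <- c(rej_ids, rid); reasons <- c(reasons, "failed_qc")
    }
  }
  kept <- sheets[!(sheets$respondent_id %in% rej_ids) &
                   !(sheets$item_id %in% names(qc_items)), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept,
       rejected = data.frame(respondent_id = rej_ids, reason = reasons,
                             stringsAsFactors = FALSE))
}

#' Serialize an instrument to JSON
#'
#' Writes design counts, seed and the item table. With
#' `include_key = FALSE` the administrator fields (`is_pseudoword`,
#' `template`, tier, weights and the embedded master key) are omitted,
#' producing the respondent-facing export: item ids, surfaces and the
#' Likert options only.
#'
#' @param instrument An `instrument`.
#' @param path Output path.
#' @param include_key Include the administrator section (default `TRUE`).
#' @export
write_instrument <- function(instrument, path, include_key = TRUE) {
  stopifnot(inherits(instrument, "instrument"))
  doc <- list(
    format = "lexlit-instrument",
    version = 1L,
    design = list(n_tiers = instrument$n_tiers,
                  words_per_tier = instrument$words_per_tier,
                  pseudos_per_tier = instrument$pseudos_per_tier,
                  seed = instrument$seed),
    likert = names(likert_scale())
  )
  if (include_key) {
    doc$items <- instrument$items
    doc$master_key <- as.list(master_key(instrument))
  } else {
    doc$items <- instrument$items[, c("item_id", "surface")]
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read an instrument serialized by [write_instrument()]
#'
#' @param path Path to the JSON file (must contain the administrator
#'   section).
#' @return An `instrument` object.
#' @export
read_instrument <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "lexlit-instrument")) {
    stop("not an instrument file: ", path, call. = FALSE)
  }
  if (is.null(doc$items$weight)) {
    stop("respondent-facing export has no administrator section; ",
         "cannot score with it", call. = FALSE)
  }
  items <- doc$items
  items$template <- as.character(items$template)
  structure(
    list(items = items, n_tiers = doc$design$n_tiers,
         words_per_tier = doc$design$words_per_tier,
         pseudos_per_tier = doc$design$pseudos_per_tier,
         seed = doc$design$seed),
    class = "instrument"
  )
}

#' Read response sheets from CSV
#'
#' Expects the header `respondent_id,item_id,category` with categories in
#' 1..4.
#'
#' @param path CSV path.
#' @return Long-format data.frame of responses.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(respondent_id = "character",
                                       item_id = "character"))
  need <- c("respondent_id", "item_id", "category")
  if (!all(need %in% names(df))) {
    stop("response file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(!(df$category %in% 1:4))) {
    stop("response categories must be integers in 1..4", call. = FALSE)
  }
  df[need]
}
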