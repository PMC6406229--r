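#' Generate a synthetic Zipf-distributed vocabulary
#'
#' Produces a heavy-tailed word-frequency table emulating the shape of a
#' large-corpus vocabulary: counts follow `round(1e6 * rank^-exponent)`,
#' floored at `min_count`, over unique pronounceable surfaces built from
#' random consonant-vowel syllables. The result can stand in for a real
#' corpus-derived frequency list anywhere the package expects one.
#'
#' @param n_words Vocabulary size (at least 100 so tiers are meaningful).
#' @param zipf_exponent Positive Zipf exponent (default 1).
#' @param seed Integer seed; the output is bit-for-bit reproducible.
#' @param min_count Floor for rounded counts (default 1).
#' @param path Optional output path; when given, the table is written in
#'   the package's tab-separated frequency format.
#' @return Invisibly when `path` is given, otherwise visibly: a
#'   vocabulary data.frame (`word`, `count`, `rel_freq`).
#' @export
generate_vocabulary <- function(n_words = 5000, zipf_exponent = 1,
                                seed = 1L, min_count = 1L, path = NULL) {
  stopifnot(n_words >= 100, zipf_exponent > 0, min_count >= 1)
  n_words <- as.integer(n_words)
  words <- withr::with_seed(seed, random_surfaces(n_words))
  count <- pmax(round(1e6 * seq_len(n_words)^(-zipf_exponent)),
                min_count)
  vocab <- data.frame(word = words, count = count,
                      stringsAsFactors = FALSE)
  vocab$rel_freq <- vocab$count / sum(vocab$count)
  if (!is.null(path)) {
    writeLines(c("# synthetic Zipf vocabulary",
                 paste(vocab$word, vocab$count, sep = "\t")), path)
    return(invisible(vocab))
  }
  vocab
}

# Unique pronounceable CV-pattern strings: 1-4 syllables, each a random
# consonant + vowel, optionally closed by a final consonant.
random_surfaces <- function(n) {
  consonants <- setdiff(letters, c(VOWELS, "y"))
  out <- character(0)
  while (length(out) < n) {
    m <- n - length(out)
    ns <- sample(1:4, m, replace = TRUE,
                 prob = c(0.25, 0.4, 0.25, 0.1))
    w <- vapply(ns, function(k) {
      syll <- paste0(sample(consonants, k, replace = TRUE),
                     sample(VOWELS, k, replace = TRUE))
      word <- paste(syll, collapse = "")
      if (stats::runif(1) < 0.5) {
        word <- paste0(word, sample(consonants, 1))
      }
      word
    }, "")
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

#' Default graded-response respondent model
#'
#' The simulator's behavioral model for synthetic respondents. True-word
#' responses follow a graded-response mechanism: the latent familiarity
#' with item n is `a * (theta - b_n)` plus standard-logistic noise, where
#' ability `theta` is standard normal in the population and the item
#' difficulty `b_n` is the negative standardized log frequency (rarer
#' words are harder); the Likert category is 1 plus the number of
#' thresholds `tau` below the latent value. Pseudoword false alarms
#' (categories 3-4) occur with probability
#' `pseudo_base * (1 - plogis(pseudo_slope * theta))`, decreasing in
#' ability, mirroring the calibration role of pseudowords in Yes-No
#' vocabulary testing.
#'
#' These parameter values are simulation fixtures, not claims about human
#' respondents.
#'
#' @param a Discrimination (default 1.5).
#' @param tau Strictly increasing thresholds (default `c(-1, 0, 1)`).
#' @param pseudo_base Maximal false-alarm probability (default 0.3).
#' @param pseudo_slope Ability sensitivity of false alarms (default 1).
#' @return A `respondent_model` list.
#' @export
respondent_model <- function(a = 1.5, tau = c(-1, 0, 1),
                             pseudo_base = 0.3, pseudo_slope = 1) {
  stopifnot(a > 0, length(tau) == 3, all(diff(tau) > 0),
            pseudo_base >= 0, pseudo_base <= 1, pseudo_slope >= 0)
  structure(list(a = a, tau = tau, pseudo_base = pseudo_base,
                 pseudo_slope = pseudo_slope),
            class = "respondent_model")
}

#' Simulate respondents answering an instrument
#'
#' Draws one Likert category per item per respondent under the
#' graded-response model of [respondent_model()]. For pseudoword items
#' the false-alarm probability mass `q(theta)` is split evenly over
#' categories 3 and 4; category 2 ("seen but unknown") receives an equal
#' decreasing mass `q(theta)` (capped so probabilities stay valid), so a
#' noise-free low-ability respondent with `pseudo_base = 0` answers 1.
#'
#' @param instrument An `instrument`.
#' @param thetas Numeric vector of respondent abilities.
#' @param model A `respondent_model`.
#' @param seed Integer seed for reproducibility.
#' @return Long-format data.frame (`respondent_id`, `item_id`,
#'   `category`); respondent ids are `r0001`, `r0002`, ... in `thetas`
#'   order.
#' @export
simulate_responses <- function(instrument, thetas,
                               model = respondent_model(), seed = 1L) {
  stopifnot(inherits(instrument, "instrument"),
            inherits(model, "respondent_model"))
  if (!length(thetas)) stop("ability list is empty", call. = FALSE)
  items <- instrument$items
  rid <- sprintf("r%04d", seq_along(thetas))
  withr::with_seed(seed, {
    out <- lapply(seq_along(thetas), function(i) {
      data.frame(respondent_id = rid[i], item_id = items$item_id,
                 category = draw_categories(items, thetas[i], model),
                 stringsAsFactors = FALSE)
    })
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

draw_categories <- function(items, theta, model) {
  cat <- integer(nrow(items))
  tw <- !items$is_pseudoword
  if (any(tw)) {
    b <- -items$log_z[tw]
    x <- model$a * (theta - b) + stats::rlogis(sum(tw))
    cat[tw] <- 1L + vapply(x, function(xi) sum(xi > model$tau), 0L)
  }
  if (any(!tw)) {
    q <- model$pseudo_base *
      (1 - stats::plogis(model$pseudo_slope * theta))
    q2 <- min(q, 1 - q)
    p <- c(1 - q - q2, q2, q / 2, q / 2)
    cat[!tw] <- sample.int(4L, sum(!tw), replace = TRUE, prob = p)
  }
  cat
}

#' In-silico parallel-form reliability experiment
#'
#' Reproduces the design of a parallel-form reliability study: two
#' item-disjoint instruments are built from the same corpus, the same
#' simulated respondents (standard-normal abilities) answer both, both
#' sheets are scored against their master keys, and the Pearson
#' correlation between the two score vectors is returned with a Fisher-z
#' 95% confidence interval. Any correlation magnitude obtained here is a
#' property of the simulation fixtures, not an empirical human value.
#'
#' @param vocab A vocabulary data.frame (e.g. [generate_vocabulary()]).
#' @param n_respondents Number of simulated respondents (>= 10).
#' @param model A `respondent_model`.
#' @param seed Master seed driving form construction, abilities and
#'   responses.
#' @param n_tiers,words_per_tier,pseudos_per_tier Design counts.
#' @param v Disagreement matrix.
#' @return A list: `scores` (data.frame `respondent_id`, `theta`,
#'   `score_a`, `score_b`), `pearson_r`, `ci` (length-2 vector),
#'   `forms` (the two instruments).
#' @export
parallel_form_experiment <- function(vocab, n_respondents = 100,
                                     model = respondent_model(),
                                     seed = 1L, n_tiers = 10,
                                     words_per_tier = 5,
                                     pseudos_per_tier = 2,
                                     v = disagreement_weights("linear")) {
  stopifnot(n_respondents >= 10)
  weighted <- compute_item_weights(vocab)
  part <- partition_tiers(weighted, n_tiers)
  chain <- build_chain(vocab$word)
  seeds <- withr::with_seed(seed,
                            sample.int(.Machine$integer.max - 1L, 3L))
  forms <- make_parallel_forms(part, chain, vocab$word,
                               words_per_tier, pseudos_per_tier,
                               seed = seeds[1L])
  thetas <- withr::with_seed(seeds[2L], stats::rnorm(n_respondents))
  sheets_a <- simulate_responses(forms$form_a, thetas, model,
                                 seed = seeds[3L])
  sheets_b <- simulate_responses(forms$form_b, thetas, model,
                                 seed = seeds[3L] %% 1000000L + 7L)
  sa <- score_batch(sheets_a, forms$form_a, v)
  sb <- score_batch(sheets_b, forms$form_b, v)
  stopifnot(identical(sa$respondent_id, sb$respondent_id))
  scores <- data.frame(respondent_id = sa$respondent_id,
                       theta = thetas[match(sa$respondent_id,
                                            sprintf("r%04d",
                                                    seq_along(thetas)))],
                       score_a = sa$kappa, score_b = sb$kappa)
  r <- stats::cor(scores$score_a, scores$score_b)
  list(scores = scores, pearson_r = r,
       ci = fisher_ci(r, nrow(scores)), forms = forms)
}

# Fisher z-transform 95% CI for a Pearson correlation.
fisher_ci <- function(r, n, level = 0.95) {
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  hw <- stats::qnorm(1 - (1 - level) / 2) * se
  tanh(c(lower = z - hw, upper = z + hw))
}

#' In-silico criterion validity experiment
#'
#' Simulates respondents on a single instrument and correlates their
#' kappa scores with a noisy external criterion defined as
#' `theta + N(0, criterion_noise_sd)`; with zero noise the returned value
#' is the score-ability correlation itself.
#'
#' @inheritParams parallel_form_experiment
#' @param criterion_noise_sd Standard deviation of the criterion noise.
#' @return A list: `scores` (data.frame with `theta`, `criterion`,
#'   `kappa`), `pearson_r`, `ci`.
#' @export
criterion_validity_experiment <- function(vocab, n_respondents = 200,
                                          model = respondent_model(),
                                          criterion_noise_sd = 0.5,
                                          seed = 1L, n_tiers = 10,
                                          words_per_tier = 5,
                                          pseudos_per_tier = 2,
                                          v = disagreement_weights("linear")) {
  stopifnot(n_respondents >= 10, criterion_noise_sd >= 0)
  weighted <- compute_item_weights(vocab)
  part <- partition_tiers(weighted, n_tiers)
  chain <- build_chain(vocab$word)
  seeds <- withr::with_seed(seed,
                            sample.int(.Machine$integer.max - 1L, 4L))
  inst <- build_instrument(part, chain, vocab$word, words_per_tier,
                           pseudos_per_tier, seed = seeds[1L])
  thetas <- withr::with_seed(seeds[2L], stats::rnorm(n_respondents))
  criterion <- thetas +
    withr::with_seed(seeds[3L],
                     stats::rnorm(n_respondents, 0, criterion_noise_sd))
  sheets <- simulate_responses(inst, thetas, model, seed = seeds[4L])
  sc <- score_batch(sheets, inst, v)
  ord <- match(sc$respondent_id, sprintf("r%04d", seq_along(thetas)))
  scores <- data.frame(respondent_id = sc$respondent_id,
                       theta = thetas[ord], criterion = criterion[ord],
                       kappa = sc$kappa)
  r <- stats::cor(scores$kappa, scores$criterion)
  list(scores = scores, pearson_r = r, ci = fisher_ci(r, nrow(scores)))
}

#' Proportion of scores at the test maximum (ceiling report)
#'
#' A test with a strong ceiling effect cannot separate high-ability
#' respondents: many of them attain the maximal score. This reports the
#' fraction of scores within 1e-9 of `max_score`.
#'
#' @param scores Numeric vector of test scores.
#' @param max_score The test's maximal attainable score.
#' @return Proportion in \[0, 1\].
#' @export
ceiling_report <- function(scores, max_score) {
  stopifnot(length(scores) > 0, is.numeric(scores))
  mean(abs(scores - max_score) <= 1e-9)
}
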