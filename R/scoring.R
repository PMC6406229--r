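#' Disagreement weight matrix between ordinal categories
#'
#' Builds the penalty matrix v(i, j) quantifying the disagreement when
#' one rater assigns category i and the other j. The linear scheme,
#' v(i, j) = |i - j|, is the default used for literacy scoring; the
#' quadratic scheme v(i, j) = (i - j)^2 is provided as an alternative.
#' Any such matrix is symmetric with a zero diagonal.
#'
#' @param scheme `"linear"` or `"quadratic"`.
#' @param n_categories Number of ordinal categories (default 4).
#' @return A `n_categories` x `n_categories` numeric matrix with the
#'   scheme recorded in the `"scheme"` attribute.
#' @export
disagreement_weights <- function(scheme = c("linear", "quadratic"),
                                 n_categories = 4L) {
  scheme <- match.arg(scheme)
  d <- abs(outer(seq_len(n_categories), seq_len(n_categories), `-`))
  v <- if (scheme == "linear") d else d^2
  structure(v * 1.0, scheme = scheme)
}

check_alignment <- function(responses, key, weights) {
  if (is.null(names(responses)) || is.null(names(key)) ||
      is.null(names(weights))) {
    stop("responses, key and weights must be named by item id",
         call. = FALSE)
  }
  if (!setequal(names(responses), names(key)) ||
      !setequal(names(weights), names(key))) {
    stop("item ids of responses, key and weights do not match",
         call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-6) {
    stop("item weights must be normalized to sum to 1 (got ",
         format(sum(weights)), ")", call. = FALSE)
  }
  if (any(!(responses %in% seq_len(4))) || any(!(key %in% seq_len(4)))) {
    stop("categories must lie in 1..4", call. = FALSE)
  }
}

#' Observed item-weighted disagreement
#'
#' The observed disagreement between a respondent and the master key is
#' the item-weight-weighted sum of per-item category disagreements:
#' `q_o = sum_n u_n * v(k_n, l_n)`, where `u` are the normalized item
#' weights and `k_n`, `l_n` the categories the two raters assigned to
#' item n.
#'
#' @param responses Named integer vector (item id -> category 1..4).
#' @param key Named integer vector, same item ids (e.g. [master_key()]).
#' @param weights Named numeric item weights summing to 1.
#' @param v Disagreement matrix from [disagreement_weights()].
#' @return The observed disagreement, a nonnegative scalar.
#' @export
observed_disagreement <- function(responses, key, weights,
                                  v = disagreement_weights("linear")) {
  check_alignment(responses, key, weights)
  ids <- names(key)
  k <- responses[ids]
  u <- weights[ids]
  sum(u * v[cbind(k, key)])
}

#' Chance item-weighted disagreement
#'
#' The chance disagreement generalizes the weighted-kappa chance term by
#' weighting each rater's category distribution by the item weights:
#' `p1(i) = sum_n u_n [l_n = i]`, `p2(j) = sum_n u_n [k_n = j]`, and
#' `q_e = sum_i sum_j p1(i) p2(j) v(i, j)`. With uniform item weights
#' this reduces exactly to the chance term of textbook weighted kappa on
#' the K x K contingency table.
#'
#' @inheritParams observed_disagreement
#' @return The chance disagreement, a nonnegative scalar.
#' @export
chance_disagreement <- function(responses, key, weights,
                                v = disagreement_weights("linear")) {
  check_alignment(responses, key, weights)
  ids <- names(key)
  p1 <- weighted_marginal(key[ids], weights[ids], ncol(v))
  p2 <- weighted_marginal(responses[ids], weights[ids], ncol(v))
  as.numeric(p1 %*% v %*% p2)
}

weighted_marginal <- function(categories, weights, n_categories) {
  vapply(seq_len(n_categories),
         function(i) sum(weights[categories == i]), numeric(1))
}

#' Item-weighted generalized kappa score
#'
#' Chance-corrected agreement between a response sheet and the master
#' key: `kappa = 1 - q_o / q_e`, with `q_o` the observed and `q_e` the
#' chance item-weighted disagreement. The literacy score is the raw value
#' clamped to \[0, 1\] (1 is attained only by the master itself, i.e.
#' when `q_o = 0`; negative raw values arise only from systematically
#' anti-master responding and are reported alongside the clamped score).
#' If both disagreements are zero (two identical constant raters, a
#' degenerate comparison) the score is defined as 1 and flagged.
#'
#' @inheritParams observed_disagreement
#' @return A one-row `data.frame` (`q_obs`, `q_exp`, `kappa_raw`,
#'   `kappa`, `n_items`, `degenerate`).
#' @export
generalized_kappa <- function(responses, key, weights,
                              v = disagreement_weights("linear")) {
  q_o <- observed_disagreement(responses, key, weights, v)
  q_e <- chance_disagreement(responses, key, weights, v)
  degenerate <- FALSE
  if (q_e == 0) {
    if (q_o > 0) {
      stop("internal error: chance disagreement 0 with positive ",
           "observed disagreement", call. = FALSE)
    }
    kappa_raw <- 1
    degenerate <- TRUE
  } else {
    kappa_raw <- 1 - q_o / q_e
  }
  data.frame(q_obs = q_o, q_exp = q_e, kappa_raw = kappa_raw,
             kappa = min(max(kappa_raw, 0), 1),
             n_items = length(key), degenerate = degenerate)
}

#' Score a batch of response sheets against an instrument
#'
#' Scores each respondent's sheet against the instrument's master key
#' using the instrument's normalized item weights. Sheets that fail
#' validation (missing or extra items, out-of-range categories) are
#' reported with an error message; the batch continues.
#'
#' @param sheets Long-format responses (`respondent_id`, `item_id`,
#'   `category`), e.g. from [read_responses()] or [simulate_responses()].
#' @param instrument An `instrument`.
#' @param v Disagreement matrix from [disagreement_weights()].
#' @return A `data.frame` with one row per scored respondent
#'   (`respondent_id`, `q_obs`, `q_exp`, `kappa_raw`, `kappa`,
#'   `n_items`), ordered by respondent id; failures are returned in the
#'   `"failures"` attribute (`respondent_id`, `error`).
#' @export
score_batch <- function(sheets, instrument,
                        v = disagreement_weights("linear")) {
  stopifnot(inherits(instrument, "instrument"), is.data.frame(sheets))
  key <- master_key(instrument)
  u <- item_weights(instrument)
  ids <- sort(unique(sheets$respondent_id))
  rows <- vector("list", length(ids))
  fails <- list()
  for (i in seq_along(ids)) {
    sub <- sheets[sheets$respondent_id == ids[i], , drop = FALSE]
    res <- tryCatch({
      resp <- stats::setNames(as.integer(sub$category), sub$item_id)
      if (anyDuplicated(names(resp))) {
        stop("duplicate answers for an item", call. = FALSE)
      }
      generalized_kappa(resp, key, u, v)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <-
        data.frame(respondent_id = ids[i], error = conditionMessage(res),
                   stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- cbind(data.frame(respondent_id = ids[i],
                                    stringsAsFactors = FALSE),
                         res[c("q_obs", "q_exp", "kappa_raw", "kappa",
                               "n_items")])
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(respondent_id = character(0), q_obs = numeric(0),
                      q_exp = numeric(0), kappa_raw = numeric(0),
                      kappa = numeric(0), n_items = integer(0))
  }
  rownames(out) <- NULL
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails) else
    data.frame(respondent_id = character(0), error = character(0))
  out
}
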