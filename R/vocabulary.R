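#' Read a word-frequency vocabulary
#'
#' Reads a plain-text frequency table (one record per line: word and
#' occurrence count, tab- or whitespace-separated; `#` lines are comments)
#' and returns a tidy vocabulary data frame. Words are folded to lowercase,
#' duplicates are merged by summing counts and, when a reference lexicon is
#' supplied, words absent from the lexicon are dropped (filtering a raw
#' corpus vocabulary against a curated word list removes digitization
#' artifacts and non-words).
#'
#' @param path Path to the frequency table.
#' @param lexicon Optional path to a reference lexicon (one word per line),
#'   or a character vector of words. `NULL` disables filtering.
#' @return A `data.frame` with columns `word` (character), `count`
#'   (numeric, nonnegative) and `rel_freq` (count / total count over the
#'   retained entries), sorted by descending count with lexicographic
#'   tie-break.
#' @examples
#' tf <- tempfile()
#' writeLines(c("cat\t100", "dog\t50", "cat\t20"), tf)
#' load_vocabulary(tf)  # cat merged to 120
#' @export
load_vocabulary <- function(path, lexicon = NULL) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) {
    stop("vocabulary file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[\t ]+")
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad)) {
    stop("malformed vocabulary line ", idx[bad[1L]],
         ": expected <word> <count>", call. = FALSE)
  }
  word <- tolower(vapply(fields, `[[`, "", 1L))
  count <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  badn <- which(is.na(count) | count < 0 | count != floor(count))
  if (length(badn)) {
    stop("malformed vocabulary line ", idx[badn[1L]],
         ": count must be a nonnegative integer", call. = FALSE)
  }
  if (!is.null(lexicon)) {
    lex <- read_lexicon(lexicon)
    in_lex <- word %in% lex
    word <- word[in_lex]
    count <- count[in_lex]
  }
  if (!length(word)) {
    stop("vocabulary is empty after lexicon filtering", call. = FALSE)
  }
  agg <- rowsum(count, group = word)
  vocab <- data.frame(word = rownames(agg), count = as.numeric(agg[, 1L]),
                      stringsAsFactors = FALSE)
  vocab$rel_freq <- vocab$count / sum(vocab$count)
  vocab <- vocab[order(-vocab$count, vocab$word), , drop = FALSE]
  rownames(vocab) <- NULL
  vocab
}

#' @keywords internal
read_lexicon <- function(lexicon) {
  if (length(lexicon) == 1L && file.exists(lexicon)) {
    lexicon <- readLines(lexicon, encoding = "UTF-8", warn = FALSE)
  }
  lex <- tolower(trimws(lexicon))
  lex[nzchar(lex) & !startsWith(lex, "#")]
}

#' Compute logistic item weights from word frequencies
#'
#' Natural-log counts are standardized (z-scored) over the full vocabulary
#' and passed through a logistic function, so common words receive weights
#' near 1 and rare words near 0. Under the framework's behavioral premise,
#' high-frequency words should be known by nearly all native speakers, so
#' unfamiliarity with them is strong evidence of limited literacy; rare
#' words discriminate poorly and are down-weighted.
#'
#' The weight of a word with count `c` is
#' `1 / (1 + exp(-slope * (z(log c) - center)))`, where `z()` standardizes
#' over the whole vocabulary (mean 0, sd 1 on the natural-log scale).
#'
#' @param vocab A vocabulary data frame from [load_vocabulary()]; all
#'   counts must be strictly positive and at least two distinct counts must
#'   be present (otherwise the z-score is undefined).
#' @param slope Positive steepness of the logistic; default 1.
#' @param center Midpoint on the z-score scale; default 0 (a word of
#'   average log frequency gets weight 0.5).
#' @return The input with `log_z` (standardized log count) and `weight`
#'   columns added. Weights are strictly increasing in count.
#' @export
compute_item_weights <- function(vocab, slope = 1, center = 0) {
  stopifnot(is.data.frame(vocab), all(c("word", "count") %in% names(vocab)),
            is.numeric(slope), length(slope) == 1L, slope > 0,
            is.numeric(center), length(center) == 1L)
  if (nrow(vocab) < 2L) {
    stop("cannot standardize a vocabulary of fewer than 2 words",
         call. = FALSE)
  }
  if (any(vocab$count <= 0)) {
    stop("all counts must be positive to take logs; drop zero-count ",
         "entries first", call. = FALSE)
  }
  lc <- log(vocab$count)
  s <- stats::sd(lc)
  if (s == 0) {
    stop("cannot standardize: all counts are identical", call. = FALSE)
  }
  vocab$log_z <- (lc - mean(lc)) / s
  vocab$weight <- stats::plogis(slope * (vocab$log_z - center))
  vocab
}

#' Partition a vocabulary into frequency tiers
#'
#' Sorts the vocabulary by descending count (ties broken lexicographically
#' so the partition is deterministic) and splits it into `n_tiers`
#' contiguous, equally sized blocks; tier 1 holds the most frequent words.
#' When the size is not divisible, earlier tiers receive the extra word.
#'
#' @param vocab A vocabulary data frame (at least `word` and `count`).
#' @param n_tiers Number of tiers; default 10.
#' @return An object of class `tier_partition`: a list with `n_tiers` and
#'   `tiers`, a list of character vectors of words (tier 1 first), plus
#'   `entries`, the sorted vocabulary with a `tier` column.
#' @export
partition_tiers <- function(vocab, n_tiers = 10) {
  stopifnot(is.data.frame(vocab), all(c("word", "count") %in% names(vocab)))
  if (!is.numeric(n_tiers) || length(n_tiers) != 1L || n_tiers < 1 ||
      n_tiers != floor(n_tiers)) {
    stop("n_tiers must be a positive integer", call. = FALSE)
  }
  n_tiers <- as.integer(n_tiers)
  n <- nrow(vocab)
  if (n < n_tiers) {
    stop("vocabulary has ", n, " words; need at least ", n_tiers,
         " for ", n_tiers, " tiers", call. = FALSE)
  }
  ord <- order(-vocab$count, vocab$word)
  entries <- vocab[ord, , drop = FALSE]
  rownames(entries) <- NULL
  base <- n %/% n_tiers
  extra <- n %% n_tiers
  sizes <- rep(base, n_tiers) + as.integer(seq_len(n_tiers) <= extra)
  entries$tier <- rep(seq_len(n_tiers), times = sizes)
  structure(
    list(n_tiers = n_tiers,
         tiers = split(entries$word, entries$tier),
         entries = entries),
    class = "tier_partition"
  )
}

#' @export
print.tier_partition <- function(x, ...) {
  sizes <- lengths(x$tiers)
  cat("Tier partition: ", sum(sizes), " words in ", x$n_tiers,
      " tiers (sizes ", paste(sizes, collapse = ", "), ")\n", sep = "")
  invisible(x)
}
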