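## Pseudoword generation via a first-order chain of subsyllabic elements
## (onset, nucleus, coda), in the spirit of multilingual pseudoword
## generators used for lexical-decision stimuli: segment a lexicon into
## subsyllabic elements, accumulate transition counts between consecutive
## elements, then search for letter strings that match a template word's
## syllabic structure while only using transitions attested in the chain.

VOWELS <- c("a", "e", "i", "o", "u")

#' Segment a word into subsyllabic elements
#'
#' Deterministic syllabification: maximal vowel clusters become nuclei;
#' consonants before the first nucleus form the first onset; all
#' intervocalic consonants attach to the onset of the following syllable
#' (maximal-onset convention); trailing consonants form the final coda.
#' `y` is treated as a vowel only when the word contains no other vowel
#' letter (e.g. "gym").
#'
#' @param word A nonempty alphabetic string.
#' @return A `data.frame` with one row per syllable and character columns
#'   `onset`, `nucleus`, `coda`. Concatenating all elements in order
#'   reproduces `word`.
#' @examples
#' segment_word("doctor")
#' @export
segment_word <- function(word) {
  stopifnot(is.character(word), length(word) == 1L)
  word <- tolower(word)
  if (!nzchar(word) || grepl("[^a-z]", word)) {
    stop("word must be a nonempty alphabetic string: ", dQuote(word),
         call. = FALSE)
  }
  chars <- strsplit(word, "")[[1L]]
  is_vowel <- chars %in% VOWELS
  if (!any(is_vowel)) is_vowel <- chars == "y"
  if (!any(is_vowel)) {
    stop("cannot segment ", dQuote(word), ": no vowel letters",
         call. = FALSE)
  }
  # runs of vowels = nuclei
  r <- rle(is_vowel)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nuc <- which(r$values)
  syll <- vector("list", length(nuc))
  for (k in seq_along(nuc)) {
    i <- nuc[k]
    onset <- ""
    if (i > 1L && (k == 1L || nuc[k - 1L] < i - 1L)) {
      # consonant run before this nucleus: first onset takes it all, and by
      # maximal onset so does every later syllable
      onset <- substr(word, starts[i - 1L], ends[i - 1L])
    }
    coda <- ""
    if (k == length(nuc) && i < length(r$values)) {
      coda <- substr(word, starts[i + 1L], ends[i + 1L])
    }
    syll[[k]] <- data.frame(onset = onset,
                            nucleus = substr(word, starts[i], ends[i]),
                            coda = coda, stringsAsFactors = FALSE)
  }
  do.call(rbind, syll)
}

# Typed element keys ("O:str", "N:str", "C:str") for one segmentation;
# empty onset/coda slots are dropped, so transitions run between the
# nonempty elements in reading order.
element_keys <- function(seg) {
  keys <- character(0)
  for (k in seq_len(nrow(seg))) {
    if (nzchar(seg$onset[k]))   keys <- c(keys, paste0("O:", seg$onset[k]))
    keys <- c(keys, paste0("N:", seg$nucleus[k]))
    if (nzchar(seg$coda[k]))    keys <- c(keys, paste0("C:", seg$coda[k]))
  }
  keys
}

#' Build a subsyllabic transition chain from a lexicon
#'
#' Segments every word and accumulates counts of transitions between
#' consecutive subsyllabic elements (onset -> nucleus -> coda -> next
#' onset, ...). Words that cannot be segmented (no vowel letters) are
#' skipped and counted.
#'
#' @param lexicon Character vector of words.
#' @return An object of class `segment_chain`: a list with `transitions`
#'   (data.frame `from`, `to`, `count`), `elements` (a named list of
#'   element inventories with occurrence counts, by type `O`/`N`/`C`),
#'   `n_words` and `n_skipped`.
#' @export
build_chain <- function(lexicon) {
  stopifnot(is.character(lexicon))
  lexicon <- unique(tolower(lexicon))
  if (!length(lexicon)) stop("lexicon is empty", call. = FALSE)
  from <- to <- character(0)
  all_keys <- character(0)
  skipped <- 0L
  for (w in lexicon) {
    seg <- tryCatch(segment_word(w), error = function(e) NULL)
    if (is.null(seg)) {
      skipped <- skipped + 1L
      next
    }
    keys <- element_keys(seg)
    all_keys <- c(all_keys, keys)
    if (length(keys) > 1L) {
      from <- c(from, keys[-length(keys)])
      to <- c(to, keys[-1L])
    }
  }
  if (skipped > 0L) {
    warning(skipped, " word(s) could not be segmented and were skipped",
            call. = FALSE)
  }
  if (!length(all_keys)) {
    stop("no segmentable words in lexicon; cannot build chain",
         call. = FALSE)
  }
  trans <- if (length(from)) {
    tab <- table(from = from, to = to)
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(df)[3L] <- "count"
    df[df$count > 0, , drop = FALSE]
  } else {
    data.frame(from = character(0), to = character(0), count = integer(0))
  }
  rownames(trans) <- NULL
  ktab <- table(all_keys)
  type <- substr(names(ktab), 1L, 1L)
  elements <- lapply(c(O = "O", N = "N", C = "C"), function(tp) {
    sel <- type == tp
    stats::setNames(as.integer(ktab[sel]),
                    substring(names(ktab)[sel], 3L))
  })
  structure(
    list(transitions = trans, elements = elements,
         trans_set = paste(trans$from, trans$to, sep = ">"),
         n_words = length(lexicon) - skipped, n_skipped = skipped),
    class = "segment_chain"
  )
}

#' @export
print.segment_chain <- function(x, ...) {
  cat("Subsyllabic chain: ", x$n_words, " words, ",
      nrow(x$transitions), " distinct transitions\n", sep = "")
  invisible(x)
}

has_transition <- function(chain, from, to) {
  paste(from, to, sep = ">") %in% chain$trans_set
}

# All adjacent transitions of a candidate segmentation attested?
chain_consistent <- function(chain, keys) {
  if (length(keys) < 2L) {
    tp <- substr(keys, 1L, 1L)
    return(substring(keys, 3L) %in% names(chain$elements[[tp]]))
  }
  all(has_transition(chain, keys[-length(keys)], keys[-1L]))
}

#' Generate a pseudoword matched to a template word
#'
#' Performs a seeded random search for a letter string with the template's
#' exact per-syllable element pattern (onset present/absent, coda
#' present/absent, same syllable count) in which every transition between
#' consecutive subsyllabic elements is attested in the chain, and which is
#' neither the template itself nor any word of the supplied lexicon. Each
#' proposal replaces a random nonempty subset of the template's elements
#' with elements of the same type, sampled from the chain's inventory with
#' probability proportional to their lexicon frequency.
#'
#' @param template Template word (must be segmentable).
#' @param chain A `segment_chain` from [build_chain()].
#' @param lexicon Character vector of real words the output must avoid.
#' @param rng_seed Optional integer seed; when given, the search is run
#'   under a local RNG state so the same seed always yields the same
#'   pseudoword. When `NULL`, the ambient RNG stream is used.
#' @param max_attempts Proposal budget before giving up (default 1000).
#' @return A single pseudoword string.
#' @export
generate_pseudoword <- function(template, chain, lexicon,
                                rng_seed = NULL, max_attempts = 1000L) {
  stopifnot(inherits(chain, "segment_chain"), max_attempts >= 1)
  run <- function() {
    pseudoword_search(template, chain, tolower(lexicon), max_attempts)
  }
  if (is.null(rng_seed)) run() else withr::with_seed(rng_seed, run())
}

pseudoword_search <- function(template, chain, lexicon, max_attempts) {
  template <- tolower(template)
  seg <- segment_word(template)
  slots <- slot_table(seg)
  nslot <- nrow(slots)
  for (attempt in seq_len(max_attempts)) {
    k <- sample.int(nslot, 1L)
    repl <- sample.int(nslot, k)
    cand <- slots$value
    ok <- TRUE
    for (s in repl) {
      inv <- chain$elements[[slots$type[s]]]
      if (!length(inv)) { ok <- FALSE; break }
      cand[s] <- sample(names(inv), 1L, prob = inv)
    }
    if (!ok) next
    keys <- paste0(slots$type, ":", cand)
    if (!chain_consistent(chain, keys)) next
    out <- syllables_to_word(slots, cand)
    if (identical(out, template) || out %in% lexicon) next
    return(out)
  }
  stop("no pseudoword found for template ", dQuote(template), " within ",
       max_attempts, " attempts", call. = FALSE)
}

# Flatten a segmentation into its nonempty slots (type + value + syllable).
slot_table <- function(seg) {
  rows <- list()
  for (k in seq_len(nrow(seg))) {
    if (nzchar(seg$onset[k])) {
      rows[[length(rows) + 1L]] <- data.frame(type = "O",
                                              value = seg$onset[k],
                                              syll = k)
    }
    rows[[length(rows) + 1L]] <- data.frame(type = "N",
                                            value = seg$nucleus[k],
                                            syll = k)
    if (nzchar(seg$coda[k])) {
      rows[[length(rows) + 1L]] <- data.frame(type = "C",
                                              value = seg$coda[k],
                                              syll = k)
    }
  }
  do.call(rbind, rows)
}

syllables_to_word <- function(slots, values) {
  paste(values, collapse = "")
}
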