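test_that("a default instrument has the 50 + 20 design with unit-sum
           weights and per-tier composition", {
  inst <- fixture_instrument()
  items <- inst$items
  expect_equal(nrow(items), 70L)
  expect_equal(sum(!items$is_pseudoword), 50L)
  expect_equal(sum(items$is_pseudoword), 20L)
  expect_equal(sum(items$weight), 1, tolerance = 1e-12)
  expect_false(anyDuplicated(items$surface) > 0)
  for (tier in 1:10) {
    expect_equal(sum(items$tier == tier & !items$is_pseudoword), 5L)
    expect_equal(sum(items$tier == tier & items$is_pseudoword), 2L)
  }
  # pseudoword templates never coincide with selected true words
  expect_length(intersect(items$template[items$is_pseudoword],
                          items$surface[!items$is_pseudoword]), 0)
})

test_that("per-tier composition holds across seeds and designs", {
  vocab <- fixture_vocab(1000)
  weighted <- compute_item_weights(vocab)
  part <- partition_tiers(weighted, 10)
  chain <- build_chain(vocab$word)
  for (seed in c(2, 17)) {
    inst <- build_instrument(part, chain, vocab$word,
                             words_per_tier = 3, pseudos_per_tier = 1,
                             seed = seed)
    expect_equal(nrow(inst$items), 40L)
    expect_equal(as.integer(table(inst$items$tier)), rep(4L, 10))
    expect_equal(sum(inst$items$weight), 1, tolerance = 1e-12)
  }
})

test_that("each pseudoword weight equals the mean true-word weight", {
  inst <- fixture_instrument()
  items <- inst$items
  mean_true <- mean(items$weight[!items$is_pseudoword])
  expect_equal(items$weight[items$is_pseudoword],
               rep(mean_true, 20), tolerance = 1e-12)
})

test_that("instrument construction is deterministic under the seed", {
  vocab <- fixture_vocab(1000)
  weighted <- compute_item_weights(vocab)
  part <- partition_tiers(weighted, 10)
  chain <- build_chain(vocab$word)
  a <- build_instrument(part, chain, vocab$word, seed = 42)
  b <- build_instrument(part, chain, vocab$word, seed = 42)
  expect_identical(a, b)
  f1 <- tempfile(); f2 <- tempfile()
  write_instrument(a, f1); write_instrument(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("tiers too small for the design raise a size error", {
  vocab <- fixture_vocab(1000)[1:30, ]
  weighted <- compute_item_weights(vocab)
  part <- partition_tiers(weighted, 10)
  chain <- build_chain(vocab$word)
  expect_error(build_instrument(part, chain, vocab$word, seed = 1),
               "need at least")
})

test_that("the master key answers true words 4 and pseudowords 1, over
           exactly the instrument's items", {
  inst <- fixture_instrument()
  key <- master_key(inst)
  expect_setequal(names(key), inst$items$item_id)
  expect_equal(sum(key == 4L), 50L)
  expect_equal(sum(key == 1L), 20L)
  expect_true(all(key[inst$items$item_id[inst$items$is_pseudoword]] == 1L))
})

test_that("parallel forms share no surface form and are reproducible", {
  vocab <- fixture_vocab(1000)
  weighted <- compute_item_weights(vocab)
  part <- partition_tiers(weighted, 10)
  chain <- build_chain(vocab$word)
  forms <- make_parallel_forms(part, chain, vocab$word, seed = 5)
  expect_length(intersect(forms$form_a$items$surface,
                          forms$form_b$items$surface), 0)
  for (f in forms) {
    expect_equal(nrow(f$items), 70L)
    expect_equal(sum(f$items$weight), 1, tolerance = 1e-12)
  }
  forms2 <- make_parallel_forms(part, chain, vocab$word, seed = 5)
  expect_identical(forms, forms2)
})

test_that("quality-control filtering keeps clean sheets and rejects
           failures and missing answers", {
  qc <- c(qc_1 = 4L, qc_2 = 1L, qc_3 = 4L)
  mk_sheet <- function(rid, qc_ans, extra = 2L) {
    data.frame(respondent_id = rid,
               item_id = c(names(qc_ans), "t1_1"),
               category = c(unname(qc_ans), extra))
  }
  sheets <- rbind(
    mk_sheet("good", c(qc_1 = 4L, qc_2 = 1L, qc_3 = 4L)),
    mk_sheet("cheat", c(qc_1 = 4L, qc_2 = 4L, qc_3 = 4L)),
    data.frame(respondent_id = "partial", item_id = c("qc_1", "t1_1"),
               category = c(4L, 2L)))
  res <- filter_responses(sheets, qc)
  expect_equal(unique(res$kept$respondent_id), "good")
  expect_false("qc_1" %in% res$kept$item_id)
  expect_equal(res$rejected$reason[res$rejected$respondent_id == "cheat"],
               "failed_qc")
  expect_equal(res$rejected$reason[res$rejected$respondent_id == "partial"],
               "missing")
})

test_that("seeded quality-control failures are rejected at exactly the
           seeded rate", {
  qc <- c(qc_1 = 4L)
  n <- 100
  fail <- seq_len(10)
  sheets <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(respondent_id = sprintf("r%03d", i),
               item_id = c("qc_1", "t1_1"),
               category = c(if (i %in% fail) 1L else 4L, 3L))
  }))
  res <- filter_responses(sheets, qc)
  expect_equal(length(unique(res$kept$respondent_id)), 90L)
  expect_equal(nrow(res$rejected), 10L)
})

test_that("instrument serialization round-trips and the respondent
           export hides the key", {
  inst <- fixture_instrument()
  f <- tempfile(fileext = ".json")
  write_instrument(inst, f)
  back <- read_instrument(f)
  expect_equal(back$items$item_id, inst$items$item_id)
  expect_equal(back$items$weight, inst$items$weight, tolerance = 1e-12)
  expect_equal(master_key(back), master_key(inst))

  fr <- tempfile(fileext = ".json")
  write_instrument(inst, fr, include_key = FALSE)
  txt <- paste(readLines(fr), collapse = "")
  expect_false(grepl("is_pseudoword|master_key|weight", txt))
  expect_error(read_instrument(fr), "administrator")
})
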