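test_that("disagreement weight matrices are symmetric, zero-diagonal
           and scheme-correct", {
  v <- disagreement_weights("linear")
  expect_equal(diag(v), rep(0, 4))
  expect_equal(v, t(v))
  expect_equal(v[1, 4], 3)
  vq <- disagreement_weights("quadratic")
  expect_equal(vq[1, 4], 9)
  expect_true(all(vq == v^2))
})

test_that("observed and chance disagreement match the hand-worked
           three-item case", {
  u <- c(i1 = 0.5, i2 = 0.3, i3 = 0.2)
  key <- c(i1 = 4L, i2 = 4L, i3 = 1L)
  sheet <- c(i1 = 4L, i2 = 3L, i3 = 1L)
  v <- disagreement_weights("linear")
  expect_equal(observed_disagreement(sheet, key, u, v), 0.3)
  # p1 = {4: .8, 1: .2}; p2 = {4: .5, 3: .3, 1: .2}
  expect_equal(chance_disagreement(sheet, key, u, v), 1.14)
  res <- generalized_kappa(sheet, key, u, v)
  expect_equal(res$kappa_raw, 1 - 0.3 / 1.14)
  expect_equal(res$kappa, res$kappa_raw)
})

test_that("agreement with the key scores exactly 1 and identical
           constant raters are flagged degenerate", {
  inst <- fixture_instrument()
  key <- master_key(inst)
  res <- generalized_kappa(key, key, item_weights(inst))
  expect_equal(res$q_obs, 0)
  expect_equal(res$kappa, 1)
  expect_false(res$degenerate)

  u <- c(a = 0.5, b = 0.5)
  const <- c(a = 2L, b = 2L)
  res2 <- generalized_kappa(const, const, u)
  expect_equal(res2$kappa, 1)
  expect_true(res2$degenerate)
})

test_that("uniform-weight generalized kappa equals the textbook
           contingency-table weighted kappa", {
  set.seed(101)
  for (scheme in c("linear", "quadratic")) {
    v <- disagreement_weights(scheme)
    for (rep in 1:200) {
      n <- sample(5:40, 1)
      ids <- sprintf("i%02d", seq_len(n))
      k <- stats::setNames(sample.int(4L, n, replace = TRUE), ids)
      l <- stats::setNames(sample.int(4L, n, replace = TRUE), ids)
      if (all(k == l)) next
      u <- stats::setNames(rep(1 / n, n), ids)
      mine <- generalized_kappa(l, k, u, v)
      oracle <- textbook_weighted_kappa(k, l, v)
      expect_equal(mine$q_obs, oracle$q_o, tolerance = 1e-10)
      expect_equal(mine$q_exp, oracle$q_e, tolerance = 1e-10)
      expect_equal(mine$kappa_raw, oracle$kappa, tolerance = 1e-10)
    }
  }
})

test_that("chance disagreement equals brute-force double summation for
           arbitrary weights", {
  set.seed(202)
  v <- disagreement_weights("linear")
  for (rep in 1:200) {
    n <- sample(3:30, 1)
    ids <- sprintf("i%02d", seq_len(n))
    k <- stats::setNames(sample.int(4L, n, replace = TRUE), ids)
    l <- stats::setNames(sample.int(4L, n, replace = TRUE), ids)
    w <- stats::runif(n)
    u <- stats::setNames(w / sum(w), ids)
    expect_equal(chance_disagreement(l, k, u, v),
                 brute_force_chance(l, k, u, v), tolerance = 1e-12)
  }
})

test_that("scores are invariant to item order and to scaling the
           disagreement weights", {
  set.seed(303)
  inst <- fixture_instrument()
  key <- master_key(inst)
  u <- item_weights(inst)
  v <- disagreement_weights("linear")
  for (rep in 1:20) {
    sheet <- random_sheet(key)
    base <- generalized_kappa(sheet, key, u, v)
    perm <- sample(names(key))
    permd <- generalized_kappa(sheet[perm], key[perm], u[perm], v)
    expect_equal(permd, base, tolerance = 1e-12)
    scaled <- generalized_kappa(sheet, key, u, v * 7.5)
    expect_equal(scaled$kappa_raw, base$kappa_raw, tolerance = 1e-12)
  }
})

test_that("moving one answer further from the key never raises kappa", {
  set.seed(404)
  inst <- fixture_instrument()
  key <- master_key(inst)
  u <- item_weights(inst)
  v <- disagreement_weights("linear")
  worse <- 0L
  for (rep in 1:50) {
    sheet <- random_sheet(key)
    n <- sample(names(key), 1)
    cur_d <- abs(sheet[n] - key[n])
    further <- (1:4)[abs(1:4 - key[n]) > cur_d]
    if (!length(further)) next
    pert <- sheet
    pert[n] <- sample(rep(further, 2), 1)
    k0 <- generalized_kappa(sheet, key, u, v)$kappa_raw
    k1 <- generalized_kappa(pert, key, u, v)$kappa_raw
    expect_lte(k1, k0 + 1e-12)
    worse <- worse + 1L
  }
  expect_gt(worse, 20)
})

test_that("misaligned items, bad categories and unnormalized weights
           are rejected", {
  key <- c(a = 4L, b = 1L)
  u <- c(a = 0.6, b = 0.4)
  expect_error(generalized_kappa(c(a = 4L, c = 1L), key, u),
               "do not match")
  expect_error(generalized_kappa(c(a = 4L, b = 5L), key, u), "1..4")
  expect_error(generalized_kappa(c(a = 4L, b = 1L), key, u * 2),
               "normalized")
  expect_error(generalized_kappa(unname(c(4L, 1L)), key, u), "named")
})

test_that("batch scoring matches per-sheet calls, orders by respondent
           and survives per-sheet failures", {
  inst <- fixture_instrument()
  key <- master_key(inst)
  u <- item_weights(inst)
  set.seed(505)
  good <- do.call(rbind, lapply(c("r2", "r1"), function(rid) {
    data.frame(respondent_id = rid, item_id = names(key),
               category = as.integer(random_sheet(key)))
  }))
  bad <- data.frame(respondent_id = "rX",
                    item_id = names(key)[1:10],
                    category = rep(2L, 10))
  res <- score_batch(rbind(good, bad), inst)
  expect_equal(res$respondent_id, c("r1", "r2"))
  expect_equal(attr(res, "failures")$respondent_id, "rX")
  for (rid in c("r1", "r2")) {
    sub <- good[good$respondent_id == rid, ]
    solo <- generalized_kappa(
      stats::setNames(sub$category, sub$item_id), key, u)
    expect_equal(res$kappa[res$respondent_id == rid], solo$kappa)
  }
  empty <- score_batch(good[0, ], inst)
  expect_equal(nrow(empty), 0L)
})
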