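# Laplacian-corrected naive Bayes: hand-checked weights, brute-force oracle
# equality, additivity, and the augmentation arithmetic.

test_that("weights match hand-evaluated Laplacian-corrected densities", {
  # 10 compounds, 2 active (base rate 0.2);
  # feature 1: N=4, A=2 -> ln(3 / (5 * 0.2)) = ln 3
  # feature 2: N=9, A=0 -> ln(1 / (10 * 0.2)) = -0.693
  fps <- tibble::tibble(
    compound_id = sprintf("c%02d", 1:10),
    fp_bits = c(list(c(1L, 2L), c(1L, 2L)),                  # actives
                list(c(1L, 2L), c(1L, 2L)),
                rep(list(2L), 5), list(3L)))
  m <- bayes_fit(fps, c("c01", "c02"))
  w <- tidy(m)
  expect_equal(m$base_rate, 0.2)
  expect_equal(w$weight[w$feature == 1], log(3))
  expect_equal(w$weight[w$feature == 1], 1.0986, tolerance = 1e-4)
  expect_equal(w$weight[w$feature == 2], log(3 / (10 * 0.2)))
  f3 <- log((0 + 1) / ((1 + 1) * 0.2))
  expect_equal(w$weight[w$feature == 3], f3)

  expect_error(bayes_fit(fps, character(0)), "subset")
  expect_error(bayes_fit(fps, fps$compound_id), "subset")
})

test_that("an uninformative feature's weight vanishes in the large-count limit", {
  n <- 4000; n_act <- 800                     # base rate 0.2
  fps <- tibble::tibble(
    compound_id = sprintf("c%05d", 1:n),
    fp_bits = c(rep(list(1L), n_act * 5), rep(list(2L), n - n_act * 5)))
  # every compound with feature 1; actives are the first 800 -> A/N = 0.2
  m <- bayes_fit(fps, sprintf("c%05d", 1:n_act))
  w <- tidy(m)
  expect_equal(w$weight[w$feature == 1], 0, tolerance = 1e-3)
})

test_that("scoring sums present-feature weights and ignores unknown features", {
  fps <- tibble::tibble(compound_id = c("a", "b", "c", "d"),
                        fp_bits = list(c(1L, 2L), 2L, 3L, integer(0)))
  m <- bayes_fit(fps, "a")
  sc <- bayes_score(fps, m)
  expect_equal(sc$score[sc$compound_id == "d"], 0)  # empty fingerprint
  w <- m$weights
  expect_equal(sc$score[sc$compound_id == "c"], unname(w["3"]))
  # unknown feature contributes nothing
  alien <- tibble::tibble(compound_id = "z", fp_bits = list(c(3L, 99L)))
  expect_equal(bayes_score(alien, m)$score, unname(w["3"]))
})

test_that("fit and score agree with a brute-force oracle on random instances", {
  for (rep in 1:12) {
    withr::with_seed(100 + rep, {
      n <- sample(5:50, 1)
      n_feat <- sample(3:16, 1)
      fps <- tibble::tibble(
        compound_id = sprintf("c%03d", seq_len(n)),
        fp_bits = lapply(seq_len(n), function(i) {
          sort(sample.int(n_feat, sample(0:n_feat, 1)))
        }))
      n_act <- sample(seq_len(n - 1), 1)
      act <- sample(fps$compound_id, n_act)
    })
    m <- bayes_fit(fps, act)
    sc <- bayes_score(fps, m)
    oracle <- nb_oracle(fps$fp_bits, fps$compound_id %in% act, seq_len(n_feat))
    expect_equal(sort(names(m$weights)), sort(names(oracle$weights)))
    expect_equal(m$weights[names(oracle$weights)], oracle$weights,
                 tolerance = 1e-12)
    expect_equal(sc$score, unname(oracle$scores), tolerance = 1e-12)
  }
})

test_that("scores are additive over disjoint fingerprint unions", {
  withr::with_seed(9, {
    fps <- tibble::tibble(
      compound_id = sprintf("c%03d", 1:30),
      fp_bits = lapply(1:30, function(i) sort(sample.int(40, 8))))
  })
  m <- bayes_fit(fps, fps$compound_id[1:5])
  a <- list(c(1L, 5L, 9L)); b <- list(c(2L, 7L))
  s <- function(bits) bayes_score(tibble::tibble(compound_id = "x",
                                                 fp_bits = bits), m)$score
  expect_equal(s(list(c(1L, 2L, 5L, 7L, 9L))), s(a) + s(b))
})

test_that("augmentation unions the top-ranked list with the actives", {
  # 3107 actives; top-500 contains 230 of them plus 270 others -> 3377
  actives <- sprintf("A%04d", 1:3107)
  others <- sprintf("N%05d", 1:6893)
  scores <- tibble::tibble(
    compound_id = c(actives, others),
    score = c(seq(1000, by = -0.1, length.out = 230),    # top actives
              rep(-100, 3107 - 230),
              seq(900, by = -0.1, length.out = 270),     # top non-actives
              rep(-200, 6893 - 270)))
  res <- augment_actives(scores, actives, top_n = 500)
  expect_identical(length(intersect(res$top_ids, actives)), 230L)
  expect_identical(res$n_added, 270L)
  expect_identical(length(res$augmented), 3377L)

  expect_identical(augment_actives(scores, actives, 0)$augmented,
                   sort(actives))
  all_act <- augment_actives(scores, actives,
                             top_n = 100)$n_added  # top-100 all active
  expect_identical(all_act, 0L)
  expect_error(augment_actives(scores, actives, nrow(scores) + 1), "exceeds")
})

test_that("ranking ties break deterministically by compound id", {
  sc <- tibble::tibble(compound_id = c("b", "a", "c"), score = c(1, 1, 0))
  expect_identical(augment_actives(sc, character(0), 2)$top_ids, c("a", "b"))
})
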