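test_that("emotion ranking is a strict permutation with fixed tie order", {
  r <- rank_emotions(c(a = 0.5, b = 0.3, c = 0.2, d = 0, e = 0, f = 0, g = 0))
  expect_equal(unname(r), 1:7)

  tie <- setNames(rep(0.2, 7), letters[1:7])
  expect_equal(unname(rank_emotions(tie)), 1:7)

  expect_error(rank_emotions(setNames(rep(0, 7), letters[1:7])), "empty")

  set.seed(13)
  for (rep in 1:25) {
    v <- setNames(sample(c(0, 0.1, 0.25, 0.3, 0.3), 7, replace = TRUE) +
                    runif(7) * sample(0:1, 7, replace = TRUE), letters[1:7])
    if (all(v == 0)) next
    expect_equal(unname(rank_emotions(v)), oracle_rank_row(unname(v)))
    expect_setequal(rank_emotions(v), 1:7)
  }
})

test_that("phase covariance matches the direct Pearson formula", {
  # identical and perfectly opposed series
  base <- matrix(runif(5 * 7), 5, 7)
  base[, 2] <- base[, 1]
  base[, 3] <- -base[, 1] + 1
  M <- make_emotion_matrix(base)
  cv <- phase_covariance(M, whole_phase(M))
  expect_equal(cv$r["joy", "anger"], 1)
  expect_equal(cv$r["joy", "sadness"], -1)

  # toy phase with small integers vs textbook formula
  toy <- make_emotion_matrix(matrix(c(1, 2, 3, 4, 5,
                                      2, 4, 5, 4, 1,
                                      5, 4, 3, 2, 1,
                                      rep(1, 5 * 4)), 5, 7))
  cvt <- phase_covariance(toy, whole_phase(toy))
  for (i in 1:3) {
    for (j in 1:3) {
      expect_equal(cvt$r[i, j],
                   oracle_pearson(unclass(toy)[, i], unclass(toy)[, j]),
                   tolerance = 1e-12)
    }
  }
  # constant series are flagged undefined
  expect_true(all(is.na(cvt$r[4, ])))

  few <- make_emotion_matrix(matrix(runif(14), 2, 7))
  expect_error(phase_covariance(few, whole_phase(few)), "at least 3")
})

test_that("covariance ignores empty units and is affine invariant", {
  set.seed(29)
  vals <- matrix(runif(6 * 7), 6, 7)
  M <- make_emotion_matrix(vals, empty = c(FALSE, TRUE, FALSE, FALSE,
                                           FALSE, FALSE))
  cv <- phase_covariance(M, whole_phase(M))
  expect_equal(cv$n_units, 5L)
  direct <- suppressWarnings(cor(vals[-2, ]))
  expect_equal(unname(cv$r), unname(direct), tolerance = 1e-12)

  # positive affine transform of one label's series leaves r unchanged
  vals2 <- vals
  vals2[, 3] <- 4.2 * vals2[, 3] + 0.7
  cv2 <- phase_covariance(make_emotion_matrix(vals2,
                                              empty = attr(M, "empty")),
                          whole_phase(M))
  expect_equal(cv2$r, cv$r, tolerance = 1e-12)
})

test_that("transition matrices count rank matches between neighbours", {
  # constant ranking over m units: (m-1) x identity
  vals <- matrix(rep(c(7, 6, 5, 4, 3, 2, 1) / 28, each = 4), 4, 7)
  M <- make_emotion_matrix(vals)
  tr <- transition_matrix(M, whole_phase(M))
  expect_equal(unname(unclass(tr)), diag(3L, 7L) * 1L + 0L,
               ignore_attr = TRUE)
  expect_equal(sum(tr), 7L * 3L)

  # full rank reversal between two units: anti-diagonal
  rev2 <- rbind(seq(0.7, 0.1, by = -0.1), seq(0.1, 0.7, by = 0.1))
  M2 <- make_emotion_matrix(rev2)
  tr2 <- transition_matrix(M2, whole_phase(M2))
  expect_equal(unname(unclass(tr2)), unname(diag(7)[, 7:1]) + 0L,
               ignore_attr = TRUE)

  one <- make_emotion_matrix(matrix(runif(7), 1, 7))
  expect_error(transition_matrix(one, whole_phase(one)), "at least 2")
})

test_that("transitions equal the brute-force double loop on random sequences", {
  set.seed(37)
  for (rep in 1:10) {
    m <- sample(3:6, 1)
    vals <- matrix(runif(m * 7), m, 7)
    M <- make_emotion_matrix(vals)
    tr <- transition_matrix(M, whole_phase(M))
    ranks <- t(apply(vals, 1, oracle_rank_row))
    expect_equal(unname(unclass(tr)), oracle_transition(ranks),
                 ignore_attr = TRUE)
    # conservation: every row and column sums to the number of pairs
    expect_true(all(rowSums(tr) == m - 1))
    expect_true(all(colSums(tr) == m - 1))
  }
})

test_that("transitions skip empty units and depend only on ranks", {
  set.seed(41)
  vals <- matrix(runif(5 * 7), 5, 7)
  M <- make_emotion_matrix(vals, empty = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  tr <- transition_matrix(M, whole_phase(M))
  expect_equal(attr(tr, "n_pairs"), 3L)
  expect_equal(attr(tr, "n_skipped"), 1L)

  # strictly monotone transform within each unit preserves the matrix
  M2 <- make_emotion_matrix(exp(3 * vals), empty = attr(M, "empty"))
  expect_equal(unclass(transition_matrix(M2, whole_phase(M2))),
               unclass(tr))
})

test_that("a dominant planted emotion owns the transition diagonal maximum", {
  # full-size lexicon so document frequencies stay unsaturated and idf > 0
  lex <- generate_lexicon(seed = 55)
  n_days <- 8
  W <- matrix((1 - 0.82) / 6, n_days, 7,
              dimnames = list(NULL, emotion_categories()))
  W[, "love"] <- 0.82
  cfg <- generator_config(seed = 55, n_days = n_days,
                          date_start = as.Date("2020-02-01"),
                          posts_per_day = c(common = 60, large = 0),
                          n_users = c(common = 20L, large = 0L),
                          emotion_trajectory = W)
  gen <- generate_corpus(cfg, lex)
  docs <- bucket_documents(gen$corpus)
  M <- suppressWarnings(build_emotion_matrix(docs, lex))
  tr <- transition_matrix(M, list(label = "all", start = docs$date[1],
                                  end = docs$date[n_days]))
  expect_equal(names(which.max(diag(unclass(tr)))), "love")
  expect_equal(max(unclass(tr)), unclass(tr)["love", "love"])
})
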