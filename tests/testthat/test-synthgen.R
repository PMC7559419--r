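test_that("generated lexicons cover the scheme and are substring-free", {
  lex <- generate_lexicon(seed = 1, words_per_subcategory = 2)
  expect_equal(nrow(lex$entries), 42L)
  expect_setequal(unique(lex$entries$category), emotion_categories())
  expect_setequal(unique(lex$entries$subcategory),
                  subcategory_scheme()$subcategory)
  expect_true(all(lex$entries$degree %in% c(1, 3, 5, 7, 9)))

  # exhaustive pairwise substring scan
  w <- lex$entries$word
  for (i in seq_along(w)) {
    hits <- vapply(w[-i], function(x) grepl(w[i], x, fixed = TRUE), TRUE)
    expect_false(any(hits), label = sprintf("word %s is a substring", w[i]))
  }

  # same seed -> byte-identical files
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_lexicon(generate_lexicon(seed = 5, words_per_subcategory = 3), p1)
  write_lexicon(generate_lexicon(seed = 5, words_per_subcategory = 3), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("corpus generation is seed-deterministic and seed-sensitive", {
  lex <- generate_lexicon(seed = 8, words_per_subcategory = 2)
  cfg <- function(s) generator_config(seed = s, n_days = 5,
                                      date_start = as.Date("2020-02-01"),
                                      posts_per_day = c(common = 15, large = 3),
                                      n_users = c(common = 10L, large = 2L))
  a <- generate_corpus(cfg(4), lex)
  b <- generate_corpus(cfg(4), lex)
  c <- generate_corpus(cfg(9), lex)
  expect_identical(a$corpus$records, b$corpus$records)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$corpus$records, c$corpus$records))
})

test_that("generated corpora pass loading validation with zero rejects", {
  lex <- generate_lexicon(seed = 12, words_per_subcategory = 2)
  cfg <- generator_config(seed = 12, n_days = 4,
                          date_start = as.Date("2020-02-01"),
                          posts_per_day = c(common = 12, large = 3),
                          n_users = c(common = 8L, large = 2L))
  gen <- generate_corpus(cfg, lex)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(gen$corpus, path)
  expect_no_warning(back <- read_corpus(path))
  expect_null(attr(back, "rejected"))
  expect_equal(nrow(back$records), nrow(gen$corpus$records))
})

test_that("a pure single-category mixture is recovered exactly", {
  # full-size lexicon so document frequencies stay unsaturated and idf > 0
  lex <- generate_lexicon(seed = 14)
  n_days <- 6
  W <- matrix(0, n_days, 7, dimnames = list(NULL, emotion_categories()))
  W[, "joy"] <- 1
  cfg <- generator_config(seed = 14, n_days = n_days,
                          date_start = as.Date("2020-02-01"),
                          posts_per_day = c(common = 20, large = 0),
                          n_users = c(common = 10L, large = 0L),
                          emotion_trajectory = W)
  gen <- generate_corpus(cfg, lex)
  docs <- bucket_documents(gen$corpus)
  M <- suppressWarnings(build_emotion_matrix(docs, lex))
  nonempty <- !attr(M, "empty")
  expect_true(any(nonempty))
  expect_equal(unname(M[nonempty, "joy"]), rep(1, sum(nonempty)),
               tolerance = 1e-12)
})

test_that("announcement probability one plants a recoverable skeleton", {
  lex <- generate_lexicon(seed = 16, words_per_subcategory = 2)
  cfg <- generator_config(seed = 16, n_days = 7,
                          date_start = as.Date("2020-02-05"),
                          posts_per_day = c(common = 6, large = 2),
                          n_users = c(common = 6L, large = 2L))
  gen <- generate_corpus(cfg, lex)
  expect_length(gen$truth$announcement_days, 7L)
  sk <- extract_case_counts(bucket_documents(gen$corpus))
  expect_equal(sk$n_new, gen$truth$epidemic_curve$n_new)
  expect_equal(sk$n_acc, gen$truth$epidemic_curve$n_acc)
})

test_that("the large group always crosses the comment threshold", {
  lex <- generate_lexicon(seed = 18, words_per_subcategory = 2)
  cfg <- generator_config(seed = 18, n_days = 2,
                          date_start = as.Date("2020-02-01"),
                          posts_per_day = c(common = 5, large = 2),
                          n_users = c(common = 5L, large = 2L),
                          engagement_scale = c(common = 1, large = 1))
  gen <- generate_corpus(cfg, lex)
  large_users <- gen$truth$user_groups$user_id[
    gen$truth$user_groups$group == "large"]
  lu <- gen$corpus$records$user_id %in% large_users
  expect_true(any(gen$corpus$records$n_comment[lu] > 1000))
})

test_that("infeasible configurations are rejected", {
  expect_error(generator_config(topics = default_topic_catalog()[0, ]),
               "infeasible")
  bad_traj <- matrix(1 / 7, 3, 7)
  bad_traj[1, 1] <- 0.9
  expect_error(generator_config(n_days = 3, emotion_trajectory = bad_traj))
})

test_that("simulate_dataset writes a loadable, self-consistent bundle", {
  out <- withr::local_tempdir()
  sim <- simulate_dataset(out, seed = 2, words_per_subcategory = 2,
                          config = generator_config(
                            seed = 2, n_days = 3,
                            date_start = as.Date("2020-02-01"),
                            posts_per_day = c(common = 8, large = 2),
                            n_users = c(common = 6L, large = 2L)))
  expect_true(all(file.exists(sim$paths)))
  lex <- read_lexicon(sim$paths[["lexicon"]])
  corp <- read_corpus(sim$paths[["corpus"]])
  truth <- jsonlite::fromJSON(sim$paths[["truth"]])
  expect_equal(nrow(corp$records), nrow(sim$corpus$records))
  expect_equal(truth$epidemic_curve$n_new,
               sim$truth$epidemic_curve$n_new)
  expect_equal(nrow(lex$entries), 42L)
})
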