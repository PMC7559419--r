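corpus_line <- function(id = "a1", n_like = 3, created = "2020-02-01T10:00:00+0800") {
  sprintf(paste0(
    '{"id":"%s","user_id":"u1","created_at":"%s","text":"hi",',
    '"super_topic":"t1","topic_category":"isolation","n_retweet":1,',
    '"n_comment":2,"n_like":%s,"topic_discussions":10,"topic_reads":100}'),
    id, created, n_like)
}

test_that("corpus loading accepts valid lines and reports rejects", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(corpus_line("a1"), corpus_line("a2"), corpus_line("a3")), path)
  corp <- read_corpus(path)
  expect_equal(nrow(corp$records), 3L)

  writeLines(c(corpus_line("a1"), corpus_line("a2", n_like = -1)), path)
  expect_warning(corp <- read_corpus(path), "rejected")
  expect_equal(nrow(corp$records), 1L)
  expect_equal(attr(corp, "rejected")$line, 2L)

  writeLines(c(corpus_line("a1"),
               corpus_line("a2", created = "not-a-date")), path)
  expect_warning(corp <- read_corpus(path), "rejected")
  expect_equal(attr(corp, "rejected")$reason, "unparseable timestamp")

  writeLines(sub('"n_like":3,', "", corpus_line("a1")), path)
  expect_error(read_corpus(path), "missing field 'n_like'")
})

test_that("write/read round trip preserves a generated corpus exactly", {
  lex <- generate_lexicon(seed = 3, words_per_subcategory = 2)
  cfg <- generator_config(seed = 3, n_days = 4,
                          date_start = as.Date("2020-02-01"),
                          posts_per_day = c(common = 10, large = 2),
                          n_users = c(common = 10L, large = 2L))
  corp <- generate_corpus(cfg, lex)$corpus
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corp, path)
  back <- read_corpus(path)
  expect_null(attr(back, "rejected"))
  expect_equal(back$records$id, corp$records$id)
  expect_equal(back$records$text, corp$records$text)
  expect_equal(as.numeric(back$records$created_at),
               as.numeric(corp$records$created_at))
  expect_equal(back$records$n_comment, corp$records$n_comment)
  expect_equal(back$records$topic_reads, corp$records$topic_reads)
})

test_that("topic-size filter uses a strict 'fewer than' boundary", {
  r50 <- make_records(50, super_topic = "big")
  r49 <- make_records(49, super_topic = "small")
  r49$id <- paste0("s", r49$id)
  corp <- as_corpus(rbind(r50, r49))
  kept <- filter_corpus(corp, min_topic_posts = 50)
  expect_setequal(unique(kept$records$super_topic), "big")
  expect_equal(nrow(kept$records), 50L)
  # threshold met exactly: retained
  expect_equal(nrow(filter_corpus(corp, 49)$records), 99L)
})

test_that("filtering equals a brute-force two-pass filter and is idempotent", {
  set.seed(11)
  n <- 120
  recs <- make_records(n)
  recs$super_topic <- sample(paste0("t", 1:5), n, replace = TRUE)
  days <- seq(as.Date("2020-02-01"), by = "day", length.out = 10)
  recs$created_at <- as.POSIXct(paste(sample(as.character(days), n, TRUE),
                                      "10:00:00"), tz = "Asia/Shanghai")
  corp <- as_corpus(recs, date_range = range(days))
  ds <- as.Date("2020-02-03"); de <- as.Date("2020-02-08")
  got <- filter_corpus(corp, min_topic_posts = 10,
                       date_start = ds, date_end = de)

  # brute force: date window first, then topic sizes within the window
  dt <- as.Date(recs$created_at, tz = "Asia/Shanghai")
  in_win <- dt >= ds & dt <= de
  win_sizes <- table(recs$super_topic[in_win])
  keep <- in_win & recs$super_topic %in%
    names(win_sizes)[win_sizes >= 10]
  expect_setequal(got$records$id, recs$id[keep])

  twice <- filter_corpus(got, min_topic_posts = 10,
                         date_start = ds, date_end = de)
  expect_equal(twice$records, got$records)

  # alternative reading: topic sizes counted on the unrestricted input
  alt <- filter_corpus(corp, min_topic_posts = 25, date_start = ds,
                       date_end = de, topic_filter_first = TRUE)
  sizes <- table(recs$super_topic)
  keep_alt <- sizes[recs$super_topic] >= 25 & in_win
  expect_setequal(alt$records$id, recs$id[keep_alt])
})

test_that("user classification uses a strict comment threshold", {
  recs <- rbind(make_records(1, user_id = "just_over", n_comment = 1001),
                make_records(1, user_id = "exactly", n_comment = 1000),
                make_records(1, user_id = "quiet", n_comment = 3))
  recs$id <- paste0("r", 1:3)
  g <- classify_users(as_corpus(recs))
  expect_equal(g$group[g$user_id == "just_over"], "large")
  expect_equal(g$group[g$user_id == "exactly"], "common")
  expect_equal(g$group[g$user_id == "quiet"], "common")
})

test_that("user classification matches a per-user max scan, order invariant", {
  set.seed(5)
  n <- 300
  recs <- make_records(n)
  recs$user_id <- sample(sprintf("u%03d", 1:100), n, replace = TRUE)
  recs$n_comment <- sample(c(0:20, 900:1100, 5000), n, replace = TRUE)
  corp <- as_corpus(recs)
  g <- classify_users(corp)
  mx <- tapply(recs$n_comment, recs$user_id, max)
  for (u in names(mx)) {
    expect_equal(g$group[g$user_id == u],
                 if (mx[[u]] > 1000) "large" else "common")
  }
  shuf <- as_corpus(recs[sample(n), ])
  expect_equal(classify_users(shuf), g)
})

test_that("day bucketing partitions the corpus and flags empty days", {
  recs <- make_records(3, date = "2020-02-01")
  corp <- as_corpus(recs, date_range = as.Date(c("2020-02-01", "2020-02-01")))
  docs <- bucket_documents(corp)
  expect_length(docs$date, 1L)
  expect_equal(docs$n_posts, 3L)
  expect_false(docs$empty)

  corp3 <- as_corpus(recs, date_range = as.Date(c("2020-02-01", "2020-02-03")))
  docs3 <- bucket_documents(corp3)
  expect_equal(docs3$empty, c(FALSE, TRUE, TRUE))
  expect_equal(docs3$text[2], "")

  # 30-day generated corpus: membership equals brute-force date bucketing
  lex <- generate_lexicon(seed = 9, words_per_subcategory = 2)
  cfg <- generator_config(seed = 9, n_days = 30,
                          date_start = as.Date("2020-01-15"),
                          posts_per_day = c(common = 8, large = 2),
                          n_users = c(common = 12L, large = 3L))
  gc2 <- generate_corpus(cfg, lex)$corpus
  docs30 <- bucket_documents(gc2)
  r <- gc2$records
  dt <- as.Date(r$created_at, tz = gc2$tz)
  for (j in seq_along(docs30$date)) {
    expect_setequal(docs30$member_ids[[j]], r$id[dt == docs30$date[j]])
  }
  expect_equal(sort(unlist(docs30$member_ids)), sort(r$id))
})

test_that("group engagement means are exact and planted scales recovered", {
  recs <- make_records(2, n_like = c(10, 30), topic_category = "treatment")
  recs$n_retweet <- c(1, 3); recs$n_comment <- c(2, 4)
  corp <- as_corpus(recs)
  g <- classify_users(corp)
  st <- group_engagement_stats(corp, g)
  expect_equal(st$mean_likes, 20)
  expect_equal(st$mean_retweets, 2)
  expect_equal(st$n_posts, 2L)

  # planted group scale: large-group means exceed common in every column
  lex <- generate_lexicon(seed = 4, words_per_subcategory = 2)
  cfg <- generator_config(seed = 4, n_days = 6,
                          date_start = as.Date("2020-02-01"),
                          posts_per_day = c(common = 25, large = 8),
                          n_users = c(common = 30L, large = 4L))
  gen <- generate_corpus(cfg, lex)
  truth_groups <- setNames(gen$truth$user_groups$group,
                           gen$truth$user_groups$user_id)
  ga <- data.frame(user_id = unique(gen$corpus$records$user_id),
                   stringsAsFactors = FALSE)
  ga$group <- ifelse(is.na(truth_groups[ga$user_id]), "common",
                     truth_groups[ga$user_id])
  class(ga) <- c("user_groups", "data.frame")
  st2 <- group_engagement_stats(gen$corpus, ga)
  for (col in c("mean_retweets", "mean_comments", "mean_likes")) {
    lg <- st2[[col]][st2$group == "large"]
    cm <- st2[[col]][st2$group == "common"]
    expect_gt(min(lg), max(cm))
  }
})
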