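# Fixtures and independent oracles. Every oracle is a deliberately naive
# re-implementation (brute force / straight-line formula evaluation) that
# shares no helpers with the package code paths it checks.

# small handmade lexicon with prefix pairs to exercise leftmost-longest
tiny_lexicon <- function() {
  emotion_lexicon(data.frame(
    word = c("hooray", "hoo", "gloom", "gloomy", "rage", "dread",
             "yuck", "adore", "whoa"),
    category = c("joy", "joy", "sadness", "sadness", "anger", "fear",
                 "disgust", "love", "surprise"),
    subcategory = c("happiness", "happiness", "grief", "disappointment",
                    "rage", "fright", "hatred", "fondness", "amazement"),
    degree = c(5L, 1L, 7L, 3L, 9L, 5L, 3L, 7L, 1L),
    stringsAsFactors = FALSE))
}

# brute-force leftmost-longest scan: every start position, all words by
# decreasing length, advance past accepted matches
oracle_match <- function(text, words) {
  text <- stringi::stri_trans_nfc(text)
  words <- words[order(-nchar(words), words)]
  counts <- setNames(integer(length(words)), words)
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    hit <- NA_character_
    for (w in words) {
      if (substr(text, i, i + nchar(w) - 1L) == w) {
        hit <- w
        break
      }
    }
    if (!is.na(hit)) {
      counts[hit] <- counts[hit] + 1L
      i <- i + nchar(hit)
    } else {
      i <- i + 1L
    }
  }
  counts <- counts[counts > 0L]
  counts[order(names(counts))]
}

# hand-build a document_set from texts (one per day)
make_docs <- function(texts, start = as.Date("2020-02-01")) {
  k <- length(texts)
  structure(list(date = seq(start, by = "day", length.out = k),
                 text = texts,
                 member_ids = replicate(k, character(0L), simplify = FALSE),
                 n_posts = rep(1L, k),
                 empty = !nzchar(texts),
                 tz = "Asia/Shanghai"),
            class = "document_set")
}

# hand-build an emotion_matrix from a plain value matrix
make_emotion_matrix <- function(M, start = as.Date("2020-02-01"),
                                empty = rep(FALSE, nrow(M))) {
  colnames(M) <- colnames(M) %||% emotion_categories()
  dates <- seq(start, by = "day", length.out = nrow(M))
  rownames(M) <- as.character(dates)
  structure(M, dates = dates, empty = empty, resolution = "category",
            class = c("emotion_matrix", class(M)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

whole_phase <- function(M) {
  d <- attr(M, "dates")
  list(label = "phase1", start = min(d), end = max(d))
}

# convenience record builder with sane defaults
make_records <- function(n, date = "2020-02-01", user_id = "u1",
                         text = "hello", super_topic = "t1",
                         topic_category = "confirmed_cases",
                         n_retweet = 0, n_comment = 0, n_like = 0,
                         topic_discussions = 0, topic_reads = 0,
                         hour = 10) {
  data.frame(
    id = sprintf("id%04d", seq_len(n)),
    user_id = rep_len(user_id, n),
    created_at = as.POSIXct(paste(rep_len(date, n),
                                  sprintf("%02d:00:00", rep_len(hour, n))),
                            tz = "Asia/Shanghai"),
    text = rep_len(text, n),
    super_topic = rep_len(super_topic, n),
    topic_category = rep_len(topic_category, n),
    n_retweet = rep_len(n_retweet, n),
    n_comment = rep_len(n_comment, n),
    n_like = rep_len(n_like, n),
    topic_discussions = rep_len(topic_discussions, n),
    topic_reads = rep_len(topic_reads, n),
    stringsAsFactors = FALSE)
}

# random per-document term-count maps over a lexicon, plus texts whose
# matching recovers exactly those counts (words joined by spaces)
random_count_corpus <- function(lexicon, k, max_terms = 20L) {
  words <- lexicon$entries$word
  count_maps <- vector("list", k)
  texts <- character(k)
  for (j in seq_len(k)) {
    n_terms <- sample(0:min(max_terms, length(words)), 1L)
    if (n_terms == 0L) {
      count_maps[[j]] <- setNames(integer(0L), character(0L))
      texts[j] <- ""
      next
    }
    w <- sample(words, n_terms)
    cnt <- sample(1:3, n_terms, replace = TRUE)
    count_maps[[j]] <- setNames(cnt, w)[order(w)]
    texts[j] <- paste(sample(rep(w, cnt)), collapse = " ")
  }
  list(count_maps = count_maps, docs = make_docs(texts))
}

# straight-line evaluation of tf, idf, degree-weighted ratio and
# accumulated emotion from raw count maps (no shared helpers)
oracle_scores <- function(count_maps, lexicon, resolution = "category") {
  lex_df <- lexicon$entries
  labels <- if (resolution == "category") emotion_categories() else
    subcategory_scheme()$subcategory
  label_of <- function(w) {
    row <- which(lex_df$word == w)
    if (resolution == "category") lex_df$category[row] else
      lex_df$subcategory[row]
  }
  k <- length(count_maps)
  ratio <- matrix(0, k, length(labels), dimnames = list(NULL, labels))
  acc <- matrix(0, k, length(labels), dimnames = list(NULL, labels))
  empty <- logical(k)
  for (j in seq_len(k)) {
    cm <- count_maps[[j]]
    if (length(cm) == 0L) {
      empty[j] <- TRUE
      next
    }
    total <- 0
    for (w in names(cm)) total <- total + cm[[w]]
    num <- setNames(numeric(length(labels)), labels)
    den <- 0
    for (w in names(cm)) {
      tf <- cm[[w]] / total
      dfw <- 0L
      for (jj in seq_len(k)) {
        if (w %in% names(count_maps[[jj]])) dfw <- dfw + 1L
      }
      idf <- log(k / (dfw + 1))
      L <- lex_df$degree[lex_df$word == w]
      lab <- label_of(w)
      num[lab] <- num[lab] + L * tf * idf
      den <- den + L * tf * idf
      acc[j, lab] <- acc[j, lab] + L * tf
    }
    if (den <= 0) {
      empty[j] <- TRUE
    } else {
      ratio[j, ] <- num / den
    }
  }
  list(ratio = ratio, acc = acc, empty = empty)
}

# textbook Pearson correlation, direct formula
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# stable-sort ranking oracle: rank of label = position in an order sorted
# by decreasing value, ties by original position
oracle_rank_row <- function(v) {
  n <- length(v)
  ranks <- integer(n)
  taken <- rep(FALSE, n)
  for (r in seq_len(n)) {
    best <- NA_integer_
    for (i in seq_len(n)) {
      if (taken[i]) next
      if (is.na(best) || v[i] > v[best]) best <- i
    }
    ranks[best] <- r
    taken[best] <- TRUE
  }
  ranks
}

# brute-force transition accumulation: double loop over label pairs and
# consecutive unit pairs of a rank-sequence matrix (rows = units)
oracle_transition <- function(rank_rows) {
  n <- ncol(rank_rows)
  Tm <- matrix(0L, n, n)
  for (i in seq_len(nrow(rank_rows) - 1L)) {
    for (p in seq_len(n)) {
      for (q in seq_len(n)) {
        if (rank_rows[i, p] == rank_rows[i + 1L, q]) {
          Tm[p, q] <- Tm[p, q] + 1L
        }
      }
    }
  }
  Tm
}

# counting-rank oracle: number of strictly greater values + 1
oracle_rank_counting <- function(v) {
  vapply(v, function(x) sum(v > x) + 1L, integer(1L))
}

# straight-line hot-degree evaluation for one engagement table
oracle_hot <- function(eng, w1 = 0.5, w2 = 0.5) {
  n <- nrow(eng)
  rk <- function(col) oracle_rank_counting(eng[[col]])
  sapply(seq_len(n), function(i) {
    w1 * (rk("mean_retweets")[i] + rk("mean_comments")[i] +
            rk("mean_likes")[i]) +
      w2 * (rk("discussions")[i] + rk("reads")[i])
  })
}

# random engagement table mimicking the generator's log-normal metrics,
# optionally with one topic boosted on all five metrics
random_engagement <- function(n_topics, sdlog = 1, boost_idx = NULL,
                              boost = 10) {
  eng <- data.frame(
    super_topic = sprintf("t%02d", seq_len(n_topics)),
    mean_retweets = rlnorm(n_topics, log(50), sdlog),
    mean_comments = rlnorm(n_topics, log(80), sdlog),
    mean_likes = rlnorm(n_topics, log(300), sdlog),
    discussions = rlnorm(n_topics, log(1e4), sdlog),
    reads = rlnorm(n_topics, log(1e6), sdlog),
    n_posts = sample(1:50, n_topics, replace = TRUE),
    stringsAsFactors = FALSE)
  if (!is.null(boost_idx)) {
    for (col in c("mean_retweets", "mean_comments", "mean_likes",
                  "discussions", "reads")) {
      eng[[col]][boost_idx] <- eng[[col]][boost_idx] * boost
    }
  }
  eng
}
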