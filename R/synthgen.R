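#' Default synthetic super-topic catalog
#'
#' Two super topics per topic category (18 in total) with popularity
#' weights, topic-level counter bases (discussions and reads per elapsed
#' day, reads two to three orders of magnitude above discussions, as on
#' real platforms) and an engagement boost factor of 1. Confirmed-case
#' topics are the most popular, mirroring real epidemic corpora where
#' case-announcement topics dominate.
#'
#' @return Data frame with columns `super_topic`, `category`, `weight`,
#'   `boost`, `disc_base`, `read_base`.
#' @export
default_topic_catalog <- function() {
  cats <- topic_categories()
  weight <- c(fighting_covid19 = 0.06, novel_coronavirus = 0.12,
              wenliang_li = 0.05, treatment = 0.05,
              epidemic_development = 0.12, epidemic_control = 0.05,
              confirmed_cases = 0.35, isolation = 0.10,
              support_wuhan = 0.10)
  out <- data.frame(
    super_topic = c(rbind(paste0("st_", cats, "_a"), paste0("st_", cats, "_b"))),
    category = rep(cats, each = 2L),
    weight = c(rbind(weight[cats] * 0.6, weight[cats] * 0.4)),
    boost = 1,
    stringsAsFactors = FALSE)
  out$disc_base <- round(2e4 * out$weight) + 100L
  out$read_base <- round(2e7 * out$weight) + 1e5
  rownames(out) <- NULL
  out
}

#' Default daily emotion mixture trajectory
#'
#' Per-day mixture weights over the seven emotion categories, drifting
#' linearly from an early-outbreak profile (fear and surprise dominant) to
#' a late profile (love and joy dominant, as public attention shifts to
#' support and recovery); each day's weights are non-negative and sum
#' to 1.
#'
#' @param n_days Number of days.
#' @return Numeric matrix `n_days x 7` with category column names.
#' @export
default_emotion_trajectory <- function(n_days) {
  start <- c(joy = 0.10, anger = 0.10, sadness = 0.15, fear = 0.25,
             disgust = 0.10, love = 0.15, surprise = 0.15)
  end <- c(joy = 0.20, anger = 0.08, sadness = 0.12, fear = 0.10,
           disgust = 0.08, love = 0.32, surprise = 0.10)
  a <- if (n_days == 1L) 0 else (seq_len(n_days) - 1L) / (n_days - 1L)
  W <- outer(1 - a, start) + outer(a, end)
  W <- W / rowSums(W)
  colnames(W) <- emotion_categories()
  W
}

#' Default synthetic epidemic curve
#'
#' Deterministic daily new-case counts: zero during a quiet lead-in,
#' quadratic growth from the outbreak onset to the peak, then a linear
#' decline; accumulated cases are the running sum. When the calendar dates
#' of the historical onset (10 Jan 2020) and peak (12 Feb 2020) fall inside
#' the range they are used; otherwise the onset sits at 30% and the peak at
#' 75% of the range.
#'
#' @param n_days Number of days.
#' @param date_start First day (`Date`).
#' @param peak_height New cases on the peak day (default 3000).
#' @return Data frame with columns `date`, `n_new`, `n_acc`.
#' @export
default_epidemic_curve <- function(n_days, date_start, peak_height = 3000L) {
  dates <- seq(as.Date(date_start), by = "day", length.out = n_days)
  idx_of <- function(d, frac) {
    i <- match(as.Date(d), dates)
    if (is.na(i)) max(1L, ceiling(frac * n_days)) else i
  }
  onset <- idx_of("2020-01-10", 0.30)
  peak <- idx_of("2020-02-12", 0.75)
  if (peak <= onset) peak <- min(n_days, onset + 1L)
  i <- seq_len(n_days)
  n_new <- integer(n_days)
  rise <- i >= onset & i <= peak
  n_new[rise] <- round(peak_height * ((i[rise] - onset) / (peak - onset))^2)
  fall <- i > peak
  n_new[fall] <- pmax(0L, round(peak_height * (1 - 0.12 * (i[fall] - peak))))
  data.frame(date = dates, n_new = as.integer(n_new),
             n_acc = as.integer(cumsum(n_new)))
}

#' Configuration of the synthetic corpus generator
#'
#' Bundles and validates everything the generator needs. The defaults
#' describe the study conditions the package is meant to analyse: a 58-day
#' window ending 17 February 2020 (so the 21 January - 17 February analysis
#' window lies inside it), a large common-user group and a small large-user
#' group with engagement roughly three orders of magnitude apart, nine
#' topic categories, emotion mixtures drifting from fear-dominant to
#' love-dominant, and one case announcement per day following the epidemic
#' curve.
#'
#' @param seed Integer seed; a fixed seed fully determines the corpus.
#' @param n_days Number of days (default 58).
#' @param date_start First day (default 2019-12-22).
#' @param posts_per_day Named numeric `c(common=, large=)`: Poisson mean
#'   posts per day per group (0 disables a group).
#' @param n_users Named integer `c(common=, large=)`: users per group.
#' @param topics Super-topic catalog as in [default_topic_catalog()].
#' @param emotion_trajectory `n_days x 7` mixture-weight matrix (rows sum
#'   to 1); default [default_emotion_trajectory()].
#' @param epidemic_curve Data frame `date, n_new, n_acc` (`n_acc`
#'   non-decreasing); default [default_epidemic_curve()].
#' @param announcement_prob Probability a day's text embeds the case
#'   announcement (default 1).
#' @param engagement_scale Named numeric `c(common=, large=)` multiplying
#'   the engagement location (default 1 and 1000).
#' @param words_per_post Poisson mean of emotion words per post, plus one
#'   guaranteed word (default 3).
#' @param fillers_per_post Poisson mean of neutral filler tokens per post,
#'   plus one (default 4).
#' @param n_fillers Size of the filler vocabulary (default 60).
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(seed = 1L, n_days = 58L,
                             date_start = as.Date("2019-12-22"),
                             posts_per_day = c(common = 200, large = 10),
                             n_users = c(common = 500L, large = 20L),
                             topics = default_topic_catalog(),
                             emotion_trajectory = NULL,
                             epidemic_curve = NULL,
                             announcement_prob = 1,
                             engagement_scale = c(common = 1, large = 1000),
                             words_per_post = 3,
                             fillers_per_post = 4,
                             n_fillers = 60L) {
  stopifnot(n_days >= 1L, announcement_prob >= 0, announcement_prob <= 1,
            all(c("common", "large") %in% names(posts_per_day)),
            all(c("common", "large") %in% names(n_users)),
            all(c("common", "large") %in% names(engagement_scale)),
            all(posts_per_day >= 0), all(n_users >= 0))
  date_start <- as.Date(date_start)
  if (!is.data.frame(topics) || nrow(topics) == 0L) {
    stop("infeasible config: topic catalog is empty")
  }
  need <- c("super_topic", "category", "weight", "boost",
            "disc_base", "read_base")
  stopifnot(all(need %in% names(topics)), all(topics$weight > 0),
            all(topics$boost > 0))
  emotion_trajectory <- emotion_trajectory %||% default_emotion_trajectory(n_days)
  stopifnot(is.matrix(emotion_trajectory),
            nrow(emotion_trajectory) == n_days,
            ncol(emotion_trajectory) == 7L,
            all(emotion_trajectory >= 0),
            all(abs(rowSums(emotion_trajectory) - 1) < 1e-9))
  if (is.null(colnames(emotion_trajectory))) {
    colnames(emotion_trajectory) <- emotion_categories()
  }
  epidemic_curve <- epidemic_curve %||% default_epidemic_curve(n_days, date_start)
  stopifnot(nrow(epidemic_curve) == n_days,
            all(c("date", "n_new", "n_acc") %in% names(epidemic_curve)),
            all(diff(epidemic_curve$n_acc) >= 0))
  structure(list(seed = as.integer(seed), n_days = as.integer(n_days),
                 date_start = date_start, posts_per_day = posts_per_day,
                 n_users = n_users, topics = topics,
                 emotion_trajectory = emotion_trajectory,
                 epidemic_curve = epidemic_curve,
                 announcement_prob = announcement_prob,
                 engagement_scale = engagement_scale,
                 words_per_post = words_per_post,
                 fillers_per_post = fillers_per_post,
                 n_fillers = as.integer(n_fillers),
                 tz = "Asia/Shanghai"),
            class = "generator_config")
}

#' Generate a synthetic emotion lexicon
#'
#' Synthetic vocabulary covering all 21 sub-emotions with
#' `words_per_subcategory` words each; degrees are sampled uniformly from
#' \{1, 3, 5, 7, 9\}. All words have the same character length, so no word
#' can be a substring of another and ground-truth term counts are exactly
#' recoverable by the matcher. The default size (150 words per
#' sub-emotion, 3150 words) is a scaled-down analogue of full affective
#' ontologies, large enough that document frequencies do not saturate on
#' realistic corpora.
#'
#' @param seed Integer seed.
#' @param words_per_subcategory Words per sub-emotion (at least 1).
#' @return An `emotion_lexicon`.
#' @export
generate_lexicon <- function(seed = 1L, words_per_subcategory = 150L) {
  stopifnot(words_per_subcategory >= 1L)
  set.seed(as.integer(seed))
  scheme <- subcategory_scheme()
  n <- nrow(scheme) * words_per_subcategory
  sub_idx <- rep(seq_len(nrow(scheme)), each = words_per_subcategory)
  word_idx <- rep(seq_len(words_per_subcategory), times = nrow(scheme))
  emotion_lexicon(data.frame(
    word = sprintf("qw%02d%04d", sub_idx, word_idx),
    category = scheme$category[sub_idx],
    subcategory = scheme$subcategory[sub_idx],
    degree = sample(c(1L, 3L, 5L, 7L, 9L), n, replace = TRUE),
    stringsAsFactors = FALSE))
}

#' Generate a synthetic microblog corpus with planted ground truth
#'
#' Simulates, day by day and group by group, posts whose emotion words are
#' drawn from the day's planted category mixture (uniformly within a
#' category) and joined with neutral filler tokens from a disjoint
#' alphabet, so true emotion-term counts are exactly recoverable. Post
#' engagement is log-normal with the group's location scale (large-group
#' engagement roughly three orders of magnitude above common, and at least
#' one large-group post is guaranteed to exceed 1000 comments when that
#' group is enabled); boosted topics have all five engagement metrics
#' multiplied by their boost factor. With the configured probability, each
#' day also carries an official bulletin post embedding the planted case
#' announcement in the default pattern language. Everything is a
#' deterministic function of the seed.
#'
#' @param config A `generator_config`.
#' @param lexicon An `emotion_lexicon` (typically from
#'   [generate_lexicon()]).
#' @return List with elements `corpus` (a `corpus`) and `truth` (planted
#'   mixtures, epidemic curve, topic catalog with boosts, user groups, and
#'   announcement days).
#' @export
generate_corpus <- function(config, lexicon) {
  stopifnot(inherits(config, "generator_config"),
            inherits(lexicon, "emotion_lexicon"))
  set.seed(config$seed)
  dates <- seq(config$date_start, by = "day", length.out = config$n_days)
  cats <- emotion_categories()
  words_by_cat <- split(lexicon$entries$word, lexicon$entries$category)[cats]
  if (any(vapply(words_by_cat, length, 0L) == 0L)) {
    stop("infeasible config: lexicon must cover all 7 categories")
  }
  fillers <- sprintf("fl%03d", seq_len(config$n_fillers))
  groups <- names(config$posts_per_day)[config$posts_per_day > 0 &
                                          config$n_users[names(config$posts_per_day)] > 0]
  users <- lapply(setNames(nm = groups), function(g) {
    sprintf("u_%s_%04d", g, seq_len(config$n_users[[g]]))
  })
  base_loc <- c(retweet = 8, comment = 12, like = 100)
  announce_topic <- config$topics$super_topic[
    match("confirmed_cases", config$topics$category)]
  if (is.na(announce_topic)) announce_topic <- config$topics$super_topic[1L]
  announce_cat <- config$topics$category[
    config$topics$super_topic == announce_topic]

  chunks <- list()
  announced <- logical(config$n_days)
  id_counter <- 0L
  for (d in seq_len(config$n_days)) {
    day <- dates[d]
    day_base <- as.POSIXct(paste(day, "00:00:00"), tz = config$tz)
    for (g in groups) {
      np <- rpois(1L, config$posts_per_day[[g]])
      if (np == 0L) next
      t_idx <- sample.int(nrow(config$topics), np, replace = TRUE,
                          prob = config$topics$weight)
      uid <- sample(users[[g]], np, replace = TRUE)
      nw <- rpois(np, config$words_per_post) + 1L
      wcat <- sample.int(7L, sum(nw), replace = TRUE,
                         prob = config$emotion_trajectory[d, ])
      wtok <- character(sum(nw))
      for (ci in seq_len(7L)) {
        sel <- wcat == ci
        if (any(sel)) {
          wtok[sel] <- sample(words_by_cat[[ci]], sum(sel), replace = TRUE)
        }
      }
      nf <- rpois(np, config$fillers_per_post) + 1L
      ftok <- sample(fillers, sum(nf), replace = TRUE)
      w_split <- split(wtok, rep(seq_len(np), nw))
      f_split <- split(ftok, rep(seq_len(np), nf))
      text <- vapply(seq_len(np), function(p) {
        paste(sample(c(w_split[[p]], f_split[[p]])), collapse = " ")
      }, "")
      scale <- config$engagement_scale[[g]]
      boost <- config$topics$boost[t_idx]
      chunks[[length(chunks) + 1L]] <- data.frame(
        id = sprintf("mb%07d", id_counter + seq_len(np)),
        user_id = uid,
        created_at = day_base + sort(floor(runif(np, 0, 86400))),
        text = text,
        super_topic = config$topics$super_topic[t_idx],
        topic_category = config$topics$category[t_idx],
        n_retweet = round(rlnorm(np, log(base_loc[["retweet"]] * scale), 1) * boost),
        n_comment = round(rlnorm(np, log(base_loc[["comment"]] * scale), 1) * boost),
        n_like = round(rlnorm(np, log(base_loc[["like"]] * scale), 1) * boost),
        topic_discussions = round(config$topics$disc_base[t_idx] * d *
                                    config$topics$boost[t_idx]),
        topic_reads = round(config$topics$read_base[t_idx] * d *
                              config$topics$boost[t_idx]),
        stringsAsFactors = FALSE)
      id_counter <- id_counter + np
    }
    if (runif(1L) < config$announcement_prob) {
      announced[d] <- TRUE
      cp <- config$epidemic_curve[d, ]
      id_counter <- id_counter + 1L
      chunks[[length(chunks) + 1L]] <- data.frame(
        id = sprintf("mb%07d", id_counter),
        user_id = "u_official_0001",
        created_at = day_base + 36000,
        text = sprintf("fl000 \u65b0\u589e\u786e\u8bca%d\u4f8b \u7d2f\u8ba1\u786e\u8bca%d\u4f8b",
                       cp$n_new, cp$n_acc),
        super_topic = announce_topic,
        topic_category = announce_cat,
        n_retweet = 5, n_comment = 5, n_like = 50,
        topic_discussions = 100, topic_reads = 1000,
        stringsAsFactors = FALSE)
    }
  }
  if (length(chunks) == 0L) stop("infeasible config: no posts generated")
  records <- do.call(rbind, chunks)

  # guarantee the large-group comment threshold is crossed at least once
  if ("large" %in% groups) {
    lu <- records$user_id %in% users[["large"]]
    if (any(lu) && max(records$n_comment[lu]) <= 1000) {
      bump <- which(lu)[1L]
      records$n_comment[bump] <- 1500
    }
  }

  corpus <- as_corpus(records, tz = config$tz,
                      date_range = c(dates[1L], dates[config$n_days]))
  truth_groups <- do.call(rbind, lapply(names(users), function(g) {
    data.frame(user_id = users[[g]], group = g, stringsAsFactors = FALSE)
  }))
  truth <- list(
    seed = config$seed,
    dates = as.character(dates),
    emotion_trajectory = config$emotion_trajectory,
    epidemic_curve = data.frame(date = as.character(config$epidemic_curve$date),
                                n_new = config$epidemic_curve$n_new,
                                n_acc = config$epidemic_curve$n_acc),
    announcement_days = as.character(dates[announced]),
    topics = config$topics,
    user_groups = truth_groups,
    posts_per_day = as.list(config$posts_per_day),
    engagement_scale = as.list(config$engagement_scale))
  list(corpus = corpus, truth = truth)
}

#' Generate and write a full synthetic dataset
#'
#' Convenience wrapper: generates a lexicon and corpus and writes
#' `lexicon.tsv`, `corpus.jsonl` and `truth.json` into `out_dir`. The
#' ground-truth file suffices to recompute every planted quantity.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving both lexicon and corpus.
#' @param words_per_subcategory Lexicon size parameter (default 150).
#' @param config Optional `generator_config`; default
#'   `generator_config(seed = seed)`.
#' @return Invisibly, a list with `lexicon`, `corpus`, `truth` and the
#'   written `paths`.
#' @export
simulate_dataset <- function(out_dir, seed = 1L,
                             words_per_subcategory = 150L, config = NULL) {
  config <- config %||% generator_config(seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lexicon <- generate_lexicon(seed = seed,
                              words_per_subcategory = words_per_subcategory)
  gen <- generate_corpus(config, lexicon)
  paths <- c(lexicon = file.path(out_dir, "lexicon.tsv"),
             corpus = file.path(out_dir, "corpus.jsonl"),
             truth = file.path(out_dir, "truth.json"))
  write_lexicon(lexicon, paths[["lexicon"]])
  write_corpus(gen$corpus, paths[["corpus"]])
  jsonlite::write_json(gen$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", matrix = "rowmajor")
  invisible(list(lexicon = lexicon, corpus = gen$corpus, truth = gen$truth,
                 paths = paths))
}
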