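#' Per-day engagement profile of every super topic
#'
#' For one time unit and (optionally) one user group, aggregates the posts
#' of each super topic into the five engagement measures the hot-degree
#' score fuses: post-level means of retweets, comments and likes, and the
#' topic-level discussion and read counters. The topic-level counters are
#' cumulative platform snapshots, so the largest value reported within the
#' unit is used.
#'
#' @param corpus A `corpus`.
#' @param unit The day (`Date` or coercible), inside the corpus date range.
#' @param groups Optional `user_groups`; required when `group` is given.
#' @param group Optional `"large"` or `"common"`.
#' @return Data frame with one row per super topic having at least one post
#'   in the unit (by the group, if given): columns `super_topic`,
#'   `mean_retweets`, `mean_comments`, `mean_likes`, `discussions`,
#'   `reads`, `n_posts`. Empty units give a zero-row frame.
#' @export
topic_engagement <- function(corpus, unit, groups = NULL, group = NULL) {
  stopifnot(inherits(corpus, "corpus"))
  unit <- as.Date(unit)
  if (unit < corpus$date_range[1L] || unit > corpus$date_range[2L]) {
    stop("unit ", unit, " outside the corpus date range")
  }
  r <- corpus$records
  if (!is.null(group)) {
    if (is.null(groups)) stop("'groups' must be supplied when 'group' is given")
    group <- match.arg(group, c("large", "common"))
    r <- r[r$user_id %in% groups$user_id[groups$group == group], , drop = FALSE]
  }
  r <- r[as.Date(r$created_at, tz = corpus$tz) == unit, , drop = FALSE]
  empty <- data.frame(super_topic = character(0L), mean_retweets = numeric(0L),
                      mean_comments = numeric(0L), mean_likes = numeric(0L),
                      discussions = numeric(0L), reads = numeric(0L),
                      n_posts = integer(0L), stringsAsFactors = FALSE)
  if (nrow(r) == 0L) return(empty)
  f <- factor(r$super_topic)
  out <- data.frame(
    super_topic = levels(f),
    mean_retweets = as.numeric(tapply(r$n_retweet, f, mean)),
    mean_comments = as.numeric(tapply(r$n_comment, f, mean)),
    mean_likes = as.numeric(tapply(r$n_like, f, mean)),
    discussions = as.numeric(tapply(r$topic_discussions, f, max)),
    reads = as.numeric(tapply(r$topic_reads, f, max)),
    n_posts = as.integer(tapply(r$id, f, length)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Competition ranks of a metric vector
#'
#' Rank 1 for the largest value; tied values all receive the minimum
#' ("competition") rank, so a metric on which every topic ties gives every
#' topic rank 1 and the all-rank-1 lower bound of the hot score stays
#' exact.
#'
#' @param values Numeric vector (at least one value).
#' @param direction `"descending"` (default: largest value gets rank 1) or
#'   `"ascending"`.
#' @return Integer vector of ranks, same length as `values`.
#' @export
#' @examples
#' rank_vector(c(10, 5, 1))
#' rank_vector(c(7, 7, 1))
rank_vector <- function(values, direction = c("descending", "ascending")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(values), length(values) >= 1L)
  if (direction == "descending") values <- -values
  as.integer(rank(values, ties.method = "min"))
}

#' Rank-fusion hot degree of super topics
#'
#' Each of the five engagement measures is ranked across the unit's topics
#' with [rank_vector()]; the hot degree of a topic is the weighted sum of
#' its rank positions,
#' \deqn{hot(e) = w_1 \|rank(\bar H_e)\|_1 + w_2 \|rank(S_e)\|_1,}
#' where the first term sums the three post-level ranks (mean retweets,
#' comments, likes) and the second the two topic-level ranks (discussions,
#' reads). Because rank sums are small for popular topics, a *lower* hot
#' value means a *hotter* topic; the minimum possible value is
#' \eqn{3 w_1 + 2 w_2} (rank 1 on all five measures). The structural
#' imbalance (three ranks against two, equal weights) is kept as stated;
#' `normalize = TRUE` optionally divides each side by its rank count.
#'
#' @param engagements Engagement table for a single (unit, group) from
#'   [topic_engagement()].
#' @param w1,w2 Weights of the post-level and topic-level rank sums
#'   (default 0.5 each).
#' @param normalize Divide the two rank sums by 3 and 2 respectively
#'   (default `FALSE`).
#' @return Data frame with columns `super_topic`, `rank_sum_H`,
#'   `rank_sum_S`, `hot`, `n_posts`; empty input gives a zero-row frame.
#' @export
hot_degree <- function(engagements, w1 = 0.5, w2 = 0.5, normalize = FALSE) {
  need <- c("super_topic", "mean_retweets", "mean_comments", "mean_likes",
            "discussions", "reads", "n_posts")
  stopifnot(is.data.frame(engagements), all(need %in% names(engagements)))
  if (nrow(engagements) == 0L) {
    return(data.frame(super_topic = character(0L), rank_sum_H = numeric(0L),
                      rank_sum_S = numeric(0L), hot = numeric(0L),
                      n_posts = integer(0L), stringsAsFactors = FALSE))
  }
  rH <- rank_vector(engagements$mean_retweets) +
    rank_vector(engagements$mean_comments) +
    rank_vector(engagements$mean_likes)
  rS <- rank_vector(engagements$discussions) +
    rank_vector(engagements$reads)
  hot <- if (normalize) w1 * rH / 3 + w2 * rS / 2 else w1 * rH + w2 * rS
  data.frame(super_topic = engagements$super_topic,
             rank_sum_H = as.numeric(rH), rank_sum_S = as.numeric(rS),
             hot = hot, n_posts = engagements$n_posts,
             stringsAsFactors = FALSE)
}

#' Extract the hottest events of a time unit
#'
#' Orders topics by ascending hot degree (lower = hotter, the argmin rule),
#' breaking ties by larger post count and then lexicographic topic name,
#' and returns the first `top_k`.
#'
#' @param scores Hot-score table from [hot_degree()].
#' @param top_k Number of events to return (at least 1).
#' @return Character vector of super-topic names, hottest first, length
#'   `min(top_k, nrow(scores))`.
#' @export
hottest_events <- function(scores, top_k = 3L) {
  stopifnot(is.data.frame(scores), top_k >= 1L)
  if (nrow(scores) == 0L) return(character(0L))
  ord <- order(scores$hot, -scores$n_posts, scores$super_topic)
  head(scores$super_topic[ord], top_k)
}

#' Category distribution of extracted hot events
#'
#' Given the per-unit top-k hottest-event lists over an observation window,
#' computes the share of top slots occupied by each topic category:
#' \eqn{share(cat) = 100 \times (slots\ listing\ cat) / (total\ filled\
#' slots)}. Shares sum to 100 when any slot is filled.
#'
#' @param top_lists List of character vectors, one per time unit, each an
#'   ordered hottest-event list ([hottest_events()]).
#' @param category_map Named character vector mapping every listed super
#'   topic to its topic category.
#' @return Data frame with columns `topic_category` and `share_percent`,
#'   sorted by descending share.
#' @export
hot_event_distribution <- function(top_lists, category_map) {
  topics <- unlist(top_lists, use.names = FALSE)
  if (length(topics) == 0L) {
    return(data.frame(topic_category = character(0L),
                      share_percent = numeric(0L), stringsAsFactors = FALSE))
  }
  miss <- setdiff(topics, names(category_map))
  if (length(miss)) stop("no category for super topic(s): ", miss[1L])
  tab <- table(unname(category_map[topics]))
  out <- data.frame(topic_category = names(tab),
                    share_percent = 100 * as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$share_percent, out$topic_category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
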