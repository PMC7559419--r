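.microblog_fields <- c("id", "user_id", "created_at", "text", "super_topic",
                       "topic_category", "n_retweet", "n_comment", "n_like",
                       "topic_discussions", "topic_reads")
.count_fields <- c("n_retweet", "n_comment", "n_like",
                   "topic_discussions", "topic_reads")

#' The nine super-topic categories
#'
#' Thematic categories that super topics (platform-level hashtag-like labels
#' grouping posts about one event) are assigned to during an epidemic:
#' collective action against the disease, the pathogen itself, a prominent
#' individual, treatment, epidemic development, official prevention and
#' control, confirmed-case announcements, isolation, and support for the
#' outbreak region. Records may also carry `"unknown"`.
#'
#' @return Character vector of length 9.
#' @export
topic_categories <- function() {
  c("fighting_covid19", "novel_coronavirus", "wenliang_li", "treatment",
    "epidemic_development", "epidemic_control", "confirmed_cases",
    "isolation", "support_wuhan")
}

#' Construct a microblog corpus from a record table
#'
#' Validates a data frame of microblog records and wraps it as a `corpus`.
#' Counts must be non-negative, ids unique, `created_at` a POSIXct.
#'
#' @param records Data frame with columns `id`, `user_id`, `created_at`
#'   (POSIXct), `text`, `super_topic`, `topic_category`, `n_retweet`,
#'   `n_comment`, `n_like`, `topic_discussions`, `topic_reads`.
#' @param tz Time zone used for day bucketing; defaults to `"Asia/Shanghai"`
#'   (UTC+8), the platform's home zone.
#' @param date_range Optional inclusive `c(start, end)` `Date` pair; defaults
#'   to the range of record dates.
#' @return An object of class `corpus`: list with `records`, `date_range`,
#'   `time_unit` (always `"day"`) and `tz`.
#' @export
as_corpus <- function(records, tz = "Asia/Shanghai", date_range = NULL) {
  missing_f <- setdiff(.microblog_fields, names(records))
  if (length(missing_f)) {
    stop("records missing field(s): ", paste(missing_f, collapse = ", "))
  }
  records <- records[.microblog_fields]
  if (!inherits(records$created_at, "POSIXct")) {
    stop("'created_at' must be POSIXct")
  }
  for (f in .count_fields) {
    v <- records[[f]]
    if (anyNA(v) || any(v < 0)) stop("field '", f, "' must be non-negative")
  }
  dup <- records$id[duplicated(records$id)]
  if (length(dup)) stop("duplicate microblog id(s): ", dup[1L])
  if (is.null(date_range)) {
    if (nrow(records) == 0L) stop("cannot infer date_range of an empty corpus")
    d <- as.Date(records$created_at, tz = tz)
    date_range <- range(d)
  }
  date_range <- as.Date(date_range)
  stopifnot(length(date_range) == 2L, date_range[1L] <= date_range[2L])
  rownames(records) <- NULL
  structure(list(records = records, date_range = date_range,
                 time_unit = "day", tz = tz),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("Microblog corpus: %d records, %d users, %d super topics\n",
              nrow(x$records), length(unique(x$records$user_id)),
              length(unique(x$records$super_topic))))
  cat(sprintf("Date range: %s to %s (time unit: %s, tz %s)\n",
              x$date_range[1L], x$date_range[2L], x$time_unit, x$tz))
  invisible(x)
}

.parse_timestamps <- function(x) {
  as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%S%z", tz = "UTC"))
}

#' Read a microblog corpus from a JSONL file
#'
#' One JSON object per line with exactly the microblog field names (see
#' [as_corpus()]); timestamps ISO-8601 with numeric zone offset
#' (`2020-02-01T08:30:00+0800`). A line that is not valid JSON or lacks a
#' required field raises a parse error naming the line (and field). Lines
#' with unparseable timestamps, negative counts, or duplicate ids are
#' dropped; the per-line report is attached as `attr(corpus, "rejected")`
#' and summarised in a warning.
#'
#' @param path Path to the JSONL corpus file.
#' @inheritParams as_corpus
#' @return A `corpus` (possibly with a `rejected` attribute).
#' @export
read_corpus <- function(path, tz = "Asia/Shanghai") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty corpus file: ", path)
  parsed <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(rec)) stop(sprintf("line %d: not valid JSON", i))
    missing_f <- setdiff(.microblog_fields, names(rec))
    if (length(missing_f)) {
      stop(sprintf("line %d: missing field '%s'", i, missing_f[1L]))
    }
    parsed[[i]] <- rec
  }
  get_chr <- function(f) vapply(parsed, function(r) as.character(r[[f]]), "")
  get_num <- function(f) {
    vapply(parsed, function(r) suppressWarnings(as.numeric(r[[f]])), 0)
  }
  df <- data.frame(
    id = get_chr("id"), user_id = get_chr("user_id"),
    created_at_raw = get_chr("created_at"), text = get_chr("text"),
    super_topic = get_chr("super_topic"),
    topic_category = get_chr("topic_category"),
    stringsAsFactors = FALSE)
  for (f in .count_fields) df[[f]] <- get_num(f)
  ts <- .parse_timestamps(df$created_at_raw)

  reason <- rep(NA_character_, nrow(df))
  reason[is.na(ts)] <- "unparseable timestamp"
  neg <- Reduce(`|`, lapply(.count_fields,
                            function(f) is.na(df[[f]]) | df[[f]] < 0))
  reason[is.na(reason) & neg] <- "negative or missing count"
  reason[is.na(reason) & duplicated(df$id)] <- "duplicate id"

  rejected <- data.frame(line = which(!is.na(reason)),
                         id = df$id[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  keep <- is.na(reason)
  if (!any(keep)) stop("no valid records in ", path)
  df <- df[keep, , drop = FALSE]
  df$created_at <- ts[keep]
  df$created_at_raw <- NULL
  out <- as_corpus(df, tz = tz)
  if (nrow(rejected)) {
    warning(sprintf("%d record(s) rejected (see attr(,'rejected')): lines %s",
                    nrow(rejected),
                    paste(rejected$line, collapse = ", ")))
    attr(out, "rejected") <- rejected
  }
  out
}

#' Write a corpus to a JSONL file
#'
#' Inverse of [read_corpus()]: one JSON object per line, timestamps formatted
#' ISO-8601 in the corpus time zone. Output is byte-deterministic.
#'
#' @param corpus A `corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "corpus"))
  r <- corpus$records
  ts <- format(r$created_at, "%Y-%m-%dT%H:%M:%S%z", tz = corpus$tz)
  lines <- vapply(seq_len(nrow(r)), function(i) {
    as.character(jsonlite::toJSON(list(
      id = r$id[i], user_id = r$user_id[i], created_at = ts[i],
      text = r$text[i], super_topic = r$super_topic[i],
      topic_category = r$topic_category[i],
      n_retweet = r$n_retweet[i], n_comment = r$n_comment[i],
      n_like = r$n_like[i], topic_discussions = r$topic_discussions[i],
      topic_reads = r$topic_reads[i]), auto_unbox = TRUE, digits = NA))
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

#' Filter a corpus by super-topic size and date window
#'
#' Restricts to the inclusive `[date_start, date_end]` window, then removes
#' records whose super topic has fewer than `min_topic_posts` records in the
#' window ("fewer than" is strict: a topic with exactly `min_topic_posts`
#' posts is retained). Because the topic filter drops whole topics without
#' shrinking the survivors, this order makes the operation idempotent. Set
#' `topic_filter_first = TRUE` to count topic sizes on the unrestricted
#' input corpus instead (the filters' effects overlap either way; both
#' readings of the cleaning procedure are supported).
#'
#' @param corpus A `corpus`.
#' @param min_topic_posts Minimum posts a super topic needs to be kept
#'   (default 50).
#' @param date_start,date_end Inclusive window bounds (`Date` or coercible);
#'   `NULL` keeps the corpus bound.
#' @param topic_filter_first Logical; see above. Default `FALSE`.
#' @return A filtered `corpus` with `date_range` set to the window.
#' @export
filter_corpus <- function(corpus, min_topic_posts = 50L,
                          date_start = NULL, date_end = NULL,
                          topic_filter_first = FALSE) {
  stopifnot(inherits(corpus, "corpus"), min_topic_posts >= 0L)
  date_start <- as.Date(date_start %||% corpus$date_range[1L])
  date_end <- as.Date(date_end %||% corpus$date_range[2L])
  stopifnot(date_start <= date_end)
  r <- corpus$records
  dt <- as.Date(r$created_at, tz = corpus$tz)
  in_window <- dt >= date_start & dt <= date_end

  if (topic_filter_first) {
    sizes <- table(r$super_topic)
    keep_topic <- r$super_topic %in% names(sizes)[sizes >= min_topic_posts]
    keep <- keep_topic & in_window
  } else {
    rw <- r$super_topic[in_window]
    sizes <- table(rw)
    keep_topic <- r$super_topic %in% names(sizes)[sizes >= min_topic_posts]
    keep <- in_window & keep_topic
  }
  as_corpus(r[keep, , drop = FALSE], tz = corpus$tz,
            date_range = c(date_start, date_end))
}

#' Split users into large and common groups
#'
#' A user is *large* if at least one of their posts drew strictly more than
#' `comment_threshold` comments (a post with exactly `comment_threshold`
#' comments does not qualify); all other users are *common*. Large accounts
#' are typically official news outlets whose posts attract platform-scale
#' attention; common accounts express personal views.
#'
#' @param corpus A non-empty `corpus`.
#' @param comment_threshold Comment count a post must exceed (default 1000).
#' @return A `user_groups` data frame with columns `user_id` and `group`
#'   (`"large"` or `"common"`), exhaustive over corpus users.
#' @export
classify_users <- function(corpus, comment_threshold = 1000L) {
  stopifnot(inherits(corpus, "corpus"))
  if (nrow(corpus$records) == 0L) stop("cannot classify users of an empty corpus")
  mx <- tapply(corpus$records$n_comment, corpus$records$user_id, max)
  out <- data.frame(user_id = names(mx),
                    group = ifelse(unname(mx) > comment_threshold,
                                   "large", "common"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$user_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("user_groups", "data.frame")
  out
}

#' Bucket a corpus into one document per day
#'
#' Partitions corpus records into calendar-day documents (in the corpus time
#' zone) covering the full `date_range`; days with no posts yield empty,
#' flagged documents so the timeline stays aligned with the epidemic
#' skeleton. Member texts are concatenated with a single newline, a
#' separator no valid lexicon word can contain. Optionally restricts to one
#' user group first.
#'
#' @param corpus A `corpus` (already filtered).
#' @param groups Optional `user_groups` from [classify_users()]; required
#'   when `group` is given.
#' @param group Optional `"large"` or `"common"`: keep only that group's
#'   posts.
#' @return A `document_set`: list with parallel vectors `date`, `text`,
#'   `n_posts`, `empty` and list column `member_ids`, one element per day.
#' @export
bucket_documents <- function(corpus, groups = NULL, group = NULL) {
  stopifnot(inherits(corpus, "corpus"))
  r <- corpus$records
  if (!is.null(group)) {
    if (is.null(groups)) stop("'groups' must be supplied when 'group' is given")
    group <- match.arg(group, c("large", "common"))
    miss <- setdiff(unique(r$user_id), groups$user_id)
    if (length(miss)) stop("user(s) missing from group assignment: ", miss[1L])
    keep_users <- groups$user_id[groups$group == group]
    r <- r[r$user_id %in% keep_users, , drop = FALSE]
  }
  days <- seq(corpus$date_range[1L], corpus$date_range[2L], by = "day")
  dt <- as.Date(r$created_at, tz = corpus$tz)
  # deterministic member order within a day
  ord <- order(dt, r$created_at, r$id)
  r <- r[ord, , drop = FALSE]
  dt <- dt[ord]
  f <- factor(as.character(dt), levels = as.character(days))
  ids <- split(r$id, f)
  texts <- vapply(split(r$text, f), paste, "", collapse = "\n")
  n_posts <- vapply(ids, length, 0L)
  structure(list(date = days, text = unname(texts),
                 member_ids = unname(ids), n_posts = unname(n_posts),
                 empty = unname(n_posts) == 0L, tz = corpus$tz),
            class = "document_set")
}

#' @export
print.document_set <- function(x, ...) {
  cat(sprintf("Document set: %d daily documents (%s to %s), %d empty\n",
              length(x$date), min(x$date), max(x$date), sum(x$empty)))
  invisible(x)
}

#' Mean engagement per user group and topic category
#'
#' Arithmetic means of the five engagement metrics (retweets, comments,
#' likes, topic discussions, topic reads) for every (group, topic category)
#' cell present in the corpus; cells with no posts are simply absent.
#'
#' @param corpus A `corpus`.
#' @param groups A `user_groups` assignment covering the corpus users.
#' @return Data frame with columns `group`, `topic_category`, `n_posts`, and
#'   `mean_retweets`, `mean_comments`, `mean_likes`, `mean_discussions`,
#'   `mean_reads`.
#' @export
group_engagement_stats <- function(corpus, groups) {
  stopifnot(inherits(corpus, "corpus"))
  r <- corpus$records
  g <- groups$group[match(r$user_id, groups$user_id)]
  if (anyNA(g)) stop("group assignment does not cover all corpus users")
  key <- list(group = g, topic_category = r$topic_category)
  out <- aggregate(r[.count_fields], by = key, FUN = mean)
  names(out)[match(.count_fields, names(out))] <-
    c("mean_retweets", "mean_comments", "mean_likes",
      "mean_discussions", "mean_reads")
  cnt <- aggregate(list(n_posts = r$id), by = key, FUN = length)
  out <- merge(cnt, out, by = c("group", "topic_category"), sort = TRUE)
  rownames(out) <- NULL
  out
}
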