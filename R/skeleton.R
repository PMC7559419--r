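#' Default announcement patterns for case-count extraction
#'
#' Perl-compatible regular expressions, one capture group each, covering the
#' common Chinese case-announcement forms: *xinzeng quezhen ... li*
#' ("newly confirmed ... cases") for the `new` dimension and *leiji
#' quezhen ... li* ("accumulated confirmed ... cases") for the `acc`
#' dimension. Digits are normalised (full-width to ASCII, thousands
#' separators stripped) before matching, and a trailing *wan* character
#' (\eqn{\times 10^4}) in the captured number is honoured.
#'
#' @return List of `list(dimension, pattern)` entries.
#' @seealso [extract_case_counts()]
#' @export
default_case_patterns <- function() {
  num <- "([0-9]+(?:\\.[0-9]+)?\u4e07?)"   # optional wan = x10^4
  list(
    list(dimension = "new",                 # xinzeng (quezhen) (bingli) N li
         pattern = paste0("\u65b0\u589e(?:\u786e\u8bca)?(?:\u75c5\u4f8b)?",
                          num, "\u4f8b")),
    list(dimension = "acc",                 # leiji (quezhen) (bingli) N li
         pattern = paste0("\u7d2f\u8ba1(?:\u786e\u8bca)?(?:\u75c5\u4f8b)?",
                          num, "\u4f8b"))
  )
}

# full-width digit and separator normalisation applied before pattern matching
.normalize_numbers <- function(text) {
  text <- chartr("\uff10\uff11\uff12\uff13\uff14\uff15\uff16\uff17\uff18\uff19",
                 "0123456789", text)
  gsub("(?<=[0-9]),(?=[0-9])", "", text, perl = TRUE)
}

.parse_count <- function(s) {
  wan <- grepl("\u4e07", s, fixed = TRUE)
  v <- suppressWarnings(as.numeric(sub("\u4e07", "", s, fixed = TRUE)))
  v[wan] <- v[wan] * 1e4
  v
}

.n_capture_groups <- function(pattern) {
  m <- regexpr(pattern, "", perl = TRUE)
  cs <- attr(m, "capture.start")
  if (is.null(cs)) 0L else ncol(cs)
}

#' Extract the epidemic skeleton from daily documents
#'
#' Scans each day's document for case announcements and builds the epidemic
#' *skeleton*: per day, the number of newly confirmed cases (`n_new`) and the
#' number of accumulated confirmed cases (`n_acc`). When a day contains
#' several announcements for a dimension, the largest captured value is
#' retained (counts are revised upward within a day); days with no match get
#' `NA`. The two dimensions are extracted independently. A non-monotone
#' accumulated series is flagged with a warning (attribute
#' `acc_violations`), not an error.
#'
#' @param documents A `document_set` from [bucket_documents()].
#' @param patterns Pattern set as in [default_case_patterns()]; every pattern
#'   must contain at least one capture group (the number).
#' @return A `skeleton` data frame with columns `date`, `n_new`, `n_acc`.
#' @export
extract_case_counts <- function(documents, patterns = default_case_patterns()) {
  stopifnot(inherits(documents, "document_set"))
  dims <- vapply(patterns, function(p) p$dimension, "")
  if (!all(dims %in% c("new", "acc"))) {
    stop("pattern dimension must be 'new' or 'acc'")
  }
  for (p in patterns) {
    if (.n_capture_groups(p$pattern) < 1L) {
      stop("pattern has no capture group: ", p$pattern)
    }
  }
  one_dim <- function(txt, dim) {
    vals <- numeric(0L)
    for (p in patterns[dims == dim]) {
      m <- gregexpr(p$pattern, txt, perl = TRUE)[[1L]]
      if (m[1L] == -1L) next
      cs <- attr(m, "capture.start")[, 1L]
      cl <- attr(m, "capture.length")[, 1L]
      vals <- c(vals, .parse_count(substring(txt, cs, cs + cl - 1L)))
    }
    if (length(vals)) max(vals) else NA_real_
  }
  texts <- vapply(documents$text, .normalize_numbers, "")
  out <- data.frame(
    date = documents$date,
    n_new = vapply(texts, one_dim, 0, dim = "new", USE.NAMES = FALSE),
    n_acc = vapply(texts, one_dim, 0, dim = "acc", USE.NAMES = FALSE))
  class(out) <- c("skeleton", "data.frame")
  acc <- out$n_acc[!is.na(out$n_acc)]
  if (length(acc) > 1L && any(diff(acc) < 0)) {
    bad <- which(diff(acc) < 0)
    warning("accumulated case series decreases at ", length(bad), " point(s)")
    attr(out, "acc_violations") <- bad
  }
  out
}

# last-observation-carried-forward (leading NAs backfilled from first value)
.locf <- function(x) {
  if (all(is.na(x))) return(x)
  first <- which(!is.na(x))[1L]
  x[seq_len(first - 1L)] <- x[first]
  for (i in seq_along(x)[-1L]) if (is.na(x[i])) x[i] <- x[i - 1L]
  x
}

.moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  if (window %% 2L == 0L) stop("smoothing window must be odd")
  h <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n),
         function(i) mean(x[max(1L, i - h):min(n, i + h)]), 0)
}

#' Segment the epidemic timeline into phases
#'
#' Cuts the skeleton's date range into contiguous phases at change points of
#' the new-case series. In `auto` mode, missing values are filled by last
#' observation carried forward, the series is (optionally) smoothed with a
#' centred moving average, and interior local extrema (peaks and valleys of
#' the plateau-compressed series) become break points; a break date ends
#' its phase. In `manual` mode the supplied break dates are used directly
#' (each break date ends its phase), which lets an analyst reproduce
#' published phase boundaries exactly.
#'
#' @param skeleton A `skeleton` from [extract_case_counts()].
#' @param mode `"auto"` or `"manual"`.
#' @param manual_breaks `Date` vector of break dates (manual mode); must lie
#'   inside the skeleton's date range (a break on the final date would leave
#'   an empty phase and is an error).
#' @param smooth_window Odd moving-average window for auto mode; `1` disables
#'   smoothing. Default 3.
#' @return A `phase_set` data frame with columns `label`, `start`, `end`
#'   (inclusive); phases are ordered, contiguous, non-overlapping and tile
#'   the skeleton's date range. At least one phase is always returned.
#' @export
segment_phases <- function(skeleton, mode = c("auto", "manual"),
                           manual_breaks = NULL, smooth_window = 3L) {
  stopifnot(inherits(skeleton, "skeleton"))
  mode <- match.arg(mode)
  dates <- skeleton$date
  d0 <- min(dates); d1 <- max(dates)

  if (mode == "manual") {
    if (is.null(manual_breaks) || length(manual_breaks) == 0L) {
      stop("manual mode requires at least one break date")
    }
    breaks <- sort(unique(as.Date(manual_breaks)))
    if (any(breaks < d0) || any(breaks >= d1)) {
      stop("manual break outside the skeleton date range")
    }
  } else {
    x <- skeleton$n_new
    if (sum(!is.na(x)) < 5L) {
      stop("auto segmentation needs n_new present for at least 5 units")
    }
    s <- .moving_average(.locf(x), smooth_window)
    r <- rle(s)
    k <- length(r$values)
    breaks <- as.Date(character(0L))
    if (k >= 3L) {
      ends <- cumsum(r$lengths)
      for (j in 2L:(k - 1L)) {
        peak <- r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L]
        valley <- r$values[j] < r$values[j - 1L] && r$values[j] < r$values[j + 1L]
        if (peak || valley) breaks <- c(breaks, dates[ends[j]])
      }
    }
  }
  starts <- c(d0, breaks + 1L)
  ends <- c(breaks, d1)
  out <- data.frame(label = sprintf("phase%d", seq_along(starts)),
                    start = starts, end = ends, stringsAsFactors = FALSE)
  class(out) <- c("phase_set", "data.frame")
  out
}

#' Write a skeleton to CSV
#'
#' Columns `date,n_new,n_acc`; missing values become empty cells.
#'
#' @param skeleton A `skeleton`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_skeleton <- function(skeleton, path) {
  write.csv(skeleton, path, row.names = FALSE, na = "")
  invisible(path)
}
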