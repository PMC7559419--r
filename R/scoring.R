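#' Term statistics over a document list
#'
#' Matches every document against the lexicon once and collects the raw
#' term-count maps, per-document emotional-term totals, and per-term document
#' frequencies that the tf-idf scoring needs. `|D|` is the number of
#' documents in the list, empty documents included (they contribute to
#' `|D|` but to no document frequency).
#'
#' @param documents A `document_set`.
#' @param lexicon An `emotion_lexicon`.
#' @return A `term_stats` object: list with `counts` (one named integer
#'   vector per document), `df` (named document-frequency vector over all
#'   matched terms), `doc_totals`, and `n_docs`.
#' @export
document_term_stats <- function(documents, lexicon) {
  stopifnot(inherits(documents, "document_set"),
            inherits(lexicon, "emotion_lexicon"))
  counts <- lapply(documents$text, match_emotion_terms, lexicon = lexicon)
  terms <- sort(unique(unlist(lapply(counts, names), use.names = FALSE)))
  df <- setNames(integer(length(terms)), terms)
  for (ct in counts) df[names(ct)] <- df[names(ct)] + 1L
  structure(list(counts = counts,
                 df = df,
                 doc_totals = vapply(counts, sum, 0L),
                 n_docs = length(counts)),
            class = "term_stats")
}

#' Term frequency within a document
#'
#' The frequency of each emotional term relative to all emotional-term
#' occurrences in the document:
#' \deqn{tf_{ij} = n_{i,j} / \sum_p n_{p,j}.}
#'
#' @param counts Named non-negative count vector for one document (a
#'   term-count map from [match_emotion_terms()]).
#' @return Named numeric vector summing to 1; empty input gives an empty
#'   result.
#' @export
#' @examples
#' term_frequency(c(a = 2, b = 3))
term_frequency <- function(counts) {
  if (length(counts) == 0L) return(setNames(numeric(0L), character(0L)))
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("counts sum to zero")
  counts / total
}

#' Inverse document frequency of emotional terms
#'
#' \deqn{idf_i = \log\left(|D| / (df_i + 1)\right)} with the natural
#' logarithm, where \eqn{df_i} is the number of documents containing the
#' term. The add-one in the denominator means a term present in every
#' document gets a slightly negative idf; such values are retained, not
#' clamped (see the scoring vignette for the consequences).
#'
#' @param terms Character vector of terms.
#' @param stats A `term_stats` object; unseen terms get document frequency 0.
#' @return Named numeric vector of idf values.
#' @export
#' @examples
#' s <- structure(list(df = c(w = 4L), n_docs = 10L), class = "term_stats")
#' inverse_document_frequency("w", s)  # log(10/5)
inverse_document_frequency <- function(terms, stats) {
  stopifnot(inherits(stats, "term_stats"), stats$n_docs >= 1L)
  df <- stats$df[terms]
  df[is.na(df)] <- 0L
  setNames(log(stats$n_docs / (df + 1)), terms)
}

.resolution_labels <- function(lexicon, resolution) {
  if (resolution == "category") lexicon$category_order else lexicon$subcategory_order
}

#' Emotion distribution of one document (one emotion-matrix row)
#'
#' Weights every matched emotional term by its degree level times its tf-idf
#' value and normalises per emotion label:
#' \deqn{Ratio(c) = \frac{\sum_{w \in d_j,\, cat(w) = c} L(w)\, tfIdf(w, d_j)}
#'                      {\sum_{w \in d_j} L(w)\, tfIdf(w, d_j)}}
#' at category (7 labels) or subcategory (21 labels) resolution. A document
#' with no emotional terms - or whose denominator is not strictly positive
#' (possible when negative idf values dominate) - yields an all-zero row
#' flagged `empty`; the non-positive-denominator case additionally warns.
#'
#' @param counts Term-count map of the document ([match_emotion_terms()]).
#' @param lexicon An `emotion_lexicon`.
#' @param stats `term_stats` built over the same document list.
#' @param resolution `"category"` or `"subcategory"`.
#' @return Named numeric vector over the full label order with attribute
#'   `empty` (logical). Non-empty rows sum to 1.
#' @export
emotion_ratio <- function(counts, lexicon, stats,
                          resolution = c("category", "subcategory")) {
  resolution <- match.arg(resolution)
  labels <- .resolution_labels(lexicon, resolution)
  zero <- setNames(numeric(length(labels)), labels)
  if (length(counts) == 0L) return(structure(zero, empty = TRUE))

  tf <- term_frequency(counts)
  idf <- inverse_document_frequency(names(counts), stats)
  info <- .lexicon_lookup(lexicon, names(counts))
  if (anyNA(info$word)) {
    stop("term(s) not in lexicon: ",
         names(counts)[is.na(info$word)][1L])
  }
  w <- info$degree * tf * idf
  denom <- sum(w)
  if (denom <= 0) {
    warning("non-positive tf-idf denominator; row flagged empty")
    return(structure(zero, empty = TRUE))
  }
  grp <- if (resolution == "category") info$category else info$subcategory
  s <- tapply(w, factor(grp, levels = labels), sum)
  s[is.na(s)] <- 0
  structure(setNames(as.numeric(s) / denom, labels), empty = FALSE)
}

#' Build the per-day emotion matrix
#'
#' Stacks [emotion_ratio()] rows for every document in order: a \eqn{k
#' \times 7} matrix at category resolution or \eqn{k \times 21} at
#' subcategory resolution, with one row per time unit. Empty rows (days with
#' no emotional terms) are all-zero and flagged.
#'
#' @param documents A `document_set` (at least one document).
#' @param lexicon An `emotion_lexicon`.
#' @param resolution `"category"` or `"subcategory"`.
#' @param stats Optional precomputed [document_term_stats()] (reused across
#'   resolutions to avoid re-matching).
#' @return An `emotion_matrix`: numeric matrix with one row per day
#'   (rownames are dates), attributes `dates` (`Date`), `empty` (logical per
#'   row) and `resolution`.
#' @export
build_emotion_matrix <- function(documents, lexicon,
                                 resolution = c("category", "subcategory"),
                                 stats = NULL) {
  resolution <- match.arg(resolution)
  stopifnot(inherits(documents, "document_set"))
  if (length(documents$date) < 1L) stop("need at least one document")
  stats <- stats %||% document_term_stats(documents, lexicon)
  labels <- .resolution_labels(lexicon, resolution)
  k <- length(documents$date)
  M <- matrix(0, nrow = k, ncol = length(labels),
              dimnames = list(as.character(documents$date), labels))
  empty <- logical(k)
  for (j in seq_len(k)) {
    row <- emotion_ratio(stats$counts[[j]], lexicon, stats, resolution)
    M[j, ] <- row
    empty[j] <- attr(row, "empty")
  }
  structure(M, dates = documents$date, empty = empty,
            resolution = resolution,
            class = c("emotion_matrix", class(M)))
}

#' @export
print.emotion_matrix <- function(x, ...) {
  cat(sprintf("Emotion matrix: %d days x %d labels (%s resolution), %d empty day(s)\n",
              nrow(x), ncol(x), attr(x, "resolution"), sum(attr(x, "empty"))))
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' Accumulated emotion intensity per day
#'
#' The accumulated value of an emotion label in a time unit is its
#' degree-weighted term-frequency mass:
#' \deqn{Acc_j(c) = \sum_{w \in d_j,\, cat(w) = c} L(w)\, tf_{wj},}
#' deliberately using tf only (no idf) so that days with very different post
#' volumes remain comparable. With `cumulative = TRUE` the running sum over
#' days is returned instead.
#'
#' @inheritParams build_emotion_matrix
#' @param cumulative Logical; return the running cumulative series.
#' @return An `accumulated_emotion` matrix (days x labels) with attributes
#'   `dates`, `empty`, `resolution`, `cumulative`. Per-day values lie in
#'   `[0, 9]` (degrees are at most 9 and tf sums to 1); empty days are all
#'   zero.
#' @export
accumulated_emotion <- function(documents, lexicon,
                                resolution = c("category", "subcategory"),
                                cumulative = FALSE, stats = NULL) {
  resolution <- match.arg(resolution)
  stopifnot(inherits(documents, "document_set"))
  stats <- stats %||% document_term_stats(documents, lexicon)
  labels <- .resolution_labels(lexicon, resolution)
  k <- length(documents$date)
  A <- matrix(0, nrow = k, ncol = length(labels),
              dimnames = list(as.character(documents$date), labels))
  empty <- logical(k)
  for (j in seq_len(k)) {
    counts <- stats$counts[[j]]
    if (length(counts) == 0L) {
      empty[j] <- TRUE
      next
    }
    tf <- term_frequency(counts)
    info <- .lexicon_lookup(lexicon, names(counts))
    grp <- if (resolution == "category") info$category else info$subcategory
    s <- tapply(info$degree * tf, factor(grp, levels = labels), sum)
    s[is.na(s)] <- 0
    A[j, ] <- as.numeric(s)
  }
  if (cumulative) A <- apply(A, 2L, cumsum)
  if (k == 1L) A <- matrix(A, nrow = 1L,
                           dimnames = list(as.character(documents$date), labels))
  structure(A, dates = documents$date, empty = empty,
            resolution = resolution, cumulative = cumulative,
            class = c("accumulated_emotion", class(A)))
}
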