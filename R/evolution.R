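#' Convert an emotion-distribution row to a rank vector
#'
#' Rank 1 goes to the label with the largest Ratio; ties are broken by
#' position in `label_order` (the earlier label gets the better rank), so
#' the result is always a strict permutation of `1..n`. Ranking a flagged
#' empty (all-zero) row is an error: such units carry no emotion signal and
#' must be dropped by the caller.
#'
#' @param row Named numeric vector (one row of an `emotion_matrix`).
#' @param label_order Fixed label order used for tie-breaking; defaults to
#'   the names of `row`.
#' @return Named integer vector of ranks, a permutation of `1..length(row)`.
#' @export
#' @examples
#' rank_emotions(c(joy = 0.5, anger = 0.3, sadness = 0.2))
rank_emotions <- function(row, label_order = names(row)) {
  if (is.null(label_order)) stop("'row' must be named or 'label_order' given")
  if (isTRUE(attr(row, "empty"))) {
    stop("cannot rank an empty emotion row; drop this unit")
  }
  v <- if (is.null(names(row))) as.numeric(row) else as.numeric(row[label_order])
  if (length(v) != length(label_order) || anyNA(v)) {
    stop("'row' does not cover 'label_order'")
  }
  if (all(v == 0)) stop("cannot rank an empty emotion row; drop this unit")
  ord <- order(-v, seq_along(v))
  ranks <- integer(length(v))
  ranks[ord] <- seq_along(v)
  setNames(ranks, label_order)
}

# indices of non-empty units of M falling inside the phase interval
.phase_units <- function(M, phase) {
  dates <- attr(M, "dates")
  empty <- attr(M, "empty")
  start <- as.Date(phase$start)
  end <- as.Date(phase$end)
  in_phase <- dates >= start & dates <= end
  list(use = which(in_phase & !empty),
       skipped = sum(in_phase & empty),
       label = as.character(phase$label))
}

#' Phase-wise emotion covariance matrix
#'
#' Pearson correlation between every pair of emotion Ratio series,
#' restricted to the non-empty units of one epidemic phase. A positive
#' entry means the two emotions rose and fell together during the phase; a
#' negative entry means they moved in opposition. Entries involving a
#' series that is constant within the phase are undefined and reported as
#' `NA`.
#'
#' @param M An `emotion_matrix`.
#' @param phase One phase: a single row of a `phase_set` (or any list with
#'   `label`, `start`, `end`).
#' @return A `phase_covariance` object: list with `phase` (label), `r`
#'   (symmetric correlation matrix over the emotion labels) and `n_units`.
#' @export
phase_covariance <- function(M, phase) {
  stopifnot(inherits(M, "emotion_matrix"))
  pu <- .phase_units(M, phase)
  if (length(pu$use) < 3L) {
    stop(sprintf("phase '%s': need at least 3 non-empty units, found %d",
                 pu$label, length(pu$use)))
  }
  sub <- unclass(M)[pu$use, , drop = FALSE]
  r <- suppressWarnings(cor(sub))
  constant <- apply(sub, 2L, function(v) max(v) == min(v))
  r[constant, ] <- NA_real_
  r[, constant] <- NA_real_
  structure(list(phase = pu$label, r = r, n_units = length(pu$use),
                 n_skipped = pu$skipped),
            class = "phase_covariance")
}

#' @export
print.phase_covariance <- function(x, ...) {
  cat(sprintf("Emotion covariance, %s (%d units):\n", x$phase, x$n_units))
  print(round(x$r, 3L))
  invisible(x)
}

#' Phase-wise emotion transition matrix
#'
#' For every pair of consecutive non-empty units \eqn{(i, i+1)} in a phase,
#' both units' emotion distributions are converted to rank vectors and the
#' cell \eqn{T(x, y)} is incremented when emotion \eqn{y} occupies at unit
#' \eqn{i+1} the rank emotion \eqn{x} held at unit \eqn{i}. The per-pair
#' matrices are summed over the phase, so the diagonal counts rank
#' retention ("stability") and off-diagonal cells count rank exchanges.
#' Empty units are skipped; pairs are formed between consecutive non-empty
#' units only, and the number skipped is recorded.
#'
#' @param M An `emotion_matrix`.
#' @param phase One phase (as in [phase_covariance()]).
#' @param label_order Tie-break label order; defaults to the matrix columns.
#' @return A `transition_matrix`: integer matrix over the emotion labels
#'   with attributes `phase`, `n_pairs` and `n_skipped`. Every row and
#'   every column sums to `n_pairs`.
#' @export
transition_matrix <- function(M, phase, label_order = colnames(M)) {
  stopifnot(inherits(M, "emotion_matrix"))
  pu <- .phase_units(M, phase)
  if (length(pu$use) < 2L) {
    stop(sprintf("phase '%s': need at least 2 non-empty units, found %d",
                 pu$label, length(pu$use)))
  }
  sub <- unclass(M)[pu$use, label_order, drop = FALSE]
  n <- length(label_order)
  ranks <- t(apply(sub, 1L, rank_emotions, label_order = label_order))
  Tm <- matrix(0L, n, n, dimnames = list(label_order, label_order))
  for (i in seq_len(nrow(ranks) - 1L)) {
    Tm <- Tm + outer(ranks[i, ], ranks[i + 1L, ], `==`)
  }
  storage.mode(Tm) <- "integer"
  structure(Tm, phase = pu$label, n_pairs = nrow(ranks) - 1L,
            n_skipped = pu$skipped,
            class = c("transition_matrix", class(Tm)))
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("Emotion transitions, %s (%d unit pair(s), %d empty unit(s) skipped):\n",
              attr(x, "phase"), attr(x, "n_pairs"), attr(x, "n_skipped")))
  print(unclass(x))
  invisible(x)
}
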