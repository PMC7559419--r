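#' The seven emotion categories
#'
#' Fixed, ordered label set of the top-level emotion categories used
#' throughout the package. The scheme follows the fine-grained affective
#' vocabulary tradition for Chinese text: Ekman's six universal emotions
#' (joy, anger, sadness, fear, disgust, surprise) extended with *love*.
#' The order is used everywhere a deterministic tie-break over categories is
#' needed (ranking, matrix columns, CSV output).
#'
#' @return Character vector of length 7.
#' @seealso [subcategory_scheme()] for the 21 sub-emotions.
#' @export
#' @examples
#' emotion_categories()
emotion_categories <- function() {
  c("joy", "anger", "sadness", "fear", "disgust", "love", "surprise")
}

#' The 21 sub-emotion labels and their parent categories
#'
#' Each of the seven emotion categories subdivides into one or more
#' sub-emotions (21 in total), mirroring the structure of fine-grained
#' Chinese affective vocabularies (e.g. respect and praise are sub-emotions
#' of love). Every lexicon entry must carry a subcategory from this table
#' whose parent equals its category.
#'
#' @return A data frame with columns `subcategory` and `category`, 21 rows,
#'   ordered by parent category (in [emotion_categories()] order).
#' @export
#' @examples
#' table(subcategory_scheme()$category)
subcategory_scheme <- function() {
  data.frame(
    subcategory = c(
      "happiness", "reassurance",                               # joy
      "rage",                                                   # anger
      "grief", "disappointment", "guilt", "longing",            # sadness
      "panic", "fright", "shame",                               # fear
      "boredom", "hatred", "reprimand", "jealousy", "doubt",    # disgust
      "respect", "praise", "trust", "fondness", "wishing",      # love
      "amazement"                                               # surprise
    ),
    category = rep(emotion_categories(), times = c(2L, 1L, 4L, 3L, 5L, 5L, 1L)),
    stringsAsFactors = FALSE
  )
}

# matching index: hash of words, candidate lengths (longest first), and the
# set of characters any lexicon word can start with (fast skip during scans)
.lexicon_index <- function(words) {
  dict <- new.env(parent = emptyenv(), hash = TRUE, size = length(words) * 2L)
  for (w in words) assign(w, TRUE, envir = dict)
  list(
    dict = dict,
    lengths = sort(unique(nchar(words)), decreasing = TRUE),
    first_chars = unique(substr(words, 1L, 1L))
  )
}

#' Construct and validate an emotion lexicon
#'
#' Builds an `emotion_lexicon` from a table of entries. Each entry assigns a
#' word to one of the seven emotion categories, one of the 21 sub-emotions
#' (whose parent must equal the category) and an intensity *degree level*
#' `L(w)` in \{1, 3, 5, 7, 9\}. Words are NFC-normalised; duplicates and
#' words containing whitespace are rejected.
#'
#' @param entries Data frame with columns `word`, `category`, `subcategory`,
#'   `degree`.
#' @return An object of class `emotion_lexicon`: a list with elements
#'   `entries` (the validated table), `category_order` (7 labels),
#'   `subcategory_order` (21 labels) and a precomputed matching index.
#' @seealso [read_lexicon()], [match_emotion_terms()]
#' @export
#' @examples
#' lex <- emotion_lexicon(data.frame(
#'   word = c("hurray", "sobbing"),
#'   category = c("joy", "sadness"),
#'   subcategory = c("happiness", "grief"),
#'   degree = c(5L, 7L)))
#' lex
emotion_lexicon <- function(entries) {
  required <- c("word", "category", "subcategory", "degree")
  if (!is.data.frame(entries) || !all(required %in% names(entries))) {
    stop("'entries' must be a data frame with columns ",
         paste(required, collapse = ", "))
  }
  entries <- entries[required]
  if (nrow(entries) == 0L) stop("empty lexicon")

  entries$word <- stringi::stri_trans_nfc(as.character(entries$word))
  entries$category <- as.character(entries$category)
  entries$subcategory <- as.character(entries$subcategory)
  entries$degree <- as.integer(entries$degree)

  if (any(!nzchar(entries$word))) stop("lexicon words must be non-empty")
  if (any(grepl("[ \t\r\n]", entries$word))) {
    stop("lexicon words must not contain whitespace")
  }
  dup <- entries$word[duplicated(entries$word)]
  if (length(dup)) {
    stop("duplicate lexicon word(s): ", paste(unique(dup), collapse = ", "))
  }

  scheme <- subcategory_scheme()
  bad_cat <- setdiff(entries$category, emotion_categories())
  if (length(bad_cat)) {
    stop("unknown emotion category: ", paste(bad_cat, collapse = ", "))
  }
  bad_sub <- setdiff(entries$subcategory, scheme$subcategory)
  if (length(bad_sub)) {
    stop("unknown sub-emotion: ", paste(bad_sub, collapse = ", "))
  }
  parent <- scheme$category[match(entries$subcategory, scheme$subcategory)]
  mism <- which(parent != entries$category)
  if (length(mism)) {
    stop(sprintf(
      "subcategory '%s' does not belong to category '%s' (word '%s')",
      entries$subcategory[mism[1L]], entries$category[mism[1L]],
      entries$word[mism[1L]]))
  }
  bad_deg <- which(!entries$degree %in% c(1L, 3L, 5L, 7L, 9L))
  if (length(bad_deg)) {
    stop(sprintf("degree level must be one of 1,3,5,7,9; word '%s' has %s",
                 entries$word[bad_deg[1L]], entries$degree[bad_deg[1L]]))
  }

  rownames(entries) <- NULL
  structure(
    list(entries = entries,
         category_order = emotion_categories(),
         subcategory_order = scheme$subcategory,
         index = .lexicon_index(entries$word)),
    class = "emotion_lexicon")
}

#' Read an emotion lexicon from a TSV file
#'
#' The file must be UTF-8, tab-separated, with the header line
#' `word<TAB>category<TAB>subcategory<TAB>degree` and one entry per line.
#' Rows with the wrong number of fields or a non-integer degree raise a parse
#' error naming the offending line; validation errors (unknown labels,
#' degrees outside \{1,3,5,7,9\}, duplicate words) are reported by
#' [emotion_lexicon()].
#'
#' @param path Path to the lexicon file.
#' @return An `emotion_lexicon`.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty lexicon: no header in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (!identical(header, c("word", "category", "subcategory", "degree"))) {
    stop("lexicon header must be 'word<TAB>category<TAB>subcategory<TAB>degree'")
  }
  body <- fields[-1L]
  if (length(body) == 0L) stop("empty lexicon: ", path, " has a header only")
  nf <- lengths(body)
  bad <- which(nf != 4L)
  if (length(bad)) {
    stop(sprintf("malformed lexicon row at line %d: expected 4 fields, found %d",
                 bad[1L] + 1L, nf[bad[1L]]))
  }
  m <- matrix(unlist(body, use.names = FALSE), ncol = 4L, byrow = TRUE)
  degree <- suppressWarnings(as.integer(m[, 4L]))
  if (anyNA(degree)) {
    stop(sprintf("malformed lexicon row at line %d: degree '%s' is not an integer",
                 which(is.na(degree))[1L] + 1L, m[which(is.na(degree))[1L], 4L]))
  }
  emotion_lexicon(data.frame(
    word = m[, 1L], category = m[, 2L], subcategory = m[, 3L],
    degree = degree, stringsAsFactors = FALSE))
}

#' Write an emotion lexicon to a TSV file
#'
#' Inverse of [read_lexicon()]; output is UTF-8 and byte-deterministic for a
#' given lexicon.
#'
#' @param lexicon An `emotion_lexicon`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "emotion_lexicon"))
  e <- lexicon$entries
  lines <- c("word\tcategory\tsubcategory\tdegree",
             paste(e$word, e$category, e$subcategory, e$degree, sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

#' @export
print.emotion_lexicon <- function(x, ...) {
  cat(sprintf("Emotion lexicon: %d words, %d categories, %d sub-emotions in use\n",
              nrow(x$entries), length(unique(x$entries$category)),
              length(unique(x$entries$subcategory))))
  cat("Degree levels:",
      paste(names(table(x$entries$degree)), collapse = " "), "\n")
  invisible(x)
}

# row-lookup of lexicon metadata for a vector of (known) words
.lexicon_lookup <- function(lexicon, words) {
  lexicon$entries[match(words, lexicon$entries$word), , drop = FALSE]
}

#' Count emotion-term occurrences in text
#'
#' Scans a string for occurrences of lexicon words using leftmost-longest
#' dictionary matching: at each position, the longest lexicon word starting
#' there (if any) is accepted and the scan resumes after it, so matches never
#' overlap and no general-purpose word segmenter is needed. Text is
#' NFC-normalised before matching. An optional substitution table (e.g.
#' emoji to bracketed token) is applied, as fixed-string replacements, before
#' matching.
#'
#' @param text A single character string (may be empty).
#' @param lexicon An `emotion_lexicon`.
#' @param substitutions Optional named character vector; each occurrence of a
#'   name in `text` is replaced by its value before matching. Default `NULL`
#'   (identity).
#' @return A named integer vector mapping each matched word to its occurrence
#'   count; words absent from the text are absent from the result. Names are
#'   sorted for determinism.
#' @export
#' @examples
#' lex <- emotion_lexicon(data.frame(
#'   word = c("ha", "haha"), category = "joy",
#'   subcategory = "happiness", degree = c(1L, 5L)))
#' match_emotion_terms("hahaha!", lex)  # leftmost-longest: haha then ha
match_emotion_terms <- function(text, lexicon, substitutions = NULL) {
  stopifnot(inherits(lexicon, "emotion_lexicon"),
            is.character(text), length(text) == 1L, !is.na(text))
  txt <- stringi::stri_trans_nfc(text)
  if (!is.null(substitutions)) {
    if (is.null(names(substitutions)) || any(!nzchar(names(substitutions)))) {
      stop("'substitutions' must be a named character vector")
    }
    for (i in seq_along(substitutions)) {
      txt <- gsub(names(substitutions)[i], substitutions[[i]], txt, fixed = TRUE)
    }
  }
  empty <- setNames(integer(0L), character(0L))
  if (!nzchar(txt)) return(empty)

  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  idx <- lexicon$index
  start_ok <- chars %in% idx$first_chars
  counts <- new.env(parent = emptyenv(), hash = TRUE)
  i <- 1L
  while (i <= n) {
    if (start_ok[i]) {
      adv <- 1L
      for (len in idx$lengths) {
        j <- i + len - 1L
        if (j > n) next
        cand <- paste(chars[i:j], collapse = "")
        if (exists(cand, envir = idx$dict, inherits = FALSE)) {
          prev <- if (exists(cand, envir = counts, inherits = FALSE)) {
            get(cand, envir = counts)
          } else 0L
          assign(cand, prev + 1L, envir = counts)
          adv <- len
          break
        }
      }
      i <- i + adv
    } else {
      i <- i + 1L
    }
  }
  words <- ls(counts)
  if (length(words) == 0L) return(empty)
  out <- vapply(words, get, integer(1L), envir = counts)
  out[order(names(out))]
}
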