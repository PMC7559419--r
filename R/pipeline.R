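#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the standard
#' defaults: super topics need at least 50 posts, a user is large once a
#' post exceeds 1000 comments, hot-degree weights are 0.5/0.5, the top 3
#' events are extracted per day, idf uses the natural logarithm (fixed,
#' recorded in the resolved config), and ties in emotion ranking follow
#' [emotion_categories()] order. A copy of the resolved configuration is
#' written beside every run's outputs.
#'
#' @param corpus Path to the JSONL corpus file.
#' @param lexicon Path to the TSV lexicon file.
#' @param out_dir Output directory for the artifact bundle.
#' @param timezone Day-bucketing time zone (default `"Asia/Shanghai"`).
#' @param date_start,date_end Optional inclusive analysis window.
#' @param min_topic_posts Super-topic size filter (default 50).
#' @param comment_threshold Large-user comment threshold (default 1000).
#' @param patterns Case-announcement pattern set
#'   ([default_case_patterns()]).
#' @param phase_mode `"auto"` or `"manual"` ([segment_phases()]).
#' @param manual_breaks Break dates for manual mode.
#' @param smooth_window Smoothing window for auto mode (default 3).
#' @param resolutions Emotion resolutions to compute (default both
#'   `"category"` and `"subcategory"`).
#' @param w1,w2 Hot-degree weights (default 0.5 each).
#' @param top_k Hottest events per day (default 3).
#' @param label_order Tie-break order for emotion ranking.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(corpus, lexicon, out_dir,
                            timezone = "Asia/Shanghai",
                            date_start = NULL, date_end = NULL,
                            min_topic_posts = 50L,
                            comment_threshold = 1000L,
                            patterns = default_case_patterns(),
                            phase_mode = c("auto", "manual"),
                            manual_breaks = NULL,
                            smooth_window = 3L,
                            resolutions = c("category", "subcategory"),
                            w1 = 0.5, w2 = 0.5, top_k = 3L,
                            label_order = emotion_categories()) {
  phase_mode <- match.arg(phase_mode)
  resolutions <- match.arg(resolutions, several.ok = TRUE)
  stopifnot(is.character(corpus), is.character(lexicon),
            is.character(out_dir), min_topic_posts >= 0L,
            comment_threshold >= 0L, top_k >= 1L)
  structure(list(corpus = corpus, lexicon = lexicon, out_dir = out_dir,
                 time_unit = "day", timezone = timezone,
                 date_start = date_start, date_end = date_end,
                 min_topic_posts = as.integer(min_topic_posts),
                 comment_threshold = as.integer(comment_threshold),
                 patterns = patterns, phase_mode = phase_mode,
                 manual_breaks = manual_breaks,
                 smooth_window = as.integer(smooth_window),
                 resolutions = resolutions,
                 w1 = w1, w2 = w2, top_k = as.integer(top_k),
                 idf_log_base = "e",
                 label_order = label_order),
            class = "pipeline_config")
}

.write_matrix_csv <- function(M, path) {
  df <- data.frame(date = rownames(M), unclass(M),
                   empty = as.integer(attr(M, "empty")),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  path
}

.write_square_csv <- function(m, path) {
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

#' Run the full emotion-evolution analysis
#'
#' Executes every stage in order - load, filter, classify users, bucket,
#' skeleton extraction, phase segmentation, emotion matrices and
#' accumulated series per user group and resolution, per-phase covariance
#' and transition matrices, hot events and their category distribution -
#' and writes the artifact bundle into `config$out_dir`:
#' `skeleton.csv`, `phases.json`, `emotion_matrix_<group>.csv`,
#' `subemotion_matrix_<group>.csv`, `accumulated[_cumulative]_<group>.csv`,
#' `covariance_<group>_<phase>.csv`, `transition_<group>_<phase>.csv`,
#' `hot_events_<group>.csv`, `distribution_<group>.csv`,
#' `resolved_config.yaml` and `run_log.txt`. The epidemic skeleton is
#' shared by both user groups (the epidemic timeline is common); emotion
#' models are group-stratified. Phases with too few usable units for a
#' covariance or transition matrix are logged and skipped. Identical
#' config and inputs produce byte-identical outputs. Any stage error
#' aborts the run with the stage name; partial outputs are removed.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, an `emovolve_run` list: `out_dir`, `files`, plus the
#'   in-memory `skeleton`, `phases`, matrices and hot-event tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0L)
  log_lines <- character(0L)
  addlog <- function(...) log_lines <<- c(log_lines, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  wfile <- function(path) {
    written <<- c(written, path)
    path
  }
  out <- function(...) file.path(config$out_dir, sprintf(...))

  lexicon <- stage("load_lexicon", read_lexicon(config$lexicon))
  corpus <- stage("load_corpus", read_corpus(config$corpus,
                                             tz = config$timezone))
  addlog("loaded %d records, %d lexicon words",
         nrow(corpus$records), nrow(lexicon$entries))

  corpus <- stage("filter", filter_corpus(
    corpus, min_topic_posts = config$min_topic_posts,
    date_start = config$date_start, date_end = config$date_end))
  addlog("after filtering: %d records, window %s..%s",
         nrow(corpus$records), corpus$date_range[1L], corpus$date_range[2L])

  groups <- stage("classify_users",
                  classify_users(corpus, config$comment_threshold))
  addlog("users: %d large, %d common", sum(groups$group == "large"),
         sum(groups$group == "common"))

  docs_all <- stage("bucket", bucket_documents(corpus))
  skeleton <- stage("skeleton", extract_case_counts(docs_all,
                                                    config$patterns))
  stage("skeleton", write_skeleton(skeleton, wfile(out("skeleton.csv"))))
  phases <- stage("phases", segment_phases(
    skeleton, mode = config$phase_mode,
    manual_breaks = config$manual_breaks,
    smooth_window = config$smooth_window))
  stage("phases", jsonlite::write_json(
    data.frame(label = phases$label, start = as.character(phases$start),
               end = as.character(phases$end)),
    wfile(out("phases.json")), auto_unbox = TRUE, digits = NA,
    dataframe = "rows"))
  addlog("skeleton: %d/%d days with new-case counts; %d phase(s)",
         sum(!is.na(skeleton$n_new)), nrow(skeleton), nrow(phases))

  cat_map <- stage("events", {
    u <- corpus$records[!duplicated(corpus$records$super_topic),
                        c("super_topic", "topic_category")]
    setNames(u$topic_category, u$super_topic)
  })

  results <- list()
  for (g in intersect(c("common", "large"), unique(groups$group))) {
    docs_g <- stage(paste0("bucket_", g),
                    bucket_documents(corpus, groups, g))
    stats_g <- stage(paste0("score_", g),
                     suppressWarnings(document_term_stats(docs_g, lexicon)))
    addlog("[%s] %d posts over %d days (%d empty)", g,
           sum(docs_g$n_posts), length(docs_g$date), sum(docs_g$empty))

    M_cat <- NULL
    for (res in config$resolutions) {
      M <- stage(paste0("score_", g), suppressWarnings(
        build_emotion_matrix(docs_g, lexicon, res, stats = stats_g)))
      if (res == "category") M_cat <- M
      fn <- if (res == "category") "emotion_matrix_%s.csv" else "subemotion_matrix_%s.csv"
      .write_matrix_csv(M, wfile(out(fn, g)))
      A <- stage(paste0("score_", g), accumulated_emotion(
        docs_g, lexicon, res, cumulative = FALSE, stats = stats_g))
      Ac <- stage(paste0("score_", g), accumulated_emotion(
        docs_g, lexicon, res, cumulative = TRUE, stats = stats_g))
      pre <- if (res == "category") "" else "sub_"
      .write_matrix_csv(A, wfile(out("%saccumulated_%s.csv", pre, g)))
      .write_matrix_csv(Ac, wfile(out("%saccumulated_cumulative_%s.csv", pre, g)))
      results[[paste0(substr(res, 1L, 3L), "_matrix_", g)]] <- M
    }

    for (p in seq_len(nrow(phases))) {
      ph <- phases[p, ]
      cv <- tryCatch(phase_covariance(M_cat, ph), error = function(e) e)
      if (inherits(cv, "error")) {
        addlog("[%s] covariance %s skipped: %s", g, ph$label,
               conditionMessage(cv))
      } else {
        .write_square_csv(cv$r, wfile(out("covariance_%s_%s.csv", g, ph$label)))
        addlog("[%s] covariance %s: %d units", g, ph$label, cv$n_units)
        results[[paste0("covariance_", g, "_", ph$label)]] <- cv
      }
      tr <- tryCatch(transition_matrix(M_cat, ph, config$label_order),
                     error = function(e) e)
      if (inherits(tr, "error")) {
        addlog("[%s] transition %s skipped: %s", g, ph$label,
               conditionMessage(tr))
      } else {
        .write_square_csv(unclass(tr), wfile(out("transition_%s_%s.csv",
                                                 g, ph$label)))
        addlog("[%s] transition %s: %d pair(s), %d empty unit(s) skipped",
               g, ph$label, attr(tr, "n_pairs"), attr(tr, "n_skipped"))
        results[[paste0("transition_", g, "_", ph$label)]] <- tr
      }
    }

    hot_rows <- list()
    top_lists <- list()
    for (d in seq_along(docs_all$date)) {
      unit <- docs_all$date[d]
      eng <- stage(paste0("events_", g),
                   topic_engagement(corpus, unit, groups, g))
      scores <- hot_degree(eng, w1 = config$w1, w2 = config$w2)
      top <- hottest_events(scores, config$top_k)
      top_lists[[d]] <- top
      if (length(top)) {
        sc <- scores[match(top, scores$super_topic), , drop = FALSE]
        hot_rows[[length(hot_rows) + 1L]] <- data.frame(
          date = as.character(unit), group = g, rank = seq_along(top),
          super_topic = top,
          topic_category = unname(cat_map[top]),
          hot = sc$hot, rank_sum_H = sc$rank_sum_H,
          rank_sum_S = sc$rank_sum_S, n_posts = sc$n_posts,
          stringsAsFactors = FALSE)
      }
    }
    hot_df <- if (length(hot_rows)) do.call(rbind, hot_rows) else
      data.frame(date = character(0L), group = character(0L),
                 rank = integer(0L), super_topic = character(0L),
                 topic_category = character(0L), hot = numeric(0L),
                 rank_sum_H = numeric(0L), rank_sum_S = numeric(0L),
                 n_posts = integer(0L), stringsAsFactors = FALSE)
    write.csv(hot_df, wfile(out("hot_events_%s.csv", g)), row.names = FALSE)
    dist <- stage(paste0("events_", g),
                  hot_event_distribution(top_lists, cat_map))
    if (nrow(dist)) dist <- cbind(group = g, dist)
    write.csv(dist, wfile(out("distribution_%s.csv", g)), row.names = FALSE)
    addlog("[%s] hot events: %d filled slot(s) over %d day(s)", g,
           nrow(hot_df), length(docs_all$date))
    results[[paste0("hot_events_", g)]] <- hot_df
    results[[paste0("distribution_", g)]] <- dist
  }

  resolved <- config
  resolved$manual_breaks <- as.character(resolved$manual_breaks %||% character(0L))
  resolved$date_start <- as.character(corpus$date_range[1L])
  resolved$date_end <- as.character(corpus$date_range[2L])
  stage("config", yaml::write_yaml(unclass(resolved),
                                   wfile(out("resolved_config.yaml"))))
  writeLines(log_lines, wfile(out("run_log.txt")))

  invisible(structure(
    c(list(out_dir = config$out_dir, files = written,
           skeleton = skeleton, phases = phases, groups = groups),
      results),
    class = "emovolve_run"))
}

#' Summarise an artifact bundle
#'
#' Reads only the files of a completed [run_pipeline()] bundle and prints a
#' compact report: the phase table, each group's strongest within-phase
#' correlations, most retained (diagonal) and most exchanged (off-diagonal)
#' emotion transitions, and the hottest event per day. Every number in the
#' report is read from one artifact file cell.
#'
#' @param bundle_dir Directory written by [run_pipeline()].
#' @return Invisibly, a list with the reported numbers (per-group unit
#'   counts, top covariance/transition entries, hot-event counts).
#' @export
summarize_run <- function(bundle_dir) {
  must <- function(f) {
    p <- file.path(bundle_dir, f)
    if (!file.exists(p)) stop("missing bundle file: ", f)
    p
  }
  phases <- jsonlite::fromJSON(must("phases.json"))
  cat(sprintf("Phases (%d):\n", nrow(phases)))
  for (i in seq_len(nrow(phases))) {
    cat(sprintf("  %s: %s .. %s\n", phases$label[i], phases$start[i],
                phases$end[i]))
  }
  out <- list(phases = phases)
  for (g in c("common", "large")) {
    hot_path <- file.path(bundle_dir, sprintf("hot_events_%s.csv", g))
    if (!file.exists(hot_path)) next
    hot <- read.csv(hot_path, stringsAsFactors = FALSE)
    units <- unique(hot$date)
    cat(sprintf("\n[%s] hottest event per day (%d day(s) with events):\n",
                g, length(units)))
    top1 <- hot[hot$rank == 1L, , drop = FALSE]
    for (i in seq_len(nrow(top1))) {
      cat(sprintf("  %s  %s (%s, hot=%g)\n", top1$date[i],
                  top1$super_topic[i], top1$topic_category[i], top1$hot[i]))
    }
    out[[paste0("n_units_", g)]] <- length(units)
    out[[paste0("top1_", g)]] <- top1

    for (p in phases$label) {
      cov_path <- file.path(bundle_dir,
                            sprintf("covariance_%s_%s.csv", g, p))
      if (file.exists(cov_path)) {
        cv <- read.csv(cov_path, check.names = FALSE,
                       stringsAsFactors = FALSE)
        m <- as.matrix(cv[, -1L])
        rownames(m) <- cv$label
        off <- m
        diag(off) <- NA
        if (any(!is.na(off))) {
          ij <- which(abs(off) == max(abs(off), na.rm = TRUE),
                      arr.ind = TRUE)[1L, ]
          cat(sprintf("[%s] %s strongest covariance: %s ~ %s (r=%.3f)\n",
                      g, p, rownames(m)[ij[1L]], colnames(m)[ij[2L]],
                      off[ij[1L], ij[2L]]))
          out[[paste0("cov_", g, "_", p)]] <-
            c(r = off[ij[1L], ij[2L]])
        }
      }
      tr_path <- file.path(bundle_dir,
                           sprintf("transition_%s_%s.csv", g, p))
      if (file.exists(tr_path)) {
        tv <- read.csv(tr_path, check.names = FALSE,
                       stringsAsFactors = FALSE)
        m <- as.matrix(tv[, -1L])
        rownames(m) <- tv$label
        stab <- which.max(diag(m))
        cat(sprintf("[%s] %s most stable emotion: %s (%d retention(s))\n",
                    g, p, rownames(m)[stab], diag(m)[stab]))
        out[[paste0("stab_", g, "_", p)]] <-
          setNames(diag(m)[stab], rownames(m)[stab])
      }
    }
  }
  invisible(out)
}
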