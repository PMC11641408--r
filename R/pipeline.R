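#' Assemble a pipeline configuration
#'
#' @param corpus Path to the corpus file.
#' @param corpus_format `"jsonl"` or `"csv"`.
#' @param labels Path to the two-rater label CSV.
#' @param out_dir Output directory (created if absent).
#' @param keywords Keyword phrases for the inclusion filter.
#' @param window_start,window_end Study window (half-open).
#' @param dedup_threshold Similarity threshold for [leader_cluster()].
#' @param min_cluster_size Cluster size that marks non-human content.
#' @param drop_nonhuman_leaders Remove flagged cluster leaders too?
#' @param aggregation,k,confidence_floor Passed to [classify_corpus()].
#' @param per_category_correct Yates correction in per-category gender tests.
#' @param top_n_terms,top_n_hashtags Lengths of the frequency tables.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(corpus, labels, out_dir,
                            corpus_format = c("jsonl", "csv"),
                            keywords = default_keywords(),
                            window_start = as.Date("2017-01-01"),
                            window_end = as.Date("2020-01-01"),
                            dedup_threshold = 0.8,
                            min_cluster_size = 3,
                            drop_nonhuman_leaders = FALSE,
                            aggregation = "max", k = 3,
                            confidence_floor = 0.1,
                            per_category_correct = TRUE,
                            top_n_terms = 20, top_n_hashtags = 10) {
  structure(list(
    corpus = corpus, corpus_format = match.arg(corpus_format),
    labels = labels, out_dir = out_dir,
    keywords = keyword_set(keywords),
    window_start = as.Date(window_start), window_end = as.Date(window_end),
    dedup_threshold = dedup_threshold,
    min_cluster_size = min_cluster_size,
    drop_nonhuman_leaders = drop_nonhuman_leaders,
    aggregation = aggregation, k = k, confidence_floor = confidence_floor,
    per_category_correct = per_category_correct,
    top_n_terms = top_n_terms, top_n_hashtags = top_n_hashtags
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' @param path JSON file whose keys mirror the arguments of
#'   [pipeline_config()]; `corpus` and `labels` paths are resolved relative
#'   to the config file's directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  raw$corpus <- resolve(raw$corpus)
  raw$labels <- resolve(raw$labels)
  known <- intersect(names(raw), names(formals(pipeline_config)))
  do.call(pipeline_config, raw[known])
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full content-analysis pipeline
#'
#' Executes read, keyword filter, tokenization, near-duplicate elimination,
#' non-human flagging, one-post-per-author reduction, seed-set construction
#' with inter-rater agreement, nearest-seed classification, and the quarterly
#' trend / gender / frequency statistics, writing all artifacts to the output
#' directory (`corpus_retained.jsonl`, `clusters.csv`, `assignments.csv`,
#' `quarter_series.csv`, `stats_report.json`, `run_report.json`). Identical
#' config and inputs give byte-identical reports. Labelled posts that were
#' eliminated upstream (duplicates of retained content) are dropped from the
#' seed labels, with the count recorded in the report. Any stage error aborts
#' with the stage name and removes partial outputs.
#'
#' @param config A `pipeline_config` or path to a JSON config file.
#' @return The run report (a list), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  artifacts <- file.path(config$out_dir,
                         c("corpus_retained.jsonl", "clusters.csv",
                           "assignments.csv", "quarter_series.csv",
                           "stats_report.json", "run_report.json"))
  ok <- FALSE
  on.exit(if (!ok) unlink(artifacts), add = TRUE)

  corpus <- stage("read_corpus",
                  read_corpus(config$corpus, config$corpus_format))
  labels <- stage("read_labels", read_labels(config$labels))
  filtered <- stage("filter_by_keywords",
                    filter_by_keywords(corpus, config$keywords))
  dedup <- stage("leader_cluster",
                 leader_cluster(filtered, config$dedup_threshold))
  dedup <- stage("flag_nonhuman",
                 flag_nonhuman(dedup, config$min_cluster_size,
                               config$drop_nonhuman_leaders))
  unique_authors <- stage("enforce_unique_authors",
                          enforce_unique_authors(dedup$retained))

  kept_labels <- labels[labels$tweet_id %in% unique_authors$id, , drop = FALSE]
  n_labels_dropped <- (length(unique(labels$tweet_id)) -
                       length(unique(kept_labels$tweet_id)))
  seeded <- stage("build_seed_set", build_seed_set(kept_labels, unique_authors))
  classified <- stage("classify_corpus",
                      classify_corpus(unique_authors, seeded$seeds,
                                      aggregation = config$aggregation,
                                      k = config$k,
                                      confidence_floor = config$confidence_floor))

  qs <- stage("build_quarter_series",
              build_quarter_series(classified$assignments, unique_authors,
                                   config$window_start, config$window_end))
  desc <- stage("describe_counts", describe_counts(qs$total))
  runs <- stage("runs_test", lapply(setNames(nm = categories()), function(cat) {
    tryCatch(runs_test(qs[[cat]]), error = function(e) {
      list(n_runs = NA, n_above = NA, n_below = NA, p_value = NA,
           method = "unavailable")
    })
  }))
  genders <- unique_authors$gender
  chi <- if (all(genders == "unknown") ||
             length(unique(genders[genders != "unknown"])) < 2) {
    NULL
  } else {
    stage("gender_chi_square", list(
      omnibus = gender_chi_square(unique_authors, classified$assignments,
                                  "omnibus"),
      per_category = gender_chi_square(unique_authors, classified$assignments,
                                       "per_category",
                                       correct = config$per_category_correct)
    ))
  }
  terms <- stage("term_frequencies",
                 term_frequencies(unique_authors$text, config$top_n_terms))
  tags <- stage("hashtag_frequencies",
                hashtag_frequencies(unique_authors$text,
                                    config$top_n_hashtags))

  stage("write_artifacts", {
    write_corpus(unique_authors, artifacts[1], "jsonl")
    write_table(dedup$clusters, artifacts[2], "csv")
    write_table(classified$assignments, artifacts[3], "csv")
    write_table(qs, artifacts[4], "csv")
  })

  chi_export <- function(x) {
    if (is.null(x)) return(NULL)
    list(statistic = x$statistic, df = x$df, p_value = x$p_value,
         p_bonferroni = x$p_bonferroni, observed = x$observed,
         correct = x$correct)
  }
  stats_report <- list(
    descriptives = desc,
    runs_tests = runs,
    chi_square = if (is.null(chi)) NULL else list(
      omnibus = chi_export(chi$omnibus),
      per_category = lapply(chi$per_category, chi_export)
    ),
    top_terms = terms,
    top_hashtags = tags
  )
  jsonlite::write_json(stats_report, artifacts[5], auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, na = "null")

  report <- list(
    software = list(package = "fluortweet",
                    version = as.character(utils::packageVersion("fluortweet"))),
    config = c(config[setdiff(names(config), c("window_start", "window_end"))],
               list(window_start = as.character(config$window_start),
                    window_end = as.character(config$window_end))),
    stage_counts = list(
      collected = nrow(corpus),
      keyword_filtered = nrow(filtered),
      eliminated_by_dedup = dedup$n_eliminated,
      flagged_nonhuman = length(dedup$flagged_nonhuman),
      removed_by_unique_author = nrow(dedup$retained) - nrow(unique_authors),
      labels_dropped = n_labels_dropped,
      classified = nrow(classified$assignments)
    ),
    category_summary = classified$summary,
    agreement = list(per_category = seeded$agreement,
                     n_rated = seeded$n_rated,
                     n_consensus = seeded$n_consensus),
    quarterly_descriptives = desc,
    runs_tests = runs
  )
  jsonlite::write_json(report, artifacts[6], auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, na = "null")
  ok <- TRUE
  invisible(report)
}
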