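#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` where `p_o` is the
#' observed diagonal fraction and `p_e` the chance agreement from the row and
#' column marginals.
#'
#' @param table A 2x2 matrix of agreement counts (rater 1 in rows, rater 2 in
#'   columns, same class order).
#' @return Kappa in \[-1, 1\].
#' @export
#' @examples
#' cohens_kappa(matrix(c(20, 10, 5, 15), 2))
cohens_kappa <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0)) {
    abort("table must be a 2x2 matrix of non-negative counts")
  }
  n <- sum(table)
  if (n <= 0) abort("table must have a positive total")
  po <- sum(diag(table)) / n
  pe <- sum(rowSums(table) * colSums(table)) / n^2
  if (abs(1 - pe) < 1e-12) {
    abort("degenerate marginals: chance agreement equals 1")
  }
  (po - pe) / (1 - pe)
}

percent_agreement <- function(table) {
  table <- as.matrix(table)
  sum(diag(table)) / sum(table)
}

#' Build the consensus seed set and the inter-rater agreement report
#'
#' Every labelled post must carry exactly two ratings from two distinct
#' raters. Posts on which both raters chose the same category form the seed
#' set; disagreements are dropped but still count toward `n_rated`.
#' Agreement is quantified per category one-vs-rest: percent agreement and
#' Cohen's kappa of the 2x2 table "rater 1 chose this category" against
#' "rater 2 chose this category".
#'
#' @param labels Label tibble (`tweet_id`, `rater_id`, `category`), e.g. from
#'   [read_labels()].
#' @param corpus Corpus tibble containing every labelled id.
#' @return A list with
#'   \describe{
#'     \item{seeds}{a `seed_set`: named list (category -> tibble of
#'       `tweet_id` and token sequences)}
#'     \item{agreement}{tibble `category`, `percent_agreement`, `kappa`}
#'     \item{n_rated, n_consensus}{sample sizes}
#'   }
#' @export
build_seed_set <- function(labels, corpus) {
  bad <- !(labels$category %in% categories())
  if (any(bad)) {
    abort(sprintf("unknown category string(s): %s",
                  paste(unique(labels$category[bad]), collapse = ", ")))
  }
  counts <- table(labels$tweet_id)
  wrong <- names(counts)[counts != 2]
  if (length(wrong) > 0) {
    abort(sprintf("tweet(s) without exactly 2 ratings: %s",
                  paste(head(wrong, 10), collapse = ", ")))
  }
  missing <- setdiff(labels$tweet_id, corpus$id)
  if (length(missing) > 0) {
    abort(sprintf("labelled tweet id(s) not in corpus: %s",
                  paste(head(missing, 10), collapse = ", ")))
  }
  labels <- labels[order(labels$tweet_id, labels$rater_id), , drop = FALSE]
  first <- labels[!duplicated(labels$tweet_id), , drop = FALSE]
  second <- labels[duplicated(labels$tweet_id), , drop = FALSE]
  if (any(first$rater_id == second$rater_id)) {
    abort("each tweet must be rated by two distinct raters")
  }
  pair <- tibble::tibble(tweet_id = first$tweet_id,
                         r1 = first$category, r2 = second$category)
  agreement <- purrr::map_dfr(categories(), function(cat) {
    tab <- matrix(0, 2, 2)
    tab[1, 1] <- sum(pair$r1 == cat & pair$r2 == cat)
    tab[1, 2] <- sum(pair$r1 == cat & pair$r2 != cat)
    tab[2, 1] <- sum(pair$r1 != cat & pair$r2 == cat)
    tab[2, 2] <- sum(pair$r1 != cat & pair$r2 != cat)
    tibble::tibble(category = cat,
                   percent_agreement = percent_agreement(tab),
                   kappa = cohens_kappa(tab))
  })
  consensus <- pair[pair$r1 == pair$r2, , drop = FALSE]
  tokens <- normalize_text(corpus$text[match(consensus$tweet_id, corpus$id)])
  members <- lapply(categories(), function(cat) {
    idx <- which(consensus$r1 == cat)
    tibble::tibble(tweet_id = consensus$tweet_id[idx], tokens = tokens[idx])
  })
  names(members) <- categories()
  seeds <- structure(members, class = "seed_set")
  list(seeds = seeds, agreement = agreement,
       n_rated = nrow(pair), n_consensus = nrow(consensus))
}

#' @export
print.seed_set <- function(x, ...) {
  cat("<seed_set>",
      paste(sprintf("%s: %d", names(x), vapply(x, nrow, integer(1))),
            collapse = ", "), "\n")
  invisible(x)
}

validate_seed_set <- function(seeds) {
  stopifnot(inherits(seeds, "seed_set"))
  empty <- names(seeds)[vapply(seeds, nrow, integer(1)) == 0]
  if (length(empty) > 0) {
    abort(sprintf("seed set has empty categor%s: %s",
                  if (length(empty) > 1) "ies" else "y",
                  paste(empty, collapse = ", ")))
  }
  invisible(seeds)
}

# Aggregate a query-vs-seed similarity matrix into per-category max and mean
# scores. simmat: n x total_seeds; sizes: seeds per category.
aggregate_scores <- function(simmat, sizes) {
  stopifnot(sum(sizes) == ncol(simmat))
  stops <- cumsum(sizes)
  starts <- stops - sizes + 1
  max_s <- matrix(0, nrow(simmat), length(sizes))
  mean_s <- matrix(0, nrow(simmat), length(sizes))
  for (k in seq_along(sizes)) {
    block <- simmat[, starts[k]:stops[k], drop = FALSE]
    max_s[, k] <- apply(block, 1, max)
    mean_s[, k] <- rowMeans(block)
  }
  list(max = max_s, mean = mean_s)
}

# Pick the winning category per row: argmax of score, ties broken by mean
# similarity over the tied categories, then by canonical category order.
pick_category <- function(score, mean_score) {
  n <- nrow(score)
  cats <- categories()
  choice <- integer(n)
  best <- apply(score, 1, max)
  second <- numeric(n)
  for (i in seq_len(n)) {
    tied <- which(score[i, ] >= best[i] - 1e-12)
    if (length(tied) > 1) {
      tied <- tied[mean_score[i, tied] >= max(mean_score[i, tied]) - 1e-12]
    }
    choice[i] <- tied[1]  # canonical order
    others <- score[i, -choice[i]]
    second[i] <- if (length(others) > 0) max(others) else 0
  }
  tibble::tibble(category = cats[choice], score = best,
                 runner_up_margin = best - second)
}

#' Assign one post to its most syntactically similar category
#'
#' Scores the post against every seed in each category with the normalized
#' word-level Levenshtein similarity; the per-category score is the maximum
#' over that category's seeds (nearest neighbour) or, with
#' `aggregation = "mean_top_k"`, the mean of the top `k` seed similarities.
#' The post joins the arg-max category; exact ties are broken by the mean
#' similarity over the tied categories' seeds, then by canonical category
#' order. A score below `confidence_floor` marks the assignment low
#' confidence (an empty token sequence scores 0 everywhere and falls through
#' the tie rule).
#'
#' @param tokens Character vector of normalized tokens (one post).
#' @param seeds A validated `seed_set` (see [build_seed_set()]).
#' @param aggregation `"max"` (nearest neighbour, default) or `"mean_top_k"`.
#' @param k Number of top seeds averaged when `aggregation = "mean_top_k"`.
#' @param confidence_floor Score below which `low_confidence` is set.
#' @return One-row tibble: `category`, `score`, `runner_up_margin`,
#'   `low_confidence`.
#' @export
assign_category <- function(tokens, seeds, aggregation = c("max", "mean_top_k"),
                            k = 3, confidence_floor = 0.1) {
  aggregation <- match.arg(aggregation)
  validate_seed_set(seeds)
  res <- score_against_seeds(list(as.character(tokens)), seeds, aggregation, k)
  out <- pick_category(res$score, res$mean)
  out$low_confidence <- out$score < confidence_floor
  out
}

score_against_seeds <- function(token_list, seeds, aggregation = "max", k = 3) {
  sizes <- vapply(seeds, nrow, integer(1))
  all_seed_tokens <- unlist(lapply(seeds, function(m) m$tokens),
                            recursive = FALSE)
  simmat <- sim_matrix(token_list, all_seed_tokens)
  agg <- aggregate_scores(simmat, sizes)
  score <- if (aggregation == "max") {
    agg$max
  } else {
    stops <- cumsum(sizes); starts <- stops - sizes + 1
    sc <- matrix(0, nrow(simmat), length(sizes))
    for (j in seq_along(sizes)) {
      block <- simmat[, starts[j]:stops[j], drop = FALSE]
      kk <- min(k, ncol(block))
      sc[, j] <- apply(block, 1, function(r) mean(sort(r, decreasing = TRUE)[1:kk]))
    }
    sc
  }
  list(score = score, mean = agg$mean)
}

#' Classify a deduplicated corpus against the seed set
#'
#' Seed posts keep their consensus label and are not re-scored; every other
#' post is assigned by [assign_category()]. Category counts include the seed
#' posts; percentages are reported to one decimal (half-up rounding).
#'
#' @param records Deduplicated, author-unique corpus tibble.
#' @param seeds A `seed_set` whose four categories are all non-empty.
#' @inheritParams assign_category
#' @return A list with `assignments` (tibble `tweet_id`, `category`, `score`,
#'   `runner_up_margin`, `low_confidence`, `seeded`) and `summary` (tibble
#'   `category`, `n`, `pct`).
#' @export
classify_corpus <- function(records, seeds, aggregation = c("max", "mean_top_k"),
                            k = 3, confidence_floor = 0.1) {
  aggregation <- match.arg(aggregation)
  validate_seed_set(seeds)
  seed_ids <- unlist(lapply(seeds, function(m) m$tweet_id), use.names = FALSE)
  seed_cat <- rep(names(seeds), vapply(seeds, nrow, integer(1)))
  is_seed <- records$id %in% seed_ids
  seed_part <- tibble::tibble(
    tweet_id = records$id[is_seed],
    category = seed_cat[match(records$id[is_seed], seed_ids)],
    score = 1.0, runner_up_margin = NA_real_,
    low_confidence = FALSE, seeded = TRUE
  )
  query <- records[!is_seed, , drop = FALSE]
  if (nrow(query) > 0) {
    tokens <- normalize_text(query$text)
    res <- score_against_seeds(tokens, seeds, aggregation, k)
    picked <- pick_category(res$score, res$mean)
    query_part <- tibble::tibble(
      tweet_id = query$id,
      category = picked$category,
      score = picked$score,
      runner_up_margin = picked$runner_up_margin,
      low_confidence = picked$score < confidence_floor,
      seeded = FALSE
    )
  } else {
    query_part <- seed_part[0, ]
  }
  assignments <- dplyr::bind_rows(seed_part, query_part)
  assignments <- assignments[match(records$id, assignments$tweet_id), ,
                             drop = FALSE]
  list(assignments = assignments,
       summary = summarize_assignments(assignments))
}

#' Category counts and percentages of an assignment table
#'
#' @param assignments Tibble with a `category` column.
#' @return Tibble `category`, `n`, `pct` (percent of total, one decimal,
#'   half-up rounding), in canonical category order.
#' @export
summarize_assignments <- function(assignments) {
  n <- vapply(categories(), function(cat) {
    sum(assignments$category == cat)
  }, integer(1))
  total <- sum(n)
  tibble::tibble(
    category = categories(),
    n = unname(n),
    pct = if (total > 0) round_half_up(100 * unname(n) / total, 1) else
      rep(NA_real_, length(n))
  )
}
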