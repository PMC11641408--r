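#' Configuration for the synthetic corpus generator
#'
#' The defaults state the world the analysis targets: four latent content
#' categories at the published corpus proportions (48.5% concern, 7%
#' experience, 18.1% positive, 26.4% negative), a 2017-01-01 to 2020-01-01
#' posting window split into 12 quarters, retweet near-duplicates,
#' advertisement clusters posted by distinct accounts, occasional repeat
#' authors, a female-skewed gender mix (75/12/13 female/male/unknown) and a
#' rising quarterly trend in concern posts (first-to-last quarter volume
#' ratio about 2.75, matching the reported 478 to 1,315 rise).
#'
#' Category texts are rendered from a unigram model with disjoint
#' per-category vocabularies plus a shared pool, so classification against
#' seed posts has a well-defined ground truth.
#'
#' @param n_tweets Total number of posts (originals + duplicates + ads).
#' @param category_proportions Four probabilities (canonical category order)
#'   summing to 1.
#' @param duplicate_fraction Fraction of posts that are retweet copies of an
#'   original, in \[0, 1).
#' @param ad_clusters,ad_cluster_size Number and size of near-identical
#'   advertisement clusters (distinct authors within a cluster).
#' @param author_repeat_rate Probability that an original post reuses an
#'   existing author instead of a fresh one.
#' @param gender_probs Probabilities (female, male, unknown) per author.
#' @param vocab_size_per_category,shared_vocab_size Vocabulary sizes.
#' @param tweet_length Integer (min, max) token count per post body.
#' @param trend Per-category linear slope of quarterly volume: quarter q
#'   (0-based, of 11) has sampling weight `1 + slope * q / 11`.
#' @param shared_token_rate Probability a body token comes from the shared
#'   pool rather than the category vocabulary.
#' @param hashtag_rate Probability a post carries one hashtag from the
#'   planted hashtag pool.
#' @param window_start,window_end Posting window (half-open).
#' @param rng_seed Integer seed; all generator randomness flows from it.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_tweets = 2000,
                             category_proportions = c(concern = 0.485,
                                                      experience = 0.07,
                                                      positive = 0.181,
                                                      negative = 0.264),
                             duplicate_fraction = 0.2,
                             ad_clusters = 5,
                             ad_cluster_size = 8,
                             author_repeat_rate = 0.05,
                             gender_probs = c(female = 0.75, male = 0.12,
                                              unknown = 0.13),
                             vocab_size_per_category = 120,
                             shared_vocab_size = 60,
                             tweet_length = c(6, 18),
                             trend = c(concern = 1.75, experience = 0,
                                       positive = 0.5, negative = 0.3),
                             shared_token_rate = 0.2,
                             hashtag_rate = 0.3,
                             window_start = as.Date("2017-01-01"),
                             window_end = as.Date("2020-01-01"),
                             rng_seed = 20170101) {
  if (length(category_proportions) != 4 ||
      abs(sum(category_proportions) - 1) > 1e-9) {
    abort("category_proportions must be 4 values summing to 1")
  }
  if (duplicate_fraction < 0 || duplicate_fraction >= 1) {
    abort("duplicate_fraction must be in [0, 1)")
  }
  if (abs(sum(gender_probs) - 1) > 1e-9) {
    abort("gender_probs must sum to 1")
  }
  if (length(tweet_length) != 2 || tweet_length[1] > tweet_length[2] ||
      tweet_length[1] < 1) {
    abort("tweet_length must be (min, max) with 1 <= min <= max")
  }
  n_ad <- ad_clusters * ad_cluster_size
  n_dup <- round(duplicate_fraction * n_tweets)
  if (n_tweets - n_ad - n_dup < 1) {
    abort("infeasible config: no room for original posts")
  }
  structure(list(
    n_tweets = n_tweets,
    category_proportions = setNames(category_proportions, categories()),
    duplicate_fraction = duplicate_fraction,
    ad_clusters = ad_clusters, ad_cluster_size = ad_cluster_size,
    author_repeat_rate = author_repeat_rate,
    gender_probs = setNames(gender_probs, c("female", "male", "unknown")),
    vocab_size_per_category = vocab_size_per_category,
    shared_vocab_size = shared_vocab_size,
    tweet_length = as.integer(tweet_length),
    trend = setNames(trend, categories()),
    shared_token_rate = shared_token_rate,
    hashtag_rate = hashtag_rate,
    window_start = as.Date(window_start), window_end = as.Date(window_end),
    rng_seed = as.integer(rng_seed)
  ), class = "generator_config")
}

# Planted hashtag pool with strongly separated frequencies, mirroring the
# kinds of tags seen in topical-fluoride posts.
planted_hashtags <- function() {
  tibble::tibble(
    tag = c("#caries", "#fluoridevarnish", "#toothvarnish",
            "#topicalfluoride", "#pediatricdentistry"),
    weight = c(8627, 4823, 3441, 1258, 1021)
  )
}

#' Generate a synthetic post corpus with full ground truth
#'
#' Originals are drawn per category from a unigram model over that category's
#' vocabulary plus a shared pool, each embedding one study keyword phrase so
#' the keyword filter retains them. Retweet duplicates copy an original with
#' an `"RT @user:"` prefix and a later timestamp; advertisement clusters are
#' near-identical texts from distinct authors. Timestamps follow per-category
#' quarterly weights implementing the planted linear trend. The generator is
#' fully deterministic given `rng_seed` and touches no global RNG state.
#'
#' @param config A [generator_config()].
#' @return A list with `records` (corpus tibble in chronological order) and
#'   `truth` (tibble `tweet_id`, `true_category`, `duplicate_of`, `is_ad`).
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  withr::local_seed(config$rng_seed)
  cats <- categories()
  kw <- default_keywords()
  n_ad <- config$ad_clusters * config$ad_cluster_size
  n_dup <- round(config$duplicate_fraction * config$n_tweets)
  n_orig <- config$n_tweets - n_ad - n_dup

  vocab <- lapply(seq_along(cats), function(k) {
    sprintf("%sw%03d", substr(cats[k], 1, 4), seq_len(config$vocab_size_per_category))
  })
  shared <- sprintf("comw%03d", seq_len(config$shared_vocab_size))
  # Zipf word weights: same-stance posts reuse the same high-frequency
  # phrases, which is what makes nearest-seed lookup work on real text.
  vocab_w <- 1 / seq_len(config$vocab_size_per_category)
  shared_w <- 1 / seq_len(config$shared_vocab_size)

  grid <- quarter_sequence(config$window_start, config$window_end)
  nq <- nrow(grid)
  q_bounds <- as.POSIXct(paste(seq(config$window_start, config$window_end,
                                   by = "3 months"), "00:00:00"), tz = "UTC")
  q_weights <- lapply(cats, function(cat) {
    w <- 1 + config$trend[[cat]] * (seq_len(nq) - 1) / (nq - 1)
    w <- pmax(w, 0.05)
    w / sum(w)
  })
  names(q_weights) <- cats

  draw_timestamp <- function(qi) {
    q_bounds[qi] + stats::runif(length(qi)) *
      as.numeric(difftime(q_bounds[qi + 1], q_bounds[qi], units = "secs"))
  }

  # --- originals -----------------------------------------------------------
  cat_idx <- sample.int(4, n_orig, replace = TRUE,
                        prob = config$category_proportions)
  q_idx <- integer(n_orig)
  for (k in 1:4) {
    sel <- cat_idx == k
    if (any(sel)) {
      q_idx[sel] <- sample.int(nq, sum(sel), replace = TRUE,
                               prob = q_weights[[k]])
    }
  }
  lens <- sample(seq(config$tweet_length[1], config$tweet_length[2]),
                 n_orig, replace = TRUE)
  tags <- planted_hashtags()
  texts <- character(n_orig)
  for (i in seq_len(n_orig)) {
    k <- cat_idx[i]
    from_shared <- stats::runif(lens[i]) < config$shared_token_rate
    toks <- ifelse(from_shared,
                   sample(shared, lens[i], replace = TRUE, prob = shared_w),
                   sample(vocab[[k]], lens[i], replace = TRUE, prob = vocab_w))
    pos <- sample.int(lens[i] + 1, 1) - 1
    toks <- append(toks, sample(kw, 1), after = pos)
    if (stats::runif(1) < config$hashtag_rate) {
      toks <- c(toks, sample(tags$tag, 1, prob = tags$weight))
    }
    texts[i] <- paste(toks, collapse = " ")
  }
  authors <- character(n_orig)
  n_new <- 0L
  for (i in seq_len(n_orig)) {
    if (i > 1 && stats::runif(1) < config$author_repeat_rate) {
      authors[i] <- authors[sample.int(i - 1, 1)]
    } else {
      n_new <- n_new + 1L
      authors[i] <- sprintf("u%06d", n_new)
    }
  }
  orig <- tibble::tibble(
    text = texts, created_at = draw_timestamp(q_idx), author_id = authors,
    true_category = cats[cat_idx], duplicate_of_row = NA_integer_,
    is_ad = FALSE
  )

  # --- retweet duplicates --------------------------------------------------
  if (n_dup > 0) {
    src <- sample.int(n_orig, n_dup, replace = TRUE)
    win_end <- as.POSIXct(paste(config$window_end, "00:00:00"), tz = "UTC")
    slack <- pmin(7 * 86400,
                  0.9 * as.numeric(difftime(win_end, orig$created_at[src],
                                            units = "secs")))
    dup <- tibble::tibble(
      text = paste0("RT @", orig$author_id[src], ": ", orig$text[src]),
      created_at = orig$created_at[src] + stats::runif(n_dup, 0.01, 1) * slack,
      author_id = sprintf("rt%06d", seq_len(n_dup)),
      true_category = orig$true_category[src],
      duplicate_of_row = src,
      is_ad = FALSE
    )
  } else {
    dup <- orig[0, ]
  }

  # --- advertisement clusters ----------------------------------------------
  ads <- NULL
  if (config$ad_clusters > 0) {
    ad_rows <- vector("list", config$ad_clusters)
    for (cl in seq_len(config$ad_clusters)) {
      k <- sample.int(4, 1, prob = config$category_proportions)
      base <- c(sample(shared, 10, replace = TRUE, prob = shared_w),
                sample(kw, 1), sprintf("promo%03d", cl))
      qi <- sample.int(nq, config$ad_cluster_size, replace = TRUE)
      member_texts <- vapply(seq_len(config$ad_cluster_size), function(j) {
        toks <- base
        if (j > 1) {
          # mutate a filler position only, never the keyword or promo token
          toks[sample.int(10, 1)] <- sample(shared, 1)
        }
        paste(toks, collapse = " ")
      }, character(1))
      ad_rows[[cl]] <- tibble::tibble(
        text = member_texts,
        created_at = draw_timestamp(qi),
        author_id = sprintf("ad%03d_%03d", cl, seq_len(config$ad_cluster_size)),
        true_category = cats[k],
        duplicate_of_row = NA_integer_,
        is_ad = TRUE
      )
    }
    ads <- dplyr::bind_rows(ad_rows)
  }

  all_rows <- dplyr::bind_rows(orig, dup, ads)
  ord <- order(all_rows$created_at)
  all_rows <- all_rows[ord, , drop = FALSE]
  inv <- integer(nrow(all_rows))
  inv[ord] <- seq_len(nrow(all_rows))  # old row -> new position
  ids <- sprintf("t%06d", seq_len(nrow(all_rows)))
  dup_of <- ifelse(is.na(all_rows$duplicate_of_row), NA_character_,
                   ids[inv[all_rows$duplicate_of_row]])

  author_pool <- unique(all_rows$author_id)
  g <- sample(c("female", "male", "unknown"), length(author_pool),
              replace = TRUE, prob = config$gender_probs)
  records <- tibble::tibble(
    id = ids,
    text = all_rows$text,
    created_at = all_rows$created_at,
    author_id = all_rows$author_id,
    gender = g[match(all_rows$author_id, author_pool)]
  )
  truth <- tibble::tibble(
    tweet_id = ids,
    true_category = all_rows$true_category,
    duplicate_of = dup_of,
    is_ad = all_rows$is_ad
  )
  list(records = records, truth = truth)
}

#' Simulate a two-rater labelling of a random seed sample
#'
#' Samples posts without replacement from the original (non-duplicate,
#' non-advertisement) part of the corpus and labels each twice: each
#' simulated rater reports the true category with probability `1 - e`, else
#' a uniformly random other category, independently.
#'
#' @param truth Ground-truth tibble from [generate_corpus()].
#' @param sample_size Number of posts to label (ignored when `per_category`
#'   is given).
#' @param rater_error_rates Two error probabilities in \[0, 0.5).
#' @param rng_seed Integer seed for the sampling and rater noise.
#' @param per_category Optional: sample exactly this many posts from each
#'   true category (stratified seed sample) instead of `sample_size` overall.
#' @return Label tibble `tweet_id`, `rater_id`, `category` (two rows per
#'   sampled post).
#' @export
generate_rater_labels <- function(truth, sample_size = 500,
                                  rater_error_rates = c(0, 0),
                                  rng_seed = 1, per_category = NULL) {
  if (any(rater_error_rates < 0) || any(rater_error_rates >= 0.5)) {
    abort("rater_error_rates must be in [0, 0.5)")
  }
  withr::local_seed(rng_seed)
  pool <- truth[is.na(truth$duplicate_of) & !truth$is_ad, , drop = FALSE]
  if (!is.null(per_category)) {
    ids <- unlist(lapply(categories(), function(cat) {
      avail <- pool$tweet_id[pool$true_category == cat]
      if (length(avail) < per_category) {
        abort(sprintf("category %s has only %d original posts, need %d",
                      cat, length(avail), per_category))
      }
      sample(avail, per_category)
    }), use.names = FALSE)
  } else {
    if (sample_size > nrow(pool)) {
      abort(sprintf("sample_size %d exceeds %d original posts",
                    sample_size, nrow(pool)))
    }
    ids <- sample(pool$tweet_id, sample_size)
  }
  true_cat <- pool$true_category[match(ids, pool$tweet_id)]
  rate_one <- function(e) {
    flip <- stats::runif(length(ids)) < e
    out <- true_cat
    if (any(flip)) {
      out[flip] <- vapply(true_cat[flip], function(ct) {
        sample(setdiff(categories(), ct), 1)
      }, character(1))
    }
    out
  }
  labels <- dplyr::bind_rows(
    tibble::tibble(tweet_id = ids, rater_id = "expert1",
                   category = rate_one(rater_error_rates[1])),
    tibble::tibble(tweet_id = ids, rater_id = "expert2",
                   category = rate_one(rater_error_rates[2]))
  )
  labels[order(labels$tweet_id, labels$rater_id), , drop = FALSE]
}
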