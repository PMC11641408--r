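#' Per-quarter category counts over the study window
#'
#' Joins assignments to their records' timestamps and tabulates counts per
#' calendar quarter and category; every quarter of the window appears even
#' when empty (12 quarters for the default 2017-2020 window).
#'
#' @param assignments Assignment tibble (`tweet_id`, `category`).
#' @param records Corpus tibble supplying `id` and `created_at`.
#' @inheritParams quarter_of
#' @return Tibble with columns `quarter` (label), one column per category,
#'   and `total`, in chronological order.
#' @export
build_quarter_series <- function(assignments, records,
                                 window_start = as.Date("2017-01-01"),
                                 window_end = as.Date("2020-01-01")) {
  idx <- match(assignments$tweet_id, records$id)
  if (anyNA(idx)) abort("assignment tweet_id(s) missing from records")
  q <- quarter_of(records$created_at[idx], window_start, window_end)
  grid <- quarter_sequence(window_start, window_end)
  out <- tibble::tibble(quarter = grid$label)
  for (cat in categories()) {
    tab <- table(factor(q$label[assignments$category == cat],
                        levels = grid$label))
    out[[cat]] <- as.integer(tab)
  }
  out$total <- rowSums(as.matrix(out[, categories()]))
  out
}

#' Descriptive statistics of quarterly counts
#'
#' Sample standard deviation (n-1 denominator); the median uses the midpoint
#' convention for even n. The mean is reported both as a real number and
#' truncated toward zero (`mean_trunc`), the headline convention for
#' "average posts per quarter".
#'
#' @param values Non-empty numeric vector.
#' @return A list: `mean`, `mean_trunc`, `sd`, `median`, `min`, `max`.
#' @export
#' @examples
#' describe_counts(c(1, 2, 3))
describe_counts <- function(values) {
  if (length(values) == 0) abort("values must be non-empty")
  values <- as.numeric(values)
  list(
    mean = mean(values),
    mean_trunc = trunc(mean(values)),
    sd = if (length(values) > 1) sd(values) else NA_real_,
    median = median(values),
    min = min(values),
    max = max(values)
  )
}

# Exact distribution of the number of runs given n1 symbols of one kind and
# n2 of the other, all arrangements equally likely. Returns P(R = r) for
# r = 1 .. n1 + n2.
runs_distribution <- function(n1, n2) {
  n <- n1 + n2
  pr <- numeric(n)
  denom <- choose(n, n1)
  for (r in 2:n) {
    if (r %% 2 == 0) {
      k <- r / 2
      pr[r] <- 2 * choose(n1 - 1, k - 1) * choose(n2 - 1, k - 1) / denom
    } else {
      k <- (r - 1) / 2
      pr[r] <- (choose(n1 - 1, k) * choose(n2 - 1, k - 1) +
                choose(n1 - 1, k - 1) * choose(n2 - 1, k)) / denom
    }
  }
  pr
}

count_runs <- function(x) {
  if (length(x) == 0) return(0L)
  1L + sum(x[-1] != x[-length(x)])
}

#' Wald-Wolfowitz runs test about the median
#'
#' Dichotomizes the series about its sample median (values equal to the
#' cutpoint are dropped), counts runs, and computes a two-sided p-value:
#' exactly, from the closed-form run-count distribution, when at most 30
#' values remain; otherwise by normal approximation with continuity
#' correction. The exact two-sided p is `min(1, 2 * min(P(R <= r),
#' P(R >= r)))`. The test detects non-randomness (e.g. trend) of the
#' sequence; it carries no information about the direction of a trend.
#'
#' @param values Numeric vector, length >= 2.
#' @param cutpoint Dichotomization point; defaults to the sample median.
#' @return A list: `n_runs`, `n_above`, `n_below`, `p_value`, `method`
#'   (`"exact"` or `"normal_approx"`).
#' @export
#' @examples
#' runs_test(c(5, 5, 5, 9, 9, 9))
runs_test <- function(values, cutpoint = median(values)) {
  if (length(values) < 2) abort("need at least 2 values")
  x <- values[values != cutpoint]
  if (length(x) < 2) {
    abort("fewer than 2 values remain after dropping ties with the cutpoint")
  }
  above <- x > cutpoint
  n1 <- sum(above)
  n2 <- sum(!above)
  r <- count_runs(above)
  if (n1 == 0 || n2 == 0) {
    return(list(n_runs = r, n_above = n1, n_below = n2,
                p_value = 1, method = "exact"))
  }
  if (n1 + n2 <= 30) {
    pr <- runs_distribution(n1, n2)
    lower <- sum(pr[seq_len(r)])
    upper <- sum(pr[r:length(pr)])
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- 1 + 2 * n1 * n2 / n
    sigma <- sqrt(2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1)))
    z <- (abs(r - mu) - 0.5) / sigma
    z <- max(z, 0)
    p <- 2 * pnorm(-z)
    method <- "normal_approx"
  }
  list(n_runs = r, n_above = n1, n_below = n2, p_value = p, method = method)
}

#' Pearson chi-square test for a contingency table
#'
#' Hand-rolled Pearson statistic so the arithmetic is transparent and
#' cross-checkable against `stats::chisq.test()`. Yates continuity
#' correction (subtracting `min(0.5, |O - E|)` before squaring) is available
#' for 2x2 tables.
#'
#' @param observed Matrix of non-negative counts.
#' @param correct Apply Yates continuity correction (2x2 only)?
#' @return A list: `statistic`, `df`, `p_value`, `observed`, `expected`,
#'   `correct`.
#' @export
chi_square_table <- function(observed, correct = FALSE) {
  observed <- as.matrix(observed)
  if (any(observed < 0)) abort("observed counts must be non-negative")
  n <- sum(observed)
  if (n <= 0) abort("table total must be positive")
  expected <- outer(rowSums(observed), colSums(observed)) / n
  zero <- which(expected == 0, arr.ind = TRUE)
  if (nrow(zero) > 0) {
    abort(sprintf("expected count is zero in cell (%d, %d)",
                  zero[1, 1], zero[1, 2]))
  }
  dev <- abs(observed - expected)
  if (correct) {
    if (!all(dim(observed) == c(2, 2))) {
      abort("continuity correction applies to 2x2 tables only")
    }
    dev <- dev - pmin(0.5, dev)
  }
  statistic <- sum(dev^2 / expected)
  df <- (nrow(observed) - 1) * (ncol(observed) - 1)
  list(statistic = statistic, df = df,
       p_value = pchisq(statistic, df, lower.tail = FALSE),
       observed = observed, expected = expected, correct = correct)
}

#' Chi-square tests for gender differences across categories
#'
#' Posts with unknown gender are excluded (shares are reported among
#' identified users). `mode = "omnibus"` tests the full 2 x 4
#' gender-by-category table without continuity correction;
#' `mode = "per_category"` runs one 2x2 test per category (that category vs
#' the rest; Yates correction by default) and reports raw and
#' Bonferroni-adjusted p-values.
#'
#' @param records Corpus tibble with a `gender` column.
#' @param assignments Assignment tibble (`tweet_id`, `category`).
#' @param mode `"omnibus"` or `"per_category"`.
#' @param correct Yates correction for the per-category 2x2 tables.
#' @return For `"omnibus"`, one result list from [chi_square_table()]; for
#'   `"per_category"`, a named list of four such results, each with an added
#'   `p_bonferroni`.
#' @export
gender_chi_square <- function(records, assignments,
                              mode = c("omnibus", "per_category"),
                              correct = TRUE) {
  mode <- match.arg(mode)
  idx <- match(assignments$tweet_id, records$id)
  if (anyNA(idx)) abort("assignment tweet_id(s) missing from records")
  gender <- records$gender[idx]
  keep <- gender != "unknown"
  gender <- factor(gender[keep], levels = c("female", "male"))
  category <- factor(assignments$category[keep], levels = categories())
  tab <- table(gender, category)
  if (mode == "omnibus") {
    chi_square_table(unclass(tab), correct = FALSE)
  } else {
    out <- lapply(categories(), function(cat) {
      m <- cbind(tab[, cat], rowSums(tab) - tab[, cat])
      colnames(m) <- c(cat, "other")
      res <- chi_square_table(m, correct = correct)
      res$p_bonferroni <- min(1, res$p_value * length(categories()))
      res
    })
    names(out) <- categories()
    out
  }
}

#' Ranked term frequencies
#'
#' Counts tokens over a corpus, ranked descending by count with lexicographic
#' tie-breaking.
#'
#' @param tokens A list of token character vectors (e.g. [normalize_text()]
#'   output) or a character vector of raw texts (normalized first).
#' @param top_n Number of top terms to keep (default all).
#' @return Tibble `term`, `count`.
#' @export
term_frequencies <- function(tokens, top_n = Inf) {
  if (top_n < 1) abort("top_n must be >= 1")
  if (is.character(tokens)) tokens <- normalize_text(tokens)
  words <- unlist(tokens, use.names = FALSE)
  if (length(words) == 0) {
    return(tibble::tibble(term = character(0), count = integer(0)))
  }
  tab <- table(words)
  out <- tibble::tibble(term = names(tab), count = as.integer(tab))
  out <- out[order(-out$count, out$term), , drop = FALSE]
  head(out, top_n)
}

#' Ranked hashtag frequencies
#'
#' @param texts Character vector of raw texts.
#' @param top_n Number of top hashtags to keep (default all).
#' @return Tibble `term` (with leading `#`), `count`.
#' @export
hashtag_frequencies <- function(texts, top_n = Inf) {
  if (top_n < 1) abort("top_n must be >= 1")
  tags <- unlist(extract_hashtags(texts), use.names = FALSE)
  if (length(tags) == 0) {
    return(tibble::tibble(term = character(0), count = integer(0)))
  }
  tab <- table(tags)
  out <- tibble::tibble(term = names(tab), count = as.integer(tab))
  out <- out[order(-out$count, out$term), , drop = FALSE]
  head(out, top_n)
}
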