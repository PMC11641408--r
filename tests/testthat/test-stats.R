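test_that("quarter series indexes categories into the right quarters", {
  empty <- build_quarter_series(
    tibble::tibble(tweet_id = character(0), category = character(0)),
    make_corpus(character(0)))
  expect_equal(nrow(empty), 12)
  expect_true(all(empty$total == 0))

  corp <- make_corpus("one concern post", start = "2018-05-10 12:00:00")
  qs <- build_quarter_series(
    tibble::tibble(tweet_id = "t001", category = "concern"), corp)
  expect_equal(qs$concern, c(rep(0, 5), 1, rep(0, 6)))  # 2018-Q2 is index 6
  expect_equal(sum(qs$total), 1)
})

test_that("quarterly totals conserve the classified corpus size", {
  sim <- generate_corpus(generator_config(n_tweets = 400, rng_seed = 21))
  res <- leader_cluster(sim$records, 0.8)
  ua <- enforce_unique_authors(res$retained)
  truth_as_assign <- tibble::tibble(tweet_id = ua$id,
                                    category = sim$truth$true_category[
                                      match(ua$id, sim$truth$tweet_id)])
  qs <- build_quarter_series(truth_as_assign, ua)
  expect_equal(sum(qs$total), nrow(ua))
  expect_equal(rowSums(as.matrix(qs[, categories()])), qs$total)
})

test_that("descriptives use n-1 sd, midpoint median and truncated mean", {
  d <- describe_counts(c(1, 2, 3))
  expect_equal(d$mean, 2); expect_equal(d$sd, 1)
  expect_equal(d$median, 2); expect_equal(d$min, 1); expect_equal(d$max, 3)

  d2 <- describe_counts(c(1, 2, 3, 10))
  expect_equal(d2$median, 2.5)

  expect_error(describe_counts(numeric(0)), "non-empty")

  withr::local_seed(31)
  for (i in 1:100) {
    x <- sample(0:5000, sample(2:30, 1), replace = TRUE)
    d <- describe_counts(x)
    naive_sd <- sqrt(sum((x - sum(x) / length(x))^2) / (length(x) - 1))
    expect_equal(d$sd, naive_sd, tolerance = 1e-9)
    expect_equal(d$mean, sum(x) / length(x), tolerance = 1e-9)
    sx <- sort(x); n <- length(x)
    naive_median <- if (n %% 2 == 1) sx[(n + 1) / 2] else
      (sx[n / 2] + sx[n / 2 + 1]) / 2
    expect_equal(d$median, naive_median)
    expect_equal(d$mean_trunc, trunc(d$mean))
  }
})

test_that("runs are counted per definition and ties with the cutpoint drop", {
  alt <- rep(c(10, 1), 6)  # strictly alternating, 6 above / 6 below
  r <- runs_test(alt)
  expect_equal(r$n_runs, 12)
  expect_equal(c(r$n_above, r$n_below), c(6, 6))

  r2 <- runs_test(c(5, 5, 5, 9, 9, 9))  # median 7: three below then three above
  expect_equal(r2$n_runs, 2)

  expect_error(runs_test(c(3)), "at least 2")
  expect_error(runs_test(c(4, 4, 4)), "fewer than 2")
})

test_that("exact runs p-values match enumeration for small series", {
  # (n_above = 6, n_below = 6, runs = 2): both tails from C(12,6) arrangements
  dist <- runs_dist_enum(6, 6)
  x <- c(rep(1, 6), rep(9, 6))
  r <- runs_test(x)
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, min(1, 2 * min(sum(dist[1:2]), sum(dist[2:12]))))
})

test_that("large series switch to the continuity-corrected normal approximation", {
  withr::local_seed(32)
  x <- rnorm(40)
  r <- runs_test(x)
  expect_equal(r$method, "normal_approx")
  n1 <- r$n_above; n2 <- r$n_below; n <- n1 + n2
  mu <- 1 + 2 * n1 * n2 / n
  sigma <- sqrt(2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1)))
  expect_equal(r$p_value,
               2 * pnorm(-(abs(r$n_runs - mu) - 0.5) / sigma))
})

test_that("chi-square matches hand computation and base R", {
  perfect <- chi_square_table(matrix(c(10, 10, 10, 10), 2), correct = FALSE)
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p_value, 1)

  skew <- chi_square_table(matrix(c(30, 10, 10, 30), 2), correct = FALSE)
  expect_equal(skew$statistic, 20)  # sum (O-E)^2/E with all E = 20

  tab <- matrix(c(12, 5, 9, 14, 7, 3, 11, 8), 2)
  ours <- chi_square_table(tab, correct = FALSE)
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
  expect_equal(rowSums(ours$expected), rowSums(tab), tolerance = 1e-9)
  expect_equal(colSums(ours$expected), colSums(tab), tolerance = 1e-9)

  expect_error(chi_square_table(matrix(c(0, 0, 5, 5), 2)), "cell")
})

test_that("gender tests exclude unknowns and per-category mode emits 4 results", {
  withr::local_seed(33)
  n <- 240
  corp <- make_corpus(sprintf("post %d", 1:n),
                      genders = sample(c("female", "male", "unknown"), n,
                                       replace = TRUE, prob = c(.6, .25, .15)))
  assigns <- tibble::tibble(tweet_id = corp$id,
                            category = sample(categories(), n, replace = TRUE))
  omni <- gender_chi_square(corp, assigns, "omnibus")
  expect_equal(omni$df, 3)
  expect_equal(sum(omni$observed), sum(corp$gender != "unknown"))

  per <- gender_chi_square(corp, assigns, "per_category")
  expect_named(per, categories())
  for (res in per) {
    expect_equal(res$df, 1)
    expect_true(res$p_bonferroni >= res$p_value)
    ref <- suppressWarnings(chisq.test(res$observed, correct = TRUE))
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("term and hashtag frequencies rank by count then lexicographically", {
  expect_equal(nrow(term_frequencies(character(0))), 0)
  tf <- term_frequencies(c("a a b", "a"))
  expect_equal(tf$term, c("a", "b"))
  expect_equal(tf$count, c(3, 1))

  ties <- term_frequencies(c("beta alpha", "alpha beta"))
  expect_equal(ties$term, c("alpha", "beta"))

  hf <- hashtag_frequencies(c("#caries and #Caries", "#rare"), top_n = 1)
  expect_equal(hf$term, "#caries")
  expect_equal(hf$count, 2)
})

test_that("planted hashtag frequencies are recovered in rank order", {
  sim <- generate_corpus(generator_config(n_tweets = 3000, rng_seed = 34,
                                          duplicate_fraction = 0,
                                          ad_clusters = 0, hashtag_rate = 0.6))
  hf <- hashtag_frequencies(sim$records$text)
  top2 <- c("#caries", "#fluoridevarnish")  # heaviest planted weights
  expect_equal(hf$term[1:2], top2)
})
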