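test_that("consensus builds the seed set; disagreements count only toward n_rated", {
  corp <- make_corpus(c("fluoride scares me", "the varnish tasted odd",
                        "fluoride prevents cavities", "fluoride is poison"))
  labels <- tibble::tibble(
    tweet_id = rep(c("t001", "t002", "t003", "t004"), each = 2),
    rater_id = rep(c("r1", "r2"), 4),
    category = c("concern", "concern",
                 "experience", "positive",   # disagreement -> excluded
                 "positive", "positive",
                 "negative", "negative")
  )
  out <- build_seed_set(labels, corp)
  expect_equal(out$n_rated, 4)
  expect_equal(out$n_consensus, 3)
  expect_equal(out$seeds$concern$tweet_id, "t001")
  expect_equal(nrow(out$seeds$experience), 0)
  expect_equal(out$seeds$positive$tweet_id, "t003")
})

test_that("label validation: two distinct raters per tweet, known categories, ids present", {
  corp <- make_corpus("some text")
  one_rating <- tibble::tibble(tweet_id = "t001", rater_id = "r1",
                               category = "concern")
  expect_error(build_seed_set(one_rating, corp), "exactly 2 ratings")
  bad_cat <- tibble::tibble(tweet_id = rep("t001", 2),
                            rater_id = c("r1", "r2"),
                            category = c("concern", "worried"))
  expect_error(build_seed_set(bad_cat, corp), "unknown category")
  missing_id <- tibble::tibble(tweet_id = rep("t999", 2),
                               rater_id = c("r1", "r2"),
                               category = rep("concern", 2))
  expect_error(build_seed_set(missing_id, corp), "not in corpus")
  same_rater <- tibble::tibble(tweet_id = rep("t001", 2),
                               rater_id = c("r1", "r1"),
                               category = rep("concern", 2))
  expect_error(build_seed_set(same_rater, corp), "distinct raters")
})

test_that("Cohen's kappa matches hand-computed examples and rejects degeneracy", {
  expect_equal(cohens_kappa(matrix(c(25, 0, 0, 25), 2)), 1)
  expect_equal(cohens_kappa(matrix(c(9, 21, 21, 49), 2)), 0)
  # p_o = 0.7, p_e = 0.5 -> kappa = 0.4
  expect_equal(cohens_kappa(matrix(c(20, 10, 5, 15), 2)), 0.4)
  expect_error(cohens_kappa(matrix(c(10, 0, 0, 0), 2)), "degenerate")
  expect_error(cohens_kappa(matrix(0, 2, 2)), "positive total")
})

test_that("assignment goes to the nearest seed category with deterministic ties", {
  seeds <- structure(list(
    concern = tibble::tibble(tweet_id = "s1",
                             tokens = list(c("fluoride", "lowers", "iq"))),
    experience = tibble::tibble(tweet_id = "s2",
                                tokens = list(c("the", "varnish", "visit"))),
    positive = tibble::tibble(tweet_id = "s3",
                              tokens = list(c("fluoride", "prevents", "cavities"))),
    negative = tibble::tibble(tweet_id = "s4",
                              tokens = list(c("fluoride", "is", "toxic")))
  ), class = "seed_set")

  exact <- assign_category(c("fluoride", "prevents", "cavities"), seeds)
  expect_equal(exact$category, "positive")
  expect_equal(exact$score, 1)

  # hand check with the oracle: d(concern)=1 of 4 -> 0.75; the runner-up is
  # positive or negative, both at d=3 of 4 -> 0.25
  tw <- c("fluoride", "lowers", "iq", "maybe")
  expect_equal(lev_oracle_plain(tw, c("fluoride", "lowers", "iq")), 1)
  expect_equal(lev_oracle_plain(tw, c("fluoride", "prevents", "cavities")), 3)
  expect_equal(lev_oracle_plain(tw, c("fluoride", "is", "toxic")), 3)
  near <- assign_category(tw, seeds)
  expect_equal(near$category, "concern")
  expect_equal(near$score, 0.75)
  expect_equal(near$runner_up_margin, 0.75 - 0.25)

  nomatch <- assign_category(c("zz", "yy"), seeds)
  expect_equal(nomatch$score, 0)
  expect_true(nomatch$low_confidence)
  expect_equal(nomatch$category, "concern")  # canonical-order tie-break

  empty <- assign_category(character(0), seeds)
  expect_equal(empty$score, 0)
  expect_true(empty$low_confidence)
})

test_that("classification is deterministic, covers every record, and seeds keep labels", {
  sim <- generate_corpus(generator_config(n_tweets = 300, rng_seed = 12,
                                          duplicate_fraction = 0,
                                          ad_clusters = 0))
  labels <- generate_rater_labels(sim$truth, per_category = 10, rng_seed = 13)
  built <- build_seed_set(labels, sim$records)
  out1 <- classify_corpus(sim$records, built$seeds)
  out2 <- classify_corpus(sim$records, built$seeds)
  expect_identical(out1$assignments, out2$assignments)
  expect_equal(nrow(out1$assignments), nrow(sim$records))
  expect_equal(sum(out1$summary$n), nrow(sim$records))
  expect_lt(abs(sum(out1$summary$pct) - 100), 0.2)

  # seeds keep their consensus category and, re-scored, attain similarity 1
  seed_rows <- out1$assignments[out1$assignments$seeded, ]
  for (cat in categories()) {
    ids <- built$seeds[[cat]]$tweet_id
    expect_true(all(seed_rows$category[seed_rows$tweet_id %in% ids] == cat))
    for (i in seq_len(nrow(built$seeds[[cat]]))) {
      re <- assign_category(built$seeds[[cat]]$tokens[[i]], built$seeds)
      expect_equal(re$score, 1)
      expect_equal(re$category, cat)
    }
  }
})

test_that("single-record corpus classifies at 100.0%", {
  corp <- make_corpus("fluoride lowers iq they say")
  seeds <- structure(list(
    concern = tibble::tibble(tweet_id = "s1",
                             tokens = list(c("fluoride", "lowers", "iq"))),
    experience = tibble::tibble(tweet_id = "s2", tokens = list("visit")),
    positive = tibble::tibble(tweet_id = "s3", tokens = list("great")),
    negative = tibble::tibble(tweet_id = "s4", tokens = list("toxic"))
  ), class = "seed_set")
  out <- classify_corpus(corp, seeds)
  expect_equal(out$summary$pct[out$summary$category == "concern"], 100)
})

test_that("an empty seed category blocks classification", {
  seeds <- structure(list(
    concern = tibble::tibble(tweet_id = "s1", tokens = list("a")),
    experience = tibble::tibble(tweet_id = character(0), tokens = list()),
    positive = tibble::tibble(tweet_id = "s3", tokens = list("b")),
    negative = tibble::tibble(tweet_id = "s4", tokens = list("c"))
  ), class = "seed_set")
  expect_error(assign_category("a", seeds), "empty categor")
})
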