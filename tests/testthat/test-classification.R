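test_that("threshold fitting recovers a separating midpoint", {
  m <- fit_threshold(c(0.1, 0.4, 0.6, 0.9), c(FALSE, FALSE, TRUE, TRUE),
                     "similarity_high_is_match")
  expect_equal(m$threshold, 0.5)
  expect_equal(m$training_f1, 1.0)
  # distance direction mirrors it
  m <- fit_threshold(c(0.1, 0.4, 0.6, 0.9), c(TRUE, TRUE, FALSE, FALSE),
                     "distance_low_is_match")
  expect_equal(m$threshold, 0.5)
  expect_equal(m$training_f1, 1.0)
})

test_that("non-separable scores reach the brute-force optimum", {
  m <- fit_threshold(c(0.2, 0.8), c(TRUE, FALSE), "similarity_high_is_match")
  expect_equal(m$training_f1,
               ref_best_f1(c(0.2, 0.8), c(TRUE, FALSE),
                           "similarity_high_is_match"))
  expect_error(fit_threshold(c(0.1, 0.9), c(TRUE, TRUE),
                             "similarity_high_is_match"), "positive and a")
  expect_error(fit_threshold(c(0.1, 0.9), c(FALSE, FALSE),
                             "distance_low_is_match"), "positive and a")
})

test_that("fitted training F1 is recomputable from the model itself", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    scores <- round(runif(n), 2)
    labels <- runif(n) < 0.4
    if (all(labels) || !any(labels)) next
    dir <- sample(c("similarity_high_is_match", "distance_low_is_match"), 1)
    m <- fit_threshold(scores, labels, dir)
    pred <- classify(scores, m)
    tp <- sum(pred & labels)
    f1 <- 2 * tp / (2 * tp + sum(pred & !labels) + sum(!pred & labels))
    expect_equal(m$training_f1, f1, tolerance = 1e-12)
  }
})

test_that("classification respects direction, boundary and eligibility", {
  sim <- structure(list(method = "cosine_sim", stratum = NA, threshold = 0.5,
                        direction = "similarity_high_is_match",
                        training_f1 = 1), class = "threshold_model")
  expect_equal(classify(c(0.9, 0.5, 0.49), sim), c(TRUE, TRUE, FALSE))
  dist <- structure(list(method = "cosine", stratum = NA, threshold = 0.5,
                         direction = "distance_low_is_match",
                         training_f1 = 1), class = "threshold_model")
  expect_equal(classify(c(0.7, 0.5, 0.1), dist), c(FALSE, TRUE, TRUE))
  expect_equal(classify(c(0.1, 0.1), dist, eligible = c(TRUE, FALSE)),
               c(TRUE, FALSE))
  expect_error(classify(0.3, dist, method = "city_block"), "does not match")
})

test_that("raising a similarity threshold never adds predicted positives", {
  set.seed(31)
  scores <- runif(200)
  base <- structure(list(method = NA, stratum = NA, threshold = 0,
                         direction = "similarity_high_is_match",
                         training_f1 = NA), class = "threshold_model")
  prev <- Inf
  for (t in seq(0, 1, by = 0.1)) {
    base$threshold <- t
    n_pos <- sum(classify(scores, base))
    expect_lte(n_pos, prev)
    prev <- n_pos
  }
})

test_that("threshold models survive the plain-text round trip", {
  models <- list(
    fit_threshold(c(0.1, 0.9), c(FALSE, TRUE), "similarity_high_is_match",
                  method = "jaro_winkler", stratum = "fife:all_ages"),
    fit_threshold(c(0.2, 0.7), c(TRUE, FALSE), "distance_low_is_match",
                  method = "cosine", stratum = "fife:over65")
  )
  path <- tempfile(fileext = ".tsv")
  write_threshold_models(models, path)
  back <- read_threshold_models(path)
  for (i in seq_along(models)) {
    expect_equal(back[[i]]$threshold, models[[i]]$threshold)
    expect_equal(back[[i]]$direction, models[[i]]$direction)
    expect_equal(back[[i]]$method, models[[i]]$method)
  }
})

test_that("whole-dataset prediction records decision provenance", {
  reg <- make_registry("Sunnybank Care Home", "12 High St", "KY1 1AA",
                       "Kirkcaldy")
  addr <- make_addresses(list(
    c("Beech Residential Home", "ZZ1 1ZZ"),      # rule 1
    c("9 Elm Row", "Dundee", "ZZ9 9ZZ"),         # rule 2
    c("12 High St", "Kirkcaldy", "KY1 1AA"),     # scored, perfect match
    c("14 High St", "Kirkcaldy", "KY1 1AA")      # scored, gated out
  ), gold = c(TRUE, FALSE, TRUE, FALSE))
  model <- structure(list(method = "levenshtein_ratio", stratum = NA,
                          threshold = 0.4,
                          direction = "similarity_high_is_match",
                          training_f1 = NA), class = "threshold_model")
  pred <- predict_dataset(addr, reg, "levenshtein_ratio", model)
  expect_equal(pred$predicted, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(pred$provenance,
               c("filter_rule1", "filter_rule2", "threshold", "threshold"))
})
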