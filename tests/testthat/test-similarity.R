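EDIT_METHODS <- method_roster()$name[method_roster()$family == "edit_distance"]
VECTOR_METHODS <- method_roster()$name[method_roster()$family == "vector_space"]

test_that("the roster defines 4 edit-distance and 7 vector-space methods", {
  r <- method_roster()
  expect_equal(sum(r$family == "edit_distance"), 4)
  expect_equal(sum(r$family == "vector_space"), 7)
  expect_true(all(r$direction[r$family == "edit_distance"] ==
                    "similarity_high_is_match"))
  expect_error(method_spec("soundex_ratio"), "unknown")
})

test_that("edit similarities handle identity, single edits and empties", {
  for (m in EDIT_METHODS) {
    expect_equal(edit_similarity("care home", "care home", m), 1.0)
    expect_equal(edit_similarity("", "", m), 1.0)
  }
  expect_equal(edit_similarity("care home", "care hom", "levenshtein_ratio"),
               1 - 1 / 9)
  expect_equal(edit_similarity("abdc", "abcd", "damerau_levenshtein_ratio"),
               1 - 1 / 4) # one transposition
  expect_equal(edit_similarity("abdc", "abcd", "levenshtein_ratio"),
               1 - 2 / 4) # two substitutions without transposition
  expect_equal(edit_similarity("abc", "xyz", "jaro_winkler"), 0)
  expect_equal(edit_similarity("care home", "care hom", "lcs_ratio"),
               2 * 8 / 17)
})

test_that("edit similarities match dynamic-programming references", {
  set.seed(101)
  for (i in 1:100) {
    a <- random_string()
    b <- random_string()
    for (m in EDIT_METHODS) {
      expect_equal(edit_similarity(a, b, m), ref_edit_similarity(a, b, m),
                   tolerance = 1e-12,
                   info = sprintf("%s('%s','%s')", m, a, b))
    }
    # extra independent cross-check for Levenshtein
    if (nchar(a) > 0 || nchar(b) > 0) {
      expect_equal(1 - edit_similarity(a, b, "levenshtein_ratio"),
                   drop(utils::adist(a, b)) / max(nchar(a), nchar(b)))
    }
  }
})

test_that("each extra substitution never increases levenshtein similarity", {
  # corrupt a copy of the string one position at a time, always replacing a
  # character by one that differs from the original at that position
  set.seed(55)
  for (i in 1:40) {
    a <- random_string(6, 15)
    b <- a
    prev <- 1
    for (pos in sample(nchar(a), min(5, nchar(a)))) {
      orig <- substr(a, pos, pos)
      sub <- sample(setdiff(letters[1:10], orig), 1)
      b <- paste0(substr(b, 1, pos - 1), sub, substring(b, pos + 1))
      s <- edit_similarity(a, b, "levenshtein_ratio")
      expect_lte(s, prev + 1e-12)
      prev <- s
    }
  }
})

test_that("vector distances evaluate their defining formulas", {
  expect_equal(vector_distance(c(1, 2, 0), c(0, 2, 3), "city_block"), 4)
  expect_equal(vector_distance(c(1, 2, 0), c(0, 2, 3), "euclidean"),
               sqrt(10))
  expect_equal(vector_distance(c(1, 2, 0), c(0, 2, 3), "chebyshev"), 3)
  expect_equal(vector_distance(c(1, 2, 0), c(0, 2, 3), "bray_curtis"), 4 / 8)
  expect_equal(vector_distance(c(1, 0), c(0, 1), "cosine"), 1)
  expect_equal(vector_distance(c(1, 2, 3), c(2, 4, 6), "cosine"), 0,
               tolerance = 1e-12)
  # Jensen-Shannon: identity, and the closed-form maximum for disjoint support
  p <- c(0.2, 0.5, 0.3)
  expect_equal(vector_distance(p, p, "jensen_shannon"), 0)
  expect_equal(vector_distance(c(1, 0), c(0, 1), "jensen_shannon"), 1)
  expect_error(vector_distance(c(0, 0), c(1, 0), "cosine"), "degenerate")
  expect_error(vector_distance(c(1, 1), c(1, 0), "correlation"), "degenerate")
  expect_error(vector_distance(c(1, 0), c(1, 0, 0), "cosine"), "vocabular")
  expect_error(vector_distance(c(2, 1), c(1, 2), "jensen_shannon"),
               "probability")
})

test_that("pairwise scores are symmetric in their arguments", {
  set.seed(303)
  for (i in 1:30) {
    a <- random_string(1, 12)
    b <- random_string(1, 12)
    for (m in EDIT_METHODS) {
      expect_equal(edit_similarity(a, b, m), edit_similarity(b, a, m),
                   tolerance = 1e-12)
    }
    u <- rpois(8, 2)
    v <- rpois(8, 2)
    for (m in setdiff(VECTOR_METHODS, "jensen_shannon")) {
      skip <- (m %in% c("cosine") && (sum(u) == 0 || sum(v) == 0)) ||
        (m == "correlation" && (sd(u) == 0 || sd(v) == 0))
      if (skip) next
      expect_equal(vector_distance(u, v, m), vector_distance(v, u, m),
                   tolerance = 1e-12)
    }
    if (sum(u) > 0 && sum(v) > 0) {
      expect_equal(
        vector_distance(u / sum(u), v / sum(v), "jensen_shannon"),
        vector_distance(v / sum(v), u / sum(u), "jensen_shannon"),
        tolerance = 1e-12)
    }
  }
})

test_that("distances respect their theoretical bounds on count vectors", {
  set.seed(909)
  for (i in 1:60) {
    u <- rpois(10, 1.5)
    v <- rpois(10, 1.5)
    expect_lte(vector_distance(u, v, "bray_curtis"), 1)
    expect_gte(vector_distance(u, v, "bray_curtis"), 0)
    if (sum(u) > 0 && sum(v) > 0) {
      co <- vector_distance(u, v, "cosine")
      expect_gte(co, -1e-12)
      expect_lte(co, 1 + 1e-12) # non-negative inputs
      js <- vector_distance(u / sum(u), v / sum(v), "jensen_shannon")
      expect_gte(js, 0)
      expect_lte(js, 1 + 1e-12)
    }
    if (sd(u) > 0 && sd(v) > 0) {
      cr <- vector_distance(u, v, "correlation")
      expect_gte(cr, -1e-12)
      expect_lte(cr, 2 + 1e-12)
    }
  }
})

test_that("registry scoring gates on numbers and reduces to the best", {
  cl <- structure(list(lines = c("sunnybank care home", "high st"),
                       numbers = "12", source_id = "a1"),
                  class = "clean_address")
  cands <- list(
    list(service_id = "s1", text = "sunnybank care home high st",
         numbers = "12"),
    list(service_id = "s2", text = "rosewood lodge mill rd",
         numbers = "3")
  )
  sc <- score_against_registry(cl, cands, "levenshtein_ratio")
  expect_equal(sc$score, 1.0)
  expect_equal(sc$best_candidate, "s1")
  expect_true(sc$eligible)

  # disjoint number tokens make every candidate ineligible
  cl89 <- structure(list(lines = "glebe street", numbers = "89",
                         source_id = "a2"), class = "clean_address")
  sc <- score_against_registry(cl89, cands, "levenshtein_ratio")
  expect_false(sc$eligible)
  expect_equal(sc$score, 0)
  expect_true(is.na(sc$best_candidate))
  # gate off: scores anyway
  sc <- score_against_registry(cl89, cands, "levenshtein_ratio",
                               number_gate = FALSE)
  expect_true(sc$eligible)

  # min-reduction for distances
  vocab <- build_vocabulary(c("abcd", "abce", "wxyz"), 2)
  clv <- structure(list(lines = "abcd", numbers = character(0),
                        source_id = "a3"), class = "clean_address")
  cands_v <- list(
    list(service_id = "s1", text = "abce", numbers = character(0),
         vector = vectorize("abce", 2, vocab)),
    list(service_id = "s2", text = "wxyz", numbers = character(0),
         vector = vectorize("wxyz", 2, vocab))
  )
  sc <- score_against_registry(clv, cands_v, "city_block",
                               address_vector = vectorize("abcd", 2, vocab))
  expect_equal(sc$best_candidate, "s1")
  expect_equal(sc$score, 2) # bc/cd vs bc/ce differ in two grams

  # empty candidate set: worst value, not an error
  sc <- score_against_registry(clv, list(), "city_block")
  expect_false(sc$eligible)
  expect_equal(sc$score, Inf)
})
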