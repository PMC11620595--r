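#' The eleven similarity-matching methods
#'
#' Four edit-distance methods operate on cleaned address strings and return
#' a similarity in \[0, 1\] (higher = better match); seven vector-space
#' methods operate on character n-gram vectors and return a distance >= 0
#' (lower = better match).
#'
#' @return Tibble with columns `name`, `family`
#'   (`edit_distance`/`vector_space`) and `direction`
#'   (`similarity_high_is_match`/`distance_low_is_match`).
#' @export
method_roster <- function() {
  tibble::tibble(
    name = c("levenshtein_ratio", "damerau_levenshtein_ratio",
             "jaro_winkler", "lcs_ratio",
             "city_block", "euclidean", "chebyshev", "bray_curtis",
             "cosine", "correlation", "jensen_shannon"),
    family = rep(c("edit_distance", "vector_space"), c(4L, 7L)),
    direction = rep(c("similarity_high_is_match", "distance_low_is_match"),
                    c(4L, 7L))
  )
}

#' Look up one method's specification
#' @param name Method name from [method_roster()].
#' @return One-row tibble (name, family, direction).
#' @export
method_spec <- function(name) {
  roster <- method_roster()
  i <- match(name, roster$name)
  if (is.na(i)) stop("unknown method: ", name)
  roster[i, ]
}

#' Normalized edit-distance similarity between two strings
#'
#' * `levenshtein_ratio`, `damerau_levenshtein_ratio`:
#'   `1 - distance / max(nchar(a), nchar(b))` (the Damerau variant is the
#'   optimal-string-alignment form, counting adjacent transpositions as one
#'   edit);
#' * `jaro_winkler`: standard Jaro-Winkler (prefix scale 0.1, max common
#'   prefix 4);
#' * `lcs_ratio`: `2 * LCS(a, b) / (nchar(a) + nchar(b))`.
#'
#' Two empty strings are perfectly similar (1) under every method.
#'
#' @param a,b Character vectors (recycled to a common length).
#' @param method One of the four edit-distance method names.
#' @return Numeric vector of similarities in \[0, 1\].
#' @export
edit_similarity <- function(a, b, method = "levenshtein_ratio") {
  spec <- method_spec(method)
  if (spec$family != "edit_distance") {
    stop(method, " is not an edit-distance method")
  }
  k <- max(length(a), length(b))
  a <- rep_len(as.character(a), k)
  b <- rep_len(as.character(b), k)
  la <- nchar(a)
  lb <- nchar(b)
  both_empty <- la == 0 & lb == 0
  out <- switch(method,
    levenshtein_ratio = {
      d <- .lev_distance_cpp(a, b)
      ifelse(both_empty, 1, 1 - d / pmax(la, lb))
    },
    damerau_levenshtein_ratio = {
      d <- .osa_distance_cpp(a, b)
      ifelse(both_empty, 1, 1 - d / pmax(la, lb))
    },
    jaro_winkler = .jaro_winkler_cpp(a, b, 0.1, 4L),
    lcs_ratio = {
      l <- .lcs_length_cpp(a, b)
      ifelse(both_empty, 1, 2 * l / (la + lb))
    }
  )
  as.numeric(out)
}

#' Distance between two n-gram vectors
#'
#' Implements the seven vector-space distances over vectors on a shared
#' vocabulary:
#' city block `sum(|u - v|)`; euclidean `sqrt(sum((u - v)^2))`; chebyshev
#' `max(|u - v|)`; Bray-Curtis `sum(|u - v|) / sum(u + v)`; cosine
#' `1 - u.v / (||u|| ||v||)`; correlation `1 - cor(u, v)`; Jensen-Shannon
#' `sqrt(KL(u||m)/2 + KL(v||m)/2)` with `m = (u + v)/2` and base-2
#' logarithms, so it lies in \[0, 1\] (probability-mode vectors required).
#'
#' @param u,v Numeric vectors of equal length (same vocabulary and n).
#' @param method One of the seven vector-space method names.
#' @return Non-negative scalar distance.
#' @export
vector_distance <- function(u, v, method = "cosine") {
  spec <- method_spec(method)
  if (spec$family != "vector_space") {
    stop(method, " is not a vector-space method")
  }
  if (length(u) != length(v)) {
    stop("vectors come from different vocabularies (lengths differ)")
  }
  u <- as.numeric(u)
  v <- as.numeric(v)
  switch(method,
    city_block = sum(abs(u - v)),
    euclidean = sqrt(sum((u - v)^2)),
    chebyshev = if (length(u) == 0) 0 else max(abs(u - v)),
    bray_curtis = {
      denom <- sum(u + v)
      if (denom == 0) 0 else sum(abs(u - v)) / denom
    },
    cosine = {
      nu <- sqrt(sum(u^2))
      nv <- sqrt(sum(v^2))
      if (nu == 0 || nv == 0) {
        stop("degenerate input: zero vector has no cosine distance")
      }
      1 - sum(u * v) / (nu * nv)
    },
    correlation = {
      if (stats::sd(u) == 0 || stats::sd(v) == 0) {
        stop("degenerate input: constant vector has no correlation distance")
      }
      1 - stats::cor(u, v)
    },
    jensen_shannon = {
      su <- sum(u)
      sv <- sum(v)
      if (su == 0 || sv == 0) {
        stop("degenerate input: zero vector has no Jensen-Shannon distance")
      }
      if (abs(su - 1) > 1e-6 || abs(sv - 1) > 1e-6) {
        stop("jensen_shannon requires probability-mode vectors")
      }
      m <- (u + v) / 2
      kl <- function(p, q) {
        i <- p > 0
        sum(p[i] * log2(p[i] / q[i]))
      }
      js2 <- kl(u, m) / 2 + kl(v, m) / 2
      sqrt(max(js2, 0))
    }
  )
}

#' Score one cleaned address against its registry candidates
#'
#' Candidates are the care_home-typed registry entries sharing the address's
#' normalized postcode (the only candidates that can survive the exclusion
#' rule), preprocessed with the same cleaning as the address. A number-token
#' gate guards against matching a neighbour at the same postcode: when both
#' the address and a candidate carry number tokens, they must share at least
#' one, otherwise the candidate is ineligible. The returned score is the
#' best over eligible candidates (max for similarity methods, min for
#' distances); with no eligible candidate the method's worst value is
#' returned (0 for similarity, `Inf` for distance) and `eligible` is
#' `FALSE`.
#'
#' @param clean A `clean_address`.
#' @param candidates List of candidate descriptors, each a list with
#'   `service_id`, `text` (cleaned comparison string), `numbers` (character
#'   vector), and, for vector-space methods, `vector` (n-gram vector on the
#'   shared vocabulary, in the mode the method needs).
#' @param method Method name.
#' @param address_vector The address's own n-gram vector (vector-space
#'   methods only).
#' @param number_gate Apply the number-token gate? Default `TRUE`.
#' @return List of class `method_score`: `address_id`, `method`, `score`,
#'   `best_candidate` (service id or `NA`), `eligible`.
#' @export
score_against_registry <- function(clean, candidates, method,
                                   address_vector = NULL,
                                   number_gate = TRUE) {
  spec <- method_spec(method)
  similarity <- spec$direction == "similarity_high_is_match"
  worst <- if (similarity) 0 else Inf
  res <- list(address_id = clean$source_id, method = method,
              score = worst, best_candidate = NA_character_,
              eligible = FALSE)
  class(res) <- "method_score"
  if (length(candidates) == 0) return(res)
  ok <- vapply(candidates, function(cand) {
    !number_gate || length(clean$numbers) == 0 ||
      length(cand$numbers) == 0 ||
      length(intersect(clean$numbers, cand$numbers)) > 0
  }, logical(1))
  if (!any(ok)) return(res)
  eligible <- candidates[ok]
  scores <- if (spec$family == "edit_distance") {
    texts <- vapply(eligible, `[[`, character(1), "text")
    edit_similarity(rep(clean_text(clean), length(texts)), texts, method)
  } else {
    if (is.null(address_vector)) {
      stop("vector-space scoring needs `address_vector`")
    }
    vapply(eligible, function(cand) {
      vector_distance(address_vector, cand$vector, method)
    }, numeric(1))
  }
  best <- if (similarity) which.max(scores) else which.min(scores)
  res$score <- scores[[best]]
  res$best_candidate <- eligible[[best]]$service_id
  res$eligible <- TRUE
  res
}
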