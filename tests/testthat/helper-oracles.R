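# Independent reference implementations used as oracles. These are written
# as direct transcriptions of the textbook definitions (full dynamic
# programming tables, explicit sums over the whole vocabulary) and share no
# code with the package.

ref_levenshtein <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  la <- length(ca)
  lb <- length(cb)
  d <- matrix(0L, la + 1, lb + 1)
  d[, 1] <- 0:la
  d[1, ] <- 0:lb
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (ca[i] != cb[j]))
    }
  }
  d[la + 1, lb + 1]
}

ref_osa <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  la <- length(ca)
  lb <- length(cb)
  d <- matrix(0L, la + 1, lb + 1)
  d[, 1] <- 0:la
  d[1, ] <- 0:lb
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (ca[i] != cb[j]))
      if (i > 1 && j > 1 && ca[i] == cb[j - 1] && ca[i - 1] == cb[j]) {
        d[i + 1, j + 1] <- min(d[i + 1, j + 1], d[i - 1, j - 1] + 1L)
      }
    }
  }
  d[la + 1, lb + 1]
}

ref_lcs <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  la <- length(ca)
  lb <- length(cb)
  d <- matrix(0L, la + 1, lb + 1)
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      d[i + 1, j + 1] <- if (ca[i] == cb[j]) d[i, j] + 1L else
        max(d[i, j + 1], d[i + 1, j])
    }
  }
  d[la + 1, lb + 1]
}

ref_jaro_winkler <- function(a, b, p = 0.1, max_l = 4) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  la <- length(ca)
  lb <- length(cb)
  if (la == 0 && lb == 0) return(1)
  if (la == 0 || lb == 0) return(0)
  win <- max(floor(max(la, lb) / 2) - 1, 0)
  ma <- logical(la)
  mb <- logical(lb)
  for (i in seq_len(la)) {
    lo <- max(1, i - win)
    hi <- min(lb, i + win)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!mb[j] && ca[i] == cb[j]) {
        ma[i] <- TRUE
        mb[j] <- TRUE
        break
      }
    }
  }
  m <- sum(ma)
  if (m == 0) return(0)
  sa <- ca[ma]
  sb <- cb[mb]
  t <- sum(sa != sb) / 2
  jaro <- mean(c(m / la, m / lb, (m - t) / m))
  l <- 0
  while (l < min(la, lb, max_l) && ca[l + 1] == cb[l + 1]) l <- l + 1
  jaro + l * p * (1 - jaro)
}

ref_edit_similarity <- function(a, b, method) {
  la <- nchar(a)
  lb <- nchar(b)
  if (la == 0 && lb == 0) return(1)
  switch(method,
    levenshtein_ratio = 1 - ref_levenshtein(a, b) / max(la, lb),
    damerau_levenshtein_ratio = 1 - ref_osa(a, b) / max(la, lb),
    jaro_winkler = ref_jaro_winkler(a, b),
    lcs_ratio = 2 * ref_lcs(a, b) / (la + lb)
  )
}

ref_vector_distance <- function(u, v, method) {
  switch(method,
    city_block = {
      s <- 0
      for (i in seq_along(u)) s <- s + abs(u[i] - v[i])
      s
    },
    euclidean = {
      s <- 0
      for (i in seq_along(u)) s <- s + (u[i] - v[i])^2
      sqrt(s)
    },
    chebyshev = {
      s <- 0
      for (i in seq_along(u)) s <- max(s, abs(u[i] - v[i]))
      s
    },
    bray_curtis = {
      num <- den <- 0
      for (i in seq_along(u)) {
        num <- num + abs(u[i] - v[i])
        den <- den + u[i] + v[i]
      }
      if (den == 0) 0 else num / den
    },
    cosine = {
      dot <- nu <- nv <- 0
      for (i in seq_along(u)) {
        dot <- dot + u[i] * v[i]
        nu <- nu + u[i]^2
        nv <- nv + v[i]^2
      }
      1 - dot / (sqrt(nu) * sqrt(nv))
    },
    correlation = {
      mu <- mean(u)
      mv <- mean(v)
      num <- du <- dv <- 0
      for (i in seq_along(u)) {
        num <- num + (u[i] - mu) * (v[i] - mv)
        du <- du + (u[i] - mu)^2
        dv <- dv + (v[i] - mv)^2
      }
      1 - num / sqrt(du * dv)
    },
    jensen_shannon = {
      p <- u / sum(u)
      q <- v / sum(v)
      m <- (p + q) / 2
      kl <- 0
      for (i in seq_along(p)) {
        if (p[i] > 0) kl <- kl + 0.5 * p[i] * log2(p[i] / m[i])
        if (q[i] > 0) kl <- kl + 0.5 * q[i] * log2(q[i] / m[i])
      }
      sqrt(kl)
    }
  )
}

# Exhaustive threshold search: every observed score and every midpoint as a
# candidate, F1 computed by direct counting.
ref_best_f1 <- function(scores, labels, direction) {
  vals <- sort(unique(scores[is.finite(scores)]))
  cands <- unique(c(-Inf, Inf, vals, vals - 1e-9, vals + 1e-9,
                    if (length(vals) > 1)
                      (vals[-1] + vals[-length(vals)]) / 2))
  best <- 0
  for (t in cands) {
    pred <- if (direction == "similarity_high_is_match") scores >= t
            else scores <= t
    tp <- sum(pred & labels)
    fp <- sum(pred & !labels)
    fn <- sum(!pred & labels)
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
    best <- max(best, f1)
  }
  best
}

random_string <- function(min_len = 0, max_len = 12,
                          alphabet = c(letters[1:6], " ")) {
  n <- sample(min_len:max_len, 1)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

make_addresses <- function(lines_list, person_count = NULL, over65 = NULL,
                           gold = NULL) {
  n <- length(lines_list)
  tibble::tibble(
    address_id = sprintf("T%03d", seq_len(n)),
    lines = lines_list,
    person_count = if (is.null(person_count)) rep(1L, n) else person_count,
    has_over65 = if (is.null(over65)) rep(FALSE, n) else over65,
    region = "test",
    gold_is_care_home = if (is.null(gold)) rep(FALSE, n) else gold
  )
}

make_registry <- function(names, addresses, postcodes, towns,
                          types = NULL) {
  n <- length(names)
  tibble::tibble(
    service_id = sprintf("S%03d", seq_len(n)),
    name = names,
    lines = as.list(addresses),
    postcode = postcodes,
    town = towns,
    service_type = if (is.null(types)) rep("care_home", n) else types
  )
}
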