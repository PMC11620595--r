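#' Postcode-matching baseline
#'
#' An address is allocated as a care home address when its normalized
#' postcode is identical to any postcode in the official care home list.
#' Addresses with no detectable postcode are never matched.
#'
#' @param postcodes Character vector of normalized address postcodes (`NA`
#'   when none was found); raw address text is also accepted and normalized.
#' @param care_home_postcodes Set of normalized care home postcodes.
#' @return Logical vector.
#' @export
postcode_match <- function(postcodes, care_home_postcodes) {
  pc <- ifelse(is.na(postcodes) | postcodes == normalize_postcode(postcodes),
               postcodes, normalize_postcode(postcodes))
  !is.na(pc) & pc %in% care_home_postcodes
}

MARKOV_START <- "\x01" # sentinel preceding the first character of a string

#' Train a first-order character Markov chain on care home address text
#'
#' Accumulates character-transition counts (with a start sentinel before
#' each string) over the cleaned training strings. Scoring smooths the
#' transition probabilities with an add-k rule over the alphabet plus one
#' reserved slot for unseen characters.
#'
#' @param care_home_texts Non-empty character vector of cleaned care home
#'   address strings.
#' @param smoothing_k Add-k smoothing constant, default 1.
#' @return Object of class `markov_model`: transition count matrix,
#'   `alphabet`, `smoothing_k`.
#' @export
train_markov <- function(care_home_texts, smoothing_k = 1) {
  care_home_texts <- care_home_texts[nzchar(care_home_texts)]
  if (length(care_home_texts) == 0) {
    stop("Markov training needs at least one non-empty string")
  }
  alphabet <- sort(unique(c(" ",
    unlist(strsplit(care_home_texts, "", fixed = TRUE), use.names = FALSE))),
    method = "radix")
  states <- c(MARKOV_START, alphabet)
  counts <- matrix(0, nrow = length(states), ncol = length(alphabet),
                   dimnames = list(states, alphabet))
  for (s in care_home_texts) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    from <- c(MARKOV_START, ch[-length(ch)])
    idx <- cbind(match(from, states), match(ch, alphabet))
    for (r in seq_len(nrow(idx))) {
      counts[idx[r, 1], idx[r, 2]] <- counts[idx[r, 1], idx[r, 2]] + 1
    }
  }
  structure(list(counts = counts, alphabet = alphabet,
                 smoothing_k = smoothing_k),
            class = "markov_model")
}

#' Markov care-home-likeness score
#'
#' 100 times the geometric mean of the add-k-smoothed transition
#' probabilities along the string (including the start transition). A
#' string whose transitions all have probability 1 under the model scores
#' 100; the score always lies in \[0, 100\]. Characters outside the trained
#' alphabet fall into a reserved unseen slot, so with alphabet size A every
#' unseen transition has smoothed probability `k / (n_from + k * (A + 1))`.
#'
#' @param model A `markov_model`.
#' @param texts Character vector of cleaned, non-empty strings.
#' @param smoothing_k Optional override of the model's smoothing constant.
#' @return Numeric vector of scores in \[0, 100\].
#' @export
markov_score <- function(model, texts, smoothing_k = model$smoothing_k) {
  stopifnot(inherits(model, "markov_model"))
  if (any(!nzchar(texts))) {
    stop("degenerate input: cannot score an empty string")
  }
  k <- smoothing_k
  A <- length(model$alphabet)
  states <- rownames(model$counts)
  row_tot <- rowSums(model$counts)
  vapply(texts, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    from <- c(MARKOV_START, ch[-length(ch)])
    fi <- match(from, states)
    ti <- match(ch, model$alphabet)
    n_from <- ifelse(is.na(fi), 0, row_tot[ifelse(is.na(fi), 1L, fi)])
    cnt <- ifelse(is.na(fi) | is.na(ti), 0,
                  model$counts[cbind(ifelse(is.na(fi), 1L, fi),
                                     ifelse(is.na(ti), 1L, ti))])
    # vocabulary of A seen characters plus one unseen slot
    p <- (cnt + k) / (n_from + k * (A + 1))
    if (any(p == 0)) return(0)
    100 * exp(mean(log(p)))
  }, numeric(1), USE.NAMES = FALSE)
}

#' American Soundex code of each token
#'
#' Standard Soundex: keep the first letter, map consonants to digit classes
#' (1 bpfv, 2 cgjkqsxz, 3 dt, 4 l, 5 mn, 6 r), drop vowels and h/w (h/w do
#' not separate a doubled class), collapse runs, pad/truncate to 4.
#' Tokens without a leading letter code to `""`.
#'
#' @param tokens Character vector of single words.
#' @return Character vector of 4-character codes.
#' @export
soundex <- function(tokens) {
  code_of <- function(word) {
    word <- toupper(gsub("[^A-Za-z]", "", word))
    if (!nzchar(word)) return("")
    map <- c(B = "1", F = "1", P = "1", V = "1",
             C = "2", G = "2", J = "2", K = "2", Q = "2", S = "2", X = "2",
             Z = "2",
             D = "3", T = "3", L = "4", M = "5", N = "5", R = "6")
    letters_ <- strsplit(word, "", fixed = TRUE)[[1]]
    digits_ <- map[letters_]
    digits_[is.na(digits_)] <- ifelse(letters_[is.na(digits_)] %in% c("H", "W"),
                                      "-", "0") # '-' transparent, '0' vowel
    out <- character(0)
    prev <- digits_[1]
    for (i in seq_along(digits_)[-1]) {
      d <- digits_[i]
      if (d == "-") next # h/w: keep prev so doubled classes still collapse
      if (d != "0" && d != prev) out <- c(out, d)
      prev <- d
    }
    paste0(letters_[1], substr(paste(c(out, "000"), collapse = ""), 1, 3))
  }
  vapply(tokens, code_of, character(1), USE.NAMES = FALSE)
}

#' Phonics baseline: phonetic token-overlap similarity
#'
#' Each string is tokenized on whitespace and every token encoded with a
#' phonetic algorithm (Soundex by default); the score is the size of the
#' multiset intersection of the two code lists divided by the larger token
#' count. Two empty strings score 1.
#'
#' @param a,b Character vectors (recycled to a common length).
#' @param encoder Function mapping a character vector of tokens to codes.
#' @return Numeric vector of similarities in \[0, 1\].
#' @export
phonics_score <- function(a, b, encoder = soundex) {
  k <- max(length(a), length(b))
  a <- rep_len(as.character(a), k)
  b <- rep_len(as.character(b), k)
  one <- function(x, y) {
    tx <- strsplit(trimws(x), "[[:space:]]+")[[1]]
    ty <- strsplit(trimws(y), "[[:space:]]+")[[1]]
    tx <- tx[nzchar(tx)]
    ty <- ty[nzchar(ty)]
    if (length(tx) == 0 && length(ty) == 0) return(1)
    if (length(tx) == 0 || length(ty) == 0) return(0)
    cx <- encoder(tx)
    cy <- encoder(ty)
    tab_x <- table(cx)
    tab_y <- table(cy)
    shared <- intersect(names(tab_x), names(tab_y))
    inter <- sum(pmin(tab_x[shared], tab_y[shared]))
    inter / max(length(tx), length(ty))
  }
  vapply(seq_len(k), function(i) one(a[i], b[i]), numeric(1))
}
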