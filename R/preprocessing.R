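#' Clean a free-text address
#'
#' Applies the cleaning convention used throughout the pipeline:
#' address lines containing commas are split into separate lines; every
#' fragment is lowercased; hyphens in plain text become spaces
#' ("newtown-on-bay" -> "newtown on bay"); whitespace-delimited tokens
#' containing at least one digit are pulled out of the text, stripped of
#' non-alphanumeric characters ("12/4" -> "124", "3B" -> "3b") and collected
#' as number tokens in reading order; remaining punctuation is removed;
#' empty fragments are dropped.
#'
#' @param lines Character vector of raw address lines (or a single-row
#'   address tibble, in which case its `lines` entry is used).
#' @return A list of class `clean_address` with elements `lines` (cleaned,
#'   comma-free, lowercase), `numbers` (character vector of number tokens)
#'   and `source_id` (the address id when one was supplied, else `NA`).
#' @examples
#' clean_address("89 Bay Street, Newtown-on-Bay")
#' @export
clean_address <- function(lines) {
  source_id <- NA_character_
  if (is.data.frame(lines)) {
    stopifnot(nrow(lines) == 1)
    source_id <- lines$address_id[[1]]
    lines <- lines$lines[[1]]
  }
  stopifnot(length(lines) >= 1)
  frags <- unlist(strsplit(tolower(lines), ",", fixed = TRUE),
                  use.names = FALSE)
  frags <- gsub("-", " ", frags, fixed = TRUE)
  out_lines <- character(0)
  out_numbers <- character(0)
  for (f in frags) {
    toks <- strsplit(trimws(f), "[[:space:]]+")[[1]]
    if (length(toks) == 0) next
    has_digit <- grepl("[0-9]", toks)
    nums <- gsub("[^a-z0-9]", "", toks[has_digit])
    nums <- nums[nzchar(nums)]
    words <- gsub("[^a-z0-9]", "", toks[!has_digit])
    words <- words[nzchar(words)]
    out_numbers <- c(out_numbers, nums)
    line <- paste(words, collapse = " ")
    if (nzchar(line)) out_lines <- c(out_lines, line)
  }
  structure(list(lines = out_lines, numbers = out_numbers,
                 source_id = source_id),
            class = "clean_address")
}

#' @export
print.clean_address <- function(x, ...) {
  cat("<clean_address> [",
      paste(x$lines, collapse = " | "), "] numbers: [",
      paste(x$numbers, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Render a cleaned address as one comparison string
#'
#' Cleaned lines joined by single spaces; number tokens are excluded (they
#' are compared separately through the number-token gate).
#'
#' @param clean A `clean_address`.
#' @return A single string.
#' @export
clean_text <- function(clean) paste(clean$lines, collapse = " ")

#' Clean every address in a dataset
#'
#' @param addresses Address tibble (see [read_address_dataset()]).
#' @return The input with list-columns `clean_lines` and `numbers` and a
#'   character column `text` (space-joined cleaned lines) appended.
#' @export
clean_addresses <- function(addresses) {
  cleaned <- lapply(addresses$lines, clean_address)
  addresses$clean_lines <- lapply(cleaned, `[[`, "lines")
  addresses$numbers <- lapply(cleaned, `[[`, "numbers")
  addresses$text <- vapply(cleaned, clean_text, character(1))
  addresses
}

#' Character n-grams of a string
#' @keywords internal
char_ngrams <- function(text, n) {
  len <- nchar(text)
  if (len < n) return(character(0))
  substring(text, seq_len(len - n + 1L), seq_len(len - n + 1L) + n - 1L)
}

#' Build a character n-gram vocabulary
#'
#' All distinct character n-grams (spaces included) over a corpus of
#' cleaned address texts, in deterministic lexicographic order.
#'
#' @param texts Character vector of cleaned address texts (or a list of
#'   `clean_address` objects).
#' @param n n-gram length, integer >= 1.
#' @return Character vector: the ordered vocabulary.
#' @export
build_vocabulary <- function(texts, n = 2L) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    stop("`n` must be a single integer >= 1")
  }
  n <- as.integer(n)
  if (is.list(texts)) texts <- vapply(texts, clean_text, character(1))
  grams <- as.character(unlist(lapply(texts, char_ngrams, n = n),
                               use.names = FALSE))
  # fixed C locale ordering so vocabularies are reproducible across machines
  sort(unique(grams), method = "radix")
}

#' n-gram count vector for one address
#'
#' Counts each vocabulary n-gram in the space-joined cleaned text.
#' Out-of-vocabulary n-grams are ignored. In probability mode counts are
#' divided by the total in-vocabulary count; an address with no
#' in-vocabulary n-gram yields an all-zero vector flagged degenerate.
#'
#' @param clean A `clean_address`, or a plain string of cleaned text.
#' @param n n-gram length used to build `vocabulary`.
#' @param vocabulary Ordered vocabulary from [build_vocabulary()].
#' @param norm_mode `"raw_count"` or `"probability"`.
#' @return Named numeric vector over the vocabulary, with attributes `n`,
#'   `norm_mode` and `degenerate` (logical).
#' @export
vectorize <- function(clean, n, vocabulary,
                      norm_mode = c("raw_count", "probability")) {
  norm_mode <- match.arg(norm_mode)
  text <- if (is.character(clean)) clean else clean_text(clean)
  grams <- char_ngrams(text, as.integer(n))
  idx <- match(grams, vocabulary)
  idx <- idx[!is.na(idx)]
  counts <- tabulate(idx, nbins = length(vocabulary))
  total <- sum(counts)
  degenerate <- total == 0
  v <- as.numeric(counts)
  if (norm_mode == "probability" && !degenerate) v <- v / total
  names(v) <- vocabulary
  attributes(v)$n <- as.integer(n)
  attr(v, "norm_mode") <- norm_mode
  attr(v, "degenerate") <- degenerate
  v
}

#' n-gram count matrix for many texts
#'
#' Row-per-text version of [vectorize()]; used by the pipeline scorer.
#'
#' @inheritParams vectorize
#' @param texts Character vector of cleaned texts.
#' @return Numeric matrix, one row per text, one column per vocabulary
#'   n-gram.
#' @export
vectorize_matrix <- function(texts, n, vocabulary,
                             norm_mode = c("raw_count", "probability")) {
  norm_mode <- match.arg(norm_mode)
  m <- matrix(0, nrow = length(texts), ncol = length(vocabulary),
              dimnames = list(NULL, vocabulary))
  for (i in seq_along(texts)) {
    grams <- char_ngrams(texts[[i]], as.integer(n))
    idx <- match(grams, vocabulary)
    idx <- idx[!is.na(idx)]
    counts <- tabulate(idx, nbins = length(vocabulary))
    tot <- sum(counts)
    if (norm_mode == "probability" && tot > 0) counts <- counts / tot
    m[i, ] <- counts
  }
  m
}
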