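#' Column mapping for a free-text address dataset
#'
#' Address extracts from different health boards lay their columns out
#' differently, so [read_address_dataset()] takes an explicit mapping from
#' the roles the pipeline needs to the column names present in the file.
#'
#' @param id Column holding the opaque address identifier.
#' @param lines Character vector of columns holding the address lines, in
#'   reading order. At least one must be non-blank per row.
#' @param person_count Column with the number of residents on the snapshot
#'   date (non-negative integer; 0 marks a historical address form).
#' @param has_over65 Column with a logical flag: does at least one person
#'   aged 65+ currently live at the address?
#' @param gold Column with the gold-standard care home label (logical).
#' @param region Optional column with a region label; when `NULL` every
#'   record gets region `"all"`.
#' @return A named list of class `address_schema`.
#' @export
address_schema <- function(id = "id",
                           lines = c("line1", "line2", "line3", "line4"),
                           person_count = "n_people",
                           has_over65 = "over65",
                           gold = "label",
                           region = NULL) {
  structure(list(id = id, lines = lines, person_count = person_count,
                 has_over65 = has_over65, gold = gold, region = region),
            class = "address_schema")
}

as_logical_col <- function(x) {
  if (is.logical(x)) return(x)
  lx <- tolower(trimws(as.character(x)))
  out <- lx %in% c("true", "t", "1", "yes", "y")
  out[is.na(x) | lx == ""] <- NA
  out
}

#' Read a free-text address dataset
#'
#' Reads one record per unique written address. Blank address lines within a
#' record are dropped; row order is preserved.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema An [address_schema()] mapping roles to column names.
#' @param delim Field delimiter (default comma).
#' @return A [tibble::tibble] with columns `address_id`, `lines`
#'   (list of character vectors), `person_count`, `has_over65`, `region`,
#'   `gold_is_care_home`.
#' @export
read_address_dataset <- function(path, schema = address_schema(), delim = ",") {
  if (!file.exists(path)) stop("address dataset not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "", check.names = FALSE)
  line_cols <- intersect(schema$lines, names(df))
  needed <- c(schema$id, schema$person_count, schema$has_over65, schema$gold,
              schema$region)
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0 || length(line_cols) == 0) {
    if (length(line_cols) == 0) missing <- c(missing, schema$lines[1])
    stop("address dataset is missing mapped column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) {
    return(tibble::tibble(address_id = character(), lines = list(),
                          person_count = integer(), has_over65 = logical(),
                          region = character(), gold_is_care_home = logical()))
  }
  line_mat <- as.matrix(df[line_cols])
  lines <- lapply(seq_len(nrow(df)), function(i) {
    v <- trimws(line_mat[i, ])
    v <- v[!is.na(v) & nzchar(v)]
    unname(v)
  })
  empties <- which(lengths(lines) == 0)
  if (length(empties) > 0) {
    stop("address record(s) with no non-blank line at row(s): ",
         paste(utils::head(empties, 5), collapse = ", "))
  }
  tibble::tibble(
    address_id = df[[schema$id]],
    lines = lines,
    person_count = as.integer(df[[schema$person_count]]),
    has_over65 = as_logical_col(df[[schema$has_over65]]),
    region = if (is.null(schema$region)) "all" else df[[schema$region]],
    gold_is_care_home = as_logical_col(df[[schema$gold]])
  )
}

#' Write an address dataset to the CSV schema read by [read_address_dataset()]
#'
#' @param addresses Tibble as returned by [read_address_dataset()] or
#'   [generate_population()].
#' @param path Output file path.
#' @export
write_address_dataset <- function(addresses, path) {
  k <- max(lengths(addresses$lines), 1L)
  mat <- t(vapply(addresses$lines,
                  function(v) c(v, rep("", k - length(v))),
                  character(k)))
  df <- data.frame(id = addresses$address_id, mat, stringsAsFactors = FALSE)
  names(df) <- c("id", paste0("line", seq_len(k)))
  df$n_people <- addresses$person_count
  df$over65 <- addresses$has_over65
  df$region <- addresses$region
  df$label <- addresses$gold_is_care_home
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Normalize a UK postcode found in free text
#'
#' Uppercases, collapses all whitespace, then locates the last UK-shaped
#' postcode token (outward code of 2-4 characters starting with a letter,
#' inward code digit-letter-letter) and re-inserts the single canonical
#' space before the final three characters. Free text around the postcode is
#' ignored. Idempotent.
#'
#' @param x Character vector.
#' @return Character vector of the same length: the canonical postcode, or
#'   `NA` where no UK-postcode-shaped token was found.
#' @export
normalize_postcode <- function(x) {
  flat <- toupper(gsub("[[:space:]]+", "", as.character(x)))
  # outward: letter (+letter) + digit (+digit/letter); inward: digit letter letter
  pat <- "[A-Z]{1,2}[0-9][0-9A-Z]?[0-9][A-Z]{2}"
  out <- rep(NA_character_, length(x))
  m <- gregexpr(pat, flat)
  hits <- regmatches(flat, m)
  has <- lengths(hits) > 0 & !is.na(flat)
  tok <- vapply(hits[has], function(h) h[[length(h)]], character(1))
  out[has] <- paste0(substr(tok, 1L, nchar(tok) - 3L), " ",
                     substring(tok, nchar(tok) - 2L))
  out
}

parse_service_type <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[grepl("care home", lx)] <- "care_home"
  out[lx %in% c("care_home", "carehome")] <- "care_home"
  out[!is.na(lx) & nzchar(lx) & is.na(out)] <- "other_care_service"
  out
}

#' Read a care home service registry
#'
#' Expects a delimited file with header columns `service_id`, `name`,
#' `address`, `postcode`, `town`, `service_type`. Postcodes are normalized
#' with [normalize_postcode()]; a `service_type` naming a care home service
#' maps to `"care_home"`, any other non-blank type to
#' `"other_care_service"` (those drive the exclusion filter but are never
#' match candidates).
#'
#' @param path Path to the registry file.
#' @param delim Field delimiter (default comma).
#' @return A tibble with columns `service_id`, `name`, `lines` (list),
#'   `postcode`, `town`, `service_type`.
#' @export
read_care_home_registry <- function(path, delim = ",") {
  if (!file.exists(path)) stop("registry file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "", check.names = FALSE)
  needed <- c("service_id", "name", "address", "postcode", "town",
              "service_type")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("registry is missing column(s): ", paste(missing, collapse = ", "))
  }
  type <- parse_service_type(df$service_type)
  if (anyNA(type) && nrow(df) > 0) {
    stop("unparseable service_type at row(s): ",
         paste(which(is.na(type)), collapse = ", "))
  }
  tibble::tibble(
    service_id = df$service_id,
    name = df$name,
    lines = as.list(df$address),
    postcode = normalize_postcode(df$postcode),
    town = df$town,
    service_type = type
  )
}

#' Write a care home registry to the CSV schema read by
#' [read_care_home_registry()]
#' @param registry Registry tibble.
#' @param path Output file path.
#' @export
write_care_home_registry <- function(registry, path) {
  df <- data.frame(
    service_id = registry$service_id,
    name = registry$name,
    address = vapply(registry$lines, paste, character(1), collapse = ", "),
    postcode = registry$postcode,
    town = registry$town,
    service_type = ifelse(registry$service_type == "care_home",
                          "Care Home Service", "Other Care Service"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Town lexicon from a registry
#'
#' The exclusion filter asks whether an address mentions the town of any
#' registered care home; this extracts the deduplicated, lowercased set of
#' registry towns.
#'
#' @param registry Registry tibble.
#' @return Character vector of distinct lowercase town names (no blanks).
#' @export
extract_town_lexicon <- function(registry) {
  towns <- tolower(trimws(registry$town))
  sort(unique(towns[!is.na(towns) & nzchar(towns)]))
}

#' Stratified train/validation split
#'
#' Randomly partitions address records into a training and a validation set,
#' stratified on the gold-standard label so that the care home prevalence is
#' preserved in both parts (the real corpora keep an identical prevalence
#' across splits).
#'
#' @param records Address tibble with a `gold_is_care_home` column.
#' @param fraction Proportion assigned to training, in (0, 1). Default 0.7.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A list of class `dataset_split` with elements `train`,
#'   `validation`, `seed`, `fraction`.
#' @export
split_train_validation <- function(records, fraction = 0.7, seed = 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      is.na(fraction) || fraction <= 0 || fraction >= 1) {
    stop("`fraction` must be a single number strictly between 0 and 1")
  }
  n <- nrow(records)
  in_train <- logical(n)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  for (stratum in unique(records$gold_is_care_home)) {
    idx <- which(records$gold_is_care_home == stratum)
    k <- round(fraction * length(idx))
    in_train[idx[sample.int(length(idx), k)]] <- TRUE
  }
  structure(list(train = records[in_train, , drop = FALSE],
                 validation = records[!in_train, , drop = FALSE],
                 seed = as.integer(seed), fraction = fraction),
            class = "dataset_split")
}
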