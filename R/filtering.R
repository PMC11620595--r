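#' Default care home name-phrase lexicon
#'
#' Phrases whose presence in the first address line marks the address as a
#' care home. The set is deliberately extensible: the canonical phrases are
#' the ones care home names carry ("care home", "nursing home",
#' "residential home"), and deployments can add local variants.
#'
#' @return Lowercase character vector.
#' @export
default_phrase_lexicon <- function() {
  c("care home", "nursing home", "residential home")
}

#' Filter rule 1: care home name phrase in the first line
#'
#' @param address One-row address tibble or a character vector of raw lines.
#' @param phrase_lexicon Lowercase phrases (non-empty).
#' @return `TRUE` iff the lowercased first line contains any phrase as a
#'   substring.
#' @export
rule_name_phrase <- function(address, phrase_lexicon = default_phrase_lexicon()) {
  stopifnot(length(phrase_lexicon) >= 1)
  lines <- if (is.data.frame(address)) address$lines[[1]] else address
  first <- tolower(lines[[1]])
  any(vapply(phrase_lexicon, grepl, logical(1), x = first, fixed = TRUE))
}

# postcodes of eligible (care_home-typed) registry entries
care_home_postcodes <- function(registry) {
  pc <- registry$postcode[registry$service_type == "care_home"]
  unique(pc[!is.na(pc)])
}

#' Filter rule 2: exclusion by postcode, service type or town
#'
#' An address is ruled *not* to be a care home when any arm fires:
#' its normalized postcode matches no registry postcode, or every registry
#' entry sharing its postcode is registered for a different kind of care
#' service, or no registry town appears (case-insensitive substring) in any
#' of its lines.
#'
#' @param address One-row address tibble or character vector of raw lines.
#' @param registry Registry tibble.
#' @param town_lexicon Lowercase towns from [extract_town_lexicon()].
#' @return `TRUE` (exclude) or `FALSE`, with attribute `arm` naming the
#'   first firing arm (`postcode_mismatch`, `service_type_exclusion`,
#'   `town_mismatch`) or `none`.
#' @export
rule_exclusion <- function(address, registry, town_lexicon) {
  lines <- if (is.data.frame(address)) address$lines[[1]] else address
  pc <- normalize_postcode(paste(lines, collapse = " "))
  arm <- "none"
  shared <- !is.na(pc) & !is.na(registry$postcode) & registry$postcode == pc
  if (is.na(pc) || !any(shared)) {
    arm <- "postcode_mismatch"
  } else if (all(registry$service_type[shared] == "other_care_service")) {
    arm <- "service_type_exclusion"
  } else {
    text <- tolower(paste(lines, collapse = " "))
    town_hit <- any(vapply(town_lexicon, grepl, logical(1), x = text,
                           fixed = TRUE))
    if (!town_hit) arm <- "town_mismatch"
  }
  structure(arm != "none", arm = arm)
}

#' Apply the sequential filter rules to one address
#'
#' Rules are evaluated in pipeline order: the name-phrase rule first (its
#' decision is final), the exclusion rule second; an address that survives
#' both is left undecided and passed on to similarity scoring.
#'
#' @inheritParams rule_exclusion
#' @param phrase_lexicon Lowercase name phrases.
#' @return List of class `filter_decision` with `status` (one of
#'   `care_home_by_name`, `not_care_home`, `undecided`) and `rule_fired`
#'   (`name_phrase`, `postcode_mismatch`, `service_type_exclusion`,
#'   `town_mismatch`, or `none`).
#' @export
apply_filters <- function(address, registry,
                          phrase_lexicon = default_phrase_lexicon(),
                          town_lexicon = extract_town_lexicon(registry)) {
  if (rule_name_phrase(address, phrase_lexicon)) {
    dec <- list(status = "care_home_by_name", rule_fired = "name_phrase")
  } else {
    ex <- rule_exclusion(address, registry, town_lexicon)
    if (ex) {
      dec <- list(status = "not_care_home", rule_fired = attr(ex, "arm"))
    } else {
      dec <- list(status = "undecided", rule_fired = "none")
    }
  }
  structure(dec, class = "filter_decision")
}

#' Vectorised filtering of a whole dataset
#'
#' Same semantics as [apply_filters()], applied to every record at once.
#'
#' @param addresses Address tibble.
#' @param registry Registry tibble.
#' @param phrase_lexicon,town_lexicon As in [apply_filters()].
#' @return Tibble with `address_id`, `status`, `rule_fired`, and the
#'   address's normalized `postcode` (used downstream for blocking).
#' @export
filter_dataset <- function(addresses, registry,
                           phrase_lexicon = default_phrase_lexicon(),
                           town_lexicon = extract_town_lexicon(registry)) {
  n <- nrow(addresses)
  joined <- vapply(addresses$lines, paste, character(1), collapse = " ")
  first <- tolower(vapply(addresses$lines, `[[`, character(1), 1L))
  pc <- normalize_postcode(joined)

  phrase_hit <- rep(FALSE, n)
  for (p in phrase_lexicon) phrase_hit <- phrase_hit | grepl(p, first, fixed = TRUE)

  ch_pc <- care_home_postcodes(registry)
  all_pc <- unique(registry$postcode[!is.na(registry$postcode)])
  pc_in_registry <- !is.na(pc) & pc %in% all_pc
  pc_care_home <- !is.na(pc) & pc %in% ch_pc

  low <- tolower(joined)
  town_hit <- rep(FALSE, n)
  for (tn in town_lexicon) town_hit <- town_hit | grepl(tn, low, fixed = TRUE)

  status <- rep("undecided", n)
  rule <- rep("none", n)

  excl_pc <- !phrase_hit & !pc_in_registry
  excl_type <- !phrase_hit & pc_in_registry & !pc_care_home
  excl_town <- !phrase_hit & pc_care_home & !town_hit

  status[phrase_hit] <- "care_home_by_name"
  rule[phrase_hit] <- "name_phrase"
  status[excl_pc | excl_type | excl_town] <- "not_care_home"
  rule[excl_pc] <- "postcode_mismatch"
  rule[excl_type] <- "service_type_exclusion"
  rule[excl_town] <- "town_mismatch"

  tibble::tibble(address_id = addresses$address_id, status = status,
                 rule_fired = rule, postcode = pc)
}
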