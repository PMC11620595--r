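# Fixed word lists for the synthetic address grammar: shipped in code so
# corpora are reproducible with no download.
SYNTH_ADJECTIVES <- c("sunnybank", "rosewood", "willowbrook", "oakfield",
  "meadowview", "riverside", "hillcrest", "abbeyfield", "castlegreen",
  "heatherlea", "thistledown", "bramblewood", "orchardside", "hollybank",
  "mapleton", "cedarwood", "birchgrove", "fernlea", "lavender", "primrose")
SYNTH_NOUNS <- c("house", "lodge", "manor", "grange", "court", "hall",
  "croft", "haven", "view", "park")
SYNTH_SUFFIXES <- c("care home", "nursing home", "residential home", "")
SYNTH_STREETS <- c("high street", "station road", "church lane", "mill road",
  "main street", "school wynd", "harbour road", "victoria terrace",
  "queen street", "king street", "north road", "south street",
  "castle drive", "park avenue", "bridge street", "glebe street",
  "bay street", "shore road", "academy street", "provost road")
SYNTH_TOWNS <- c("kirkcaldy", "dunfermline", "glenrothes", "st andrews",
  "dundee", "perth", "arbroath", "forfar", "montrose", "cupar", "leven",
  "carnoustie", "brechin", "crieff", "kinross")
SYNTH_OUTWARD <- c("KY", "DD", "PH", "FK")

ABBREVIATIONS <- c(street = "st", road = "rd", avenue = "ave", drive = "dr",
                   terrace = "terr", gardens = "gdns", lane = "ln",
                   court = "ct", place = "pl")
NUMBER_WORDS <- c("one", "two", "three", "four", "five", "six", "seven",
                  "eight", "nine", "ten", "eleven", "twelve", "thirteen",
                  "fourteen", "fifteen", "sixteen", "seventeen", "eighteen",
                  "nineteen", "twenty")

#' Configuration for the synthetic address corpus generator
#'
#' Defaults emulate the structure of the real register the pipeline was
#' designed for: about 1.3% of unique written addresses are care home
#' addresses while about 0.7% of people live in one (care homes accumulate
#' several historical written forms each, most with nobody currently
#' registered there); free-text noise takes the form of typos,
#' abbreviations, merged or shuffled lines, spelled-out house numbers and
#' dropped care home name lines; and a fraction of ordinary households are
#' "neighbours" sharing a care home's postcode.
#'
#' @param n_addresses Number of unique written addresses to generate.
#' @param care_home_address_fraction Fraction of addresses that are care
#'   home forms (gold positive). Default 0.013.
#' @param resident_fraction Target fraction of people who are care home
#'   residents; used to derive `mean_care_home_size` when that is `NULL`.
#'   Default 0.007.
#' @param mean_care_home_size Mean residents per care home service on the
#'   snapshot date; `NULL` derives it from `resident_fraction`.
#' @param mean_variants Mean number of unique written forms per care home
#'   service (forms are capped at 1-5). Default 3.
#' @param typo_rate Per-character probability of a typo
#'   (substitute/delete/transpose). Default 0.
#' @param abbreviation_rate Per-token probability of abbreviating a street
#'   word ("street" -> "st"). Default 0.
#' @param number_spell_rate Per-token probability of spelling a house
#'   number out ("10" -> "ten"). Default 0.05 when any noise is on, else 0.
#' @param comma_merge_rate Per-address probability of merging two adjacent
#'   lines with a comma. Default 0.
#' @param line_shuffle_rate Per-address probability of shuffling lines.
#'   Default 0.
#' @param name_drop_rate Probability a care home form omits the name line.
#'   Default 0.
#' @param neighbour_rate Fraction of non-care-home addresses placed at a
#'   care home's postcode. Default 0.02.
#' @param other_service_fraction Fraction of registry entries registered
#'   for a different kind of care service. Default 0.15.
#' @param over65_care_home_rate Probability a care home (current form)
#'   houses someone aged 65+. Default 0.8.
#' @param n_services Number of care-home-typed registry services; `NULL`
#'   derives it from the positive-address budget and `mean_variants`.
#' @param seed Integer seed; everything is deterministic given it.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_addresses = 10000L,
                             care_home_address_fraction = 0.013,
                             resident_fraction = 0.007,
                             mean_care_home_size = NULL,
                             mean_variants = 3,
                             typo_rate = 0,
                             abbreviation_rate = 0,
                             number_spell_rate = NULL,
                             comma_merge_rate = 0,
                             line_shuffle_rate = 0,
                             name_drop_rate = 0,
                             neighbour_rate = 0.02,
                             other_service_fraction = 0.15,
                             over65_care_home_rate = 0.8,
                             n_services = NULL,
                             seed = 1L) {
  if (is.null(number_spell_rate)) {
    number_spell_rate <- if (typo_rate > 0 || abbreviation_rate > 0) 0.05 else 0
  }
  cfg <- list(n_addresses = as.integer(n_addresses),
              care_home_address_fraction = care_home_address_fraction,
              resident_fraction = resident_fraction,
              mean_care_home_size = mean_care_home_size,
              mean_variants = mean_variants,
              typo_rate = typo_rate,
              abbreviation_rate = abbreviation_rate,
              number_spell_rate = number_spell_rate,
              comma_merge_rate = comma_merge_rate,
              line_shuffle_rate = line_shuffle_rate,
              name_drop_rate = name_drop_rate,
              neighbour_rate = neighbour_rate,
              other_service_fraction = other_service_fraction,
              over65_care_home_rate = over65_care_home_rate,
              n_services = if (is.null(n_services)) NULL else
                as.integer(n_services),
              seed = as.integer(seed))
  probs <- cfg[c("care_home_address_fraction", "resident_fraction",
                 "typo_rate", "abbreviation_rate", "number_spell_rate",
                 "comma_merge_rate", "line_shuffle_rate", "name_drop_rate",
                 "neighbour_rate", "other_service_fraction",
                 "over65_care_home_rate")]
  bad <- vapply(probs, function(p) p < 0 || p > 1, logical(1))
  if (any(bad)) stop("rates must lie in [0, 1]: ",
                     paste(names(probs)[bad], collapse = ", "))
  structure(cfg, class = "synthetic_config")
}

n_positive_addresses <- function(config) {
  round(config$n_addresses * config$care_home_address_fraction)
}

derived_n_services <- function(config) {
  if (!is.null(config$n_services)) return(config$n_services)
  max(1L, as.integer(round(n_positive_addresses(config) /
                             config$mean_variants)))
}

derived_mean_size <- function(config, n_services) {
  if (!is.null(config$mean_care_home_size)) return(config$mean_care_home_size)
  max(1, config$resident_fraction * config$n_addresses / n_services)
}

random_postcodes <- function(k, exclude = character(0)) {
  out <- character(0)
  while (length(out) < k) {
    pc <- paste0(sample(SYNTH_OUTWARD, k, replace = TRUE),
                 sample(1:16, k, replace = TRUE), " ",
                 sample(0:9, k, replace = TRUE),
                 sample(LETTERS, k, replace = TRUE),
                 sample(LETTERS, k, replace = TRUE))
    out <- unique(c(out, setdiff(pc, exclude)))
  }
  out[seq_len(k)]
}

#' Generate a synthetic care home service registry
#'
#' Service names come from a fixed grammar (adjective + noun + a care home
#' suffix, or a plain name with no suffix); each service gets a unique
#' UK-shaped postcode, a house number, a street and a town from fixed word
#' lists. A configurable fraction of entries is registered for a different
#' kind of care service (those drive the exclusion filter but are never
#' match candidates).
#'
#' @param config A [synthetic_config()].
#' @return Registry tibble in the [read_care_home_registry()] layout, with
#'   an extra `house_number` column used by [generate_population()].
#' @export
generate_registry <- function(config) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  n_ch <- derived_n_services(config)
  n_other <- round(n_ch * config$other_service_fraction /
                     max(1e-9, 1 - config$other_service_fraction))
  n <- n_ch + n_other
  name <- paste(sample(SYNTH_ADJECTIVES, n, replace = TRUE),
                sample(SYNTH_NOUNS, n, replace = TRUE))
  suffix <- sample(SYNTH_SUFFIXES, n, replace = TRUE)
  name <- trimws(paste(name, suffix))
  # deterministic exact split between service types
  type <- rep(c("care_home", "other_care_service"), c(n_ch, n_other))
  house_number <- sample(1:40, n, replace = TRUE)
  street <- sample(SYNTH_STREETS, n, replace = TRUE)
  town <- sample(SYNTH_TOWNS, n, replace = TRUE)
  postcode <- random_postcodes(n)
  tibble::tibble(
    service_id = sprintf("CS%04d", seq_len(n)),
    name = name,
    lines = as.list(paste0(house_number, " ", street)),
    postcode = postcode,
    town = town,
    service_type = type,
    house_number = as.character(house_number)
  )
}

apply_typos <- function(text, rate) {
  if (rate <= 0 || !nzchar(text)) return(text)
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  editable <- grepl("[A-Za-z0-9]", ch)
  hit <- editable & stats::runif(length(ch)) < rate
  if (!any(hit)) return(text)
  kind <- sample(c("sub", "del", "swap"), sum(hit), replace = TRUE)
  pos <- which(hit)
  for (j in seq_along(pos)) {
    i <- pos[j]
    if (kind[j] == "sub") {
      ch[i] <- if (grepl("[A-Z]", ch[i])) sample(LETTERS, 1) else
        sample(letters, 1)
    } else if (kind[j] == "del") {
      ch[i] <- ""
    } else if (i < length(ch)) {
      tmp <- ch[i]
      ch[i] <- ch[i + 1]
      ch[i + 1] <- tmp
    }
  }
  out <- paste(ch, collapse = "")
  if (nzchar(trimws(out))) out else text
}

abbreviate_tokens <- function(text, rate) {
  if (rate <= 0) return(text)
  toks <- strsplit(text, " ", fixed = TRUE)[[1]]
  known <- toks %in% names(ABBREVIATIONS)
  hit <- known & stats::runif(length(toks)) < rate
  toks[hit] <- ABBREVIATIONS[toks[hit]]
  paste(toks, collapse = " ")
}

spell_numbers <- function(text, rate) {
  if (rate <= 0) return(text)
  toks <- strsplit(text, " ", fixed = TRUE)[[1]]
  num <- suppressWarnings(as.integer(toks))
  spellable <- !is.na(num) & num >= 1 & num <= 20
  hit <- spellable & stats::runif(length(toks)) < rate
  toks[hit] <- NUMBER_WORDS[num[hit]]
  paste(toks, collapse = " ")
}

#' Perturb the written form of an address
#'
#' Emulates how the same true address accumulates different written forms
#' in a free-text register: street-word abbreviation, character typos
#' (substitute/delete/transpose), spelling house numbers out, merging
#' adjacent lines with a comma, shuffling line order, and (for care home
#' forms) dropping the name line. Draws come from R's RNG, so results are
#' reproducible under `set.seed()`. Never produces an empty address.
#'
#' @param lines Character vector of address lines.
#' @param config A [synthetic_config()] holding the rates.
#' @param name_line Index of the care home name line, or 0 when there is
#'   none.
#' @return Character vector of perturbed lines.
#' @export
perturb_address <- function(lines, config, name_line = 0L) {
  if (name_line > 0 && length(lines) > 1 &&
      stats::runif(1) < config$name_drop_rate) {
    lines <- lines[-name_line]
  }
  lines <- vapply(lines, abbreviate_tokens, character(1),
                  rate = config$abbreviation_rate, USE.NAMES = FALSE)
  lines <- vapply(lines, spell_numbers, character(1),
                  rate = config$number_spell_rate, USE.NAMES = FALSE)
  lines <- vapply(lines, apply_typos, character(1),
                  rate = config$typo_rate, USE.NAMES = FALSE)
  if (length(lines) > 1 && stats::runif(1) < config$comma_merge_rate) {
    i <- sample(length(lines) - 1, 1)
    lines <- c(lines[seq_len(i - 1)],
               paste(lines[i], lines[i + 1], sep = ", "),
               lines[-seq_len(i + 1)])
  }
  if (length(lines) > 1 && stats::runif(1) < config$line_shuffle_rate) {
    lines <- lines[sample(length(lines))]
  }
  lines[nzchar(trimws(lines))]
}

# Deterministic formatting variants of a care home's registered address:
# historical forms differ in layout even before noise is applied.
format_variant <- function(name, street_line, town, postcode, v) {
  switch(((v - 1) %% 5) + 1,
    c(name, street_line, town, postcode),
    c(paste(name, street_line, sep = ", "), town, postcode),
    paste(name, street_line, town, postcode, sep = ", "),
    c(name, street_line, paste(town, gsub(" ", "", postcode))),
    c(name, paste(street_line, town, sep = ", "), postcode)
  )
}

#' Generate a synthetic address population with gold labels
#'
#' Care home addresses are written variants (formatting plus noise) of the
#' care_home-typed registry entries: each service emits 1-5 unique forms,
#' exactly one of which is "current" and carries the service's residents;
#' the rest are historical forms with nobody registered. Ordinary
#' household addresses get their own street/town/postcode, except a
#' `neighbour_rate` fraction placed at a care home's postcode (with a house
#' number disjoint from the care home's). Ordinary addresses are perturbed
#' with the same noise rates.
#'
#' @param config A [synthetic_config()].
#' @param registry Registry from [generate_registry()] (same config).
#' @return Address tibble in the [read_address_dataset()] layout
#'   (`address_id`, `lines`, `person_count`, `has_over65`, `region`,
#'   `gold_is_care_home`).
#' @export
generate_population <- function(config, registry) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed + 1L)

  ch <- registry[registry$service_type == "care_home", , drop = FALSE]
  n_ch <- nrow(ch)
  n_pos <- max(n_ch, n_positive_addresses(config))
  mean_size <- derived_mean_size(config, n_ch)

  # distribute positive written forms over services: one each, remainder
  # spread at random, at most 5 forms per service
  variants <- rep(1L, n_ch)
  extra <- n_pos - n_ch
  while (extra > 0) {
    open <- which(variants < 5L)
    if (length(open) == 0) break
    take <- open[sample.int(length(open), min(extra, length(open)))]
    variants[take] <- variants[take] + 1L
    extra <- extra - length(take)
  }

  pos_rows <- list()
  for (i in seq_len(n_ch)) {
    sizes <- 1L + stats::rpois(1, max(0, mean_size - 1))
    over65 <- stats::runif(1) < config$over65_care_home_rate
    for (v in seq_len(variants[i])) {
      base <- format_variant(ch$name[i], ch$lines[[i]], ch$town[i],
                             ch$postcode[i], v)
      # variants 2 and 3 merge the name into a longer line; dropping that
      # line would lose the street as well, so only standalone name lines
      # are droppable
      nl <- if (((v - 1) %% 5 + 1) %in% c(2L, 3L)) 0L else 1L
      lines <- perturb_address(base, config, name_line = nl)
      if (length(lines) == 0) lines <- base
      pos_rows[[length(pos_rows) + 1]] <- list(
        lines = lines,
        person_count = if (v == 1L) sizes else 0L,
        has_over65 = if (v == 1L) over65 else FALSE,
        gold = TRUE
      )
    }
  }

  n_neg <- config$n_addresses - length(pos_rows)
  n_nb <- round(n_neg * config$neighbour_rate)
  neg_pc_pool <- random_postcodes(max(50, round(n_neg / 30)),
                                  exclude = registry$postcode)

  make_negative <- function(neighbour) {
    if (neighbour && n_ch > 0) {
      s <- sample(n_ch, 1)
      num <- sample(setdiff(41:299, as.integer(ch$house_number[s])), 1)
      street <- sub("^[0-9]+ ", "", ch$lines[[s]])
      town <- ch$town[s]
      pc <- ch$postcode[s]
    } else {
      num <- sample(1:299, 1)
      street <- sample(SYNTH_STREETS, 1)
      town <- sample(SYNTH_TOWNS, 1)
      pc <- sample(neg_pc_pool, 1)
    }
    lines <- perturb_address(c(paste(num, street), town, pc), config)
    if (length(lines) == 0) lines <- c(paste(num, street), town, pc)
    pc_current <- stats::runif(1) > 0.1
    list(lines = lines,
         person_count = if (pc_current) sample(c(1L, 1L, 1L, 2L, 2L, 3L), 1)
                        else 0L,
         has_over65 = pc_current && stats::runif(1) < 0.25,
         gold = FALSE)
  }

  neg_rows <- lapply(seq_len(n_neg), function(i) make_negative(i <= n_nb))
  rows <- c(pos_rows, neg_rows)

  # enforce uniqueness of written forms: regenerate colliding negatives,
  # then force-uniquify stragglers with an unused house number
  key <- vapply(rows, function(r) paste(r$lines, collapse = "|"), character(1))
  for (pass in 1:10) {
    dup <- which(duplicated(key))
    dup <- dup[dup > length(pos_rows)] # only regenerate negatives
    if (length(dup) == 0) break
    for (i in dup) {
      rows[[i]] <- make_negative(FALSE)
      key[i] <- paste(rows[[i]]$lines, collapse = "|")
    }
  }
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    for (j in seq_along(dup)) {
      i <- dup[j]
      rows[[i]]$lines[1] <- paste(300 + j, rows[[i]]$lines[1])
      key[i] <- paste(rows[[i]]$lines, collapse = "|")
    }
  }

  tibble::tibble(
    address_id = sprintf("A%06d", seq_along(rows)),
    lines = lapply(rows, `[[`, "lines"),
    person_count = vapply(rows, `[[`, integer(1), "person_count"),
    has_over65 = vapply(rows, `[[`, logical(1), "has_over65"),
    region = "synth",
    gold_is_care_home = vapply(rows, `[[`, logical(1), "gold")
  )
}

#' Generate a full synthetic corpus (registry + population)
#'
#' @param config A [synthetic_config()].
#' @param dir Optional directory; when given, writes `registry.csv` and
#'   `addresses.csv` in the schemas the readers consume.
#' @return List with `registry` and `addresses` tibbles.
#' @export
generate_corpus <- function(config = synthetic_config(), dir = NULL) {
  registry <- generate_registry(config)
  addresses <- generate_population(config, registry)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_care_home_registry(registry, file.path(dir, "registry.csv"))
    write_address_dataset(addresses, file.path(dir, "addresses.csv"))
  }
  list(registry = registry[, c("service_id", "name", "lines", "postcode",
                               "town", "service_type")],
       addresses = addresses)
}
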