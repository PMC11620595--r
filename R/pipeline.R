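#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end run: input paths (or in-memory
#' tibbles), the train/validation split, the method roster, preprocessing
#' options and lexicons. Validated before any computation.
#'
#' @param addresses_path,registry_path Input CSV paths (optional when the
#'   tibbles are passed to [run_pipeline()] directly).
#' @param out_dir Optional output directory; when set, predictions, fitted
#'   thresholds, evaluation reports and the run log are written there.
#' @param schema [address_schema()] for the address file.
#' @param delim Input field delimiter.
#' @param split_fraction Training proportion in (0, 1). Default 0.7.
#' @param seed Integer seed for the split.
#' @param methods Similarity methods to run (subset of
#'   `method_roster()$name`).
#' @param baselines Baseline comparators to run (subset of
#'   `c("postcode_match", "markov_score", "phonics_score")`).
#' @param ngram_n Character n-gram length for vector methods. Default 2.
#' @param number_gate Apply the number-token gate during scoring?
#' @param phrase_lexicon Name-phrase lexicon for filter rule 1.
#' @param town_lexicon Optional town lexicon override (default: built from
#'   the registry).
#' @param markov_smoothing_k Add-k smoothing for the Markov baseline.
#' @param strata Population strata to fit and evaluate
#'   (`"all_ages"`, `"over65"`).
#' @param levels Evaluation levels (`"address"`, `"patient"`).
#' @return List of class `run_config`.
#' @export
run_config <- function(addresses_path = NULL, registry_path = NULL,
                       out_dir = NULL, schema = address_schema(),
                       delim = ",", split_fraction = 0.7, seed = 1L,
                       methods = method_roster()$name,
                       baselines = c("postcode_match", "markov_score",
                                     "phonics_score"),
                       ngram_n = 2L, number_gate = TRUE,
                       phrase_lexicon = default_phrase_lexicon(),
                       town_lexicon = NULL,
                       markov_smoothing_k = 1,
                       strata = c("all_ages", "over65"),
                       levels = c("address", "patient")) {
  cfg <- structure(as.list(environment()), class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' @rdname run_config
#' @param config A `run_config` to validate.
#' @export
validate_run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$split_fraction <= 0 || config$split_fraction >= 1) {
    stop("config error: split_fraction must be in (0, 1)")
  }
  unknown <- setdiff(config$methods, method_roster()$name)
  if (length(unknown) > 0) {
    stop("config error: unknown method(s): ", paste(unknown, collapse = ", "))
  }
  unknown <- setdiff(config$baselines,
                     c("postcode_match", "markov_score", "phonics_score"))
  if (length(unknown) > 0) {
    stop("config error: unknown baseline(s): ",
         paste(unknown, collapse = ", "))
  }
  if (config$ngram_n < 1) stop("config error: ngram_n must be >= 1")
  for (p in c("addresses_path", "registry_path")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]])) {
      stop("config error: ", p, " does not exist: ", config[[p]])
    }
  }
  invisible(config)
}

# Number tokens used by the matching gate: cleaned number tokens minus the
# fragments of the address's own detected postcode (the postcode is already
# compared exactly by blocking, so its pieces must not satisfy the gate).
matching_numbers <- function(numbers, postcode = NA_character_) {
  if (is.na(postcode)) return(numbers)
  flat <- tolower(gsub(" ", "", postcode))
  inward <- substring(flat, nchar(flat) - 2L)
  outward <- substr(flat, 1L, nchar(flat) - 3L)
  numbers[!numbers %in% c(flat, inward, outward)]
}

#' Prepare a dataset and registry for similarity scoring
#'
#' Cleans both sides with the same conventions, applies the sequential
#' filters, blocks care home candidates by exact postcode and builds the
#' n-gram vector representations of the undecided addresses and the
#' candidates. The registry comparison string is the cleaned name, address
#' and town (the postcode is consumed by blocking, not by text
#' comparison).
#'
#' @param addresses Address tibble.
#' @param registry Registry tibble.
#' @param config A [run_config()].
#' @param vocabulary Optional fixed vocabulary (reuse the training
#'   vocabulary when preparing validation data); default builds one from
#'   the registry and the undecided addresses.
#' @return List used by [score_methods()]: cleaned addresses, filter
#'   decisions, candidate blocks, vocabulary and vector matrices.
#' @export
prepare_matching <- function(addresses, registry, config = run_config(),
                             vocabulary = NULL) {
  addresses <- clean_addresses(addresses)
  town_lex <- if (is.null(config$town_lexicon)) {
    extract_town_lexicon(registry)
  } else config$town_lexicon
  filt <- filter_dataset(addresses, registry, config$phrase_lexicon, town_lex)
  addresses$gate_numbers <- mapply(matching_numbers, addresses$numbers,
                                   filt$postcode, SIMPLIFY = FALSE)

  reg <- registry[registry$service_type == "care_home", , drop = FALSE]
  reg_clean <- lapply(seq_len(nrow(reg)), function(i) {
    clean_address(c(reg$name[i], reg$lines[[i]], reg$town[i]))
  })
  reg_text <- vapply(reg_clean, clean_text, character(1))
  reg_numbers <- lapply(reg_clean, function(cl) matching_numbers(cl$numbers))

  und <- which(filt$status == "undecided")
  if (is.null(vocabulary)) {
    vocabulary <- build_vocabulary(c(reg_text, addresses$text[und]),
                                   n = config$ngram_n)
  }
  reg_raw <- vectorize_matrix(reg_text, config$ngram_n, vocabulary)
  und_raw <- vectorize_matrix(addresses$text[und], config$ngram_n, vocabulary)
  to_prob <- function(m) {
    tot <- rowSums(m)
    m[tot > 0, ] <- m[tot > 0, , drop = FALSE] / tot[tot > 0]
    m
  }
  list(addresses = addresses, filter = filt,
       registry_prep = list(service_id = reg$service_id,
                            postcode = reg$postcode, text = reg_text,
                            numbers = reg_numbers, raw = reg_raw,
                            prob = to_prob(reg_raw)),
       undecided = und, und_raw = und_raw, und_prob = to_prob(und_raw),
       vocabulary = vocabulary, town_lexicon = town_lex)
}

#' Score the undecided addresses under each similarity method
#'
#' For every undecided address, scores all care home candidates sharing its
#' exact postcode (subject to the number-token gate) under each requested
#' method and keeps the best score per method.
#'
#' @param prep Output of [prepare_matching()].
#' @param methods Method names.
#' @param config A [run_config()].
#' @return Named list (per method) of tibbles `address_id`, `score`,
#'   `eligible`, `best_candidate`.
#' @export
score_methods <- function(prep, methods = method_roster()$name,
                          config = run_config()) {
  roster <- method_roster()
  specs <- roster[match(methods, roster$name), ]
  und <- prep$undecided
  reg <- prep$registry_prep
  n_und <- length(und)
  blocks <- split(seq_along(reg$service_id), reg$postcode)

  out <- lapply(methods, function(m) {
    sim <- specs$direction[specs$name == m] == "similarity_high_is_match"
    list(score = rep(if (sim) 0 else Inf, n_und),
         eligible = rep(FALSE, n_und),
         best = rep(NA_character_, n_und))
  })
  names(out) <- methods

  addr_pc <- prep$filter$postcode[und]
  addr_text <- prep$addresses$text[und]
  addr_nums <- prep$addresses$gate_numbers[und]

  for (i in seq_len(n_und)) {
    cand <- blocks[[addr_pc[i]]]
    if (is.null(cand)) next
    if (config$number_gate) {
      a_n <- addr_nums[[i]]
      if (length(a_n) > 0) {
        keep <- vapply(cand, function(j) {
          length(reg$numbers[[j]]) == 0 ||
            length(intersect(a_n, reg$numbers[[j]])) > 0
        }, logical(1))
        cand <- cand[keep]
      }
    }
    if (length(cand) == 0) next
    for (m in methods) {
      fam <- specs$family[specs$name == m]
      sim <- specs$direction[specs$name == m] == "similarity_high_is_match"
      if (fam == "edit_distance") {
        sc <- edit_similarity(rep(addr_text[i], length(cand)),
                              reg$text[cand], m)
      } else {
        prob <- m == "jensen_shannon"
        u <- if (prob) prep$und_prob[i, ] else prep$und_raw[i, ]
        sc <- vapply(cand, function(j) {
          v <- if (prob) reg$prob[j, ] else reg$raw[j, ]
          if (sum(u) == 0 || sum(v) == 0) return(NA_real_)
          if (m == "correlation" &&
              (stats::sd(u) == 0 || stats::sd(v) == 0)) return(NA_real_)
          vector_distance(u, v, m)
        }, numeric(1))
      }
      ok <- which(!is.na(sc))
      if (length(ok) == 0) next
      b <- if (sim) ok[which.max(sc[ok])] else ok[which.min(sc[ok])]
      out[[m]]$score[i] <- sc[b]
      out[[m]]$eligible[i] <- TRUE
      out[[m]]$best[i] <- reg$service_id[cand[b]]
    }
  }

  lapply(out, function(o) {
    tibble::tibble(address_id = prep$addresses$address_id[und],
                   score = o$score, eligible = o$eligible,
                   best_candidate = o$best)
  })
}

stratum_subset <- function(addresses, stratum) {
  if (stratum == "over65") addresses$has_over65 else rep(TRUE, nrow(addresses))
}

# Scores for the baseline comparators, over ALL addresses (baselines do not
# use the sequential filters).
baseline_scores <- function(prep, registry, config, markov_model = NULL) {
  addresses <- prep$addresses
  ch_pc <- care_home_postcodes(registry)
  out <- list()
  if ("postcode_match" %in% config$baselines) {
    out$postcode_match <- list(
      predicted = postcode_match(prep$filter$postcode, ch_pc))
  }
  if ("markov_score" %in% config$baselines) {
    if (is.null(markov_model)) {
      markov_model <- train_markov(prep$registry_prep$text,
                                   config$markov_smoothing_k)
    }
    text <- addresses$text
    sc <- rep(0, length(text))
    ok <- nzchar(text)
    sc[ok] <- markov_score(markov_model, text[ok])
    out$markov_score <- list(score = sc, model = markov_model)
  }
  if ("phonics_score" %in% config$baselines) {
    reg <- prep$registry_prep
    blocks <- split(seq_along(reg$service_id), reg$postcode)
    sc <- rep(0, nrow(addresses))
    pc <- prep$filter$postcode
    for (i in seq_len(nrow(addresses))) {
      if (is.na(pc[i])) next
      cand <- blocks[[pc[i]]]
      if (is.null(cand)) next
      sc[i] <- max(phonics_score(rep(addresses$text[i], length(cand)),
                                 reg$text[cand]))
    }
    out$phonics_score <- list(score = sc)
  }
  out
}

#' Run the full address-matching pipeline end-to-end
#'
#' Reads (or accepts) the address dataset and the care home registry,
#' splits the addresses into training and validation, applies the
#' sequential filters, cleans and vectorizes the survivors, scores them
#' against postcode-blocked registry candidates under every configured
#' method, fits per-method per-stratum decision thresholds on the training
#' split, predicts the validation split, and evaluates PPV, sensitivity
#' and F1 at address and patient level. Deterministic given the
#' configuration and seed.
#'
#' @param config A [run_config()].
#' @param addresses,registry Optional in-memory tibbles (otherwise read
#'   from the configured paths).
#' @return List of class `pipeline_result`: `report` (evaluation tibble),
#'   `thresholds`, `predictions` (per method, validation split),
#'   `scores`, `split`, `vocabulary`, `log` (stage counts), `config`.
#' @export
run_pipeline <- function(config = run_config(), addresses = NULL,
                         registry = NULL) {
  validate_run_config(config)
  if (is.null(addresses)) {
    if (is.null(config$addresses_path)) {
      stop("config error: no address dataset given (path or tibble)")
    }
    addresses <- read_address_dataset(config$addresses_path, config$schema,
                                      config$delim)
  }
  if (is.null(registry)) {
    if (is.null(config$registry_path)) {
      stop("config error: no registry given (path or tibble)")
    }
    registry <- read_care_home_registry(config$registry_path, config$delim)
  }

  split <- split_train_validation(addresses, config$split_fraction,
                                  config$seed)
  prep_tr <- prepare_matching(split$train, registry, config)
  prep_va <- prepare_matching(split$validation, registry, config,
                              vocabulary = prep_tr$vocabulary)

  log <- list()
  for (part in c("train", "validation")) {
    pp <- if (part == "train") prep_tr else prep_va
    log[[part]] <- c(
      total = nrow(pp$addresses),
      rule1_care_home = sum(pp$filter$status == "care_home_by_name"),
      rule2_not_care_home = sum(pp$filter$status == "not_care_home"),
      scored = sum(pp$filter$status == "undecided")
    )
  }

  sc_tr <- score_methods(prep_tr, config$methods, config)
  sc_va <- score_methods(prep_va, config$methods, config)
  base_tr <- baseline_scores(prep_tr, registry, config)
  base_va <- baseline_scores(prep_va, registry, config,
                             markov_model = base_tr$markov_score$model)

  roster <- method_roster()
  regions <- unique(addresses$region)
  thresholds <- list()
  predictions <- list()
  report_rows <- list()

  for (region in regions) {
    for (stratum in config$strata) {
      in_tr <- split$train$region == region &
        stratum_subset(split$train, stratum)
      in_va <- split$validation$region == region &
        stratum_subset(split$validation, stratum)
      if (sum(in_va) == 0 || sum(in_tr) == 0) next
      gold_tr <- split$train$gold_is_care_home
      skey <- paste(region, stratum, sep = ":")

      eval_preds <- function(name, pred_va) {
        ids <- split$validation$address_id[in_va]
        gold <- stats::setNames(split$validation$gold_is_care_home,
                                split$validation$address_id)[ids]
        w <- stats::setNames(as.numeric(split$validation$person_count),
                             split$validation$address_id)[ids]
        pred <- stats::setNames(pred_va$predicted, pred_va$address_id)[ids]
        for (level in config$levels) {
          cc <- confusion_counts(pred, gold, w, level)
          report_rows[[length(report_rows) + 1]] <<-
            compute_metrics(cc, method = name, stratum = stratum,
                            region = region)
        }
      }

      # similarity methods: threshold fitted on the training addresses of
      # this stratum that reached the scoring stage
      for (m in config$methods) {
        dir <- roster$direction[roster$name == m]
        s_tr <- sc_tr[[m]]
        idx <- match(s_tr$address_id, split$train$address_id)
        use <- in_tr[idx] & s_tr$eligible
        model <- fit_threshold_safe(s_tr$score[use],
                                    gold_tr[idx][use], dir,
                                    method = m, stratum = skey)
        thresholds[[paste(m, skey)]] <- model
        pred_va <- predict_from_scores(prep_va, sc_va[[m]], model)
        predictions[[paste(m, skey)]] <- pred_va
        eval_preds(m, pred_va)
      }

      # baselines: thresholds (where applicable) fitted on all training
      # addresses of the stratum, no filter stage
      for (b in config$baselines) {
        if (b == "postcode_match") {
          pred_va <- tibble::tibble(
            address_id = split$validation$address_id,
            predicted = base_va$postcode_match$predicted,
            provenance = "baseline")
          eval_preds(b, pred_va)
          next
        }
        dir <- "similarity_high_is_match"
        model <- fit_threshold_safe(base_tr[[b]]$score[in_tr],
                                    gold_tr[in_tr], dir,
                                    method = b, stratum = skey)
        thresholds[[paste(b, skey)]] <- model
        pred_va <- tibble::tibble(
          address_id = split$validation$address_id,
          predicted = classify(base_va[[b]]$score, model),
          provenance = "baseline")
        predictions[[paste(b, skey)]] <- pred_va
        eval_preds(b, pred_va)
      }
    }
  }

  result <- structure(list(
    report = do.call(rbind, report_rows),
    thresholds = thresholds,
    predictions = predictions,
    scores = list(train = sc_tr, validation = sc_va),
    split = split,
    vocabulary = prep_tr$vocabulary,
    log = log,
    config = config
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline_outputs(result)
  result
}

write_pipeline_outputs <- function(result) {
  dir <- result$config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_evaluation_report(result$report, file.path(dir, "evaluation.csv"))
  write_threshold_models(result$thresholds, file.path(dir, "thresholds.tsv"))
  pred <- do.call(rbind, lapply(names(result$predictions), function(k) {
    cbind(model = k, as.data.frame(result$predictions[[k]]))
  }))
  utils::write.csv(pred, file.path(dir, "predictions.csv"), row.names = FALSE)
  log_lines <- unlist(lapply(names(result$log), function(part) {
    paste0(part, ".", names(result$log[[part]]), "=", result$log[[part]])
  }))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  validation addresses:", x$log$validation[["total"]], "\n")
  cat("  models evaluated:", length(unique(x$report$method)), "\n")
  best <- x$report[x$report$level == "patient" & x$report$stratum == "all_ages", ]
  if (nrow(best) > 0) {
    b <- best[which.max(best$f1), ]
    cat(sprintf("  best patient-level F1 (all ages): %s %.1f%%\n",
                b$method, b$f1))
  }
  invisible(x)
}
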