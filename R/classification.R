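#' Fit a decision threshold maximizing training F1
#'
#' Candidate cut-points are the midpoints between consecutive distinct
#' finite scores plus sentinels below and above every score, so the fitted
#' threshold never sits exactly on a training score. The candidate with the
#' highest F1 wins; ties break toward the higher PPV, then toward the more
#' conservative threshold (higher for similarity methods, lower for
#' distance methods).
#'
#' Classification is inclusive: similarity methods match when
#' `score >= threshold`, distance methods when `score <= threshold`.
#'
#' @param scores Numeric scores, one per training address.
#' @param labels Logical gold labels (needs at least one `TRUE` and one
#'   `FALSE`).
#' @param direction `"similarity_high_is_match"` or
#'   `"distance_low_is_match"`.
#' @param method Optional method name stored on the model.
#' @param stratum Optional stratum label stored on the model.
#' @return Object of class `threshold_model` with `method`, `stratum`,
#'   `threshold`, `direction`, `training_f1`.
#' @export
fit_threshold <- function(scores, labels,
                          direction = c("similarity_high_is_match",
                                        "distance_low_is_match"),
                          method = NA_character_, stratum = NA_character_) {
  direction <- match.arg(direction)
  stopifnot(length(scores) == length(labels), length(scores) >= 1)
  labels <- as.logical(labels)
  if (all(labels) || !any(labels)) {
    stop("threshold fitting needs both a positive and a negative label")
  }
  sim <- direction == "similarity_high_is_match"
  # distinct score values, ascending; per-value positive/negative tallies
  v <- sort(unique(scores))
  m <- length(v)
  grp <- match(scores, v)
  pos_at <- tabulate(grp[labels], nbins = m)
  neg_at <- tabulate(grp[!labels], nbins = m)
  n_pos <- sum(labels)
  # midpoint between consecutive values, stepping off infinite neighbours
  mid <- function(a, b) {
    if (is.finite(a) && is.finite(b)) (a + b) / 2
    else if (is.finite(a)) a + 1
    else if (is.finite(b)) b - 1
    else 0
  }
  if (sim) {
    # candidate i predicts values v[i..m] positive; i = m+1 predicts none
    tp <- rev(c(0, cumsum(rev(pos_at))))
    fp <- rev(c(0, cumsum(rev(neg_at))))
    thr <- c(mid(-Inf, v[1]),
             if (m > 1) vapply(seq_len(m - 1),
                               function(i) mid(v[i], v[i + 1]), numeric(1)),
             mid(v[m], Inf))
  } else {
    # candidate i predicts values v[1..i] positive; first candidate none
    tp <- c(0, cumsum(pos_at))
    fp <- c(0, cumsum(neg_at))
    thr <- c(mid(-Inf, v[1]),
             if (m > 1) vapply(seq_len(m - 1),
                               function(i) mid(v[i], v[i + 1]), numeric(1)),
             mid(v[m], Inf))
  }
  ppv <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  sens <- tp / n_pos
  f1 <- ifelse(ppv + sens > 0, 2 * ppv * sens / (ppv + sens), 0)
  # max F1, then max PPV, then the more conservative threshold
  keep <- which(f1 >= max(f1) - 1e-12)
  keep <- keep[ppv[keep] >= max(ppv[keep]) - 1e-12]
  best <- if (sim) keep[which.max(thr[keep])] else keep[which.min(thr[keep])]
  structure(list(method = method, stratum = stratum, threshold = thr[best],
                 direction = direction, training_f1 = f1[best]),
            class = "threshold_model")
}

# Like fit_threshold, but tolerates single-class training labels, falling
# back to the tightest threshold that classifies the one class correctly.
fit_threshold_safe <- function(scores, labels, direction,
                               method = NA_character_,
                               stratum = NA_character_) {
  labels <- as.logical(labels)
  sim <- direction == "similarity_high_is_match"
  if (any(labels) && !all(labels)) {
    return(fit_threshold(scores, labels, direction, method, stratum))
  }
  fin <- scores[is.finite(scores)]
  t <- if (all(labels)) {
    # cover every positive
    if (length(fin) == 0) {
      if (sim) -Inf else Inf
    } else if (sim) min(fin) else max(fin)
  } else {
    # exclude every negative
    if (sim) Inf else -Inf
  }
  structure(list(method = method, stratum = stratum, threshold = t,
                 direction = direction,
                 training_f1 = if (all(labels)) 1 else NA_real_),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model> %s [%s]: %s %.6g (training F1 %.3f)\n",
              x$method, x$stratum,
              if (x$direction == "similarity_high_is_match") "score >=" else
                "score <=",
              x$threshold, x$training_f1))
  invisible(x)
}

#' Classify scores with a fitted threshold
#'
#' Inclusive boundary per direction; ineligible scores (no candidate passed
#' the gate) are never classified as matches, whatever the threshold.
#'
#' @param scores Numeric score vector, or a single `method_score`.
#' @param model A `threshold_model` for the same method.
#' @param eligible Logical vector (default all `TRUE`).
#' @param method Method name of the scores, checked against the model when
#'   both are known.
#' @return Logical vector of match decisions.
#' @export
classify <- function(scores, model, eligible = TRUE, method = NULL) {
  stopifnot(inherits(model, "threshold_model"))
  if (inherits(scores, "method_score")) {
    method <- scores$method
    eligible <- scores$eligible
    scores <- scores$score
  }
  if (!is.null(method) && !is.na(model$method) && !identical(method, model$method)) {
    stop("score method ", method, " does not match model method ", model$method)
  }
  pred <- if (model$direction == "similarity_high_is_match") {
    scores >= model$threshold
  } else {
    scores <= model$threshold
  }
  pred & rep_len(eligible, length(pred))
}

#' Serialize fitted thresholds to a plain-text table
#' @param models List of `threshold_model`s.
#' @param path Output path (tab-separated key-value table).
#' @export
write_threshold_models <- function(models, path) {
  df <- do.call(rbind, lapply(models, function(m) {
    data.frame(method = m$method, stratum = m$stratum,
               threshold = m$threshold, direction = m$direction,
               training_f1 = m$training_f1, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back thresholds written by [write_threshold_models()]
#' @param path Path to the table.
#' @return List of `threshold_model`s.
#' @export
read_threshold_models <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    structure(list(method = df$method[i], stratum = df$stratum[i],
                   threshold = df$threshold[i], direction = df$direction[i],
                   training_f1 = df$training_f1[i]),
              class = "threshold_model")
  })
}

#' Predict care home status for every address in a dataset
#'
#' The sequential filters decide first (name-phrase rule fires positive,
#' exclusion rule fires negative); only the surviving undecided addresses
#' are scored against their postcode-blocked registry candidates and
#' thresholded. Provenance records which stage decided each address.
#'
#' @param addresses Address tibble.
#' @param registry Registry tibble.
#' @param method Method name (any of [method_roster()]).
#' @param model Fitted `threshold_model` for that method.
#' @param config Pipeline configuration from [run_config()] (controls the
#'   n-gram settings, number gate and lexicons).
#' @return Tibble with `address_id`, `predicted`, `provenance`
#'   (`filter_rule1`, `filter_rule2`, `threshold`).
#' @export
predict_dataset <- function(addresses, registry, method, model,
                            config = run_config()) {
  prep <- prepare_matching(addresses, registry, config)
  scores <- score_methods(prep, method, config)[[method]]
  predict_from_scores(prep, scores, model)
}

predict_from_scores <- function(prep, scores, model) {
  filt <- prep$filter
  predicted <- rep(FALSE, nrow(filt))
  provenance <- rep("filter_rule2", nrow(filt))
  r1 <- filt$status == "care_home_by_name"
  predicted[r1] <- TRUE
  provenance[r1] <- "filter_rule1"
  und <- which(filt$status == "undecided")
  provenance[und] <- "threshold"
  if (length(und) > 0) {
    predicted[und] <- classify(scores$score[match(filt$address_id[und],
                                                  scores$address_id)],
                               model,
                               eligible = scores$eligible[
                                 match(filt$address_id[und],
                                       scores$address_id)])
  }
  tibble::tibble(address_id = filt$address_id, predicted = predicted,
                 provenance = provenance)
}
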