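#' Confusion counts at address or patient level
#'
#' At address level every address contributes one unit to its confusion
#' cell. At patient level each address contributes its resident count on
#' the snapshot date, so historical address forms (0 residents) contribute
#' nothing.
#'
#' @param predictions Named logical vector (names are address ids), or a
#'   tibble with `address_id` and `predicted`.
#' @param gold Named logical vector of gold labels over the same ids.
#' @param weights Named numeric vector of resident counts (patient level).
#' @param level `"address"` or `"patient"`.
#' @return List of class `confusion_counts`: `tp`, `fp`, `fn`, `tn`,
#'   `level`.
#' @export
confusion_counts <- function(predictions, gold, weights = NULL,
                             level = c("address", "patient")) {
  level <- match.arg(level)
  if (is.data.frame(predictions)) {
    predictions <- stats::setNames(predictions$predicted,
                                   predictions$address_id)
  }
  if (!setequal(names(predictions), names(gold))) {
    stop("predictions and gold labels cover different address ids")
  }
  gold <- gold[names(predictions)]
  w <- if (level == "address") {
    rep(1, length(predictions))
  } else {
    if (is.null(weights)) stop("patient-level counts need resident weights")
    if (!all(names(predictions) %in% names(weights))) {
      stop("weights missing for some address ids")
    }
    as.numeric(weights[names(predictions)])
  }
  structure(list(
    tp = sum(w[predictions & gold]),
    fp = sum(w[predictions & !gold]),
    fn = sum(w[!predictions & gold]),
    tn = sum(w[!predictions & !gold]),
    level = level
  ), class = "confusion_counts")
}

#' F1 as the harmonic mean of PPV and sensitivity
#'
#' Accepts either proportions or percentages (both inputs on the same
#' scale); returns the harmonic mean on that scale.
#'
#' @param ppv,sensitivity Numeric vectors.
#' @return `2 * ppv * sensitivity / (ppv + sensitivity)` (0 where both are
#'   0).
#' @export
harmonic_f1 <- function(ppv, sensitivity) {
  ifelse(ppv + sensitivity > 0, 2 * ppv * sensitivity / (ppv + sensitivity), 0)
}

#' PPV, sensitivity and F1 from confusion counts
#'
#' Percentages at full precision; display rounding is left to the caller.
#' When a metric's denominator is zero (no predicted positives, or no true
#' positives in the gold standard) the metric is returned as `NA` with a
#' `defined` flag, never as a silent zero.
#'
#' @param counts A `confusion_counts`.
#' @param method,stratum,region Optional labels copied into the report.
#' @return Tibble row: `method`, `region`, `stratum`, `level`, `ppv`,
#'   `sensitivity`, `f1` (percentages), `tp`, `fp`, `fn`, `tn`, `defined`.
#' @export
compute_metrics <- function(counts, method = NA_character_,
                            stratum = NA_character_,
                            region = NA_character_) {
  stopifnot(inherits(counts, "confusion_counts"))
  ppv <- if (counts$tp + counts$fp > 0) {
    100 * counts$tp / (counts$tp + counts$fp)
  } else NA_real_
  sens <- if (counts$tp + counts$fn > 0) {
    100 * counts$tp / (counts$tp + counts$fn)
  } else NA_real_
  f1 <- if (!is.na(ppv) && !is.na(sens)) harmonic_f1(ppv, sens) else NA_real_
  tibble::tibble(method = method, region = region, stratum = stratum,
                 level = counts$level, ppv = ppv, sensitivity = sens,
                 f1 = f1, tp = counts$tp, fp = counts$fp, fn = counts$fn,
                 tn = counts$tn, defined = !is.na(ppv) && !is.na(sens))
}

#' Evaluate predictions for every method, stratum and level
#'
#' Produces one report row per (method x stratum x level), the layout the
#' published comparison tables use. The over-65 stratum restricts to
#' addresses where at least one resident is aged 65+.
#'
#' @param predictions_by_method Named list: method name -> prediction
#'   tibble (`address_id`, `predicted`).
#' @param addresses Address tibble carrying `gold_is_care_home`,
#'   `person_count`, `has_over65`, `region`.
#' @param strata Character subset of `c("all_ages", "over65")`.
#' @param levels Character subset of `c("address", "patient")`.
#' @return Tibble of report rows (see [compute_metrics()]).
#' @export
evaluate_all <- function(predictions_by_method, addresses,
                         strata = c("all_ages", "over65"),
                         levels = c("address", "patient")) {
  gold <- stats::setNames(addresses$gold_is_care_home, addresses$address_id)
  weights <- stats::setNames(as.numeric(addresses$person_count),
                             addresses$address_id)
  out <- list()
  for (method in names(predictions_by_method)) {
    pred_tbl <- predictions_by_method[[method]]
    pred <- stats::setNames(pred_tbl$predicted, pred_tbl$address_id)
    for (region in unique(addresses$region)) {
      for (stratum in strata) {
        keep <- addresses$region == region
        if (stratum == "over65") keep <- keep & addresses$has_over65
        ids <- addresses$address_id[keep]
        if (length(ids) == 0) next
        for (level in levels) {
          cc <- confusion_counts(pred[ids], gold[ids], weights[ids], level)
          out[[length(out) + 1]] <-
            compute_metrics(cc, method = method, stratum = stratum,
                            region = region)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Write an evaluation report as CSV
#' @param report Tibble from [evaluate_all()].
#' @param path Output path.
#' @export
write_evaluation_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
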