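# Diagnostic performance: confusion counts, sensitivity / specificity /
# accuracy with the reporting convention used for the printed tables
# (integer percentages, round half up), and percentile bootstrap CIs.

#' Round half up to integer percent
#'
#' The reporting convention for printed percentages: 82.5 -> 83,
#' 37.5 -> 38 (banker's rounding would give 82 and 38).
#' @param x numeric.
#' @return numeric of integers.
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Confusion counts of a predictor against HC/LG labels
#'
#' Eyes labelled `NEITHER` are ignored; every HC or LG eye must have a
#' prediction.
#'
#' @param predictions named logical vector, eye id -> predicted abnormal.
#' @param labels named character vector, eye id -> `"HC"`, `"LG"` or
#'   `"NEITHER"` (as from [label_cohort()]).
#' @return a list of class `confusion` with integer `tp`, `fn`, `fp`,
#'   `tn`.
#' @export
confusion <- function(predictions, labels) {
  eval_ids <- names(labels)[labels %in% c("HC", "LG")]
  missing <- setdiff(eval_ids, names(predictions))
  if (length(missing)) {
    stop("missing prediction for labelled eye(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pred <- predictions[eval_ids]
  lab <- labels[eval_ids]
  structure(list(
    tp = sum(lab == "LG" & pred),
    fn = sum(lab == "LG" & !pred),
    fp = sum(lab == "HC" & pred),
    tn = sum(lab == "HC" & !pred)
  ), class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("<confusion> TP=%d FN=%d FP=%d TN=%d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Percentages on a 0-100 scale; a statistic with a zero denominator is
#' `NA` rather than an error. `reported` carries the integer
#' (round-half-up) forms used in printed tables.
#'
#' @param c a `confusion` object (or list with tp/fn/fp/tn).
#' @return a list of class `performance_stats` with `sensitivity`,
#'   `specificity`, `accuracy`, their `reported` integer forms, and the
#'   counts.
#' @export
performance <- function(c) {
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  sens <- pct(c$tp, c$tp + c$fn)
  spec <- pct(c$tn, c$tn + c$fp)
  acc <- pct(c$tp + c$tn, c$tp + c$fn + c$fp + c$tn)
  structure(list(
    sensitivity = sens, specificity = spec, accuracy = acc,
    reported = c(sensitivity = round_half_up(sens),
                 specificity = round_half_up(spec),
                 accuracy = round_half_up(acc)),
    counts = c(tp = c$tp, fn = c$fn, fp = c$fp, tn = c$tn),
    ci = NULL
  ), class = "performance_stats")
}

#' @export
print.performance_stats <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", v)
  cat(sprintf("<performance> sens %s, spec %s, acc %s (TP=%d FN=%d FP=%d TN=%d)\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$accuracy),
              x$counts["tp"], x$counts["fn"], x$counts["fp"], x$counts["tn"]))
  if (!is.null(x$ci)) {
    for (s in names(x$ci)) {
      cat(sprintf("  %s 95%% CI [%.1f, %.1f]\n", s, x$ci[[s]][1],
                  x$ci[[s]][2]))
    }
  }
  invisible(x)
}

#' Per-eye predictions of a criterion over a set of records
#'
#' @param node a `criterion`.
#' @param records list of `eye_visit` records (typically one visit).
#' @param threshold,ght_other_abnormal see [eval_criterion()].
#' @return named logical vector, eye id -> prediction.
#' @export
predict_criterion <- function(node, records, threshold = "borderline",
                              ght_other_abnormal = FALSE) {
  out <- vapply(records, eval_criterion, logical(1), node = node,
                threshold = threshold,
                ght_other_abnormal = ght_other_abnormal)
  names(out) <- vapply(records, `[[`, character(1), "eye_id")
  out
}

#' Percentile bootstrap confidence intervals for performance statistics
#'
#' Eyes are resampled with replacement and the statistics recomputed per
#' replicate; the 2.5 and 97.5 percentiles of each statistic form the 95%
#' interval. Resampling is stratified by class by default, preserving the
#' HC/LG split; with `stratified = FALSE` the pooled set is resampled and
#' replicates in which a class comes up empty are dropped from that
#' statistic's percentile pool.
#'
#' @param predictions named logical vector (see [predict_criterion()]);
#'   eye-visits pooled across baselines may be supplied as independent
#'   units.
#' @param labels named character vector of HC/LG/NEITHER labels (for
#'   pooled eye-visits, named by the same keys as `predictions`).
#' @param n_iter bootstrap iterations (default 1000).
#' @param seed integer seed; results are deterministic given the seed.
#' @param level confidence level (default 0.95).
#' @param stratified resample within class (default `TRUE`).
#' @return a `performance_stats` whose `ci` element holds `(lo, hi)` per
#'   statistic.
#' @export
bootstrap_ci <- function(predictions, labels, n_iter = 1000L, seed = 1L,
                         level = 0.95, stratified = TRUE) {
  eval_ids <- names(labels)[labels %in% c("HC", "LG")]
  point <- performance(confusion(predictions, labels))
  pred <- predictions[eval_ids]
  lab <- labels[eval_ids]
  hc <- which(lab == "HC")
  lg <- which(lab == "LG")
  if (!length(hc) || !length(lg)) {
    stop("bootstrap_ci needs at least one eye in each class", call. = FALSE)
  }
  reps <- matrix(NA_real_, nrow = n_iter, ncol = 3,
                 dimnames = list(NULL, c("sensitivity", "specificity",
                                         "accuracy")))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (b in seq_len(n_iter)) {
    idx <- if (stratified) {
      c(sample(hc, length(hc), replace = TRUE),
        sample(lg, length(lg), replace = TRUE))
    } else {
      sample(seq_along(pred), length(pred), replace = TRUE)
    }
    p <- pred[idx]
    l <- lab[idx]
    tp <- sum(l == "LG" & p); fn <- sum(l == "LG" & !p)
    fp <- sum(l == "HC" & p); tn <- sum(l == "HC" & !p)
    reps[b, "sensitivity"] <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA
    reps[b, "specificity"] <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA
    reps[b, "accuracy"] <- 100 * (tp + tn) / length(idx)
  }
  alpha <- (1 - level) / 2
  point$ci <- lapply(colnames(reps), function(s) {
    v <- reps[, s]
    v <- v[!is.na(v)]
    unname(stats::quantile(v, c(alpha, 1 - alpha), type = 7))
  })
  names(point$ci) <- colnames(reps)
  point$n_iter <- n_iter
  point
}

#' Evaluate a set of criteria over labelled records
#'
#' @param records list of `eye_visit` records for one visit.
#' @param labels HC/LG/NEITHER labels (see [label_cohort()]).
#' @param catalog a [criteria_catalog()] or a subset of its rows.
#' @param threshold,ght_other_abnormal see [eval_criterion()].
#' @return data frame with one row per criterion: name, category, tp, fn,
#'   fp, tn, sensitivity, specificity, accuracy (exact percentages) and
#'   their reported integer forms.
#' @export
evaluate_criteria <- function(records, labels, catalog = criteria_catalog(),
                              threshold = "borderline",
                              ght_other_abnormal = FALSE) {
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    pred <- predict_criterion(catalog$criterion[[i]], records, threshold,
                              ght_other_abnormal)
    st <- performance(confusion(pred, labels))
    data.frame(name = catalog$name[i], category = catalog$category[i],
               tp = st$counts["tp"], fn = st$counts["fn"],
               fp = st$counts["fp"], tn = st$counts["tn"],
               sensitivity = st$sensitivity, specificity = st$specificity,
               accuracy = st$accuracy,
               sens_pct = st$reported["sensitivity"],
               spec_pct = st$reported["specificity"],
               acc_pct = st$reported["accuracy"],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Two-baseline repeatability of performance statistics
#'
#' @param records_v1,records_v2 records for baseline visits 1 and 2; the
#'   same eyes must be present in both.
#' @param labels HC/LG/NEITHER labels.
#' @param catalog criteria to evaluate.
#' @param threshold see [eval_criterion()].
#' @return data frame per criterion with visit-1 and visit-2 sensitivity,
#'   specificity, accuracy and their absolute differences.
#' @export
baseline_repeatability <- function(records_v1, records_v2, labels,
                                   catalog = criteria_catalog(),
                                   threshold = "borderline") {
  ids1 <- sort(vapply(records_v1, `[[`, character(1), "eye_id"))
  ids2 <- sort(vapply(records_v2, `[[`, character(1), "eye_id"))
  if (!identical(ids1, ids2)) {
    stop("baseline_repeatability: eye sets differ between visits",
         call. = FALSE)
  }
  t1 <- evaluate_criteria(records_v1, labels, catalog, threshold)
  t2 <- evaluate_criteria(records_v2, labels, catalog, threshold)
  data.frame(name = t1$name, category = t1$category,
             sens_v1 = t1$sensitivity, sens_v2 = t2$sensitivity,
             sens_diff = abs(t1$sensitivity - t2$sensitivity),
             spec_v1 = t1$specificity, spec_v2 = t2$specificity,
             spec_diff = abs(t1$specificity - t2$specificity),
             acc_v1 = t1$accuracy, acc_v2 = t2$accuracy,
             acc_diff = abs(t1$accuracy - t2$accuracy),
             stringsAsFactors = FALSE)
}
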