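#' Confusion counts for binary calls
#'
#' @param calls Integer 0/1 predictions.
#' @param truth Integer 0/1 labels.
#' @return A named integer vector with elements `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(calls, truth) {
  if (length(calls) != length(truth)) {
    abort("calls and truth must have equal length", class = "vitabind_input_error")
  }
  stopifnot(all(calls %in% c(0, 1)), all(truth %in% c(0, 1)))
  c(tp = sum(calls == 1 & truth == 1),
    fp = sum(calls == 1 & truth == 0),
    tn = sum(calls == 0 & truth == 0),
    fn = sum(calls == 0 & truth == 1))
}

#' Threshold-dependent evaluation indexes
#'
#' Sensitivity Sn = TP/(TP+FN), specificity Sp = TN/(TN+FP) and accuracy
#' Acc = (TP+TN)/(TP+TN+FP+FN), each as a percentage in \[0,100\]. A zero
#' denominator yields `NA` (undefined) rather than an error.
#'
#' @param counts Named counts from [confusion()] (or any vector with `tp`,
#'   `fp`, `tn`, `fn`).
#' @return Percentage, or `NA_real_` when undefined.
#' @export
sensitivity <- function(counts) {
  den <- counts[["tp"]] + counts[["fn"]]
  if (den == 0) NA_real_ else 100 * counts[["tp"]] / den
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
  den <- counts[["tn"]] + counts[["fp"]]
  if (den == 0) NA_real_ else 100 * counts[["tn"]] / den
}

#' @rdname sensitivity
#' @export
accuracy <- function(counts) {
  den <- sum(counts[c("tp", "fp", "tn", "fn")])
  if (den == 0) NA_real_ else 100 * (counts[["tp"]] + counts[["tn"]]) / den
}

#' Matthews correlation coefficient
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), computed with
#' the factors under separate square roots to avoid integer overflow on
#' large confusion tables. Any zero factor in the denominator yields 0 by
#' convention.
#'
#' @param counts Named counts from [confusion()].
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts[["tp"]]); fp <- as.numeric(counts[["fp"]])
  tn <- as.numeric(counts[["tn"]]); fn <- as.numeric(counts[["fn"]])
  f1 <- tp + fp; f2 <- tp + fn; f3 <- tn + fp; f4 <- tn + fn
  if (f1 == 0 || f2 == 0 || f3 == 0 || f4 == 0) return(0)
  (tp * tn - fp * fn) / (sqrt(f1) * sqrt(f2) * sqrt(f3) * sqrt(f4))
}

#' Area under the ROC curve by the rank statistic
#'
#' Computes AUC as the normalised Mann-Whitney statistic (equivalent to the
#' trapezoidal ROC integral), with tied scores contributing 1/2.
#'
#' @param scores Numeric scores, higher = more binding-like.
#' @param truth Integer 0/1 labels.
#' @return AUC in \[0,1\], or `NA_real_` when only one class is present.
#' @export
roc_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' @param scores Numeric scores.
#' @param truth 0/1 labels.
#' @return A tibble of (`threshold`, `fpr`, `tpr`) over all scanned
#'   thresholds, suitable for plotting or TSV export.
#' @export
roc_points <- function(scores, truth) {
  purrr::map_dfr(threshold_candidates(scores), function(t) {
    ct <- confusion(classify(scores, t), truth)
    tibble::tibble(threshold = t,
                   fpr = ct[["fp"]] / max(ct[["fp"]] + ct[["tn"]], 1),
                   tpr = ct[["tp"]] / max(ct[["tp"]] + ct[["fn"]], 1))
  })
}

#' Candidate decision thresholds for a score vector
#'
#' Midpoints between adjacent distinct scores plus the boundary values 0 and
#' 1 — a finite set complete with respect to the achievable confusion tables
#' under the strict-greater calling rule.
#'
#' @param scores Numeric scores in \[0,1\].
#' @return Sorted numeric vector of thresholds.
#' @export
threshold_candidates <- function(scores) {
  s <- sort(unique(scores))
  mids <- if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else numeric(0)
  sort(unique(c(0, mids, 1)))
}

new_report <- function(counts, auc, threshold, strategy, cv_level = "none") {
  structure(list(counts = counts,
                 sn = sensitivity(counts), sp = specificity(counts),
                 acc = accuracy(counts), mcc = mcc(counts), auc = auc,
                 threshold = threshold, strategy = strategy,
                 cv_level = cv_level),
            class = "vita_report")
}

#' Evaluate scores against labels at a threshold
#'
#' @param scores Numeric scores in \[0,1\].
#' @param truth 0/1 labels.
#' @param threshold Decision threshold.
#' @param strategy Tag recorded in the report.
#' @param cv_level Tag recorded in the report (`"residue"`, `"sequence"` or
#'   `"none"`).
#' @return A `vita_report`.
#' @export
evaluate_predictions <- function(scores, truth, threshold, strategy = "fixed",
                                 cv_level = "none") {
  counts <- confusion(classify(scores, threshold), truth)
  new_report(counts, roc_auc(scores, truth), threshold, strategy, cv_level)
}

scan_thresholds <- function(scores, truth, objective) {
  if (length(unique(truth)) < 2) {
    abort("threshold selection requires both classes", class = "vitabind_label_error")
  }
  cands <- threshold_candidates(scores)
  vals <- vapply(cands, function(t) objective(confusion(classify(scores, t), truth)),
                 numeric(1))
  best <- which.max(vals)   # first maximum = smallest threshold on ties
  cands[best]
}

#' Threshold equalising sensitivity and specificity
#'
#' Scans the candidate thresholds and returns the one minimising |Sn - Sp|
#' (ties resolved towards the smaller threshold), together with the
#' evaluation report at that threshold.
#'
#' @inheritParams evaluate_predictions
#' @param cv_level Tag recorded in the report.
#' @return A list with `threshold` and `report` (a `vita_report` with
#'   strategy `"balanced"`).
#' @export
balanced_threshold <- function(scores, truth, cv_level = "none") {
  t_opt <- scan_thresholds(scores, truth, function(ct) {
    sn <- sensitivity(ct); sp <- specificity(ct)
    if (is.na(sn) || is.na(sp)) -Inf else -abs(sn - sp)
  })
  list(threshold = t_opt,
       report = evaluate_predictions(scores, truth, t_opt, "balanced", cv_level))
}

#' Threshold maximising the Matthews correlation coefficient
#'
#' @inheritParams balanced_threshold
#' @return A list with `threshold` and `report` (strategy `"maxmcc"`).
#' @export
maxmcc_threshold <- function(scores, truth, cv_level = "none") {
  t_opt <- scan_thresholds(scores, truth, mcc)
  list(threshold = t_opt,
       report = evaluate_predictions(scores, truth, t_opt, "maxmcc", cv_level))
}

#' Round half away from zero
#'
#' Decimal rounding matching how the benchmark tables print their metrics
#' (0.275 -> 0.28), unlike R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.vita_report <- function(x, ...) {
  cat(sprintf("<vita_report (%s threshold %.4f, cv %s)>\n", x$strategy,
              x$threshold, x$cv_level))
  cat(sprintf("  TP %d  TN %d  FP %d  FN %d\n", x$counts[["tp"]],
              x$counts[["tn"]], x$counts[["fp"]], x$counts[["fn"]]))
  cat(sprintf("  Sn %.2f%%  Sp %.2f%%  Acc %.2f%%  MCC %.2f  AUC %s\n",
              x$sn, x$sp, x$acc, x$mcc,
              if (is.na(x$auc)) "NA" else sprintf("%.2f", x$auc)))
  invisible(x)
}

#' @export
tidy.vita_report <- function(x, ...) {
  tibble::tibble(metric = c("sn", "sp", "acc", "mcc", "auc"),
                 value = c(x$sn, x$sp, x$acc, x$mcc, x$auc))
}

#' @export
glance.vita_report <- function(x, ...) {
  tibble::tibble(tp = x$counts[["tp"]], tn = x$counts[["tn"]],
                 fp = x$counts[["fp"]], fn = x$counts[["fn"]],
                 sn = x$sn, sp = x$sp, acc = x$acc, mcc = x$mcc, auc = x$auc,
                 threshold = x$threshold, strategy = x$strategy,
                 cv_level = x$cv_level)
}

#' Convert a report to a JSON string
#'
#' @param report A `vita_report`.
#' @return A JSON string with counts, metrics, threshold and tags.
#' @export
report_json <- function(report) {
  jsonlite::toJSON(as.list(glance(report)), auto_unbox = TRUE, digits = NA, na = "null")
}

#' Published benchmark evaluation rows
#'
#' Reported confusion counts and printed metrics for vitamin-binding residue
#' predictors on the DVI, DVAI, DVBI and DPLPI benchmarks (cross-validation
#' and independent-validation settings, balanced and MCC-maximising
#' thresholds), shipped as a plain-text fixture. The `sn_consistent` /
#' `mcc_consistent` flags mark the few published cells whose printed metric
#' disagrees with the metric recomputed from that row's own printed counts
#' (typographic errors in the source tables).
#'
#' @return A tibble with one row per published predictor/dataset entry.
#' @export
benchmark_metrics <- function() {
  path <- system.file("extdata", "benchmark_metrics.csv", package = "vitabind")
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
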