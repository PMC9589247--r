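#' Confusion counts at a decision threshold
#'
#' Class 1 (DNA-binding) is the positive class: TP = binding predicted
#' binding, FN = binding predicted non-binding, FP = non-binding predicted
#' binding, TN = non-binding predicted non-binding.
#'
#' @param y_true Binary labels (0/1).
#' @param y_score Class-1 probabilities (or hard 0/1 predictions).
#' @param threshold Scores `>= threshold` are called positive.
#' @return An object of class `confusion_counts` (named list TP/FP/TN/FN).
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion <- function(y_true, y_score, threshold = 0.5) {
  if (length(y_true) != length(y_score)) {
    abort("y_true and y_score must have the same length",
          class = "dbpkit_value_error")
  }
  if (!all(y_true %in% c(0, 1))) {
    abort("y_true must be 0/1", class = "dbpkit_value_error")
  }
  pred <- as.integer(y_score >= threshold)
  structure(list(
    TP = sum(y_true == 1 & pred == 1),
    FP = sum(y_true == 0 & pred == 1),
    TN = sum(y_true == 0 & pred == 0),
    FN = sum(y_true == 1 & pred == 0)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d TN=%d FN=%d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Threshold metrics from confusion counts
#'
#' Computes sensitivity SN = TP/(TP+FN), specificity SP = TN/(TN+FP),
#' accuracy ACC = (TP+TN)/total and the Matthews correlation coefficient
#' MCC = (TN*TP - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN)). When any MCC
#' marginal is zero the coefficient is reported as 0 and flagged
#' (`mcc_undefined`), the common convention for degenerate tables.
#'
#' @param counts A `confusion_counts` object.
#' @return A one-row tibble with `acc`, `sn`, `sp`, `mcc`, the four counts and
#'   the `mcc_undefined` flag.
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  if (total == 0) {
    abort("no samples to evaluate", class = "dbpkit_value_error")
  }
  sn <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  sp <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  acc <- (TP + TN) / total
  denom <- as.numeric(TP + FN) * (TP + FP) * (TN + FP) * (TN + FN)
  mcc_undefined <- denom == 0
  mcc <- if (mcc_undefined) 0 else (as.numeric(TN) * TP - as.numeric(FP) * FN) / sqrt(denom)
  tibble(acc = acc, sn = sn, sp = sp, mcc = mcc,
         TP = TP, FP = FP, TN = TN, FN = FN, mcc_undefined = mcc_undefined)
}

#' ROC and precision-recall curves
#'
#' `roc_points()` sweeps every distinct score as a threshold (ties grouped),
#' returning the (FPR, TPR) staircase from (0,0) to (1,1); `auc()` integrates
#' it by the trapezoidal rule, which equals the Mann-Whitney concordance
#' probability with ties counted 1/2. `pr_points()` / `auprc()` do the same
#' for precision against recall.
#'
#' @param y_true Binary labels (0/1) with both classes present.
#' @param y_score Class-1 scores.
#' @return `roc_points`: tibble (`threshold`, `fpr`, `tpr`); `pr_points`:
#'   tibble (`threshold`, `recall`, `precision`); `auc` / `auprc`: a single
#'   number in `[0, 1]`.
#' @export
roc_points <- function(y_true, y_score) {
  check_scores(y_true, y_score)
  ord <- order(-y_score)
  ys <- y_true[ord]; sc <- y_score[ord]
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)   # last index of each tie group
  tp <- cumsum(ys == 1)[keep]
  fp <- cumsum(ys == 0)[keep]
  P <- sum(y_true == 1); N <- sum(y_true == 0)
  tibble(threshold = c(Inf, sc[keep]),
         fpr = c(0, fp / N),
         tpr = c(0, tp / P))
}

#' @rdname roc_points
#' @export
auc <- function(y_true, y_score) {
  pts <- roc_points(y_true, y_score)
  trapezoid(pts$fpr, pts$tpr)
}

#' @rdname roc_points
#' @export
pr_points <- function(y_true, y_score) {
  check_scores(y_true, y_score)
  ord <- order(-y_score)
  ys <- y_true[ord]; sc <- y_score[ord]
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- cumsum(ys == 1)[keep]
  fp <- cumsum(ys == 0)[keep]
  P <- sum(y_true == 1)
  recall <- tp / P
  precision <- tp / (tp + fp)
  tibble(threshold = sc[keep], recall = recall, precision = precision)
}

#' @rdname roc_points
#' @export
auprc <- function(y_true, y_score) {
  pts <- pr_points(y_true, y_score)
  # anchor at recall 0 with the first observed precision
  r <- c(0, pts$recall)
  p <- c(pts$precision[1], pts$precision)
  trapezoid(r, p)
}

trapezoid <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

check_scores <- function(y_true, y_score) {
  if (length(y_true) != length(y_score)) {
    abort("y_true and y_score must have the same length",
          class = "dbpkit_value_error")
  }
  if (!all(y_true %in% c(0, 1))) {
    abort("y_true must be 0/1", class = "dbpkit_value_error")
  }
  if (length(unique(y_true)) < 2) {
    abort("curve metrics are undefined when only one class is present",
          class = "dbpkit_single_class_error")
  }
  invisible(TRUE)
}

#' Full evaluation report for a score vector
#'
#' Combines threshold metrics at `threshold` with the two curve areas.
#'
#' @inheritParams roc_points
#' @param threshold Decision threshold for the confusion-based metrics.
#' @return An object of class `metrics_report`: a one-row tibble with `acc`,
#'   `sn`, `sp`, `mcc`, `auc`, `auprc`, the confusion counts and flags.
#' @export
evaluate_scores <- function(y_true, y_score, threshold = 0.5) {
  rep <- metrics(confusion(y_true, y_score, threshold))
  rep$auc <- auc(y_true, y_score)
  rep$auprc <- auprc(y_true, y_score)
  rep$threshold <- threshold
  class(rep) <- c("metrics_report", class(rep))
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  ACC %.3f  SN %.3f  SP %.3f  MCC %.3f  AUC %.3f  AUPRC %.3f\n",
              x$acc, x$sn, x$sp, x$mcc, x$auc, x$auprc))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d  (threshold %.2f)\n",
              x$TP, x$FP, x$TN, x$FN, x$threshold))
  invisible(x)
}

#' Write a metrics report as JSON (plus ROC/PR point CSVs)
#'
#' @param report A `metrics_report`.
#' @param path Output JSON path.
#' @param y_true,y_score If supplied, ROC and PR point sets are written next
#'   to `path` as `<stem>_roc.csv` / `<stem>_pr.csv`.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path, y_true = NULL, y_score = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  jsonlite::write_json(as.list(report), path, auto_unbox = TRUE, digits = NA)
  if (!is.null(y_true) && !is.null(y_score)) {
    stem <- sub("\\.json$", "", path)
    utils::write.csv(roc_points(y_true, y_score),
                     paste0(stem, "_roc.csv"), row.names = FALSE)
    utils::write.csv(pr_points(y_true, y_score),
                     paste0(stem, "_pr.csv"), row.names = FALSE)
  }
  invisible(path)
}
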