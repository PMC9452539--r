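# Metrics (conventional and Chou formulations), cross-validation protocols,
# and ROC/PR curves.

#' Confusion counts
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  stopifnot(is.numeric(v), all(v >= 0), all(v == as.integer(v)))
  structure(as.list(v), class = "confusion_counts")
}

#' Confusion counts from labelled predictions
#'
#' @param truth,predicted Vectors of class labels.
#' @param positive The label treated as positive.
#' @return A [confusion_counts()].
#' @export
counts_from_predictions <- function(truth, predicted, positive) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  confusion_counts(tp = sum(truth == positive & predicted == positive),
                   tn = sum(truth != positive & predicted != positive),
                   fp = sum(truth != positive & predicted == positive),
                   fn = sum(truth == positive & predicted != positive))
}

#' Sensitivity, specificity, accuracy and MCC
#'
#' Conventional formulations: Sn = TP/(TP+FN), Sp = TN/(TN+FP),
#' Acc = (TP+TN)/total, MCC = (TP*TN - FP*FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' A zero denominator yields `NA` (undefined) for Sn/Sp; MCC with a zero
#' denominator returns 0, the standard convention for a degenerate
#' contingency table. Values are fractions; multiply by 100 for the usual
#' percent reporting.
#'
#' @param counts A [confusion_counts()].
#' @return Object of class `classification_metrics` with fields `sn`, `sp`,
#'   `acc`, `mcc`, `counts` and `n`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  n <- tp + tn + fp + fn
  if (n == 0) stop("all confusion counts are zero", call. = FALSE)
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / n
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  structure(list(sn = sn, sp = sp, acc = acc, mcc = mcc,
                 counts = counts, n = n),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  cat("Sn ", fmt(x$sn), "  Sp ", fmt(x$sp), "  Acc ", fmt(x$acc),
      "  MCC ", fmt(x$mcc),
      if (!is.null(x$auc)) paste0("  AUC ", fmt(x$auc)),
      if (!is.null(x$aupr)) paste0("  AUPR ", fmt(x$aupr)),
      "  (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Convert between conventional and Chou-style counts
#'
#' Chou's intuitive bookkeeping uses the totals of true positives/negatives
#' and the two misclassification counts: Y+ = TP + FN, Y- = TN + FP,
#' Y+- (positives predicted negative) = FN, Y-+ (negatives predicted
#' positive) = FP. The conversion is a bijection; `chou_to_confusion`
#' inverts it exactly.
#'
#' @param counts A [confusion_counts()] (for `chou_counts`).
#' @param chou A `chou_counts` object (for `chou_to_confusion`).
#' @return `chou_counts`: object of class `chou_counts` with fields
#'   `y_plus`, `y_minus`, `y_plus_as_minus`, `y_minus_as_plus`;
#'   `chou_to_confusion`: a [confusion_counts()].
#' @export
chou_counts <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  structure(list(y_plus = counts$tp + counts$fn,
                 y_minus = counts$tn + counts$fp,
                 y_plus_as_minus = counts$fn,
                 y_minus_as_plus = counts$fp),
            class = "chou_counts")
}

#' @rdname chou_counts
#' @export
chou_to_confusion <- function(chou) {
  stopifnot(inherits(chou, "chou_counts"),
            chou$y_plus_as_minus <= chou$y_plus,
            chou$y_minus_as_plus <= chou$y_minus)
  confusion_counts(tp = chou$y_plus - chou$y_plus_as_minus,
                   tn = chou$y_minus - chou$y_minus_as_plus,
                   fp = chou$y_minus_as_plus,
                   fn = chou$y_plus_as_minus)
}

#' Metrics in the Chou formulation
#'
#' Evaluates the intuitive forms directly: Sn = 1 - Y+-/Y+,
#' Sp = 1 - Y-+/Y-, Acc = 1 - (Y+- + Y-+)/(Y+ + Y-) and the corresponding
#' MCC expression. Agrees with [compute_metrics()] to floating-point
#' precision whenever both are defined.
#'
#' @param chou A `chou_counts` object.
#' @return A `classification_metrics` object.
#' @export
metrics_chou <- function(chou) {
  stopifnot(inherits(chou, "chou_counts"))
  yp <- as.numeric(chou$y_plus); ym <- as.numeric(chou$y_minus)
  ypm <- as.numeric(chou$y_plus_as_minus); ymp <- as.numeric(chou$y_minus_as_plus)
  n <- yp + ym
  if (n == 0) stop("all counts are zero", call. = FALSE)
  sn <- if (yp > 0) 1 - ypm / yp else NA_real_
  sp <- if (ym > 0) 1 - ymp / ym else NA_real_
  acc <- 1 - (ypm + ymp) / n
  mcc <- if (yp == 0 || ym == 0) 0 else {
    num <- 1 - (ypm / yp + ymp / ym)
    rad <- (1 + (ymp - ypm) / yp) * (1 + (ypm - ymp) / ym)
    den <- sqrt(rad)
    if (!is.finite(den) || den == 0) 0 else num / den
  }
  structure(list(sn = sn, sp = sp, acc = acc, mcc = mcc,
                 counts = chou_to_confusion(chou), n = n),
            class = "classification_metrics")
}

#' ROC and precision-recall curves from continuous scores
#'
#' ROC points come from a threshold sweep over the unique scores (descending)
#' with the area by the trapezoid rule; the PR curve is built analogously
#' with the area by step-wise summation over recall increments. A perfect
#' ranker has AUC = AUPR = 1; a constant scorer has AUC = 0.5.
#'
#' @param truth Class labels (two classes required).
#' @param scores Numeric scores in `[0, 1]`, higher meaning more positive.
#' @param positive The label treated as positive.
#' @return List with `roc` (data.frame `threshold`, `fpr`, `tpr`), `auc`,
#'   `pr` (data.frame `threshold`, `recall`, `precision`) and `aupr`.
#' @export
score_curves <- function(truth, scores, positive) {
  truth <- as.character(truth)
  stopifnot(length(truth) == length(scores), is.numeric(scores),
            all(is.finite(scores)), all(scores >= 0 & scores <= 1))
  pos <- truth == positive
  if (!any(pos) || all(pos)) {
    stop("both classes must be present to build score curves", call. = FALSE)
  }
  np <- sum(pos)
  nn <- sum(!pos)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(pos & scores >= t), 0)
  fp <- vapply(thr, function(t) sum(!pos & scores >= t), 0)
  tpr <- tp / np
  fpr <- fp / nn
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  precision <- tp / (tp + fp)
  recall <- tpr
  pr <- data.frame(threshold = thr, recall = recall, precision = precision)
  aupr <- sum(diff(c(0, recall)) * precision)
  list(roc = roc, auc = auc, pr = pr, aupr = aupr)
}

#' Cross-validate one layer of the cascade
#'
#' Stratified, seeded k-fold cross-validation (or leave-one-out with
#' `k = "loo"`, the jackknife). A fresh forest is trained per fold and the
#' held-out predictions are pooled into a single confusion matrix for the
#' headline metrics; per-fold metrics and the pooled continuous scores (for
#' ROC/PR) are also returned.
#'
#' @param table A `feature_table`.
#' @param layer 1 or 2.
#' @param k Number of folds (default 5), 10, or `"loo"`.
#' @param config A [forest_config()].
#' @param seed Seed for fold assignment and the per-fold fits (defaults to
#'   `config$seed`).
#' @return Object of class `cv_result` with fields `metrics` (pooled, with
#'   `auc`/`aupr` attached), `counts`, `per_fold`, `predictions`, `curves`,
#'   `k`, `layer`, `seed`.
#' @export
cross_validate <- function(table, layer, k = 5, config = forest_config(),
                           seed = config$seed) {
  dat <- layer_training_data(table, layer)
  n <- nrow(dat$x)
  loo <- identical(k, "loo")
  if (loo) k <- n
  stopifnot(is_count(k), k >= 2, k <= n)
  if (!loo && k > min(table(dat$y))) {
    stop("k (", k, ") exceeds the smallest class size (", min(table(dat$y)), ")",
         call. = FALSE)
  }
  folds <- integer(n)
  if (loo) {
    folds <- seq_len(n)
  } else {
    with_seed(seed, {
      for (cls in levels(dat$y)) {
        idx <- sample(which(dat$y == cls))
        folds[idx] <- rep_len(seq_len(k), length(idx))
      }
    })
  }
  pos <- positive_class(layer)
  neg <- setdiff(levels(dat$y), pos)
  score <- numeric(n)
  for (f in seq_len(k)) {
    test <- folds == f
    rf <- fit_forest(dat$x[!test, , drop = FALSE], dat$y[!test],
                     config$n_trees, seed + f)
    score[test] <- stats::predict(rf, dat$x[test, , drop = FALSE],
                                  type = "prob")[, pos]
  }
  predicted <- ifelse(score >= 0.5, pos, neg)
  counts <- counts_from_predictions(dat$y, predicted, pos)
  metrics <- compute_metrics(counts)
  curves <- score_curves(dat$y, score, pos)
  metrics$auc <- curves$auc
  metrics$aupr <- curves$aupr
  per_fold <- do.call(rbind, lapply(seq_len(k), function(f) {
    sel <- folds == f
    m <- compute_metrics(counts_from_predictions(dat$y[sel], predicted[sel], pos))
    data.frame(fold = f, n = m$n, sn = m$sn, sp = m$sp, acc = m$acc, mcc = m$mcc)
  }))
  structure(list(metrics = metrics, counts = counts, per_fold = per_fold,
                 predictions = data.frame(id = rownames(dat$x),
                                          fold = folds,
                                          truth = as.character(dat$y),
                                          score = score,
                                          predicted = predicted,
                                          stringsAsFactors = FALSE),
                 curves = curves, k = k, layer = layer, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> layer ", x$layer, ", ", x$k, "-fold (pooled):\n", sep = "")
  print(x$metrics)
  invisible(x)
}
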