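#' Confusion counts for binary calls
#'
#' Standard 2x2 tally with "mechanism present" as the positive class.
#'
#' @param y_true,y_pred logical vectors of equal length.
#' @return Named integer vector `c(tp, fp, fn, tn)`.
#' @export
confusionCounts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || !length(y_true))
    .ubmStop("ubm_input_error",
             "y_true and y_pred must have equal positive length")
  y_true <- as.logical(y_true); y_pred <- as.logical(y_pred)
  c(tp = sum(y_true & y_pred), fp = sum(!y_true & y_pred),
    fn = sum(y_true & !y_pred), tn = sum(!y_true & !y_pred))
}

#' Binary classification metrics with undefined-metric flags
#'
#' Computes accuracy, sensitivity, specificity, positive and negative
#' predictive value, F1 and the Matthews correlation coefficient from a
#' confusion tally. A metric whose denominator is zero is returned as `NA`
#' and listed in the `undefined` element rather than silently coerced to
#' zero, so degenerate candidates cannot distort model selection. Wilson
#' 95% confidence intervals accompany the proportion-type metrics.
#'
#' @param counts named vector `c(tp, fp, fn, tn)` from [confusionCounts()].
#' @param ci_level confidence level for the Wilson intervals.
#' @return List with the seven point estimates, `ci` (a data frame of
#'   Wilson intervals for the proportion metrics), `undefined` (character
#'   vector) and `ci_method = "wilson"`.
#' @export
binaryMetrics <- function(counts, ci_level = 0.95) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  fn <- counts[["fn"]]; tn <- counts[["tn"]]
  n <- tp + fp + fn + tn
  if (n < 1) .ubmStop("ubm_input_error", "empty confusion table")
  undefined <- character()
  rate <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(NA_real_) }
    num / den
  }
  out <- list(
    accuracy = rate(tp + tn, n, "accuracy"),
    sensitivity = rate(tp, tp + fn, "sensitivity"),
    specificity = rate(tn, tn + fp, "specificity"),
    ppv = rate(tp, tp + fp, "ppv"),
    npv = rate(tn, tn + fn, "npv"),
    f1 = rate(2 * tp, 2 * tp + fp + fn, "f1")
  )
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  out$mcc <- if (denom == 0) { undefined <- c(undefined, "mcc"); NA_real_ }
             else (tp * tn - fp * fn) / sqrt(denom)
  ks <- c(accuracy = tp + tn, sensitivity = tp, specificity = tn,
          ppv = tp, npv = tn)
  ns <- c(accuracy = n, sensitivity = tp + fn, specificity = tn + fp,
          ppv = tp + fp, npv = tn + fn)
  ci <- do.call(rbind, lapply(names(ks), function(m) {
    if (ns[[m]] == 0) return(data.frame(metric = m, low = NA_real_,
                                        high = NA_real_))
    w <- proportionCI(ks[[m]], ns[[m]], level = ci_level)
    data.frame(metric = m, low = w[[1]], high = w[[2]])
  }))
  out$ci <- ci
  out$undefined <- undefined
  out$ci_method <- "wilson"
  out
}

#' Wilson score confidence interval for a proportion
#'
#' Well-behaved near 0 and 1, which suits the high accuracies typical of
#' this application.
#'
#' @param k number of successes (0..n).
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return Named numeric `c(low, high)`, always inside `[0, 1]`.
#' @export
proportionCI <- function(k, n, level = 0.95) {
  if (n < 1 || k < 0 || k > n)
    .ubmStop("ubm_input_error", "need 0 <= k <= n with n >= 1")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(centre - half, 0), high = min(centre + half, 1))
}

#' ROC curve and AUC by the rank (Mann-Whitney) formulation
#'
#' AUC is the probability that a random positive scores above a random
#' negative, with half credit for ties (midranks). The curve is the usual
#' (FPR, TPR) step function over descending score thresholds.
#'
#' @param scores numeric prediction scores.
#' @param labels logical vector; both classes must be present.
#' @return List with `auc` and `curve` (data frame `fpr`, `tpr`).
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    .ubmStop("ubm_undefined_metric", "AUC requires both classes")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n0, numeric(1))
  list(auc = auc,
       curve = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)))
}

#' Chi-square test for an accuracy difference
#'
#' Pearson chi-square (1 df) on the 2x2 correct/incorrect table of two
#' groups; by default without continuity correction, switchable.
#'
#' @param correct_a,n_a correct count and size of group A.
#' @param correct_b,n_b correct count and size of group B.
#' @param correct logical; apply the Yates continuity correction.
#' @return Named numeric `c(statistic, p_value)`.
#' @export
chiSquareAccuracyDiff <- function(correct_a, n_a, correct_b, n_b,
                                  correct = FALSE) {
  if (n_a < 1 || n_b < 1 || correct_a < 0 || correct_b < 0 ||
      correct_a > n_a || correct_b > n_b)
    .ubmStop("ubm_input_error", "invalid correct/total counts")
  tab <- rbind(c(correct_a, n_a - correct_a), c(correct_b, n_b - correct_b))
  if (identical(correct_a / n_a, correct_b / n_b))
    return(c(statistic = 0, p_value = 1))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  c(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Cohen's kappa for inter-rater agreement
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with chance agreement from the
#' marginal products. Returns `NA` (flagged by attribute) when chance
#' agreement is 1.
#'
#' @param rater_a,rater_b label vectors of equal length over a shared
#'   label space.
#' @return Kappa value (numeric scalar).
#' @export
cohensKappa <- function(rater_a, rater_b) {
  if (length(rater_a) != length(rater_b) || !length(rater_a))
    .ubmStop("ubm_input_error", "rater vectors must have equal length")
  lv <- sort(unique(c(as.character(rater_a), as.character(rater_b))))
  a <- factor(as.character(rater_a), levels = lv)
  b <- factor(as.character(rater_b), levels = lv)
  n <- length(a)
  tab <- table(a, b)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (isTRUE(all.equal(pe, 1))) {
    out <- NA_real_
    attr(out, "undefined") <- "chance agreement is 1"
    return(out)
  }
  (po - pe) / (1 - pe)
}

#' Multi-class accuracy and confusion table
#'
#' Exact-match accuracy for the integrated four-way assessment, with the
#' 4x4 confusion table (rows = truth, columns = prediction).
#'
#' @param y_true,y_pred vectors of [INTEGRATED_CLASSES] values (or factors).
#' @return List with `accuracy` and `confusion` (table).
#' @export
multiclassAccuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || !length(y_true))
    .ubmStop("ubm_input_error", "label vectors must have equal length")
  t_ <- factor(as.character(y_true), levels = INTEGRATED_CLASSES)
  p_ <- factor(as.character(y_pred), levels = INTEGRATED_CLASSES)
  list(accuracy = mean(t_ == p_, na.rm = FALSE),
       confusion = table(truth = t_, prediction = p_))
}
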