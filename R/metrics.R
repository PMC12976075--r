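# Pixel-level performance evaluation with white-background exclusion, the
# derived contingency-table statistics, and the cohort-level inference
# machinery (t confidence intervals, Spearman rank correlation).

#' Background-excluded pixel contingency table
#'
#' White-background pixels (as judged on the reference side) are excluded
#' from the evaluation domain: true negatives are pixels predicted background
#' that are neither tumour nor white background in the reference.
#'
#' @param pred Binary predicted tumour mask.
#' @param ref_annotation Binary reference tumour mask, same geometry.
#' @param ref_background Binary white-background mask (1 = background), same
#'   geometry; typically the complement of the tissue mask.
#' @return A `confusion_counts` object: list with integer fields `N`, `RP`,
#'   `RN`, `PP`, `PN`, `TP`, `FN`, `FP`, `TN`.
#' @export
confusion_counts <- function(pred, ref_annotation, ref_background) {
  if (!all(dim(pred) == dim(ref_annotation)) ||
      !all(dim(pred) == dim(ref_background))) {
    stop("shape mismatch")
  }
  stopifnot_binary(pred, "prediction")
  stopifnot_binary(ref_annotation, "reference annotation")
  stopifnot_binary(ref_background, "reference background")
  dom <- ref_background == 0
  p <- pred[dom] == 1
  r <- ref_annotation[dom] == 1
  # doubles, not integers: pixel-count products exceed 32-bit range
  tp <- as.numeric(sum(p & r)); fn <- as.numeric(sum(!p & r))
  fp <- as.numeric(sum(p & !r)); tn <- as.numeric(sum(!p & !r))
  structure(
    list(N = tp + fn + fp + tn, RP = tp + fn, RN = fp + tn,
         PP = tp + fp, PN = fn + tn, TP = tp, FN = fn, FP = fp, TN = tn),
    class = "confusion_counts"
  )
}

#' Combine contingency tables by elementwise addition
#'
#' @param ... `confusion_counts` objects (or a single list of them).
#' @return The summed `confusion_counts`.
#' @export
sum_confusion <- function(...) {
  cs <- list(...)
  if (length(cs) == 1 && !inherits(cs[[1]], "confusion_counts")) cs <- cs[[1]]
  out <- Reduce(function(a, b) Map(`+`, a, b), lapply(cs, unclass))
  class(out) <- "confusion_counts"
  out
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' The twelve summary statistics of a contingency table
#'
#' Computes TPR (sensitivity), FNR, TNR (specificity), FPR, PPV (precision),
#' NPV, informedness `BIN = TPR + TNR - 1`, markedness
#' `BMA = PPV + NPV - 1`, Matthews correlation coefficient, Dice similarity
#' coefficient `DSC = 2TP / (2TP + FN + FP)`, and the reference/predicted
#' positive fractions `RP/N` and `PP/N`. A statistic whose denominator is
#' zero is reported as `NA` (undefined), never as 0.
#'
#' @param c A [confusion_counts()] object.
#' @return A named numeric vector of the 12 statistics.
#' @export
metric_set <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  tpr <- safe_ratio(c$TP, c$TP + c$FN)
  fnr <- safe_ratio(c$FN, c$TP + c$FN)
  tnr <- safe_ratio(c$TN, c$TN + c$FP)
  fpr <- safe_ratio(c$FP, c$TN + c$FP)
  ppv <- safe_ratio(c$TP, c$TP + c$FP)
  npv <- safe_ratio(c$TN, c$TN + c$FN)
  mcc_den <- sqrt(c$TP + c$FN) * sqrt(c$TP + c$FP) * sqrt(c$TN + c$FN) * sqrt(c$TN + c$FP)
  mcc <- if (mcc_den == 0) NA_real_ else (c$TP * c$TN - c$FN * c$FP) / mcc_den
  dsc <- safe_ratio(2 * c$TP, 2 * c$TP + c$FN + c$FP)
  c(TPR = tpr, FNR = fnr, TNR = tnr, FPR = fpr, PPV = ppv, NPV = npv,
    BIN = tpr + tnr - 1, BMA = ppv + npv - 1, MCC = mcc, DSC = dsc,
    frac_ref_pos = safe_ratio(c$RP, c$N), frac_pred_pos = safe_ratio(c$PP, c$N))
}

#' Cohort mean with Student-t confidence interval
#'
#' @param values Per-scan metric values (n >= 2); `NA`s are dropped.
#' @param level Confidence level (default 0.95).
#' @return Named vector `mean`, `ci_low`, `ci_high`, `n`.
#' @export
cohort_mean_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("at least two values are required for a t interval")
  m <- mean(values)
  half <- qt(1 - (1 - level) / 2, df = n - 1) * sd(values) / sqrt(n)
  c(mean = m, ci_low = m - half, ci_high = m + half, n = n)
}

#' Spearman rank correlation with t-approximation p value and Fisher-z CI
#'
#' The correlation is the Pearson coefficient of the midranks. The two-sided
#' p value uses the statistic `t = r * sqrt((n-2) / (1-r^2))`, approximately
#' Student-t distributed with `n - 2` degrees of freedom under the null. The
#' confidence interval applies the Fisher z transform, whose standard error
#' is approximately `1 / sqrt(n-3)`.
#'
#' @param x,y Numeric vectors of equal length (n >= 4 for the CI).
#' @param level Confidence level (default 0.95).
#' @return A `correlation_result`: list with `rho`, `t_stat`, `p`, `ci_low`,
#'   `ci_high`, `n`.
#' @export
spearman_correlation <- function(x, y, level = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("at least 4 paired observations are required")
  if (sd(x) == 0 || sd(y) == 0) stop("correlation undefined for constant input")
  r <- cor(rank(x), rank(y))
  t_stat <- if (abs(r) >= 1) Inf * sign(r) else r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(t_stat), df = n - 2)
  z <- atanh(min(1 - 1e-15, max(-1 + 1e-15, r)))
  zcrit <- qnorm(1 - (1 - level) / 2)
  ci <- tanh(z + c(-1, 1) * zcrit / sqrt(n - 3))
  structure(list(rho = r, t_stat = t_stat, p = p,
                 ci_low = ci[1], ci_high = ci[2], n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f (95%% CI %.4f to %.4f), t = %.4f, p = %.4g, n = %d\n",
              x$rho, x$ci_low, x$ci_high, x$t_stat, x$p, x$n))
  invisible(x)
}

#' @importFrom stats qnorm var
NULL
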