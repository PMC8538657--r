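# Evaluation and statistical procedures: overlap scores, classification
# metrics, test-retest repeatability and Bland-Altman agreement.

#' Intersection-over-union (Jaccard) of two binary masks
#'
#' Two empty masks are defined to agree perfectly (IoU = 1) with a warning;
#' the degenerate case never arises on real segmentations.
#'
#' @param a,b logical arrays of identical shape.
#' @return scalar in \[0, 1\].
#' @export
iou <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stop("mask shapes differ", call. = FALSE)
  union <- sum(a | b)
  if (union == 0) {
    warning("both masks empty; IoU defined as 1")
    return(1.0)
  }
  sum(a & b) / union
}

#' Dice (F1) coefficient from an IoU value
#'
#' `F1 = 2 * IoU / (1 + IoU)`; monotone increasing, fixing 0 and 1.
#'
#' @param iou IoU value(s) in \[0, 1\].
#' @return Dice coefficient(s).
#' @export
dice_from_iou <- function(iou) {
  if (any(iou < 0 | iou > 1)) stop("IoU must be in [0, 1]", call. = FALSE)
  2 * iou / (1 + iou)
}

#' Per-class and support-weighted overlap scores for a label map
#'
#' Computes IoU per compartment (1 cortex, 2 medulla, 3 pelvis), the
#' corresponding Dice/F1 via [dice_from_iou()], the support-weighted IoU
#' (weights = ground-truth voxel counts) and the whole-mask IoU
#' (any-compartment vs any-compartment). Classes absent from the truth are
#' excluded from the weighting and flagged `NA`.
#'
#' @param pred,truth integer label maps on the same grid.
#' @return list of class `segmentation_score`: `per_class` tibble
#'   (`class`, `label`, `iou`, `f1`, `support`), `weighted_iou`,
#'   `whole_iou`.
#' @export
multiclass_scores <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("label map grids differ", call. = FALSE)
  cls <- 1:3
  per <- purrr::map_dfr(cls, function(k) {
    sup <- sum(truth == k)
    tibble::tibble(
      class = k,
      label = c("cortex", "medulla", "pelvis")[k],
      iou = if (sum(truth == k | pred == k) == 0) NA_real_ else
        sum(pred == k & truth == k) / sum(pred == k | truth == k),
      support = sup)
  })
  per$f1 <- ifelse(is.na(per$iou), NA_real_, dice_from_iou(per$iou))
  present <- per$support > 0 & !is.na(per$iou)
  weighted <- sum(per$iou[present] * per$support[present]) /
    sum(per$support[present])
  structure(list(per_class = per,
                 weighted_iou = weighted,
                 whole_iou = iou(pred > 0, truth > 0)),
            class = "segmentation_score")
}

#' @export
print.segmentation_score <- function(x, ...) {
  print(x$per_class)
  cat("support-weighted IoU:", round(x$weighted_iou, 4),
      "| whole-mask IoU:", round(x$whole_iou, 4), "\n")
  invisible(x)
}

#' Balanced accuracy with per-class recall and precision
#'
#' Balanced accuracy is the mean of per-class recalls (true-positive
#' rates). A class never predicted gets precision 0 with a flag.
#'
#' @param y_true,y_pred vectors of class labels (same length).
#' @return list of class `classification_report`: `balanced_accuracy` and
#'   a `per_class` tibble (`class`, `recall`, `precision`, `support`,
#'   `precision_defined`).
#' @export
classification_report <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("label vectors differ in length", call. = FALSE)
  cls <- sort(unique(y_true))
  per <- purrr::map_dfr(cls, function(k) {
    tp <- sum(y_true == k & y_pred == k)
    fn <- sum(y_true == k & y_pred != k)
    fp <- sum(y_true != k & y_pred == k)
    tibble::tibble(class = k,
                   recall = tp / (tp + fn),
                   precision = if (tp + fp == 0) 0 else tp / (tp + fp),
                   support = tp + fn,
                   precision_defined = tp + fp > 0)
  })
  structure(list(balanced_accuracy = mean(per$recall), per_class = per),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("balanced accuracy:", round(x$balanced_accuracy, 4), "\n")
  print(x$per_class)
  invisible(x)
}

#' Test-retest repeatability of paired measurements
#'
#' From paired measurements (m1, m2) on the same subjects: the standard
#' deviation of the within-subject differences (sample, n-1), the single
#' measurement standard deviation `sigma_sm = sqrt(2) * sigma_diff`, the
#' repeatability coefficient of variation
#' `CoV = sigma_sm / mu_pool * 100` with `mu_pool` the mean of all
#' measurements, a paired t-test of equal session means, and a
#' Shapiro--Wilk normality check of the differences.
#'
#' @param m1,m2 numeric vectors of paired measurements (length >= 3).
#' @return one-row tibble of class `repeatability_report` with columns
#'   `mean_diff`, `sigma_diff`, `sigma_sm`, `mu_pool`, `cov_pct`,
#'   `t_stat`, `p_value`, `normality_p`.
#' @examples
#' repeatability(c(50, 55, 60), c(60, 55, 50))
#' @export
repeatability <- function(m1, m2) {
  if (length(m1) != length(m2))
    stop("paired samples differ in length", call. = FALSE)
  if (length(m1) < 3)
    stop("need at least 3 pairs", call. = FALSE)
  d <- m2 - m1
  mu_pool <- mean(c(m1, m2))
  if (mu_pool == 0) stop("pooled mean is zero", call. = FALSE)
  sigma_diff <- stats::sd(d)
  sigma_sm <- sqrt(2) * sigma_diff
  tt <- stats::t.test(m2, m1, paired = TRUE)
  sw <- if (sigma_diff > 0) stats::shapiro.test(d)$p.value else NA_real_
  res <- tibble::tibble(mean_diff = mean(d),
                        sigma_diff = sigma_diff,
                        sigma_sm = sigma_sm,
                        mu_pool = mu_pool,
                        cov_pct = sigma_sm / mu_pool * 100,
                        t_stat = unname(tt$statistic),
                        p_value = tt$p.value,
                        normality_p = sw)
  class(res) <- c("repeatability_report", class(res))
  res
}

#' Bland-Altman agreement between two measurement series
#'
#' Differences d = x - y; mean difference, SD of differences, limits of
#' agreement `mu_d +/- loa_z * SD`, large-sample 95% confidence intervals
#' of the mean difference and of each limit, and a Shapiro--Wilk normality
#' p-value for the differences.
#'
#' @param x,y numeric vectors (equal length >= 3).
#' @param loa_z z-multiplier for the limits of agreement (default 1.96).
#' @return list of class `bland_altman`: `stats` (one-row tibble with
#'   `mean_diff`, `sd_diff`, `loa_lower`, `loa_upper`, their CIs,
#'   `normality_p`) and `data` (tibble of pair means and differences, for
#'   plotting).
#' @export
bland_altman <- function(x, y, loa_z = 1.96) {
  if (length(x) != length(y)) stop("series differ in length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- x - y
  md <- mean(d); sdd <- stats::sd(d)
  se_md <- sdd / sqrt(n)
  se_loa <- sdd * sqrt(1 / n + loa_z^2 / (2 * (n - 1)))
  sw <- if (sdd > 0) stats::shapiro.test(d)$p.value else NA_real_
  stats <- tibble::tibble(
    mean_diff = md, sd_diff = sdd,
    loa_lower = md - loa_z * sdd, loa_upper = md + loa_z * sdd,
    mean_diff_ci_lower = md - 1.96 * se_md,
    mean_diff_ci_upper = md + 1.96 * se_md,
    loa_lower_ci_lower = md - loa_z * sdd - 1.96 * se_loa,
    loa_lower_ci_upper = md - loa_z * sdd + 1.96 * se_loa,
    loa_upper_ci_lower = md + loa_z * sdd - 1.96 * se_loa,
    loa_upper_ci_upper = md + loa_z * sdd + 1.96 * se_loa,
    normality_p = sw)
  structure(list(stats = stats,
                 data = tibble::tibble(mean = (x + y) / 2, diff = d),
                 loa_z = loa_z),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  s <- x$stats
  cat("<bland_altman> mean difference:", signif(s$mean_diff, 4),
      "| limits of agreement: [", signif(s$loa_lower, 4), ",",
      signif(s$loa_upper, 4), "]\n")
  invisible(x)
}

#' Coefficient of determination of a least-squares line
#'
#' @param x,y numeric vectors.
#' @return r-squared of `lm(y ~ x)`.
#' @export
fit_r2 <- function(x, y) summary(stats::lm(y ~ x))$r.squared
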