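#' Area under the ROC curve
#'
#' Mann-Whitney formulation with half credit for ties, which equals the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels with both classes present.
#' @return Scalar AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present.")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve points
#'
#' @inheritParams roc_auc
#' @return A tibble with `threshold`, `tpr`, `fpr`, ordered from the
#'   all-positive to the all-negative operating point.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  thr <- c(-Inf, sort(unique(scores)), Inf)
  purrr::map_dfr(thr, function(t) {
    pred <- scores >= t
    tibble::tibble(
      threshold = t,
      tpr = sum(pred & labels == 1) / sum(labels == 1),
      fpr = sum(pred & labels == 0) / sum(labels == 0)
    )
  })
}

# Placement values: V10[i] = mean over negatives of psi(score_i, score_j),
# psi = 1/0.5/0 for greater/tie/less. mean(V10) is the AUC.
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp))
}

#' DeLong variance of a single AUC
#' @inheritParams roc_auc
#' @return Scalar variance estimate.
#' @export
auc_variance_delong <- function(scores, labels) {
  labels <- as.integer(labels)
  pl <- delong_placements(scores, labels)
  var(pl$v10) / length(pl$v10) + var(pl$v01) / length(pl$v01)
}

#' DeLong test comparing two correlated AUCs
#'
#' Fast DeLong: per-case placement values for positives and negatives give
#' each model's AUC; the variance of the AUC difference comes from the
#' empirical covariance matrices of the placement values scaled by the
#' class sizes. `z = dAUC / sqrt(var)` is referred to the standard normal.
#'
#' @param scores_a,scores_b Paired scores on identical cases.
#' @param labels Binary labels.
#' @return A tibble with `auc_a`, `auc_b`, `delta`, `var_delta`, `z`,
#'   `p_value`, `degenerate` flag.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    abort("scores and labels must be paired on identical cases.")
  }
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  auc_a <- mean(pa$v10)
  auc_b <- mean(pb$v10)
  m <- length(pa$v10)
  n <- length(pa$v01)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  sig <- s10 / m + s01 / n
  var_delta <- sig[1, 1] + sig[2, 2] - 2 * sig[1, 2]
  delta <- auc_a - auc_b
  degenerate <- FALSE
  if (var_delta <= 1e-16) {
    if (abs(delta) < 1e-12) {
      p <- 1
      z <- 0
    } else {
      degenerate <- TRUE
      p <- NA_real_
      z <- NA_real_
    }
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * pnorm(-abs(z))
  }
  tibble::tibble(
    auc_a = auc_a, auc_b = auc_b, delta = delta, var_delta = var_delta,
    z = z, p_value = p, degenerate = degenerate
  )
}

#' Youden-index-maximizing threshold
#'
#' The score cutoff maximizing sensitivity + specificity - 1 on the given
#' data; in the pipeline this is fitted on the training cohort and frozen
#' for the test cohort.
#'
#' @inheritParams roc_auc
#' @return Scalar threshold.
#' @export
youden_threshold <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  pts <- pts[is.finite(pts$threshold), , drop = FALSE]
  pts$youden <- pts$tpr - pts$fpr
  pts$threshold[which.max(pts$youden)]
}

#' Confusion-matrix classification metrics
#'
#' All metrics derive from the confusion matrix at `threshold` (predicted
#' positive when score >= threshold). Precision equals PPV and recall
#' equals sensitivity by definition; both are reported for completeness.
#' An empty predicted-positive set makes PPV/precision undefined (NA,
#' flagged).
#'
#' @inheritParams roc_auc
#' @param threshold Score cutoff; default the Youden threshold on
#'   (`scores`, `labels`).
#' @return A one-row tibble of AUC, sensitivity, specificity, PPV, NPV,
#'   precision, recall, accuracy, the threshold used, and an
#'   `undefined_ppv` flag.
#' @export
classification_metrics <- function(scores, labels, threshold = NULL) {
  labels <- as.integer(labels)
  if (is.null(threshold)) threshold <- youden_threshold(scores, labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  ppv <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  npv <- if (tn + fn == 0) NA_real_ else tn / (tn + fn)
  tibble::tibble(
    auc = roc_auc(scores, labels),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = ppv, npv = npv,
    precision = ppv, recall = tp / (tp + fn),
    accuracy = (tp + tn) / length(labels),
    threshold = threshold,
    undefined_ppv = is.na(ppv)
  )
}

#' Calibration curve with logistic recalibration summary
#'
#' Scores are grouped into quantile bins (merged when scores have fewer
#' distinct values than bins, with a warning); each bin contributes its mean
#' predicted probability and observed event rate. The logistic
#' recalibration slope/intercept (outcome on logit(score)) summarize
#' over/under-confidence; the displayed curve never refits the predictions.
#'
#' @inheritParams roc_auc
#' @param n_bins Number of quantile bins (default 5).
#' @return A `calibration_curve` tibble (`bin`, `n`, `mean_predicted`,
#'   `observed_rate`) with `slope` and `intercept` attributes.
#' @export
calibration_curve <- function(scores, labels, n_bins = 5) {
  labels <- as.integer(labels)
  if (any(scores < 0 | scores > 1)) abort("scores must be in [0, 1].")
  qs <- unique(quantile(scores, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(qs) - 1 < n_bins) {
    warn("fewer distinct score quantiles than bins; bins merged.")
  }
  if (length(qs) == 1) qs <- c(qs - 1e-9, qs + 1e-9)
  bin <- cut(scores, breaks = qs, include.lowest = TRUE, labels = FALSE)
  curve <- tibble::tibble(score = scores, label = labels, bin = bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_predicted = mean(.data$score),
      observed_rate = mean(.data$label),
      .groups = "drop"
    )
  eps <- 1e-10
  lg <- log(clamp(scores, eps, 1 - eps) / (1 - clamp(scores, eps, 1 - eps)))
  recal <- if (sd(lg) < 1e-12) {
    c(intercept = NA_real_, slope = NA_real_)
  } else {
    cf <- coef(suppressWarnings(glm(labels ~ lg, family = binomial())))
    c(intercept = unname(cf[1]), slope = unname(cf[2]))
  }
  structure(curve,
    class = c("calibration_curve", class(curve)),
    slope = recal[["slope"]], intercept = recal[["intercept"]]
  )
}

#' Decision curve analysis
#'
#' Net benefit of calling positives at each threshold probability `p_t`:
#' `NB_model = TP/n - FP/n * p_t / (1 - p_t)` (positives called at
#' score >= p_t), against the treat-all policy
#' `NB_all = pi - (1 - pi) * p_t / (1 - p_t)` (pi = prevalence) and the
#' treat-none policy `NB_none = 0`.
#'
#' @inheritParams roc_auc
#' @param thresholds Threshold-probability grid inside (0, 1); default
#'   0.01 to 0.80 in steps of 0.01.
#' @return A `decision_curve` tibble: `threshold`, `nb_model`, `nb_all`,
#'   `nb_none`.
#' @export
decision_curve <- function(scores, labels,
                           thresholds = seq(0.01, 0.80, by = 0.01)) {
  labels <- as.integer(labels)
  if (any(scores < 0 | scores > 1)) abort("scores must be in [0, 1].")
  if (any(thresholds <= 0 | thresholds >= 1)) {
    abort("thresholds must lie strictly inside (0, 1).")
  }
  n <- length(labels)
  prev <- mean(labels)
  out <- purrr::map_dfr(thresholds, function(pt) {
    pred <- scores >= pt
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    w <- pt / (1 - pt)
    tibble::tibble(
      threshold = pt,
      nb_model = tp / n - fp / n * w,
      nb_all = prev - (1 - prev) * w,
      nb_none = 0
    )
  })
  structure(out, class = c("decision_curve", class(out)))
}
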