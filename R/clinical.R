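#' Pooled-variance two-sample t-test
#'
#' Accepts either raw vectors or `(mean, sd, n)` summary triples per group —
#' baseline tables are often published as summaries only, and the pooled
#' test is exactly recoverable from them. Degrees of freedom are
#' `n1 + n2 - 2`. Zero pooled variance gives p = 1 when the means agree and
#' p = 0 otherwise.
#'
#' @param x,y Raw numeric vectors (alternative to summaries).
#' @param summary_x,summary_y Numeric `c(mean, sd, n)` triples.
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @export
ttest_pooled <- function(x = NULL, y = NULL,
                         summary_x = NULL, summary_y = NULL) {
  if (!is.null(x)) summary_x <- c(mean(x), sd(x), length(x))
  if (!is.null(y)) summary_y <- c(mean(y), sd(y), length(y))
  m1 <- summary_x[1]; s1 <- summary_x[2]; n1 <- summary_x[3]
  m2 <- summary_y[1]; s2 <- summary_y[2]; n2 <- summary_y[3]
  if (n1 < 2 || n2 < 2) abort("both groups need n >= 2.")
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  df <- n1 + n2 - 2
  if (sp2 < 1e-24) {
    p <- if (abs(m1 - m2) < 1e-12) 1 else 0
    return(tibble::tibble(statistic = if (p == 1) 0 else Inf, df = df,
                          p_value = p))
  }
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tibble::tibble(statistic = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Yates-corrected chi-square test on a 2x2 table
#'
#' Continuity-corrected chi-square with df = 1. When any expected count
#' falls below 5 the result is flagged and Fisher's exact two-sided p is
#' reported alongside.
#'
#' @param tab A 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return A tibble with `statistic`, `p_value`, `min_expected`,
#'   `small_expected` flag, and `fisher_p` (NA unless flagged).
#' @export
chi2_yates <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2)) abort("`tab` must be 2x2.")
  if (any(tab < 0)) abort("counts must be nonnegative.")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("zero margin in the 2x2 table.")
  }
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((abs(tab - expected) - pmin(0.5, abs(tab - expected)))^2 /
                expected)
  # standard Yates: (|O-E| - 0.5)^2 / E with the correction capped at |O-E|
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  small <- any(expected < 5)
  fisher_p <- if (small) fisher.test(round(tab))$p.value else NA_real_
  tibble::tibble(
    statistic = stat, p_value = p, min_expected = min(expected),
    small_expected = small, fisher_p = fisher_p
  )
}

wald_row <- function(fit, term, stage) {
  sm <- summary(fit)$coefficients
  if (!term %in% rownames(sm)) {
    return(tibble::tibble(
      feature = term, odds_ratio = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, p_value = NA_real_, stage = stage,
      flag = "degenerate_fit"
    ))
  }
  b <- sm[term, "Estimate"]
  se <- sm[term, "Std. Error"]
  sep <- abs(b) > 10 || se > 100
  tibble::tibble(
    feature = term,
    odds_ratio = exp(b),
    ci_low = exp(b - qnorm(0.975) * se),
    ci_high = exp(b + qnorm(0.975) * se),
    p_value = sm[term, "Pr(>|z|)"],
    stage = stage,
    flag = if (sep) "possible_separation" else NA_character_
  )
}

#' Univariate logistic regression screen
#'
#' One maximum-likelihood logistic fit per feature against the binary
#' outcome; Wald odds ratios, 95% CIs and p-values. Coding: outcome event
#' = 1, binary feature present = 1. Features with p < `alpha` are flagged
#' for the multivariate stage; perfect separation is flagged and its CI is
#' effectively unbounded.
#'
#' @param data Data frame / tibble.
#' @param outcome Name of the binary outcome column.
#' @param features Character vector of feature columns (default: all other
#'   numeric columns).
#' @param alpha Significance level for the multivariate flag (default 0.05).
#' @return A tibble of per-feature Wald results with a `significant` column.
#' @export
univariate_logistic <- function(data, outcome, features = NULL,
                                alpha = 0.05) {
  y <- data[[outcome]]
  if (length(unique(y)) < 2) abort("both outcome classes must be present.")
  if (is.null(features)) {
    features <- setdiff(
      names(data)[vapply(data, is.numeric, logical(1))], outcome
    )
  }
  out <- purrr::map_dfr(features, function(f) {
    if (sd(data[[f]]) < 1e-12) {
      return(tibble::tibble(
        feature = f, odds_ratio = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, p_value = NA_real_, stage = "univariate",
        flag = "degenerate_fit"
      ))
    }
    fit <- suppressWarnings(
      glm(y ~ x, data = data.frame(y = y, x = data[[f]]), family = binomial())
    )
    row <- wald_row(fit, "x", "univariate")
    row$feature <- f
    row
  })
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out
}

#' Multivariate logistic regression on selected features
#'
#' Joint maximum-likelihood logistic fit of the outcome on all selected
#' features. A rank-deficient (collinear) design is an error naming the
#' aliased columns. Predictors with p < `alpha` are reported as independent
#' predictors.
#'
#' @inheritParams univariate_logistic
#' @param features Character vector of selected features (>= 1).
#' @return A tibble of Wald results, stage `"multivariate"`.
#' @export
multivariate_logistic <- function(data, outcome, features, alpha = 0.05) {
  if (length(features) < 1) abort("need >= 1 selected feature.")
  y <- data[[outcome]]
  x <- as.matrix(data[features])
  qrx <- qr(cbind(1, x))
  if (qrx$rank < ncol(x) + 1) {
    aliased <- features[qrx$pivot[seq(qrx$rank + 1, ncol(x) + 1)] - 1]
    abort(paste0("collinear design; aliased: ",
                 paste(aliased, collapse = ", ")))
  }
  df <- data.frame(y = y, x)
  fit <- suppressWarnings(
    glm(y ~ ., data = df, family = binomial())
  )
  out <- purrr::map_dfr(make.names(features), wald_row,
                        fit = fit, stage = "multivariate")
  out$feature <- features
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out
}

#' Baseline comparison table across outcome groups
#'
#' For each cohort and each feature: mean (SD) per outcome group with the
#' pooled-variance t-test p-value for continuous features, or n (%) per
#' group with the Yates chi-square p-value for binary features.
#'
#' @param clinical Clinical tibble with `cohort` and the outcome column.
#' @param outcome Binary outcome column name (default `"label"`).
#' @param continuous,binary Feature name vectors; defaults cover the
#'   standard clinical table.
#' @return A tibble with one row per cohort x feature.
#' @export
build_baseline_table <- function(clinical, outcome = "label",
                                 continuous = NULL, binary = NULL) {
  if (is.null(continuous)) {
    continuous <- intersect(
      c("age_years", "size_mm", "solid_diameter_mm"), names(clinical)
    )
  }
  if (is.null(binary)) {
    binary <- intersect(
      c("hypertension", "diabetes", "history_tumor", "pd_infiltrative",
        "ascites", "mesenteric", "supradiaphragmatic", "bilateral",
        "ca125_high", "he4_high"),
      names(clinical)
    )
  }
  purrr::map_dfr(unique(clinical$cohort), function(ch) {
    sub <- clinical[clinical$cohort == ch, ]
    y <- sub[[outcome]]
    rows_c <- purrr::map_dfr(continuous, function(f) {
      g0 <- sub[[f]][y == 0]
      g1 <- sub[[f]][y == 1]
      tt <- ttest_pooled(x = g0, y = g1)
      tibble::tibble(
        cohort = ch, feature = f, type = "continuous",
        group0 = sprintf("%.2f ± %.2f", mean(g0), sd(g0)),
        group1 = sprintf("%.2f ± %.2f", mean(g1), sd(g1)),
        p_value = tt$p_value
      )
    })
    rows_b <- purrr::map_dfr(binary, function(f) {
      tab <- table(factor(sub[[f]], levels = 0:1), factor(y, levels = 0:1))
      p <- tryCatch(chi2_yates(t(tab))$p_value, error = function(e) NA_real_)
      tibble::tibble(
        cohort = ch, feature = f, type = "binary",
        group0 = sprintf("%d (%.2f%%)", tab[2, 1],
                         100 * tab[2, 1] / sum(tab[, 1])),
        group1 = sprintf("%d (%.2f%%)", tab[2, 2],
                         100 * tab[2, 2] / sum(tab[, 2])),
        p_value = p
      )
    })
    dplyr::bind_rows(rows_c, rows_b)
  })
}
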