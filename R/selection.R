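#' Feature-selection configuration
#'
#' Thresholds for the four-stage cascade: reproducibility (ICC >= 0.8 for
#' both inter- and intra-observer), univariate two-sided Mann-Whitney u-test
#' (p < 0.05, no multiplicity correction), Spearman redundancy pruning
#' (|rho| > 0.9), and L1-penalized logistic regression with 10-fold
#' cross-validation and the 1-SE rule.
#'
#' @param icc_threshold ICC retention threshold (default 0.8).
#' @param utest_alpha u-test retention level (default 0.05).
#' @param spearman_threshold Redundancy threshold on |rho| (default 0.9).
#' @param lasso_folds CV folds (default 10).
#' @param lasso_rule Only `"one_se"`.
#' @param seed Integer seed (CV fold assignment).
#' @return A `selection_config` list.
#' @export
selection_config <- function(icc_threshold = 0.8, utest_alpha = 0.05,
                             spearman_threshold = 0.9, lasso_folds = 10,
                             lasso_rule = c("one_se"), seed = 1L) {
  lasso_rule <- match.arg(lasso_rule)
  stopifnot(
    icc_threshold > 0, icc_threshold < 1,
    utest_alpha > 0, utest_alpha < 1,
    spearman_threshold > 0, spearman_threshold < 1,
    lasso_folds >= 2
  )
  structure(
    list(
      icc_threshold = icc_threshold, utest_alpha = utest_alpha,
      spearman_threshold = spearman_threshold,
      lasso_folds = as.integer(lasso_folds), lasso_rule = lasso_rule,
      seed = as.integer(seed)
    ),
    class = "selection_config"
  )
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement — the
#' standard choice for radiomic feature reproducibility across raters or
#' re-segmentations. Computed from the ANOVA mean squares of the
#' subjects-by-raters table.
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns
#'   (>= 3 subjects, >= 2 raters).
#' @return The ICC(2,1) estimate; `NA` when the between-subject variance is
#'   zero (ICC undefined).
#' @export
icc21 <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 3 || k < 2) abort("ICC(2,1) needs >= 3 subjects and >= 2 raters.")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr < 1e-12) return(NA_real_)
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Reproducibility (ICC) filter
#'
#' Retains a feature only when both the inter-observer ICC(2,1) (reader 1
#' vs reader 2) and the intra-observer ICC(2,1) (reader 1 vs reader 1's
#' repeat segmentation) reach the threshold. Features whose ICC is
#' undefined (zero between-subject variance) are excluded with a logged
#' reason.
#'
#' @param reader1,reader2,reader1_repeat Feature tibbles sharing subjects
#'   (rows, same order) and feature columns.
#' @param config A [selection_config()].
#' @return A tibble with `feature`, `icc_inter`, `icc_intra`, `retained`,
#'   `reason`.
#' @export
icc_filter <- function(reader1, reader2, reader1_repeat,
                       config = selection_config()) {
  feats <- intersect(
    intersect(names(reader1), names(reader2)), names(reader1_repeat)
  )
  feats <- feats[vapply(reader1[feats], is.numeric, logical(1))]
  if (nrow(reader1) < 3) abort("ICC filter needs >= 3 subjects.")
  purrr::map_dfr(feats, function(f) {
    inter <- icc21(cbind(reader1[[f]], reader2[[f]]))
    intra <- icc21(cbind(reader1[[f]], reader1_repeat[[f]]))
    undef <- is.na(inter) || is.na(intra)
    keep <- !undef && inter >= config$icc_threshold &&
      intra >= config$icc_threshold
    tibble::tibble(
      feature = f, icc_inter = inter, icc_intra = intra, retained = keep,
      reason = dplyr::case_when(
        undef ~ "icc_undefined_zero_between_subject_variance",
        keep ~ "retained",
        TRUE ~ "icc_below_threshold"
      )
    )
  })
}

#' Two-sided Mann-Whitney u-test
#'
#' Exact when both groups have <= 8 observations (full enumeration of group
#' assignments, tie-aware, two-sided tail defined by the distance of U from
#' its null mean); otherwise the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param x,y Numeric samples for the two groups.
#' @return A list with `statistic` (U of `x`) and `p_value`.
#' @export
mw_utest <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  if (sd(pooled) < 1e-12) return(list(statistic = n1 * n2 / 2, p_value = 1))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= 8 && n2 <= 8) {
    combos <- combn(n1 + n2, n1)
    us <- apply(combos, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(statistic = u_obs, p_value = 1))
    z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
  }
  list(statistic = u_obs, p_value = min(1, p))
}

#' Univariate Mann-Whitney filter
#'
#' Applies [mw_utest()] feature-wise between the two label classes and
#' retains features with p below `utest_alpha`. No multiple-testing
#' correction is applied (each feature is screened marginally). Constant
#' features get p = 1 by convention and are excluded.
#'
#' @param table Feature tibble (numeric columns are tested).
#' @param labels Binary labels (both classes present).
#' @param config A [selection_config()].
#' @return A tibble with `feature`, `p_value`, `retained`.
#' @export
mannwhitney_filter <- function(table, labels, config = selection_config()) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) abort("both classes must be present.")
  feats <- names(table)[vapply(table, is.numeric, logical(1))]
  purrr::map_dfr(feats, function(f) {
    v <- table[[f]]
    p <- if (sd(v) < 1e-12) 1 else {
      mw_utest(v[labels == 1], v[labels == 0])$p_value
    }
    tibble::tibble(feature = f, p_value = p,
                   retained = p < config$utest_alpha)
  })
}

#' Spearman redundancy pruning
#'
#' Computes pairwise Spearman correlations and, while any pair exceeds the
#' threshold in absolute value, removes one member of the currently
#' most-correlated pair. The retained member is the one with the smaller
#' univariate p-value when `p_values` are supplied (ties: lexicographically
#' smaller name).
#'
#' @param table Feature tibble.
#' @param config A [selection_config()].
#' @param p_values Optional named vector of univariate p-values used as the
#'   representativeness rule.
#' @return A list with `retained` (character), and `pruned` (tibble log of
#'   dropped features with the pair correlation).
#' @export
spearman_prune <- function(table, config = selection_config(),
                           p_values = NULL) {
  feats <- names(table)[vapply(table, is.numeric, logical(1))]
  if (length(feats) < 2) {
    return(list(retained = feats, pruned = tibble::tibble(
      dropped = character(), kept = character(), rho = numeric()
    )))
  }
  rho <- suppressWarnings(cor(as.matrix(table[feats]), method = "spearman"))
  rho[is.na(rho)] <- 0
  diag(rho) <- 0
  alive <- feats
  log_d <- character()
  log_k <- character()
  log_r <- numeric()
  repeat {
    sub <- abs(rho[alive, alive, drop = FALSE])
    mx <- max(sub)
    if (mx <= config$spearman_threshold) break
    idx <- which(sub == mx, arr.ind = TRUE)[1, ]
    a <- alive[idx[1]]
    b <- alive[idx[2]]
    drop <- pick_to_drop(a, b, p_values)
    keep <- setdiff(c(a, b), drop)
    log_d <- c(log_d, drop)
    log_k <- c(log_k, keep)
    log_r <- c(log_r, rho[a, b])
    alive <- setdiff(alive, drop)
  }
  list(
    retained = alive,
    pruned = tibble::tibble(dropped = log_d, kept = log_k, rho = log_r)
  )
}

pick_to_drop <- function(a, b, p_values) {
  if (!is.null(p_values) && !is.na(p_values[a]) && !is.na(p_values[b]) &&
      p_values[a] != p_values[b]) {
    return(if (p_values[a] < p_values[b]) b else a)
  }
  sort(c(a, b))[2] # ties: keep the lexicographically smaller name
}

#' Z-score standardization fitted on the training cohort
#'
#' `zscore_fit()` learns per-feature mean/SD on the training table;
#' `zscore_apply()` transforms any table with those parameters (test data
#' must use training parameters). Zero-variance columns get SD 1 with a
#' warning — they carry no information and transform to all zeros.
#'
#' @param table Feature tibble.
#' @return `zscore_fit()`: a `zscore_params` list; `zscore_apply()`: the
#'   transformed tibble.
#' @export
zscore_fit <- function(table) {
  feats <- names(table)[vapply(table, is.numeric, logical(1))]
  mu <- vapply(table[feats], mean, numeric(1))
  sigma <- vapply(table[feats], sd, numeric(1))
  zero <- sigma < 1e-12
  if (any(zero)) {
    warn(paste0("zero-variance columns (sd set to 1): ",
                paste(feats[zero], collapse = ", ")))
    sigma[zero] <- 1
  }
  structure(list(mean = mu, sd = sigma, features = feats),
            class = "zscore_params")
}

#' @rdname zscore_fit
#' @param params A `zscore_params` from [zscore_fit()].
#' @export
zscore_apply <- function(table, params) {
  out <- table
  for (f in params$features) {
    out[[f]] <- (table[[f]] - params$mean[[f]]) / params$sd[[f]]
  }
  out
}

#' LASSO feature selection with the 1-SE rule
#'
#' L1-penalized logistic regression over glmnet's descending lambda grid,
#' with stratified k-fold cross-validation of binomial deviance (fold
#' assignment fixed by the seed). The chosen lambda is the largest whose
#' mean CV deviance is within one standard error of the minimum; features
#' with nonzero coefficients at that lambda are returned. An all-noise
#' design may legitimately select zero features — this is flagged so callers
#' can fall back to the pre-LASSO set.
#'
#' @param table Standardized feature tibble.
#' @param labels Binary labels.
#' @param config A [selection_config()].
#' @return A list with `features`, `lambda_1se`, `lambda_min`, `path`
#'   (tibble: lambda, mean CV deviance, SE, nonzero count), `coefficients`,
#'   and `empty` flag.
#' @export
lasso_select <- function(table, labels, config = selection_config()) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) abort("both classes must be present.")
  x <- as.matrix(table[vapply(table, is.numeric, logical(1))])
  if (ncol(x) < 2) {
    return(list(features = colnames(x), lambda_1se = NA_real_,
                lambda_min = NA_real_, path = NULL,
                coefficients = NULL, empty = length(colnames(x)) == 0))
  }
  foldid <- with_seed(config$seed, stratified_folds(labels, config$lasso_folds))
  cvfit <- glmnet::cv.glmnet(
    x, labels, family = "binomial", alpha = 1,
    type.measure = "deviance", foldid = foldid, standardize = FALSE
  )
  lam <- cvfit$lambda.1se
  cf <- as.matrix(coef(cvfit, s = lam))
  nz <- rownames(cf)[cf[, 1] != 0]
  nz <- setdiff(nz, "(Intercept)")
  list(
    features = nz,
    lambda_1se = lam,
    lambda_min = cvfit$lambda.min,
    path = tibble::tibble(
      lambda = cvfit$lambda, cvm = cvfit$cvm, cvsd = cvfit$cvsd,
      nonzero = cvfit$nzero
    ),
    coefficients = setNames(cf[cf[, 1] != 0, 1], rownames(cf)[cf[, 1] != 0]),
    empty = length(nz) == 0
  )
}

stratified_folds <- function(labels, k) {
  foldid <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  foldid
}

#' Run the full selection cascade on a feature set
#'
#' Stages: optional ICC reproducibility filter (when reader tables are
#' supplied), Mann-Whitney screen, Spearman redundancy pruning, z-score
#' standardization (training parameters), LASSO with the 1-SE rule. Stage
#' survivor lists are nested by construction. A stage that would empty the
#' feature set falls back to the previous stage's survivors and is flagged,
#' so downstream modeling always has inputs.
#'
#' @param table Training-cohort feature tibble (numeric columns).
#' @param labels Training labels.
#' @param config A [selection_config()].
#' @param reader_tables Optional list with `reader1`, `reader2`,
#'   `reader1_repeat` feature tibbles for the ICC stage.
#' @return A `selection_report`: per-stage survivor lists, diagnostics, the
#'   fitted `zscore_params`, and the final feature list.
#' @export
select_features <- function(table, labels, config = selection_config(),
                            reader_tables = NULL) {
  feats0 <- names(table)[vapply(table, is.numeric, logical(1))]
  stages <- list(input = feats0)
  diagnostics <- list()
  fallbacks <- character()

  current <- feats0
  if (!is.null(reader_tables)) {
    icc <- icc_filter(
      reader_tables$reader1[current], reader_tables$reader2[current],
      reader_tables$reader1_repeat[current], config
    )
    keep <- icc$feature[icc$retained]
    diagnostics$icc <- icc
    if (!length(keep)) {
      fallbacks <- c(fallbacks, "icc")
    } else {
      current <- keep
    }
    stages$icc <- current
  }

  mw <- mannwhitney_filter(table[current], labels, config)
  diagnostics$utest <- mw
  keep <- mw$feature[mw$retained]
  if (!length(keep)) fallbacks <- c(fallbacks, "utest") else current <- keep
  stages$utest <- current

  pv <- setNames(mw$p_value, mw$feature)
  sp <- spearman_prune(table[current], config, p_values = pv)
  diagnostics$spearman <- sp$pruned
  current <- sp$retained
  stages$spearman <- current

  zs <- zscore_fit(table[current])
  zt <- zscore_apply(table[current], zs)

  las <- lasso_select(zt, labels, config)
  diagnostics$lasso <- las
  if (las$empty) {
    fallbacks <- c(fallbacks, "lasso")
    warn("LASSO selected zero features; falling back to the pre-LASSO set.")
  } else {
    current <- las$features
  }
  stages$lasso <- current

  structure(
    list(
      stages = stages, features = current, zscore = zs,
      diagnostics = diagnostics, fallbacks = fallbacks, config = config
    ),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  sizes <- vapply(x$stages, length, integer(1))
  cat("<selection_report>\n")
  for (nm in names(sizes)) cat(sprintf("  %-9s %d features\n", nm, sizes[nm]))
  if (length(x$fallbacks)) {
    cat("  fallbacks:", paste(x$fallbacks, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a selection report into a per-stage tibble
#'
#' @param x A `selection_report`.
#' @param ... Unused.
#' @return A tibble with `stage`, `n_features`, `features` (list-column).
#' @export
tidy.selection_report <- function(x, ...) {
  tibble::tibble(
    stage = names(x$stages),
    n_features = vapply(x$stages, length, integer(1)),
    features = unname(x$stages)
  )
}
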