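#' Classifier specification
#'
#' Fixed, declared hyperparameter defaults (overridable through `params`)
#' rather than silent tuning:
#' * `lr` — maximum-likelihood logistic regression.
#' * `svm` — radial-basis support vector machine, C = 1, kernel scale
#'   `gamma = 1 / (d * mean feature variance)`; probabilities come from the
#'   internal cross-validated sigmoid (Platt) calibration fitted on training
#'   data only.
#' * `gbm_leafwise` — leaf-wise histogram gradient boosting (100 rounds,
#'   learning rate 0.1, up to 8 leaves), run through the xgboost backend
#'   with `grow_policy = "lossguide"`.
#' * `xgboost` — depth-wise gradient boosting, 100 rounds, depth 3,
#'   learning rate 0.1.
#' * `mlp` — single-hidden-layer perceptron, 32 units, weight decay 1e-4.
#'
#' @param learner One of `"lr"`, `"svm"`, `"gbm_leafwise"`, `"xgboost"`,
#'   `"mlp"`.
#' @param params Named list of overrides.
#' @param seed Integer seed (MLP initialization, boosting subsampling, SVM
#'   calibration folds).
#' @return A `model_spec`.
#' @export
model_spec <- function(learner = c("lr", "svm", "gbm_leafwise", "xgboost",
                                   "mlp"),
                       params = list(), seed = 1L) {
  learner <- match.arg(learner)
  structure(list(learner = learner, params = params, seed = as.integer(seed)),
            class = "model_spec")
}

#' The five default learners
#' @param seed Integer seed shared by all specs.
#' @return Named list of [model_spec()]s.
#' @export
default_learners <- function(seed = 1L) {
  nm <- c("lr", "svm", "gbm_leafwise", "xgboost", "mlp")
  setNames(purrr::map(nm, model_spec, seed = seed), nm)
}

#' Fit a classifier
#'
#' Deterministic given `(spec, X, y)`: every stochastic component is seeded
#' from the model spec.
#'
#' @param spec A [model_spec()].
#' @param X Numeric feature matrix or tibble (already standardized/encoded).
#' @param y Binary labels with both classes present.
#' @return A `fitted_model` carrying the learner, the backend fit, and the
#'   training feature list.
#' @export
fit_classifier <- function(spec, X, y) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) abort("single-class labels.")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  p <- spec$params
  fit <- with_seed(spec$seed, switch(
    spec$learner,
    lr = {
      df <- data.frame(y = y, X)
      suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    },
    svm = {
      gam <- p$gamma %||% (1 / (ncol(X) * max(mean(apply(X, 2, var)), 1e-8)))
      e1071::svm(
        x = X, y = factor(y, levels = 0:1), kernel = "radial",
        cost = p$cost %||% 1, gamma = gam, probability = TRUE, scale = FALSE
      )
    },
    gbm_leafwise = xgboost::xgb.train(
      data = xgboost::xgb.DMatrix(X, label = y),
      nrounds = p$nrounds %||% 100,
      params = list(
        objective = "binary:logistic", eta = p$eta %||% 0.1,
        max_depth = 0, max_leaves = p$max_leaves %||% 8,
        tree_method = "hist", grow_policy = "lossguide",
        subsample = p$subsample %||% 0.8, nthread = 1,
        seed = spec$seed
      ), verbose = 0
    ),
    xgboost = xgboost::xgb.train(
      data = xgboost::xgb.DMatrix(X, label = y),
      nrounds = p$nrounds %||% 100,
      params = list(
        objective = "binary:logistic", eta = p$eta %||% 0.1,
        max_depth = p$max_depth %||% 3, subsample = p$subsample %||% 0.8,
        nthread = 1, seed = spec$seed
      ), verbose = 0
    ),
    mlp = nnet::nnet(
      x = X, y = y, size = p$size %||% 32, decay = p$decay %||% 1e-4,
      maxit = p$maxit %||% 200, entropy = TRUE, trace = FALSE,
      MaxNWts = 100000
    )
  ))
  structure(
    list(learner = spec$learner, fit = fit, features = colnames(X),
         seed = spec$seed),
    class = "fitted_model"
  )
}

#' Predict class-1 probabilities
#'
#' @param model A [fit_classifier()] result.
#' @param X New data with exactly the training feature columns; missing
#'   columns are an error naming them, never silently imputed.
#' @return Numeric scores in \[0, 1\], one per row.
#' @export
predict_proba <- function(model, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  missing <- setdiff(model$features, colnames(X))
  if (length(missing)) {
    abort(paste0("missing feature columns: ", paste(missing, collapse = ", ")))
  }
  X <- X[, model$features, drop = FALSE]
  scores <- switch(
    model$learner,
    lr = as.numeric(predict(model$fit,
                            newdata = as.data.frame(X), type = "response")),
    svm = {
      pr <- predict(model$fit, X, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    gbm_leafwise = ,
    xgboost = as.numeric(predict(model$fit, X)),
    mlp = as.numeric(predict(model$fit, X))
  )
  clamp(as.numeric(scores), 0, 1)
}

#' Fit the full feature-set x learner AUC grid
#'
#' Fits every learner on every prepared feature set and records train- and
#' test-cohort AUCs — the grid that drives optimal-model selection.
#'
#' @param feature_sets Named list; each element a list with `train` and
#'   `test` numeric tibbles/matrices (same columns).
#' @param labels_train,labels_test Binary label vectors.
#' @param learners Named list of [model_spec()]s (default the five).
#' @param permissive If `TRUE`, a failed fit yields NA cells instead of
#'   aborting the run.
#' @return An `auc_grid` tibble: `feature_set`, `learner`, `cohort`, `auc`,
#'   `n_features`.
#' @export
build_auc_grid <- function(feature_sets, labels_train, labels_test,
                           learners = default_learners(),
                           permissive = FALSE) {
  rows <- purrr::map_dfr(names(feature_sets), function(fs) {
    Xtr <- as.matrix(feature_sets[[fs]]$train)
    Xte <- as.matrix(feature_sets[[fs]]$test)
    purrr::map_dfr(names(learners), function(ln) {
      res <- tryCatch({
        m <- fit_classifier(learners[[ln]], Xtr, labels_train)
        c(roc_auc(predict_proba(m, Xtr), labels_train),
          roc_auc(predict_proba(m, Xte), labels_test))
      }, error = function(e) {
        if (!permissive) {
          abort(paste0("fit failed for ", fs, "/", ln, ": ",
                       conditionMessage(e)))
        }
        c(NA_real_, NA_real_)
      })
      tibble::tibble(
        feature_set = fs, learner = ln, cohort = c("train", "test"),
        auc = res, n_features = ncol(Xtr)
      )
    })
  })
  structure(rows, class = c("auc_grid", class(rows)))
}

#' Select the optimal feature set by average training AUC
#'
#' Returns the feature set whose mean training AUC over the learners is
#' highest; ties break toward the higher mean test AUC, then
#' lexicographically.
#'
#' @param grid An `auc_grid` (or any tibble with `feature_set`, `cohort`,
#'   `learner`, `auc`).
#' @return A one-row tibble: `feature_set`, `mean_train_auc`,
#'   `mean_test_auc`.
#' @export
select_optimal <- function(grid) {
  means <- grid |>
    dplyr::group_by(.data$feature_set, .data$cohort) |>
    dplyr::summarise(auc = mean(.data$auc), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "cohort", values_from = "auc")
  if (!"test" %in% names(means)) means$test <- NA_real_
  means <- dplyr::arrange(
    means,
    dplyr::desc(.data$train),
    dplyr::desc(dplyr::coalesce(.data$test, -Inf)),
    .data$feature_set
  )
  tibble::tibble(
    feature_set = means$feature_set[1],
    mean_train_auc = means$train[1],
    mean_test_auc = means$test[1]
  )
}

#' Glance at an AUC grid
#'
#' @param x An `auc_grid`.
#' @param ... Unused.
#' @return One row with the optimal feature set and its mean AUCs.
#' @export
glance.auc_grid <- function(x, ...) select_optimal(x)

#' Coefficient-level tidy method for fitted models
#'
#' Logistic models return their coefficient table; other learners return
#' their feature list (their parameters are not linear terms).
#'
#' @param x A `fitted_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.fitted_model <- function(x, ...) {
  if (x$learner == "lr") {
    sm <- summary(x$fit)$coefficients
    tibble::tibble(
      term = rownames(sm), estimate = sm[, "Estimate"],
      std_error = sm[, "Std. Error"], p_value = sm[, "Pr(>|z|)"]
    )
  } else {
    tibble::tibble(term = x$features, learner = x$learner)
  }
}
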