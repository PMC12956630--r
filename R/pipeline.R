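#' Run the habitat-radiomics pipeline on a synthetic or prepared cohort
#'
#' End-to-end driver: windows each volume, computes voxel-local texture
#' features, fits one population-level habitat model on the pooled training
#' voxels, assigns habitats to every patient (test voxels use the learned
#' training centroids, so habitat indices are comparable across cohorts),
#' extracts whole-tumor and per-habitat radiomic features, imputes
#' empty-habitat features by the training-cohort median, runs the selection
#' cascade per radiomic feature set, builds the clinical feature set from
#' the univariate-to-multivariate logistic screen, fits the five-learner
#' AUC grid over the eight feature sets, and selects the optimal set by
#' average training AUC.
#'
#' @param cohort A [generate_cohort()] result (or a list with the same
#'   structure: `cases`, `clinical` with `cohort`/`label` columns).
#' @param k Number of habitats (default 5).
#' @param preprocess A [preprocess_config()].
#' @param extract An [extract_config()].
#' @param selection A [selection_config()].
#' @param learners Named list of [model_spec()]s.
#' @param kernel_radius_vox,n_bins Voxel-local feature parameters.
#' @param seed Integer seed for habitat fitting.
#' @return A `habitat_pipeline` list: `feature_table`, `habitat_model`,
#'   `habitat_maps`, `selection` (per-set reports), `feature_sets`,
#'   `grid` (the `auc_grid`), `optimal`, `clinical_screen`.
#' @export
run_habitat_pipeline <- function(cohort, k = 5,
                                 preprocess = preprocess_config(),
                                 extract = extract_config(),
                                 selection = selection_config(),
                                 learners = default_learners(),
                                 kernel_radius_vox = 2, n_bins = 32,
                                 seed = 1L) {
  clinical <- cohort$clinical
  is_train <- clinical$cohort == "train"
  n <- nrow(clinical)

  windowed <- vector("list", n)
  stacks <- vector("list", n)
  for (i in seq_len(n)) {
    v <- apply_window(cohort$cases[[i]]$volume, preprocess)
    windowed[[i]] <- v
    stacks[[i]] <- voxel_feature_map(
      v, cohort$cases[[i]]$mask,
      kernel_radius_vox = kernel_radius_vox, n_bins = n_bins
    )
  }

  model <- fit_habitat_model(stacks[is_train], k = k, seed = seed)
  maps <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    maps[[i]] <- assign_habitats(stacks[[i]], cohort$cases[[i]]$mask, model)
    rows[[i]] <- extract_case(
      windowed[[i]], cohort$cases[[i]]$mask, maps[[i]], extract
    )
  }
  feature_table <- dplyr::bind_rows(rows)
  feature_table$patient_id <- clinical$patient_id
  feature_table <- dplyr::relocate(feature_table, "patient_id")

  feature_table <- impute_training_median(feature_table, is_train)

  labels_train <- clinical$label[is_train]
  labels_test <- clinical$label[!is_train]

  radiomic_sets <- list(
    radiomic = grep("^whole_", names(feature_table), value = TRUE),
    habitat_1 = grep("^habitat_1_", names(feature_table), value = TRUE),
    habitat_2 = grep("^habitat_2_", names(feature_table), value = TRUE),
    habitat_3 = grep("^habitat_3_", names(feature_table), value = TRUE),
    habitat_4 = grep("^habitat_4_", names(feature_table), value = TRUE),
    habitat_5 = grep("^habitat_5_", names(feature_table), value = TRUE),
    habitat_combined = grep("^habitat_", names(feature_table), value = TRUE)
  )
  radiomic_sets <- radiomic_sets[vapply(radiomic_sets, length, 1L) > 0]

  reports <- list()
  feature_sets <- list()

  clin_feats <- intersect(
    c("age_years", "size_mm", "solid_diameter_mm", "hypertension",
      "diabetes", "history_tumor", "pd_infiltrative", "ascites",
      "mesenteric", "supradiaphragmatic", "bilateral", "ca125_high",
      "he4_high"),
    names(clinical)
  )
  screen <- univariate_logistic(clinical[is_train, ], "label", clin_feats)
  selected_clin <- screen$feature[screen$significant]
  multi <- NULL
  if (length(selected_clin) >= 1) {
    multi <- tryCatch(
      multivariate_logistic(clinical[is_train, ], "label", selected_clin),
      error = function(e) NULL
    )
    if (!is.null(multi) && any(multi$significant)) {
      selected_clin <- multi$feature[multi$significant]
    }
  }
  if (!length(selected_clin)) selected_clin <- clin_feats # null-signal fallback
  zs_clin <- zscore_fit(clinical[is_train, selected_clin])
  feature_sets$clinical <- list(
    train = zscore_apply(clinical[is_train, selected_clin], zs_clin),
    test = zscore_apply(clinical[!is_train, selected_clin], zs_clin)
  )

  for (nm in names(radiomic_sets)) {
    cols <- radiomic_sets[[nm]]
    rep <- suppressWarnings(
      select_features(feature_table[is_train, cols], labels_train, selection)
    )
    reports[[nm]] <- rep
    zs <- rep$zscore
    feats <- rep$features
    feature_sets[[nm]] <- list(
      train = zscore_apply(feature_table[is_train, cols], zs)[feats],
      test = zscore_apply(feature_table[!is_train, cols], zs)[feats]
    )
  }

  grid <- build_auc_grid(feature_sets, labels_train, labels_test, learners)
  optimal <- select_optimal(grid)

  structure(
    list(
      feature_table = feature_table, habitat_model = model,
      habitat_maps = maps, selection = reports, feature_sets = feature_sets,
      grid = grid, optimal = optimal,
      clinical_screen = list(univariate = screen, multivariate = multi,
                             selected = selected_clin)
    ),
    class = "habitat_pipeline"
  )
}

# Empty-habitat features are missing; fill with the training-cohort median
# per feature so cohorts stay intact.
impute_training_median <- function(feature_table, is_train) {
  for (f in names(feature_table)) {
    v <- feature_table[[f]]
    if (!is.numeric(v) || !anyNA(v)) next
    med <- median(v[is_train], na.rm = TRUE)
    if (is.na(med)) med <- 0
    v[is.na(v)] <- med
    feature_table[[f]] <- v
  }
  feature_table
}

#' @export
print.habitat_pipeline <- function(x, ...) {
  cat("<habitat_pipeline>\n")
  cat(sprintf("  habitats: k = %d\n", x$habitat_model$k))
  cat(sprintf("  feature sets: %s\n",
              paste(names(x$feature_sets), collapse = ", ")))
  cat(sprintf("  optimal: %s (mean train AUC %.3f, test %.3f)\n",
              x$optimal$feature_set, x$optimal$mean_train_auc,
              x$optimal$mean_test_auc))
  invisible(x)
}

#' Glance at a fitted pipeline
#' @param x A `habitat_pipeline`.
#' @param ... Unused.
#' @return One row: optimal feature set and its mean train/test AUC.
#' @export
glance.habitat_pipeline <- function(x, ...) x$optimal
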