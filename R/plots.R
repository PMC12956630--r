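#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_text geom_line
#'   geom_abline geom_point geom_step scale_fill_gradient labs theme_minimal
#'   facet_wrap coord_equal
NULL

#' Heatmap of an AUC grid
#'
#' @param object An `auc_grid`.
#' @param ... Unused.
#' @return A ggplot: feature set x learner tiles, faceted by cohort.
#' @export
autoplot.auc_grid <- function(object, ...) {
  ggplot(object, aes(x = .data$learner, y = .data$feature_set,
                     fill = .data$auc)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$auc)), size = 3) +
    scale_fill_gradient(low = "#fff5eb", high = "#d94801",
                        limits = c(0, 1)) +
    facet_wrap(~cohort) +
    labs(x = "learner", y = "feature set", fill = "AUC") +
    theme_minimal()
}

#' ROC curve plot
#'
#' @param scores,labels As in [roc_auc()], or a named list of score vectors
#'   for multiple models on shared labels.
#' @return A ggplot of the empirical ROC curve(s) with the chance diagonal.
#' @export
plot_roc <- function(scores, labels) {
  if (!is.list(scores)) scores <- list(model = scores)
  df <- purrr::imap_dfr(scores, function(s, nm) {
    pts <- roc_points(s, labels)
    pts$model <- sprintf("%s (AUC %.3f)", nm, roc_auc(s, labels))
    pts
  })
  ggplot(df, aes(x = .data$fpr, y = .data$tpr, colour = .data$model)) +
    geom_step() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    coord_equal() +
    labs(x = "1 - specificity", y = "sensitivity", colour = NULL) +
    theme_minimal()
}

#' Calibration curve plot
#'
#' @param object A [calibration_curve()].
#' @param ... Unused.
#' @return A ggplot of observed event rate against mean predicted
#'   probability per bin, with the identity (perfect calibration) line.
#' @export
autoplot.calibration_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$mean_predicted, y = .data$observed_rate)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line() +
    geom_point(aes(size = .data$n)) +
    coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "mean predicted probability", y = "observed event rate",
         size = "bin n") +
    theme_minimal()
}

#' Decision curve plot
#'
#' @param object A [decision_curve()].
#' @param ... Unused.
#' @return A ggplot of net benefit against threshold probability for the
#'   model, treat-all and treat-none policies.
#' @export
autoplot.decision_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("nb_model", "nb_all", "nb_none"),
    names_to = "policy", values_to = "net_benefit"
  )
  df$policy <- dplyr::recode(df$policy, nb_model = "model",
                             nb_all = "treat all", nb_none = "treat none")
  ggplot(df, aes(x = .data$threshold, y = .data$net_benefit,
                 colour = .data$policy)) +
    geom_line() +
    labs(x = "threshold probability", y = "net benefit", colour = NULL) +
    theme_minimal()
}

#' Habitat map slice plot
#'
#' @param map A `habitat_map`.
#' @param slice Axial slice index (default: the slice with the most tumor
#'   voxels).
#' @return A ggplot raster of habitat labels on that slice.
#' @export
plot_habitat_slice <- function(map, slice = NULL) {
  if (is.null(slice)) {
    counts <- apply(map$grid > 0, 3, sum)
    slice <- which.max(counts)
  }
  m <- map$grid[, , slice]
  df <- tidyr::expand_grid(x = seq_len(nrow(m)), y = seq_len(ncol(m)))
  df$habitat <- factor(as.vector(m), levels = 0:map$k)
  ggplot(df[df$habitat != 0, ], aes(x = .data$x, y = .data$y,
                                    fill = .data$habitat)) +
    geom_tile() +
    coord_equal() +
    labs(title = sprintf("habitat map, slice %d", slice), fill = "habitat") +
    theme_minimal()
}
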