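#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Serialize a habitat model to JSON
#'
#' Centroids, standardization parameters, label-order rule and seed — the
#' complete state needed to re-assign habitats on new patients.
#'
#' @param model A `habitat_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly. `read_habitat_model()` restores the model.
#' @export
write_habitat_model <- function(model, path) {
  jsonlite::write_json(
    list(
      k = model$k,
      centers = model$centers,
      feature_names = colnames(model$centers),
      standardization = list(
        mean = as.list(model$standardization$mean),
        sd = as.list(model$standardization$sd)
      ),
      label_order_rule = model$label_order_rule,
      seed = model$seed
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_habitat_model
#' @export
read_habitat_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  centers <- as.matrix(x$centers)
  colnames(centers) <- x$feature_names
  rownames(centers) <- paste0("habitat_", seq_len(x$k))
  structure(
    list(
      k = as.integer(x$k), centers = centers,
      standardization = list(
        mean = unlist(x$standardization$mean),
        sd = unlist(x$standardization$sd)
      ),
      label_order_rule = x$label_order_rule,
      seed = as.integer(x$seed)
    ),
    class = "habitat_model"
  )
}

#' Write a synthetic cohort to disk
#'
#' Cases as paired NIfTI files (`<id>_image.nii.gz`, `<id>_mask.nii.gz`),
#' the clinical table as CSV, and the generation truth (planted fractions,
#' label coefficients, seeds) as a sidecar JSON.
#'
#' @param cohort A [generate_cohort()] result with volumes kept.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$cases)) {
    case <- cohort$cases[[i]]
    if (is.null(case$volume)) next
    write_nifti(case$volume, file.path(dir, sprintf("p%03d_image.nii.gz", i)))
    write_nifti(case$mask, file.path(dir, sprintf("p%03d_mask.nii.gz", i)))
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(
      fractions = cohort$truth$fractions,
      label_coefficients = cohort$truth$label_coefficients,
      seed = cohort$truth$seed
    ),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
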