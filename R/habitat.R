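#' Voxel-level local texture features inside a tumor ROI
#'
#' For every in-mask voxel, computes six local features over the cubic
#' neighborhood of radius `kernel_radius_vox`, clipped to the volume and
#' restricted to in-mask voxels (so habitat features describe tumor tissue
#' only and are invariant to whatever surrounds the ROI):
#' first-order entropy, GLCM difference entropy, GLCM joint energy, GLCM
#' joint entropy (co-occurrence counts pooled symmetrically over the 13
#' unique 3D offsets within the neighborhood), NGTDM contrast, and the raw
#' HU value. Intensities are discretized into `n_bins` equal-width bins over
#' the in-mask intensity range of the (already windowed) volume; entropies
#' are in bits with `0*log(0) = 0`.
#'
#' A constant volume is valid, not an error: every entropy is 0, joint
#' energy is 1 and contrast is 0.
#'
#' @param volume A windowed [image_volume()].
#' @param mask The paired nonempty [tumor_mask()].
#' @param kernel_radius_vox Neighborhood radius in voxels (>= 1; default 2,
#'   i.e. 5x5x5 — the smallest neighborhood giving stable co-occurrence
#'   estimates).
#' @param n_bins Discretization bins (>= 2, default 32).
#' @param voxel_subset Optional logical array (same shape as the mask)
#'   selecting the voxels whose features are returned. Neighborhoods always
#'   use the full mask, so returned values are identical to a full run
#'   restricted to that subset; see [sample_voxel_rows()] for an efficient
#'   row-wise subsample.
#' @return A `voxel_feature_stack` tibble with one row per computed voxel:
#'   `voxel_index` (linear index into the grid) and the six features.
#' @export
voxel_feature_map <- function(volume, mask, kernel_radius_vox = 2,
                              n_bins = 32, voxel_subset = NULL) {
  check_aligned(volume, mask)
  if (!any(mask$grid)) abort("mask is empty.")
  if (kernel_radius_vox < 1) abort("`kernel_radius_vox` must be >= 1.")
  if (n_bins < 2) abort("`n_bins` must be >= 2.")

  vals <- volume$grid
  rng <- range(vals[mask$grid])
  if (diff(rng) < 1e-12) {
    binned <- array(1L, dim(vals))
  } else {
    w <- diff(rng) / n_bins
    binned <- array(
      clamp(as.integer(floor((vals - rng[1]) / w)) + 1L, 1L, n_bins),
      dim(vals)
    )
  }
  compute <- if (is.null(voxel_subset)) mask$grid else {
    if (!identical(dim(voxel_subset), dim(mask$grid))) {
      abort("`voxel_subset` must match the mask shape.")
    }
    mask$grid & voxel_subset
  }
  if (!any(compute)) abort("`voxel_subset` selects no in-mask voxel.")
  feats <- cpp_voxel_features(
    as.integer(binned), as.logical(mask$grid), as.logical(compute),
    as.integer(dim(vals)), as.integer(kernel_radius_vox), as.integer(n_bins)
  )
  idx <- which(compute)
  out <- tibble::tibble(
    voxel_index = idx,
    fo_entropy = feats[, 1],
    glcm_diff_entropy = feats[, 2],
    glcm_joint_energy = feats[, 3],
    glcm_joint_entropy = feats[, 4],
    ngtdm_contrast = feats[, 5],
    hu = as.numeric(vals[idx])
  )
  structure(out, class = c("voxel_feature_stack", class(out)))
}

#' Row-wise voxel subsample for feature computation
#'
#' Selects all voxels in a random fraction of the mask's (y, z) rows —
#' the unit of work of the sliding-window feature engine — giving a
#' uniformly subsampled view of the voxel feature map at proportional cost.
#'
#' @param mask A [tumor_mask()].
#' @param fraction Fraction of rows to keep (0, 1].
#' @param seed Integer seed.
#' @return A logical array to pass as `voxel_subset`.
#' @export
sample_voxel_rows <- function(mask, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  dm <- dim(mask$grid)
  keep <- array(FALSE, dm)
  rows <- which(apply(mask$grid, c(2, 3), any))
  pick <- with_seed(seed, {
    sample(rows, size = max(1L, round(fraction * length(rows))))
  })
  yz <- arrayInd(pick, dm[2:3])
  for (i in seq_len(nrow(yz))) keep[, yz[i, 1], yz[i, 2]] <- TRUE
  keep
}

habitat_feature_names <- function() {
  c("fo_entropy", "glcm_diff_entropy", "glcm_joint_energy",
    "glcm_joint_entropy", "ngtdm_contrast", "hu")
}

# k-means++ seeding (Arthur & Vassilvitskii): greedy D^2 sampling.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ], "-")^2)
  if (k > 1) {
    for (j in 2:k) {
      p <- d2 / sum(d2)
      if (!all(is.finite(p)) || sum(d2) <= 0) {
        i <- sample.int(n, 1)
      } else {
        i <- sample.int(n, 1, prob = p)
      }
      centers[j, ] <- x[i, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ], "-")^2))
    }
  }
  centers
}

#' Fit a population-level habitat model
#'
#' Pools voxel feature stacks over the training cohort (optionally
#' subsampling per patient for tractability), standardizes each feature to
#' zero mean / unit SD over the pooled voxels, and runs k-means (Euclidean,
#' k-means++ initialization, `n_restarts` restarts, fixed seed) on the
#' standardized vectors. Centroids are then relabeled by ascending mean HU,
#' so Habitat 1 is always the lowest-attenuation subregion — a deterministic,
#' interpretable ordering that makes habitat indices comparable across
#' patients and refits.
#'
#' @param stacks A `voxel_feature_stack` or list of them (training cohort).
#' @param k Number of habitats (default 5).
#' @param seed Integer seed for subsampling and initialization.
#' @param max_voxels_per_patient Per-patient subsampling cap for the pooled
#'   fit (default 2000); assignment afterwards always uses all voxels.
#' @param n_restarts k-means restarts (default 10).
#' @return A `habitat_model` with standardized-space `centers`, the
#'   standardization parameters, `k` and the seed.
#' @export
fit_habitat_model <- function(stacks, k = 5, seed = 1L,
                              max_voxels_per_patient = 2000,
                              n_restarts = 10) {
  if (inherits(stacks, "voxel_feature_stack")) stacks <- list(stacks)
  if (k < 1) abort("`k` must be >= 1.")
  fn <- habitat_feature_names()
  with_seed(seed, {
    pooled <- purrr::map(stacks, function(s) {
      m <- as.matrix(s[, fn])
      if (nrow(m) > max_voxels_per_patient) {
        m <- m[sample.int(nrow(m), max_voxels_per_patient), , drop = FALSE]
      }
      m
    })
    x <- do.call(rbind, pooled)
    if (nrow(x) < k) abort("fewer pooled voxels than clusters.")
    mu <- colMeans(x)
    # population SD: standardization (and hence the k-means optimum) is
    # invariant to duplicating every voxel row
    sigma <- sqrt(colMeans(sweep(x, 2, mu, "-")^2))
    sigma[sigma < 1e-12] <- 1
    xs <- sweep(sweep(x, 2, mu, "-"), 2, sigma, "/")
    if (nrow(unique(xs)) < k) {
      abort("fewer distinct voxel feature vectors than clusters.")
    }
    if (k == 1) {
      centers <- matrix(colMeans(xs), 1)
    } else {
      best <- NULL
      for (r in seq_len(n_restarts)) {
        init <- kmeanspp_centers(xs, k)
        fit <- suppressWarnings(
          kmeans(xs, centers = init, iter.max = 100, algorithm = "Lloyd")
        )
        if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
      }
      centers <- best$centers
    }
    colnames(centers) <- fn
    # label order: ascending centroid HU on the original scale
    hu_raw <- centers[, "hu"] * sigma[["hu"]] + mu[["hu"]]
    ord <- order(hu_raw)
    centers <- centers[ord, , drop = FALSE]
    rownames(centers) <- paste0("habitat_", seq_len(k))
    structure(
      list(
        k = as.integer(k), centers = centers,
        standardization = list(mean = mu, sd = sigma),
        label_order_rule = "ascending_mean_hu",
        seed = as.integer(seed)
      ),
      class = "habitat_model"
    )
  })
}

#' Assign habitat labels to the voxels of one patient
#'
#' Applies the model's standardization to the voxel features and labels each
#' voxel with its nearest centroid (Euclidean); exact ties resolve to the
#' smallest habitat index.
#'
#' @param stack A `voxel_feature_stack` aligned to `mask`.
#' @param mask The patient's [tumor_mask()].
#' @param model A fitted [fit_habitat_model()].
#' @return A `habitat_map`: integer grid 0 outside the mask and habitat
#'   label 1..k inside, with `spacing_mm` and `k` attached.
#' @export
assign_habitats <- function(stack, mask, model) {
  fn <- habitat_feature_names()
  if (!all(fn %in% names(stack))) abort("feature dimension mismatch.")
  x <- as.matrix(stack[, fn])
  st <- model$standardization
  xs <- sweep(sweep(x, 2, st$mean, "-"), 2, st$sd, "/")
  # squared distances to centroids; ties -> smallest label via max.col "first"
  cc <- model$centers
  d2 <- matrix(0, nrow(xs), nrow(cc))
  for (h in seq_len(nrow(cc))) {
    d2[, h] <- rowSums(sweep(xs, 2, cc[h, ], "-")^2)
  }
  lab <- max.col(-d2, ties.method = "first")
  grid <- array(0L, dim(mask$grid))
  grid[stack$voxel_index] <- lab
  structure(
    list(grid = grid, spacing_mm = mask$spacing_mm, k = model$k),
    class = "habitat_map"
  )
}

#' Habitat composition of a habitat map
#'
#' @param map A `habitat_map`.
#' @return A length-k numeric vector of nonnegative habitat volume
#'   fractions summing to 1.
#' @export
habitat_composition <- function(map) {
  inmask <- map$grid[map$grid > 0]
  tabulate(inmask, nbins = map$k) / length(inmask)
}

#' @export
print.habitat_model <- function(x, ...) {
  cat(sprintf(
    "<habitat_model> k = %d, rule = %s, seed = %d\n",
    x$k, x$label_order_rule, x$seed
  ))
  print(round(x$centers, 3))
  invisible(x)
}

#' @export
print.habitat_map <- function(x, ...) {
  comp <- habitat_composition(x)
  cat(sprintf(
    "<habitat_map> %s voxels, k = %d, composition: %s\n",
    paste(dim(x$grid), collapse = "x"), x$k,
    paste(sprintf("%.2f", comp), collapse = " ")
  ))
  invisible(x)
}

#' Tidy a habitat model into a centroid tibble
#'
#' @param x A `habitat_model`.
#' @param ... Unused.
#' @return A tibble with one row per habitat and one column per
#'   standardized feature coordinate.
#' @export
tidy.habitat_model <- function(x, ...) {
  out <- tibble::as_tibble(x$centers)
  out$habitat <- seq_len(x$k)
  dplyr::relocate(out, "habitat")
}
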