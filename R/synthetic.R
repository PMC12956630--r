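#' Synthetic cohort configuration
#'
#' Defines the generative model for CT-like tumor volumes with planted,
#' spatially coherent texture subregions, per-patient clinical covariates,
#' and a binary label drawn from a logistic model on the planted habitat
#' composition plus standardized clinical covariates.
#'
#' Planted subregions are grown from seeded Voronoi sites inside the mask
#' and their borders are perturbed by smooth random fields, giving contiguous
#' blobs reminiscent of necrotic/proliferative zones. Each subregion has its
#' own mean attenuation, noise amplitude and correlation length, so regions
#' differ in local entropy and contrast as well as raw HU.
#'
#' @param n_train,n_test Cohort sizes (defaults mirror a 168/60 two-center
#'   design).
#' @param k_true Number of planted subregions (>= 1).
#' @param volume_shape Integer voxel grid shape.
#' @param spacing_mm Voxel spacing, mm.
#' @param tumor_diameter_range_mm Min/max maximum tumor diameter; the
#'   minimum must be >= 20 mm (lesions under 2 cm are excluded from habitat
#'   analysis as too small to carry spatial heterogeneity).
#' @param region_params Data frame with one row per planted subregion and
#'   columns `mean_hu`, `sd_hu` (>= 0), `smoothing_mm`.
#' @param label_coefficients List with `intercept`, `fraction_weights`
#'   (length `k_true`), and `clinical_weights` (named, applied to
#'   standardized covariates).
#' @param clinical_marginals Marginal distributions of the clinical table;
#'   see [default_clinical_marginals()].
#' @param boundary_wobble Amplitude of the smooth random perturbation of the
#'   planted Voronoi interfaces, as a fraction of tumor diameter (default
#'   0.10; 0 gives exact Voronoi cells).
#' @param site_bias_sd SD of the per-patient additive Voronoi site bias as a
#'   fraction of tumor diameter (default 0). Positive values make planted
#'   cell sizes — hence habitat fractions — vary more across patients
#'   (additively weighted Voronoi), useful when a wide habitat-composition
#'   distribution is wanted.
#' @param seed Integer master seed.
#' @return A validated `synthetic_config`.
#' @export
synthetic_config <- function(n_train = 168, n_test = 60, k_true = 3,
                             volume_shape = c(48, 48, 48),
                             spacing_mm = c(1, 1, 1),
                             tumor_diameter_range_mm = c(22, 34),
                             region_params = NULL,
                             label_coefficients = NULL,
                             clinical_marginals = default_clinical_marginals(),
                             boundary_wobble = 0.10,
                             site_bias_sd = 0,
                             seed = 1L) {
  if (k_true < 1) abort("`k_true` must be >= 1.")
  if (tumor_diameter_range_mm[1] < 20) {
    abort("minimum tumor diameter must be >= 20 mm (inclusion rule).")
  }
  if (diff(tumor_diameter_range_mm) < 0) abort("invalid diameter range.")
  if (is.null(region_params)) {
    defaults <- tibble::tibble(
      mean_hu = c(-20, 40, 100, 10, 70),
      sd_hu = c(4, 12, 30, 8, 18),
      smoothing_mm = c(0.6, 0.9, 1.3, 0.7, 1.1)
    )
    region_params <- defaults[rep_len(seq_len(5), k_true), ]
  }
  region_params <- tibble::as_tibble(region_params)
  if (nrow(region_params) != k_true) {
    abort("`region_params` must have one row per planted subregion.")
  }
  if (any(region_params$sd_hu < 0)) abort("all `sd_hu` must be >= 0.")
  if (is.null(label_coefficients)) {
    fw <- rep(0, k_true)
    fw[1] <- 2.5
    if (k_true >= 3) fw[k_true] <- -2.5
    label_coefficients <- list(
      intercept = -0.6,
      fraction_weights = fw,
      clinical_weights = c(history_tumor = 1.2, solid_diameter_mm = -0.4)
    )
  }
  if (length(label_coefficients$fraction_weights) != k_true) {
    abort("`fraction_weights` must have length `k_true`.")
  }
  for (nm in names(clinical_marginals$binary)) {
    p <- clinical_marginals$binary[[nm]]
    if (p < 0 || p > 1) abort("binary marginal probabilities must be in [0,1].")
  }
  # feasibility: the largest tumor must fit inside the grid with a margin
  extent <- (volume_shape - 1) * spacing_mm
  if (tumor_diameter_range_mm[2] > min(extent) - 2 * max(spacing_mm)) {
    abort("infeasible geometry: max diameter exceeds the volume extent.")
  }
  structure(
    list(
      n_train = as.integer(n_train), n_test = as.integer(n_test),
      k_true = as.integer(k_true),
      volume_shape = as.integer(volume_shape),
      spacing_mm = as.numeric(spacing_mm),
      tumor_diameter_range_mm = as.numeric(tumor_diameter_range_mm),
      region_params = region_params,
      label_coefficients = label_coefficients,
      clinical_marginals = clinical_marginals,
      boundary_wobble = boundary_wobble,
      site_bias_sd = site_bias_sd,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Default clinical covariate marginals
#'
#' Marginal distributions for the synthetic clinical table: truncated
#' normals for age and the two size measurements, Bernoulli rates for the
#' binary flags, and dichotomized tumor-marker categories (CA125 at
#' 700 U/mL, HE4 at 400 pmol/L). The default rates follow the pooled
#' prevalences of a two-cohort HGSOC case series; covariates are sampled
#' independently because only marginals are specified.
#'
#' @return A list with `continuous` (name -> c(mean, sd, min)) and `binary`
#'   (name -> prevalence) components.
#' @export
default_clinical_marginals <- function() {
  list(
    continuous = list(
      age_years = c(mean = 59.5, sd = 9.9, min = 30),
      size_mm = c(mean = 126, sd = 54, min = 25),
      solid_diameter_mm = c(mean = 50.5, sd = 24.3, min = 5)
    ),
    binary = list(
      hypertension = 0.241, diabetes = 0.066, history_tumor = 0.123,
      pd_infiltrative = 0.588, ascites = 0.482, mesenteric = 0.557,
      supradiaphragmatic = 0.342, bilateral = 0.487,
      ca125_high = 0.535, he4_high = 0.482
    )
  )
}

#' Generate one synthetic tumor volume
#'
#' Builds an ellipsoidal tumor mask whose maximum diameter is drawn from the
#' configured range, plants `k_true` contiguous subregions by perturbed
#' Voronoi growth from seeded sites, and fills each subregion with a
#' correlated Gaussian HU field (its own mean, amplitude and correlation
#' length) on top of a smooth background field. Deterministic given
#' `(config, patient_seed)`.
#'
#' @param config A [synthetic_config()].
#' @param patient_seed Non-negative integer seed for this patient.
#' @return A list with `volume` ([image_volume()]), `mask` ([tumor_mask()]),
#'   and `truth` (planted `region_map` array, `fractions`, `seed`).
#' @export
generate_tumor_volume <- function(config, patient_seed) {
  stopifnot(inherits(config, "synthetic_config"), patient_seed >= 0)
  with_seed(patient_seed, {
    dm <- config$volume_shape
    sp <- config$spacing_mm
    k <- config$k_true

    diam <- runif(1, config$tumor_diameter_range_mm[1],
                  config$tumor_diameter_range_mm[2])
    radii <- rep(diam / 2, 3)
    shrink <- runif(2, 0.8, 1)
    radii[sample.int(3, 2)] <- radii[2:3] * shrink
    radii[which.max(radii)] <- diam / 2 # the max diameter is exactly diam

    # physical coordinates of voxel centers, tumor centered in the grid
    ctr <- (dm - 1) / 2 * sp
    xs <- (seq_len(dm[1]) - 1) * sp[1]
    ys <- (seq_len(dm[2]) - 1) * sp[2]
    zs <- (seq_len(dm[3]) - 1) * sp[3]
    dx2 <- ((xs - ctr[1]) / radii[1])^2
    dy2 <- ((ys - ctr[2]) / radii[2])^2
    dz2 <- ((zs - ctr[3]) / radii[3])^2
    r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    mg <- r2 <= 1

    in_idx <- which(mg)
    coords <- arrayInd(in_idx, dm)
    phys <- sweep(coords - 1, 2, sp, "*")

    # planted subregions: Voronoi sites + smooth boundary perturbation.
    # Sites are drawn by best-candidate sampling (farthest of a handful of
    # candidates from the already-chosen sites), so cells are compact blobs
    # rather than thin slivers.
    sites <- phys[sample.int(nrow(phys), 1), , drop = FALSE]
    while (nrow(sites) < k) {
      cand <- phys[sample.int(nrow(phys), 24), , drop = FALSE]
      dmin <- apply(cand, 1, function(p) {
        min(sqrt(rowSums(sweep(sites, 2, p, "-")^2)))
      })
      sites <- rbind(sites, cand[which.max(dmin), ])
    }
    # random site-to-region assignment: no region index is systematically
    # the central (largest) cell
    sites <- sites[sample.int(k), , drop = FALSE]
    wob_amp <- config$boundary_wobble * diam
    bias <- rnorm(k, 0, (config$site_bias_sd %||% 0) * diam)
    score <- matrix(0, nrow(phys), k)
    for (h in seq_len(k)) {
      d <- sqrt(rowSums(sweep(phys, 2, sites[h, ], "-")^2))
      wob <- gaussian_field(dm, sp, corr_len_mm = 0.25 * diam)
      score[, h] <- d + bias[h] + wob_amp * wob[in_idx]
    }
    region <- max.col(-score, ties.method = "first")
    region_map <- array(0L, dm)
    region_map[in_idx] <- region

    # intensity: smooth background + per-region correlated fields
    vg <- 10 + 15 * gaussian_field(dm, sp, corr_len_mm = 3)
    for (h in seq_len(k)) {
      rp <- config$region_params[h, ]
      vox <- in_idx[region == h]
      if (!length(vox)) next
      if (rp$sd_hu > 0) {
        f <- gaussian_field(dm, sp, corr_len_mm = rp$smoothing_mm)
        vg[vox] <- rp$mean_hu + rp$sd_hu * f[vox]
      } else {
        vg[vox] <- rp$mean_hu
      }
    }

    fractions <- tabulate(region, nbins = k) / length(region)
    list(
      volume = image_volume(vg, spacing_mm = sp),
      mask = tumor_mask(mg, spacing_mm = sp),
      truth = list(
        region_map = region_map,
        fractions = fractions,
        seed = as.integer(patient_seed)
      )
    )
  })
}

#' Generate a full synthetic cohort
#'
#' Generates `n_train + n_test` cases with cohort assignment, a clinical
#' covariate table drawn from the configured marginals, and binary labels
#' from the logistic model
#' `logit(p) = intercept + fraction_weights . fractions +
#'  clinical_weights . standardized covariates`.
#' Continuous covariates are standardized with their configured marginal
#' mean/sd; binary ones with their Bernoulli mean/sd, so the coefficients are
#' on a common per-SD scale. Deterministic given `config` (patient seeds are
#' drawn once from the master seed).
#'
#' @param config A [synthetic_config()].
#' @param keep_volumes If `FALSE`, drop the voxel grids and keep only truth
#'   fractions (useful for label-model studies at large n).
#' @return A list with `cases` (per-patient volume/mask/truth), `clinical`
#'   (tibble), `labels` (0/1 integer), `cohort` (train/test), and `truth`
#'   (tibble of planted fractions, the coefficients and seeds used).
#' @export
generate_cohort <- function(config, keep_volumes = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_train + config$n_test
  with_seed(config$seed, {
    patient_seeds <- sample.int(.Machine$integer.max - 1L, n)
    clinical <- sample_clinical(config$clinical_marginals, n)

    cases <- vector("list", n)
    fracs <- matrix(0, n, config$k_true)
    for (i in seq_len(n)) {
      case <- generate_tumor_volume(config, patient_seeds[i])
      fracs[i, ] <- case$truth$fractions
      if (!keep_volumes) case$volume <- case$mask <- NULL
      cases[[i]] <- case
    }

    lc <- config$label_coefficients
    eta <- rep(lc$intercept, n) + as.vector(fracs %*% lc$fraction_weights)
    cw <- lc$clinical_weights
    std <- standardize_clinical(clinical, config$clinical_marginals)
    for (nm in names(cw)) {
      if (!nm %in% names(std)) abort(paste0("unknown clinical weight: ", nm))
      eta <- eta + cw[[nm]] * std[[nm]]
    }
    labels <- rbinom(n, 1, plogis(eta))
    cohort <- rep(c("train", "test"), c(config$n_train, config$n_test))

    truth <- tibble::as_tibble(fracs, .name_repair = ~ paste0("frac_", seq_len(config$k_true)))
    truth$patient_id <- seq_len(n)
    truth$seed <- patient_seeds
    truth <- dplyr::relocate(truth, "patient_id")

    clinical$patient_id <- seq_len(n)
    clinical$cohort <- cohort
    clinical$label <- labels
    clinical <- dplyr::relocate(clinical, "patient_id", "cohort", "label")

    list(
      cases = cases, clinical = clinical, labels = labels, cohort = cohort,
      truth = list(
        fractions = truth,
        label_coefficients = lc,
        seed = config$seed
      )
    )
  })
}

sample_clinical <- function(marginals, n) {
  out <- list()
  for (nm in names(marginals$continuous)) {
    m <- marginals$continuous[[nm]]
    out[[nm]] <- pmax(m[["min"]], rnorm(n, m[["mean"]], m[["sd"]]))
  }
  for (nm in names(marginals$binary)) {
    out[[nm]] <- rbinom(n, 1, marginals$binary[[nm]])
  }
  tibble::as_tibble(out)
}

standardize_clinical <- function(clinical, marginals) {
  std <- clinical
  for (nm in names(marginals$continuous)) {
    m <- marginals$continuous[[nm]]
    std[[nm]] <- (clinical[[nm]] - m[["mean"]]) / m[["sd"]]
  }
  for (nm in names(marginals$binary)) {
    p <- marginals$binary[[nm]]
    s <- sqrt(p * (1 - p))
    if (s < 1e-12) s <- 1
    std[[nm]] <- (clinical[[nm]] - p) / s
  }
  std
}

#' Randomly perturb a tumor mask boundary
#'
#' Emulates re-segmentation variability between readers: the mask is
#' randomly dilated or eroded with a ball structuring element whose radius is
#' drawn up to `magnitude_mm`. Dice overlap with the input decreases
#' monotonically in expectation as the magnitude grows. An erosion that
#' would empty the mask falls back to the original mask (floor rule), so the
#' result is always nonempty.
#'
#' @param mask A nonempty [tumor_mask()].
#' @param magnitude_mm Nonnegative perturbation scale in mm; 0 returns the
#'   mask unchanged.
#' @param seed Integer seed.
#' @return A perturbed [tumor_mask()].
#' @export
perturb_mask <- function(mask, magnitude_mm, seed = 1L) {
  if (!any(mask$grid)) abort("mask is empty (degenerate-mask error).")
  if (magnitude_mm < 0) abort("`magnitude_mm` must be nonnegative.")
  if (magnitude_mm == 0) return(mask)
  with_seed(seed, {
    r <- runif(1, 0.25 * magnitude_mm, magnitude_mm)
    dilate <- runif(1) < 0.5
    offs <- ball_offsets(r, mask$spacing_mm)
    if (nrow(offs) <= 1) return(mask)
    g <- mask$grid
    acc <- if (dilate) array(FALSE, dim(g)) else array(TRUE, dim(g))
    for (i in seq_len(nrow(offs))) {
      s <- shift_array(g, offs[i, ], fill = !dilate)
      acc <- if (dilate) acc | s else acc & s
    }
    if (!any(acc)) return(mask) # erosion emptied the mask: keep the original
    tumor_mask(acc, spacing_mm = mask$spacing_mm, origin = mask$origin)
  })
}

#' Dice overlap between two masks
#' @param a,b [tumor_mask()] objects on the same grid.
#' @return Scalar Dice coefficient in \[0, 1\].
#' @export
dice_overlap <- function(a, b) {
  2 * sum(a$grid & b$grid) / (sum(a$grid) + sum(b$grid))
}
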