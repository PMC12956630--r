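#' Extraction configuration for region radiomics
#'
#' @param binning Either `list(method = "fixed_width", width = 25)` (default;
#'   fixed 25-HU bins, the preferred choice for calibrated CT intensities) or
#'   `list(method = "fixed_count", n_bins = 32)`.
#' @param gldm_alpha Level-difference tolerance for dependence counting
#'   (default 0).
#' @return An `extract_config` list.
#' @export
extract_config <- function(binning = list(method = "fixed_width", width = 25),
                           gldm_alpha = 0) {
  if (!binning$method %in% c("fixed_width", "fixed_count")) {
    abort("binning method must be 'fixed_width' or 'fixed_count'.")
  }
  structure(list(binning = binning, gldm_alpha = gldm_alpha),
            class = "extract_config")
}

#' Discretize region intensities to integer gray levels
#'
#' Fixed-bin-width: `level = floor((x - min_region) / width) + 1`.
#' Fixed-bin-count: equal-width bins over the region range (the region
#' maximum falls in the top bin); a constant region maps to the single
#' level 1.
#'
#' @param volume An [image_volume()].
#' @param region Logical array marking the region (nonempty).
#' @param binning As in [extract_config()].
#' @return A `disc_volume`: integer `grid` (0 outside the region), `ng`
#'   (number of gray levels), and the binning used.
#' @export
discretize <- function(volume, region,
                       binning = list(method = "fixed_width", width = 25)) {
  if (!any(region)) abort("empty region.")
  vals <- volume$grid[region]
  rng <- range(vals)
  if (binning$method == "fixed_width") {
    lev <- as.integer(floor((vals - rng[1]) / binning$width)) + 1L
    ng <- max(lev)
  } else {
    nb <- binning$n_bins
    if (diff(rng) < 1e-12) {
      lev <- rep(1L, length(vals))
      ng <- 1L
    } else {
      w <- diff(rng) / nb
      lev <- clamp(as.integer(floor((vals - rng[1]) / w)) + 1L, 1L, nb)
      ng <- as.integer(nb)
    }
  }
  grid <- array(0L, dim(volume$grid))
  grid[region] <- lev
  structure(
    list(grid = grid, ng = as.integer(ng), binning = binning,
         spacing_mm = volume$spacing_mm),
    class = "disc_volume"
  )
}

#' First-order intensity statistics of a region
#'
#' Moments are population moments (denominator N); skewness and kurtosis of
#' a constant region are defined as 0; entropy is base-2 on the discretized
#' histogram with `0*log(0) = 0`.
#'
#' @inheritParams discretize
#' @return Named numeric vector of first-order features.
#' @export
firstorder_features <- function(volume, region,
                                binning = list(method = "fixed_width",
                                               width = 25)) {
  if (!any(region)) abort("empty region.")
  x <- volume$grid[region]
  n <- length(x)
  m <- mean(x)
  v <- mean((x - m)^2)
  s <- sqrt(v)
  skew <- if (s < 1e-12) 0 else mean((x - m)^3) / s^3
  kurt <- if (s < 1e-12) 0 else mean((x - m)^4) / v^2
  disc <- discretize(volume, region, binning)
  p <- tabulate(disc$grid[region], nbins = disc$ng)
  voxvol <- prod(volume$spacing_mm)
  c(
    mean = m, median = median(x), minimum = min(x), maximum = max(x),
    range = diff(range(x)), variance = v, skewness = skew, kurtosis = kurt,
    energy = sum(x^2), total_energy = sum(x^2) * voxvol,
    root_mean_squared = sqrt(mean(x^2)), entropy = entropy_bits(p)
  )
}

#' Shape features of a tumor mask
#'
#' Volume is voxel count times voxel volume; surface area comes from the
#' boundary-face mesh (every mask voxel face adjacent to background
#' contributes its physical face area); sphericity is
#' `pi^(1/3) * (6V)^(2/3) / A`; the maximum 3D diameter is the largest
#' pairwise distance between boundary voxel centers.
#'
#' @param mask A nonempty [tumor_mask()].
#' @return Named numeric vector of shape features.
#' @export
shape_features <- function(mask) {
  if (!any(mask$grid)) abort("empty mask.")
  g <- mask$grid
  sp <- mask$spacing_mm
  voxvol <- prod(sp)
  vol <- sum(g) * voxvol

  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  area <- 0
  exposed_any <- array(FALSE, dim(g))
  for (ax in 1:3) {
    for (sgn in c(-1L, 1L)) {
      d <- c(0L, 0L, 0L)
      d[ax] <- sgn
      nb <- shift_array(g, d, fill = FALSE)
      exposed <- g & !nb
      area <- area + sum(exposed) * face_area[ax]
      exposed_any <- exposed_any | exposed
    }
  }

  bidx <- which(exposed_any)
  coords <- sweep(arrayInd(bidx, dim(g)) - 1, 2, sp, "*")
  maxd <- 0
  nb <- nrow(coords)
  if (nb > 1) {
    step <- 512L
    for (i0 in seq(1L, nb, by = step)) {
      i1 <- min(nb, i0 + step - 1L)
      block <- coords[i0:i1, , drop = FALSE]
      d2 <- outer(rowSums(block^2), rowSums(coords^2), "+") -
        2 * block %*% t(coords)
      maxd <- max(maxd, sqrt(max(0, max(d2))))
    }
  }
  sph <- pi^(1 / 3) * (6 * vol)^(2 / 3) / area
  c(
    volume_mm3 = vol, surface_area_mm2 = area, sphericity = sph,
    max_diameter_mm = maxd, voxel_count = sum(g)
  )
}

glcm_norm <- function(counts, ng) {
  m <- matrix(counts, ng, ng)
  tot <- sum(m)
  if (tot == 0) return(NULL)
  m / tot
}

glcm_features_one <- function(p) {
  ng <- nrow(p)
  i <- row(p)
  j <- col(p)
  joint_energy <- sum(p^2)
  joint_entropy <- entropy_bits(as.vector(p))
  pd <- vapply(0:(ng - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  diff_entropy <- entropy_bits(pd)
  contrast <- sum(p * (i - j)^2)
  px <- rowSums(p)
  mu_x <- sum(seq_len(ng) * px)
  sd_x <- sqrt(sum((seq_len(ng) - mu_x)^2 * px))
  correlation <- if (sd_x < 1e-12) 1 else {
    (sum(i * j * p) - mu_x^2) / sd_x^2
  }
  idm <- sum(p / (1 + (i - j)^2))
  c(
    joint_energy = joint_energy, joint_entropy = joint_entropy,
    difference_entropy = diff_entropy, contrast = contrast,
    correlation = correlation, inverse_difference_moment = idm
  )
}

#' Gray-level co-occurrence (GLCM) features
#'
#' Symmetric co-occurrence matrices are built for the 13 unique 3D unit
#' offsets, normalized to probabilities, and each feature is averaged over
#' the offsets. A single-level region gives joint energy 1 and all
#' entropies 0 (valid degenerate case).
#'
#' @param disc A [discretize()]d region.
#' @return Named numeric vector of GLCM features.
#' @export
glcm_features <- function(disc) {
  counts <- cpp_glcm(as.integer(disc$grid), as.integer(dim(disc$grid)),
                     disc$ng)
  feats <- NULL
  for (o in seq_len(ncol(counts))) {
    p <- glcm_norm(counts[, o], disc$ng)
    if (is.null(p)) next
    feats <- rbind(feats, glcm_features_one(p))
  }
  if (is.null(feats)) {
    # no co-occurring pairs at all (single isolated voxel)
    return(c(joint_energy = 1, joint_entropy = 0, difference_entropy = 0,
             contrast = 0, correlation = 1, inverse_difference_moment = 1))
  }
  colMeans(feats)
}

glrlm_features_one <- function(m) {
  # m: ng x maxlen run counts
  nr <- sum(m)
  if (nr == 0) return(NULL)
  np <- sum(m * matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE))
  jl <- seq_len(ncol(m))
  rj <- colSums(m)
  gi <- rowSums(m)
  c(
    short_run_emphasis = sum(rj / jl^2) / nr,
    long_run_emphasis = sum(rj * jl^2) / nr,
    gray_level_nonuniformity = sum(gi^2) / nr,
    run_length_nonuniformity = sum(rj^2) / nr,
    run_percentage = nr / np
  )
}

#' Gray-level run-length (GLRLM) features
#'
#' Maximal same-level runs are counted along each of the 13 directions
#' (runs truncate at the region boundary) and features are averaged over
#' directions.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of GLRLM features.
#' @export
glrlm_features <- function(disc) {
  maxlen <- max(dim(disc$grid))
  counts <- cpp_glrlm(as.integer(disc$grid), as.integer(dim(disc$grid)),
                      disc$ng, as.integer(maxlen))
  feats <- NULL
  for (o in seq_len(ncol(counts))) {
    m <- matrix(counts[, o], disc$ng, maxlen, byrow = TRUE)
    f <- glrlm_features_one(m)
    if (!is.null(f)) feats <- rbind(feats, f)
  }
  colMeans(feats)
}

#' Gray-level size-zone (GLSZM) features
#'
#' Zones are 26-connected components of equal gray level; the matrix is
#' direction-free.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of GLSZM features.
#' @export
glszm_features <- function(disc) {
  zones <- cpp_glszm_zones(as.integer(disc$grid), as.integer(dim(disc$grid)))
  sizes <- zones[, 2]
  nz <- nrow(zones)
  np <- sum(disc$grid > 0)
  size_tab <- table(sizes)
  s <- as.numeric(names(size_tab))
  cnt <- as.numeric(size_tab)
  gl_tab <- table(zones[, 1])
  c(
    small_area_emphasis = sum(cnt / s^2) / nz,
    large_area_emphasis = sum(cnt * s^2) / nz,
    zone_size_nonuniformity = sum(cnt^2) / nz,
    gray_level_nonuniformity = sum(as.numeric(gl_tab)^2) / nz,
    zone_percentage = nz / np
  )
}

#' Neighborhood gray-tone difference (NGTDM) features
#'
#' `s(i)` sums, over region voxels of level `i` that have at least one
#' in-region 26-neighbor, the absolute difference between `i` and the mean
#' neighbor level. Contrast, coarseness and busyness follow the standard
#' closed forms; a single-level region has contrast and busyness 0, and
#' coarseness is capped at 1e6 when `sum(p_i s_i)` vanishes.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of NGTDM features.
#' @export
ngtdm_features <- function(disc) {
  acc <- cpp_ngtdm(as.integer(disc$grid), as.integer(dim(disc$grid)), disc$ng)
  ni <- acc[, 1]
  si <- acc[, 2]
  nvp <- sum(ni)
  present <- which(ni > 0)
  ngp <- length(present)
  pi_ <- ni / max(nvp, 1)
  contrast <- 0
  if (ngp > 1 && nvp > 0) {
    lv <- seq_len(disc$ng)
    c1 <- sum(outer(pi_[present], pi_[present]) *
                outer(lv[present], lv[present], "-")^2)
    contrast <- c1 / (ngp * (ngp - 1)) * sum(si) / nvp
  }
  denom <- sum(pi_ * si)
  coarseness <- if (denom < 1e-12) 1e6 else 1 / denom
  busyness <- 0
  if (ngp > 1) {
    lv <- seq_len(disc$ng)
    num <- sum(pi_ * si)
    den <- sum(abs(outer(lv[present] * pi_[present],
                         lv[present] * pi_[present], "-")))
    if (den > 1e-12) busyness <- num / den
  }
  c(contrast = contrast, coarseness = coarseness, busyness = busyness)
}

#' Gray-level dependence (GLDM) features
#'
#' The dependence of a voxel is the number of in-region 26-neighbors whose
#' level differs by at most `alpha` (default 0); the matrix is over
#' (level, dependence), with dependence size `j = dependence + 1` in the
#' emphasis formulas.
#'
#' @inheritParams glcm_features
#' @param alpha Level-difference tolerance.
#' @return Named numeric vector of GLDM features.
#' @export
gldm_features <- function(disc, alpha = 0) {
  m <- cpp_gldm(as.integer(disc$grid), as.integer(dim(disc$grid)), disc$ng,
                as.integer(alpha))
  nz <- sum(m)
  jl <- seq_len(ncol(m)) # dependence + 1
  dj <- colSums(m)
  gi <- rowSums(m)
  c(
    small_dependence_emphasis = sum(dj / jl^2) / nz,
    large_dependence_emphasis = sum(dj * jl^2) / nz,
    dependence_nonuniformity = sum(dj^2) / nz,
    gray_level_nonuniformity = sum(gi^2) / nz
  )
}

region_feature_vector <- function(volume, region, config) {
  disc <- discretize(volume, region, config$binning)
  c(
    prefix_names("firstorder",
                 firstorder_features(volume, region, config$binning)),
    prefix_names("glcm", glcm_features(disc)),
    prefix_names("glrlm", glrlm_features(disc)),
    prefix_names("glszm", glszm_features(disc)),
    prefix_names("ngtdm", ngtdm_features(disc)),
    prefix_names("gldm", gldm_features(disc, config$gldm_alpha))
  )
}

prefix_names <- function(prefix, x) {
  names(x) <- paste0(prefix, "_", names(x))
  x
}

#' Extract whole-tumor and per-habitat radiomic features for one case
#'
#' Computes the full feature vector over the whole mask (intensity and
#' texture families plus shape) and over each habitat stratum (intensity and
#' texture only: strata may be disconnected, so mesh shape descriptors are
#' reserved for the whole tumor). An empty habitat contributes missing
#' values for all its features, so the feature count per region is constant
#' across patients.
#'
#' @param volume A windowed [image_volume()].
#' @param mask The paired [tumor_mask()].
#' @param habitat_map Optional `habitat_map` from [assign_habitats()].
#' @param config An [extract_config()].
#' @return A one-row tibble with columns `whole_<family>_<name>` and
#'   `habitat_<h>_<family>_<name>`.
#' @export
extract_case <- function(volume, mask, habitat_map = NULL,
                         config = extract_config()) {
  check_aligned(volume, mask)
  out <- c(
    prefix_names("whole_shape", shape_features(mask)),
    prefix_names("whole", region_feature_vector(volume, mask$grid, config))
  )
  if (!is.null(habitat_map)) {
    template <- region_feature_template(config)
    for (h in seq_len(habitat_map$k)) {
      region <- habitat_map$grid == h
      vec <- if (any(region)) {
        region_feature_vector(volume, region, config)
      } else {
        setNames(rep(NA_real_, length(template)), template)
      }
      out <- c(out, prefix_names(paste0("habitat_", h), vec))
    }
  }
  tibble::as_tibble(as.list(out))
}

region_feature_template <- function(config) {
  vol <- image_volume(array(c(0, 25, 50, 50, 25, 0, 10, 30), c(2, 2, 2)))
  names(region_feature_vector(vol, array(TRUE, c(2, 2, 2)), config))
}
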