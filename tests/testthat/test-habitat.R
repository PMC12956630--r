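# build a voxel_feature_stack directly from a matrix of feature vectors
fake_stack <- function(x, idx = seq_len(nrow(x))) {
  colnames(x) <- c("fo_entropy", "glcm_diff_entropy", "glcm_joint_energy",
                   "glcm_joint_entropy", "ngtdm_contrast", "hu")
  out <- tibble::as_tibble(x)
  out$voxel_index <- idx
  structure(dplyr::relocate(out, "voxel_index"),
            class = c("voxel_feature_stack", class(out)))
}

test_that("k = 1 yields a single centroid at the standardized origin", {
  set.seed(1)
  st <- fake_stack(matrix(rnorm(600), 100, 6))
  m <- fit_habitat_model(st, k = 1, seed = 2)
  expect_equal(unname(m$centers[1, ]), rep(0, 6), tolerance = 1e-10)
})

test_that("well-separated clouds are recovered and labels follow mean HU", {
  set.seed(2)
  lo <- matrix(rnorm(6 * 300, -3, 0.2), ncol = 6)
  hi <- matrix(rnorm(6 * 300, 3, 0.2), ncol = 6)
  st <- fake_stack(rbind(lo, hi))
  m <- fit_habitat_model(st, k = 2, seed = 1)
  # habitat 1 = lower attenuation
  expect_lt(m$centers[1, "hu"], m$centers[2, "hu"])
  # centroids near the true standardized cluster means
  truth <- scale(rbind(lo, hi))
  mu1 <- colMeans(truth[1:300, ])
  expect_lt(max(abs(m$centers[1, ] - mu1)), 0.1)
})

test_that("duplicating every voxel row leaves the optimum unchanged", {
  set.seed(3)
  x <- rbind(matrix(rnorm(150, -2), 25, 6), matrix(rnorm(150, 2), 25, 6))
  m1 <- fit_habitat_model(fake_stack(x), k = 2, seed = 4)
  m2 <- fit_habitat_model(fake_stack(rbind(x, x)), k = 2, seed = 4)
  expect_equal(m1$centers, m2$centers, tolerance = 1e-8)
})

test_that("assignment is nearest-centroid with ties to the smallest label", {
  centers <- matrix(0, 3, 6)
  centers[1, ] <- -1; centers[2, ] <- 0; centers[3, ] <- 1
  colnames(centers) <- c("fo_entropy", "glcm_diff_entropy",
                         "glcm_joint_energy", "glcm_joint_entropy",
                         "ngtdm_contrast", "hu")
  rownames(centers) <- paste0("habitat_", 1:3)
  model <- structure(
    list(k = 3L, centers = centers,
         standardization = list(mean = setNames(rep(0, 6), colnames(centers)),
                                sd = setNames(rep(1, 6), colnames(centers))),
         label_order_rule = "ascending_mean_hu", seed = 1L),
    class = "habitat_model"
  )
  mask <- tumor_mask(array(TRUE, c(3, 1, 1)))
  x <- rbind(rep(0, 6),    # exactly centroid 2 -> label 2
             rep(1, 6),    # exactly centroid 3 -> label 3
             rep(0.5, 6))  # equidistant between 2 and 3 -> smaller label 2
  hm <- assign_habitats(fake_stack(x, idx = 1:3), mask, model)
  expect_equal(as.vector(hm$grid), c(2, 3, 2))
})

test_that("applying a model to its training voxels reproduces the fit", {
  set.seed(5)
  x <- rbind(matrix(rnorm(300, -2), 50, 6), matrix(rnorm(300, 2), 50, 6))
  st <- fake_stack(x)
  mask <- tumor_mask(array(TRUE, c(100, 1, 1)))
  m <- fit_habitat_model(st, k = 2, seed = 6, max_voxels_per_patient = 1e6)
  hm <- assign_habitats(st, mask, m)
  # converged k-means: nearest-centroid assignment is the fit's partition
  lab <- hm$grid[st$voxel_index]
  expect_equal(sort(unique(lab)), 1:2)
  within <- sapply(1:2, function(h) {
    st_std <- scale(x, center = m$standardization$mean,
                    scale = m$standardization$sd)
    sum(sweep(st_std[lab == h, , drop = FALSE], 2, m$centers[h, ])^2)
  })
  # any relabeling would not decrease the within-cluster sum of squares
  expect_lt(sum(within) / nrow(x), 6.5)
})

test_that("habitat maps and compositions are consistent", {
  cfg <- tiny_config(k_true = 3)
  case <- generate_tumor_volume(cfg, 6)
  st <- voxel_feature_map(apply_window(case$volume), case$mask)
  m <- fit_habitat_model(st, k = 3, seed = 1)
  hm <- assign_habitats(st, case$mask, m)
  expect_identical(hm$grid > 0, case$mask$grid)
  comp <- habitat_composition(hm)
  expect_length(comp, 3)
  expect_true(all(comp >= 0))
  expect_equal(sum(comp), 1, tolerance = 1e-12)
})

test_that("a single-habitat map has an indicator composition", {
  grid <- array(0L, c(4, 4, 4))
  grid[2:3, 2:3, 2:3] <- 2L
  map <- structure(list(grid = grid, spacing_mm = c(1, 1, 1), k = 5L),
                   class = "habitat_map")
  expect_equal(habitat_composition(map), c(0, 1, 0, 0, 0))
})

test_that("perfect assignment reproduces the planted fractions exactly", {
  # three point-mass clusters in feature space, one per planted region
  set.seed(7)
  region <- sample(1:3, 200, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  x <- matrix(0, 200, 6) # inert texture dims: constant across regions
  x[, 6] <- c(-10, 0, 10)[region] # hu separates the regions exactly
  x[, 1] <- c(1, 2, 3)[region]
  st <- fake_stack(x)
  mask <- tumor_mask(array(TRUE, c(200, 1, 1)))
  m <- fit_habitat_model(st, k = 3, seed = 8, max_voxels_per_patient = 1e6)
  hm <- assign_habitats(st, mask, m)
  comp <- habitat_composition(hm)
  expect_equal(comp, tabulate(region, 3) / 200, tolerance = 1e-12)
})

test_that("habitat labeling is stable under patient order permutation", {
  cfg <- tiny_config(k_true = 3)
  cases <- lapply(1:4, function(s) generate_tumor_volume(cfg, s))
  stacks <- lapply(cases, function(cs)
    voxel_feature_map(apply_window(cs$volume), cs$mask))
  m1 <- fit_habitat_model(stacks, k = 3, seed = 9)
  m2 <- fit_habitat_model(stacks[c(3, 1, 4, 2)], k = 3, seed = 9)
  lab1 <- assign_habitats(stacks[[1]], cases[[1]]$mask, m1)
  lab2 <- assign_habitats(stacks[[1]], cases[[1]]$mask, m2)
  ari <- adjusted_rand_index(lab1$grid[cases[[1]]$mask$grid],
                             lab2$grid[cases[[1]]$mask$grid])
  expect_gt(ari, 0.95)
  # and the label-order rule keeps centroid HU ascending in both fits
  expect_true(!is.unsorted(m1$centers[, "hu"]))
  expect_true(!is.unsorted(m2$centers[, "hu"]))
})

test_that("refitting with the same inputs is bit-identical", {
  cfg <- tiny_config(k_true = 2)
  case <- generate_tumor_volume(cfg, 11)
  st <- voxel_feature_map(apply_window(case$volume), case$mask)
  m1 <- fit_habitat_model(st, k = 2, seed = 3)
  m2 <- fit_habitat_model(st, k = 2, seed = 3)
  expect_identical(m1$centers, m2$centers)
})

test_that("degenerate fits error clearly", {
  x <- matrix(1, 10, 6) # all-identical voxel vectors
  expect_error(fit_habitat_model(fake_stack(x), k = 2, seed = 1), "distinct")
  expect_error(fit_habitat_model(fake_stack(x[1:3, ]), k = 5, seed = 1),
               "fewer")
})

test_that("tidy and JSON round-trip preserve the model", {
  set.seed(10)
  st <- fake_stack(rbind(matrix(rnorm(120, -2), 20, 6),
                         matrix(rnorm(120, 2), 20, 6)))
  m <- fit_habitat_model(st, k = 2, seed = 2)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  path <- tempfile(fileext = ".json")
  write_habitat_model(m, path)
  m2 <- read_habitat_model(path)
  expect_equal(m2$centers, m$centers, tolerance = 1e-12)
  expect_equal(m2$standardization$mean, m$standardization$mean,
               tolerance = 1e-12)
})
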