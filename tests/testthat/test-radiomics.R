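test_that("discretization follows the closed-form bin rules", {
  v <- image_volume(array(c(0, 25, 50, 10, 10, 10, 10, 10), c(2, 2, 2)))
  region <- array(FALSE, c(2, 2, 2))
  region[1:3] <- TRUE # values 0, 25, 50
  d <- discretize(v, region, list(method = "fixed_width", width = 25))
  expect_equal(sort(d$grid[region]), c(1, 2, 3))
  expect_equal(d$ng, 3)

  const <- image_volume(array(7, c(3, 3, 3)))
  dall <- discretize(const, array(TRUE, c(3, 3, 3)),
                     list(method = "fixed_width", width = 25))
  expect_true(all(dall$grid == 1))
  expect_equal(dall$ng, 1)
  dcnt <- discretize(const, array(TRUE, c(3, 3, 3)),
                     list(method = "fixed_count", n_bins = 8))
  expect_true(all(dcnt$grid == 1))
  expect_equal(dcnt$ng, 1)

  set.seed(1)
  vol <- array(rnorm(125, 0, 40), c(5, 5, 5))
  region <- array(TRUE, c(5, 5, 5))
  B <- 6
  d2 <- discretize(image_volume(vol), region,
                   list(method = "fixed_count", n_bins = B))
  rng <- range(vol)
  w <- diff(rng) / B
  expected <- pmin(pmax(floor((vol - rng[1]) / w) + 1, 1), B)
  expect_equal(as.vector(d2$grid), as.vector(expected))
  expect_error(discretize(image_volume(vol), array(FALSE, c(5, 5, 5)),
                          list(method = "fixed_width", width = 25)),
               "empty")
})

test_that("first-order features match direct recomputation", {
  const <- image_volume(array(3, c(3, 3, 3)))
  f <- firstorder_features(const, array(TRUE, c(3, 3, 3)))
  expect_equal(f[["entropy"]], 0)
  expect_equal(f[["variance"]], 0)
  expect_equal(f[["skewness"]], 0)

  two <- image_volume(array(rep(c(0, 50), 32), c(4, 4, 4)))
  f2 <- firstorder_features(two, array(TRUE, c(4, 4, 4)),
                            list(method = "fixed_width", width = 50))
  expect_equal(f2[["entropy"]], 1)

  set.seed(2)
  vol <- array(rnorm(100, 20, 15), c(10, 10, 1))
  x <- as.vector(vol)
  f3 <- firstorder_features(image_volume(vol), array(TRUE, c(10, 10, 1)))
  expect_equal(f3[["mean"]], mean(x))
  expect_equal(f3[["median"]], median(x))
  expect_equal(f3[["minimum"]], min(x))
  expect_equal(f3[["maximum"]], max(x))
  expect_equal(f3[["variance"]], mean((x - mean(x))^2))
  expect_equal(f3[["skewness"]],
               mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5)
  expect_equal(f3[["kurtosis"]],
               mean((x - mean(x))^4) / mean((x - mean(x))^2)^2)
  expect_equal(f3[["energy"]], sum(x^2))
  expect_equal(f3[["root_mean_squared"]], sqrt(mean(x^2)))
})

test_that("shape features agree with face/center enumeration", {
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  f <- shape_features(tumor_mask(one))
  expect_equal(f[["volume_mm3"]], 1)
  expect_equal(f[["surface_area_mm2"]], 6)
  expect_equal(f[["max_diameter_mm"]], 0)

  cube <- array(FALSE, c(4, 4, 4)); cube[2:3, 2:3, 2:3] <- TRUE
  f2 <- shape_features(tumor_mask(cube))
  expect_equal(f2[["volume_mm3"]], 8)
  expect_equal(f2[["surface_area_mm2"]], 24)
  expect_equal(f2[["max_diameter_mm"]], sqrt(3))
  # unit-cube sphericity from the closed form
  expect_equal(f[["sphericity"]], pi^(1 / 3) * 6^(2 / 3) / 6)
  expect_lte(f[["sphericity"]], 1)

  # anisotropic spacing: single voxel at (1, 2, 4) mm
  single <- array(TRUE, c(1, 1, 1))
  f3 <- shape_features(tumor_mask(single, spacing_mm = c(1, 2, 4)))
  expect_equal(f3[["volume_mm3"]], 8)
  expect_equal(f3[["surface_area_mm2"]], 2 * (2 * 4 + 1 * 4 + 1 * 2))
})

test_that("GLCM features match hand enumeration on the worked grid", {
  # 2x2x1 grid [[1,1],[2,2]]: along x the symmetric pairs are (1,1), (2,2)
  grid <- array(0L, c(2, 2, 1))
  grid[, 1, 1] <- 1L
  grid[, 2, 1] <- 2L
  counts <- habitatct:::cpp_glcm(as.integer(grid), as.integer(dim(grid)), 2L)
  m <- matrix(counts[, 1], 2, 2) # offset (1, 0, 0)
  p <- m / sum(m)
  expect_equal(p, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(sum(p^2), 0.5)                      # joint energy
  expect_equal(-sum(p[p > 0] * log2(p[p > 0])), 1) # joint entropy, bits
  expect_equal(sum(p[row(p) != col(p)]), 0)        # difference entropy = 0

  const <- disc_from_grid(array(1L, c(3, 3, 3)))
  f <- glcm_features(const)
  expect_equal(f[["joint_energy"]], 1)
  expect_equal(f[["joint_entropy"]], 0)
  expect_equal(f[["difference_entropy"]], 0)
})

test_that("texture matrices equal brute-force enumeration on random grids", {
  set.seed(33)
  for (trial in 1:12) {
    grid <- random_disc_grid(dm = sample(3:6, 3, TRUE), ng = sample(2:5, 1))
    ng <- max(grid)
    disc <- disc_from_grid(grid)

    counts <- habitatct:::cpp_glcm(as.integer(grid), as.integer(dim(grid)),
                                   as.integer(ng))
    for (o in seq_len(13)) {
      expect_equal(matrix(counts[, o], ng, ng),
                   glcm_oracle(grid, offsets13[o, ]))
    }

    maxlen <- max(dim(grid))
    rl <- habitatct:::cpp_glrlm(as.integer(grid), as.integer(dim(grid)),
                                as.integer(ng), as.integer(maxlen))
    for (o in seq_len(13)) {
      m <- matrix(rl[, o], ng, maxlen, byrow = TRUE)
      or <- glrlm_oracle(grid, offsets13[o, ])
      m2 <- matrix(0, ng, maxlen)
      for (i in seq_len(nrow(or))) {
        m2[or[i, 1], or[i, 2]] <- m2[or[i, 1], or[i, 2]] + 1
      }
      expect_equal(m, m2)
    }

    zones <- habitatct:::cpp_glszm_zones(as.integer(grid),
                                         as.integer(dim(grid)))
    orz <- glszm_oracle(grid)
    expect_equal(
      sort(paste(zones[, 1], zones[, 2])),
      sort(paste(orz[, 1], orz[, 2]))
    )

    nt <- habitatct:::cpp_ngtdm(as.integer(grid), as.integer(dim(grid)),
                                as.integer(ng))
    expect_equal(unname(nt), unname(ngtdm_oracle(grid)), tolerance = 1e-12)

    gd <- habitatct:::cpp_gldm(as.integer(grid), as.integer(dim(grid)),
                               as.integer(ng), 0L)
    expect_equal(unname(gd), unname(gldm_oracle(grid, 0)))
  }
})

test_that("GLRLM worked examples hold per direction", {
  row3 <- array(1L, c(3, 1, 1))
  rl <- habitatct:::cpp_glrlm(as.integer(row3), as.integer(dim(row3)), 1L, 3L)
  # along x: a single run of length 3 -> run percentage 1/3
  mx <- matrix(rl[, 1], 1, 3, byrow = TRUE)
  expect_equal(as.vector(mx), c(0, 0, 1))
  f <- glrlm_features_single <- local({
    nr <- sum(mx); np <- sum(mx %*% diag(1:3))
    nr / np
  })
  expect_equal(f, 1 / 3)

  distinct <- array(1:3, c(3, 1, 1))
  d3 <- disc_from_grid(distinct)
  f2 <- glrlm_features(d3)
  expect_equal(f2[["short_run_emphasis"]], 1) # every run has length 1
})

test_that("GLSZM worked examples hold", {
  const <- disc_from_grid(array(1L, c(3, 3, 2)))
  f <- glszm_features(const)
  expect_equal(f[["zone_percentage"]], 1 / 18)

  checker <- array(0L, c(2, 2, 1))
  checker[1, 1, 1] <- 1L; checker[2, 2, 1] <- 1L
  checker[1, 2, 1] <- 2L; checker[2, 1, 1] <- 2L
  zones <- habitatct:::cpp_glszm_zones(as.integer(checker),
                                       as.integer(dim(checker)))
  # diagonal neighbors share a corner under 26-connectivity: two zones of 2
  expect_equal(nrow(zones), 2)
  expect_equal(sort(zones[, 2]), c(2, 2))
})

test_that("NGTDM worked examples hold", {
  const <- disc_from_grid(array(1L, c(3, 3, 3)))
  expect_equal(ngtdm_features(const)[["contrast"]], 0)

  pair <- disc_from_grid(array(c(1L, 2L), c(2, 1, 1)))
  acc <- habitatct:::cpp_ngtdm(as.integer(pair$grid),
                               as.integer(dim(pair$grid)), 2L)
  expect_equal(acc[, 1], c(1, 1)) # n_1 = n_2 = 1
  expect_equal(acc[, 2], c(1, 1)) # s(1) = s(2) = 1
  # closed form: [sum p_i p_j (i-j)^2 / (Ngp (Ngp-1))] * [sum s / Nvp]
  f <- ngtdm_features(pair)
  expect_equal(f[["contrast"]], (2 * 0.5 * 0.5 * 1) / (2 * 1) * (2 / 2))
})

test_that("GLDM worked examples hold", {
  const <- array(1L, c(3, 3, 3))
  gd <- habitatct:::cpp_gldm(as.integer(const), as.integer(dim(const)), 1L, 0L)
  expect_equal(gd[1, 27], 1) # the center voxel has dependence 26

  distinct <- disc_from_grid(array(1:8, c(2, 2, 2)))
  f <- gldm_features(distinct)
  expect_equal(f[["small_dependence_emphasis"]], 1) # all dependences are 0
})

test_that("extract_case covers regions consistently", {
  cfg <- tiny_config(k_true = 2)
  case <- generate_tumor_volume(cfg, 3)
  v <- apply_window(case$volume)

  # habitat map entirely habitat 1: habitat_1 features equal whole-tumor
  # intensity/texture features, habitats 2+ are missing
  map1 <- structure(
    list(grid = ifelse(case$mask$grid, 1L, 0L) |> array(dim(case$mask$grid)),
         spacing_mm = case$mask$spacing_mm, k = 3L),
    class = "habitat_map"
  )
  fx <- extract_case(v, case$mask, map1)
  whole <- fx[grep("^whole_(?!shape)", names(fx), perl = TRUE)]
  hab1 <- fx[grep("^habitat_1_", names(fx))]
  expect_equal(unname(unlist(hab1)), unname(unlist(whole)))
  expect_true(all(is.na(unlist(fx[grep("^habitat_2_", names(fx))]))))

  # feature count per region is constant across patients
  case2 <- generate_tumor_volume(cfg, 4)
  st2 <- voxel_feature_map(apply_window(case2$volume), case2$mask)
  m <- fit_habitat_model(st2, k = 2, seed = 1)
  hm2 <- assign_habitats(st2, case2$mask, m)
  fx2 <- extract_case(apply_window(case2$volume), case2$mask, hm2)
  expect_setequal(names(fx2)[grepl("habitat_1_", names(fx2))] |>
                    sub("habitat_1_", "", x = _),
                  names(fx2)[grepl("habitat_2_", names(fx2))] |>
                    sub("habitat_2_", "", x = _))
})

test_that("intensity features ignore shape and shape features ignore intensity", {
  cfg <- tiny_config(k_true = 1)
  case <- generate_tumor_volume(cfg, 9)
  v <- apply_window(case$volume)
  f1 <- shape_features(case$mask)
  v2 <- image_volume(v$grid * 2 + 10, spacing_mm = v$spacing_mm)
  expect_equal(shape_features(case$mask), f1)
  a <- firstorder_features(v, case$mask$grid)
  b <- firstorder_features(v2, case$mask$grid)
  expect_equal(b[["mean"]], 2 * a[["mean"]] + 10)
})

test_that("normalized co-occurrence probabilities sum to one", {
  set.seed(8)
  for (i in 1:5) {
    grid <- random_disc_grid()
    ng <- max(grid)
    counts <- habitatct:::cpp_glcm(as.integer(grid), as.integer(dim(grid)),
                                   as.integer(ng))
    for (o in seq_len(13)) {
      if (sum(counts[, o]) == 0) next
      expect_equal(sum(counts[, o] / sum(counts[, o])), 1, tolerance = 1e-12)
    }
  }
})
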