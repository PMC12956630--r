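test_that("ICC(2,1) matches the ANOVA mean-squares oracle", {
  # published-style 6 subjects x 2 raters table
  ratings <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
  # oracle: mean squares from aov on the long layout
  long <- data.frame(
    y = as.vector(ratings),
    subject = factor(rep(1:6, 2)),
    rater = factor(rep(1:2, each = 6))
  )
  ms <- summary(stats::aov(y ~ subject + rater, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2; n <- 6
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc21(ratings), oracle, tolerance = 1e-12)
})

test_that("the ICC filter keeps reproducible features only", {
  set.seed(1)
  base <- tibble::tibble(a = rnorm(30, 10, 4), b = rnorm(30, 5, 2))
  r1 <- base
  r2 <- base |> dplyr::mutate(
    a = a + rnorm(30, 0, 0.1),   # reproducible
    b = rnorm(30, 5, 2)          # independent noise across readers
  )
  r1rep <- base |> dplyr::mutate(a = a + rnorm(30, 0, 0.1),
                                 b = b + rnorm(30, 0, 0.1))
  out <- icc_filter(r1, r2, r1rep)
  expect_true(out$retained[out$feature == "a"])
  expect_false(out$retained[out$feature == "b"])
  expect_lt(out$icc_inter[out$feature == "b"], 0.8)

  # exact copy: ICC = 1 everywhere, all retained
  out2 <- icc_filter(r1, r1, r1)
  expect_true(all(out2$retained))
  expect_equal(out2$icc_inter, c(1, 1), tolerance = 1e-12)

  # constant feature: zero between-subject variance, excluded with reason
  cst <- tibble::tibble(a = rep(1, 30))
  out3 <- icc_filter(cst, cst, cst)
  expect_false(out3$retained)
  expect_match(out3$reason, "undefined")
})

test_that("the exact Mann-Whitney u-test enumerates arrangements", {
  # U = 0 for {1,2,3} vs {4,5,6}; 2 of C(6,3) = 20 arrangements are as
  # extreme -> two-sided p = 0.1
  res <- mw_utest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)
  expect_false(res$p_value < 0.05)

  # exact path agrees with wilcox.test when there are no ties
  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    expect_equal(mw_utest(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("the large-sample u-test matches the tie-corrected approximation", {
  set.seed(3)
  for (i in 1:8) {
    x <- sample(1:6, 25, replace = TRUE)
    y <- sample(1:6, 30, replace = TRUE) + sample(0:1, 30, replace = TRUE)
    expect_equal(
      mw_utest(x, y)$p_value,
      suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value,
      tolerance = 1e-10
    )
  }
})

test_that("the u-test filter retains label-aligned features and drops constants", {
  set.seed(4)
  labels <- rep(0:1, each = 30)
  tab <- tibble::tibble(
    perfect = labels + rnorm(60, 0, 1e-6),
    constant = rep(2, 60),
    noise = rnorm(60)
  )
  out <- mannwhitney_filter(tab, labels)
  expect_true(out$retained[out$feature == "perfect"])
  expect_equal(out$p_value[out$feature == "constant"], 1)
  expect_false(out$retained[out$feature == "constant"])
})

test_that("Spearman pruning drops exactly one member per redundant pair", {
  set.seed(5)
  x <- rnorm(100)
  tab <- tibble::tibble(a = x, b = x, c = rnorm(100))
  out <- spearman_prune(tab)
  expect_length(out$retained, 2)
  expect_true("c" %in% out$retained)
  expect_equal(nrow(out$pruned), 1)

  # perfect negative correlation is pruned through the absolute value
  tab2 <- tibble::tibble(a = x, b = -x)
  out2 <- spearman_prune(tab2)
  expect_length(out2$retained, 1)
  expect_equal(out2$retained, "a") # tie -> lexicographically smaller kept

  # the member with the smaller univariate p is the representative
  out3 <- spearman_prune(tab2, p_values = c(a = 0.5, b = 0.001))
  expect_equal(out3$retained, "b")

  # independent features survive
  tab3 <- tibble::as_tibble(matrix(rnorm(600), 200, 3),
                            .name_repair = ~ c("f1", "f2", "f3"))
  expect_length(spearman_prune(tab3)$retained, 3)
})

test_that("z-score normalization fits on training and transfers to test", {
  set.seed(6)
  train <- tibble::tibble(a = rnorm(50, 10, 3), b = rnorm(50, -2, 0.5))
  zs <- zscore_fit(train)
  zt <- zscore_apply(train, zs)
  expect_lt(max(abs(colMeans(as.matrix(zt)))), 1e-12)
  expect_lt(max(abs(apply(as.matrix(zt), 2, sd) - 1)), 1e-12)

  # not idempotent: re-applying training params rescales again
  ztt <- zscore_apply(zt, zs)
  expect_false(isTRUE(all.equal(zt$a, ztt$a)))

  # constant column: sd 1 with warning, transforms to zero
  cst <- tibble::tibble(a = rep(4, 20))
  expect_warning(zs2 <- zscore_fit(cst), "zero-variance")
  expect_true(all(zscore_apply(cst, zs2)$a == 0))
})

test_that("LASSO with the 1-SE rule finds a strong predictor reliably", {
  hits <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    n <- 400
    x <- matrix(rnorm(n * 21), n)
    colnames(x) <- c("signal", paste0("noise", 1:20))
    y <- rbinom(n, 1, plogis(2 * x[, 1]))
    sel <- lasso_select(tibble::as_tibble(x), y,
                        selection_config(seed = s))
    if ("signal" %in% sel$features) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("LASSO on pure noise selects nothing and flags it", {
  sizes <- sapply(1:5, function(s) {
    set.seed(200 + s)
    x <- matrix(rnorm(200 * 50), 200)
    colnames(x) <- paste0("n", 1:50)
    y <- rbinom(200, 1, 0.5)
    sel <- lasso_select(tibble::as_tibble(x), y, selection_config(seed = s))
    length(sel$features)
  })
  expect_equal(median(sizes), 0)
})

test_that("the cascade is nested, deterministic, and falls back when empty", {
  set.seed(7)
  n <- 80
  labels <- rep(0:1, each = n / 2)
  tab <- tibble::tibble(
    s1 = labels * 2 + rnorm(n),
    s2 = labels * 2 + rnorm(n, 0, 0.1),
    s2_copy = NA, # filled below: redundant with s2
    n1 = rnorm(n), n2 = rnorm(n)
  )
  tab$s2_copy <- tab$s2 + rnorm(n, 0, 1e-8)
  rep1 <- suppressWarnings(select_features(tab, labels,
                                           selection_config(seed = 1)))
  stages <- rep1$stages
  for (j in 2:length(stages)) {
    expect_true(all(stages[[j]] %in% stages[[j - 1]]))
  }
  rep2 <- suppressWarnings(select_features(tab, labels,
                                           selection_config(seed = 1)))
  expect_identical(rep1$stages, rep2$stages)
  expect_s3_class(tidy(rep1), "tbl_df")

  # all-noise design: LASSO empties and the report flags the fallback
  set.seed(8)
  noise <- tibble::as_tibble(matrix(rnorm(200 * 20), 200),
                             .name_repair = ~ paste0("x", 1:20))
  ylab <- rbinom(200, 1, 0.5)
  repn <- suppressWarnings(select_features(noise, ylab,
                                           selection_config(seed = 3)))
  expect_true(length(repn$features) >= 1) # never empty downstream
})

test_that("the ICC stage integrates into the cascade when readers exist", {
  set.seed(9)
  n <- 30
  labels <- rep(0:1, each = n / 2)
  base <- tibble::tibble(good = labels + rnorm(n, 0, 0.3),
                         bad = rnorm(n))
  readers <- list(
    reader1 = base,
    reader2 = dplyr::mutate(base, bad = rnorm(n)),
    reader1_repeat = dplyr::mutate(base,
                                   good = good + rnorm(n, 0, 0.05),
                                   bad = rnorm(n))
  )
  rep <- suppressWarnings(
    select_features(base, labels, selection_config(seed = 2),
                    reader_tables = readers)
  )
  expect_false("bad" %in% rep$stages$icc)
  expect_true("good" %in% rep$stages$icc)
})
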