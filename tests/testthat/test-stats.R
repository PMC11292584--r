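test_that("Box-Cox with lambda = 1 composed with its inverse is identity", {
  x <- c(0.5, 1, 2, 7)
  expect_equal(inv_box_cox(box_cox_transform(x, 1), 1), x, tolerance = 1e-12)
  expect_equal(box_cox_transform(x, 1), x - 1)
  expect_equal(inv_box_cox(box_cox_transform(x, 0.3), 0.3), x,
               tolerance = 1e-12)
})

test_that("Box-Cox selects lambda within its range and needs positives", {
  set.seed(16)
  bc <- box_cox(rlnorm(60))
  expect_gte(bc$lambda, 0.1)
  expect_lte(bc$lambda, 1.1)
  expect_error(box_cox(c(-1, 1, 2)), "positive")
  off <- offset_to_positive(c(-3, 0, 2))
  expect_true(all(off$values > 0))
  expect_equal(off$values - off$offset, c(-3, 0, 2))
})

test_that("Box-Cox improves normality of log-normal samples", {
  set.seed(17)
  wins <- replicate(200, {
    x <- rlnorm(40, sdlog = 1.2)
    p_raw <- shapiro.test(x)$p.value
    p_bc <- shapiro.test(box_cox(x)$transformed)$p.value
    p_bc > p_raw
  })
  expect_gt(mean(wins), 0.8)
})

test_that("the exact Wilcoxon enumeration reproduces hand-counted cases", {
  # {1,2,3} vs {10,11,12}: complete separation, 2/C(6,3) per tail
  res <- compare_profiles(c(1, 2, 3), c(10, 11, 12), method = "wilcoxon",
                          transform = FALSE)
  expect_equal(res$p_value, 0.1)
  expect_true(res$exact)
  # identical samples -> p = 1
  same <- compare_profiles(c(2, 2), c(2, 2), method = "wilcoxon",
                           transform = FALSE)
  expect_equal(same$p_value, 1)
})

test_that("exact rank tests match the reference implementation for n <= 5", {
  set.seed(18)
  for (i in 1:20) {
    a <- round(runif(sample(3:5, 1)), 3)
    b <- round(runif(sample(3:5, 1)), 3)
    ours <- compare_profiles(a, b, method = "wilcoxon", transform = FALSE)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    # for two untied groups the exact Kruskal-Wallis p equals the exact
    # two-sided rank-sum p (H is monotone in the rank-sum deviation)
    kw <- compare_profiles(a, b, method = "kruskal_wallis",
                           transform = FALSE)
    expect_equal(kw$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large samples fall back to the asymptotic reference", {
  set.seed(19)
  a <- rnorm(10); b <- rnorm(10)
  res <- compare_profiles(a, b, method = "wilcoxon", transform = FALSE)
  expect_false(res$exact)
  expect_equal(res$p_value,
               suppressWarnings(stats::wilcox.test(a, b)$p.value))
  tt <- compare_profiles(a, b, method = "t", transform = FALSE)
  expect_equal(tt$p_value, stats::t.test(a, b)$p.value)
})

test_that("permutation ANCOVA is seeded, reproducible and validated", {
  set.seed(20)
  df <- tibble::tibble(y = rnorm(16), g = rep(c("A", "B"), each = 8),
                       age_months = runif(16, 6, 14),
                       weight_g = runif(16, 20, 40))
  r1 <- ancova_adjusted_comparison(df, "y", "g", seed = 7)
  r2 <- ancova_adjusted_comparison(df, "y", "g", seed = 7)
  expect_identical(r1, r2)
  expect_true(r1$p_value > 0 && r1$p_value <= 1)
  expect_warning(
    ancova_adjusted_comparison(dplyr::mutate(df, age_months = 5),
                               "y", "g", seed = 1),
    "constant")
  expect_error(ancova_adjusted_comparison(df[c(1:2, 9:10), ], "y", "g"),
               "at least 3")
  expect_error(ancova_adjusted_comparison(df[1:4, ], "y", "g"),
               "two levels")
  expect_error(ancova_adjusted_comparison(df, "nope", "g"), "Missing")
})

test_that("a pure covariate-driven difference is absorbed by adjustment", {
  # group effect enters only through weight; the adjusted test should
  # retain the null in most simulations
  set.seed(21)
  keeps <- replicate(100, {
    w <- c(runif(8, 20, 30), runif(8, 32, 42))
    df <- tibble::tibble(y = 0.3 * w + rnorm(16),
                         g = rep(c("A", "B"), each = 8),
                         age_months = runif(16, 6, 14), weight_g = w)
    ancova_adjusted_comparison(df, "y", "g", n_perm = 199,
                               seed = sample.int(1e6, 1))$p_value >= 0.05
  })
  expect_gt(mean(keeps), 0.9)
})

test_that("glucose AUCs match hand integration", {
  assay <- tibble::tibble(time_min = c(-30, 0, 30, 60, 90),
                          glucose = c(150, 300, 300, 250, 200))
  aucs <- glucose_aucs(assay)
  expect_equal(aucs$auc_0_30, 9000)  # constant 300 over 30 min
  expect_equal(aucs$auc_30_90, 30 * (300 + 250) / 2 + 30 * (250 + 200) / 2)
  expect_equal(aucs$baseline, 150)
  expect_error(glucose_aucs(assay[-1, ]), "must include")
  expect_error(glucose_aucs(dplyr::mutate(assay, glucose = 0)), "positive")
})

test_that("the diabetic classification gates on fasting baseline", {
  ref <- tidyr::expand_grid(mouse_id = sprintf("r%d", 1:6),
                            time_min = c(-30, 0, 30, 60, 90))
  set.seed(22)
  ref$glucose <- rep(c(150, 160, 280, 240, 200), 6) + rnorm(30, 0, 5)
  normal_low <- tibble::tibble(time_min = c(-30, 0, 30, 60, 90),
                               glucose = c(150, 160, 600, 500, 420))
  expect_false(classify_diabetic(normal_low, ref)$positive)  # baseline gate
  diabetic <- tibble::tibble(time_min = c(-30, 0, 30, 60, 90),
                             glucose = c(260, 280, 600, 520, 450))
  res <- classify_diabetic(diabetic, ref)
  expect_true(res$positive)
  expect_lt(res$detail$p_auc_0_30, 0.05)
  high_base_only <- tibble::tibble(time_min = c(-30, 0, 30, 60, 90),
                                   glucose = c(260, 160, 280, 240, 200))
  expect_false(classify_diabetic(high_base_only, ref)$positive)
})
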