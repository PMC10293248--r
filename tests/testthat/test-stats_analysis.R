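test_that("task specifications encode the three group contrasts", {
  expect_identical(task_spec(1)$positive, "PD")
  expect_identical(task_spec(1)$negative, "CG")
  expect_identical(task_spec("Task2")$positive, c("PD", "DD"))
  expect_identical(task_spec(3)$negative, "DD")
})

test_that("Spearman correlation hits the monotone extremes and the rank oracle", {
  x <- c(1, 4, 9, 16, 25, 36)
  y <- 1:6
  tbl <- spearman_table(data.frame(F2_MaxDistance = x),
                        data.frame(target = y),
                        feature_cols = "F2_MaxDistance")
  expect_equal(tbl$rho, 1)
  tbl2 <- spearman_table(data.frame(F2_MaxDistance = rev(x)),
                         data.frame(target = y),
                         feature_cols = "F2_MaxDistance")
  expect_equal(tbl2$rho, -1)

  # oracle: Pearson product-moment formula applied to ranks
  withr::local_seed(17)
  for (i in 1:10) {
    a <- rnorm(12); b <- rnorm(12)
    ra <- rank(a); rb <- rank(b)
    oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
    got <- spearman_table(data.frame(F2_MaxDistance = a),
                          data.frame(target = b),
                          feature_cols = "F2_MaxDistance")$rho
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("Spearman is invariant under strictly monotone transforms", {
  withr::local_seed(18)
  x <- runif(30, 0.1, 5); y <- rnorm(30)
  r1 <- spearman_table(data.frame(F2_MaxDistance = x),
                       data.frame(target = y),
                       feature_cols = "F2_MaxDistance")$rho
  r2 <- spearman_table(data.frame(F2_MaxDistance = log_transform_features(x)),
                       data.frame(target = y),
                       feature_cols = "F2_MaxDistance")$rho
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("constant features are reported as missing with a warning", {
  expect_warning(
    tbl <- spearman_table(data.frame(F2_MaxDistance = rep(1, 10)),
                          data.frame(target = 1:10),
                          feature_cols = "F2_MaxDistance"),
    "constant")
  expect_true(is.na(tbl$rho))
})

test_that("Mann-Whitney U reproduces exact small-sample cases", {
  res <- spiraldx:::mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1)  # 2/20 labelings as extreme
  expect_identical(res$branch, "exact")

  same <- spiraldx:::mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  degenerate <- spiraldx:::mann_whitney_u(rep(2, 4), rep(2, 5))
  expect_equal(degenerate$p_value, 1)
})

test_that("Mann-Whitney exact branch agrees with a permutation oracle", {
  # oracle: enumerate every labeling, two-sided p from the U distance
  # to its null mean (matching the exact two-sided convention)
  perm_oracle <- function(x, y) {
    n1 <- length(x); pooled <- c(x, y); n <- length(pooled)
    u_of <- function(idx) {
      sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
    }
    u_obs <- u_of(seq_len(n1))
    all_u <- apply(utils::combn(n, n1), 2, u_of)
    center <- n1 * (length(y)) / 2
    mean(abs(all_u - center) >= abs(u_obs - center) - 1e-12)
  }
  withr::local_seed(19)
  for (i in 1:8) {
    x <- rnorm(sample(4:8, 1)); y <- rnorm(sample(4:8, 1))
    got <- spiraldx:::mann_whitney_u(x, y)
    expect_identical(got$branch, "exact")
    expect_equal(got$p_value, perm_oracle(x, y), tolerance = 1e-9)
  }
})

test_that("exact and approximate branches agree near the crossover size", {
  withr::local_seed(20)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12, 0.5)
    pe <- spiraldx:::mann_whitney_u(x, y, exact_max = 12)$p_value
    pa <- spiraldx:::mann_whitney_u(x, y, exact_max = 0)$p_value
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("the Bonferroni threshold and annotation ladder match the conventions", {
  expect_equal(round(bonferroni_threshold(), 4), 0.0036)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 14), 0.01 / 14)
  expect_error(bonferroni_threshold(0.05, 0), "domain error")

  expect_identical(significance_annotation(0.5), "ns")
  expect_identical(significance_annotation(0.002), "*")
  expect_identical(significance_annotation(0.0005), "**")
  expect_identical(significance_annotation(1e-7), "****")
  # boundary cases sit on the <= side of each rung
  expect_identical(significance_annotation(0.05 / 14), "*")
  expect_identical(significance_annotation(0.01 / 14), "**")
  expect_identical(significance_annotation(0.001 / 14), "***")
  expect_identical(significance_annotation(0.0001 / 14), "****")
})

test_that("group comparisons run over all 14 features with correction", {
  withr::local_seed(23)
  fx <- synthetic_feature_table(n_cg = 10, n_pd = 10, n_dd = 10)
  res <- mann_whitney_tests(fx, "Task1")
  expect_equal(nrow(res), 14)
  expect_setequal(res$feature, feature_names())
  expect_identical(res$significant, res$p_value < 0.05 / 14)
  expect_error(mann_whitney_tests(fx[fx$group == "PD", ], "Task1"),
               "empty group")
})
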