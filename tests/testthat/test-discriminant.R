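# empirically whiten scores so the pooled within-group covariance is
# exactly the identity and group means sit exactly where requested
whitened_two_groups <- function(n_per = 40, k = 3, delta = c(3, 0, 0),
                                seed = 51) {
  set.seed(seed)
  labels <- rep(c("g1", "g2"), each = n_per)
  x <- matrix(rnorm(2 * n_per * k), ncol = k)
  for (g in c("g1", "g2")) {
    rows <- labels == g
    x[rows, ] <- sweep(x[rows, ], 2, colMeans(x[rows, ]))
  }
  W <- wingcoi:::pooled_within_cov(x, labels)
  x <- x %*% solve(chol(W))
  x[labels == "g2", ] <- sweep(x[labels == "g2", ], 2, delta, `+`)
  df <- tibble::as_tibble(as.data.frame(x))
  names(df) <- paste0("PC", seq_len(k))
  df$species <- labels
  df$specimen <- sprintf("s%03d", seq_along(labels))
  df
}

test_that("Mahalanobis D is exact under identity pooled covariance", {
  df <- whitened_two_groups(delta = c(3, 0, 0))
  cva <- discriminant_analysis(df)
  expect_equal(cva$mahalanobis["g1", "g2"], 3, tolerance = 1e-9)
  expect_equal(cva$mahalanobis, t(cva$mahalanobis))
  expect_true(all(diag(cva$mahalanobis) == 0))
})

test_that("Mahalanobis D is invariant under invertible affine transforms", {
  set.seed(52)
  df <- whitened_two_groups(delta = c(2, 1, 0), seed = 53)
  d0 <- discriminant_analysis(df)$mahalanobis["g1", "g2"]
  pcs <- grep("^PC", names(df))
  for (rep in 1:5) {
    A <- matrix(rnorm(9), 3, 3)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3, 3)
    df2 <- df
    df2[pcs] <- as.matrix(df[pcs]) %*% A + matrix(rnorm(3), nrow(df), 3,
                                                  byrow = TRUE)
    expect_equal(discriminant_analysis(df2)$mahalanobis["g1", "g2"], d0,
                 tolerance = 1e-6)
  }
})

test_that("Mahalanobis D shrinks to zero under the null", {
  set.seed(54)
  df <- null_scores(c(500, 500), k = 5)
  expect_lt(discriminant_analysis(df)$mahalanobis["g1", "g2"], 0.5)
})

test_that("group-size preconditions are enforced", {
  set.seed(55)
  df <- null_scores(c(10, 2), k = 3)
  expect_error(discriminant_analysis(df), "fewer than 3")
  expect_error(discriminant_analysis(null_scores(c(10, 0), k = 3)[1:10, ]),
               "2 species")
})

test_that("permutation test covers all pairs with Bonferroni factor g(g-1)/2", {
  set.seed(56)
  df <- null_scores(c(8, 8, 8, 8), k = 4,
                    labels = c("a", "b", "c", "d"))
  res <- mahalanobis_permutation_test(df, n_perm = 199, seed = 57)
  expect_equal(nrow(res), 6L)  # 4 groups -> 6 pairwise tests
  expect_equal(res$p_adjusted, pmin(1, res$p_value * 6))
  expect_true(all(res$p_value >= 1 / 200 & res$p_value <= 1))
})

test_that("strong separation is maximally significant after Bonferroni", {
  df <- whitened_two_groups(n_per = 25, delta = c(8, 0, 0), seed = 58)
  res <- mahalanobis_permutation_test(df, n_perm = 199, seed = 59)
  expect_equal(res$p_value, 1 / 200)
  expect_true(res$significant)
  expect_gt(res$mahalanobis_d, 6)
})

test_that("LOO classification satisfies its exact accounting identities", {
  set.seed(60)
  df <- null_scores(c(20, 15), k = 4, shift = 3)
  loo <- loo_classification(df)
  expect_equal(unname(rowSums(loo$confusion)), c(20L, 15L))
  expect_equal(loo$total_pct,
               sum(loo$per_group_pct * rowSums(loo$confusion)) / 35)
  expect_warning(one <- loo_classification(null_scores(c(12, 0), k = 3)[1:12, ]),
                 "trivially")
  expect_equal(one$total_pct, 100)
})

test_that("LOO accuracy is at chance for identical distributions", {
  # single-dataset accuracy carries binomial noise (sd ~ 5 pp at n = 100),
  # so the chance level is checked on the mean over replicate datasets
  set.seed(61)
  accs <- vapply(1:10, function(i) {
    loo_classification(null_scores(c(50, 50), k = 5))$total_pct
  }, numeric(1))
  expect_gte(mean(accs), 42)
  expect_lte(mean(accs), 58)
})

test_that("permutation p-values are near-uniform under the null", {
  set.seed(62)
  pvals <- vapply(1:120, function(i) {
    df <- null_scores(c(15, 15), k = 4)
    suppressWarnings(
      mahalanobis_permutation_test(df, n_perm = 99, seed = 1000 + i))$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("allometry regression recognises null and perfect relations", {
  set.seed(63)
  df <- null_scores(c(30, 30), k = 3)
  df$csize <- exp(rnorm(60, log(3), 0.1))
  null_fit <- allometry_regression(df, n_perm = 199, seed = 64)
  expect_lt(null_fit$r_squared, 0.1)
  expect_gt(null_fit$p_value, 0.01)

  df$PC1 <- -2 * df$csize + 5   # exact linear dependence
  fit <- allometry_regression(df, n_perm = 199, seed = 65)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$p_value, 1 / 200)
  expect_equal(fit$slope_sign, "negative")
  df$csize <- 3
  expect_error(allometry_regression(df, n_perm = 99, seed = 66),
               "size variance")
})
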