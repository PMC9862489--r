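sim_alignment <- function(n = 25, noise = 0.02, seed = 41) {
  set.seed(seed)
  base <- random_config(18)
  mats <- lapply(seq_len(n), function(i) {
    rigid_motion(base + matrix(rnorm(36, 0, noise), 18, 2),
                 scale = runif(1, 0.5, 2))
  })
  gpa_align(dataset_from_matrices(mats,
                                  species = rep(c("a", "b"), length.out = n)))
}

test_that("identical shapes yield zero shape variables with a warning", {
  set.seed(42)
  cfg <- random_config(18)
  fit <- gpa_align(dataset_from_matrices(rep(list(cfg), 5)))
  expect_warning(sv <- shape_variables(fit), "No shape variation")
  expect_equal(sv$k, 0L)
})

test_that("partial-warp + uniform scores conserve shape variance", {
  fit <- sim_alignment()
  sv <- shape_variables(fit, variance_retained = 1)
  # dimension cap: similarity transforms remove 4 dof in 2-D
  expect_lte(sv$k, 2 * 18 - 4)
  expect_true(all(diff(sv$explained) <= 1e-12))
  expect_lte(sum(sv$explained), 1 + 1e-12)

  # total variance of the scores == tangent-projected residual variance
  arr <- wingcoi:::as_landmark_array(fit$aligned)
  ref <- cbind(fit$mean_shape$x, fit$mean_shape$y)
  flat <- t(apply(arr$coords, 3, as.vector))
  resid <- sweep(flat, 2, c(ref[, 1], ref[, 2]))
  S <- wingcoi:::similarity_basis(ref)
  tang <- resid - resid %*% S %*% t(S)
  tang_var <- sum(apply(tang, 2, var))
  expect_equal(sv$total_variance, tang_var, tolerance = 1e-12)
  # ... and matches the raw Procrustes residual variance closely (the
  # aligned residuals are orthogonal to the similarity directions at the
  # GPA optimum up to second order)
  raw_var <- sum(apply(resid, 2, var))
  expect_equal(sv$total_variance, raw_var, tolerance = 1e-4)
})

test_that("retained score space spans the residual principal subspace", {
  fit <- sim_alignment(n = 30, seed = 43)
  sv <- shape_variables(fit, variance_retained = 1 - 1e-12)
  arr <- wingcoi:::as_landmark_array(fit$aligned)
  ref <- cbind(fit$mean_shape$x, fit$mean_shape$y)
  flat <- t(apply(arr$coords, 3, as.vector))
  resid <- sweep(flat, 2, c(ref[, 1], ref[, 2]))
  S <- wingcoi:::similarity_basis(ref)
  tang <- resid - resid %*% S %*% t(S)
  pca <- prcomp(tang)
  keep <- which(pca$sdev^2 > max(pca$sdev^2) * 1e-10)
  scores_pkg <- as.matrix(sv$scores[grep("^PC", names(sv$scores))])
  # canonical correlations between the two score spaces are all ~1
  cc <- stats::cancor(scores_pkg, pca$x[, keep, drop = FALSE])
  expect_true(all(cc$cor > 1 - 1e-8))
})

test_that("score truncation keeps classification identical at full variance", {
  set.seed(44)
  spec <- morpho_sim_spec(species = c("a", "b"), n_per_species = c(12, 12),
                          target_d = matrix(c(0, 5, 5, 0), 2),
                          allometry_r2 = NULL, seed = 45)
  fit <- gpa_align(simulate_wings(spec))
  full <- loo_classification(shape_variables(fit, variance_retained = 1 - 1e-15))
  near <- loo_classification(shape_variables(fit, variance_retained = 0.999999))
  expect_equal(full$confusion, near$confusion)
})
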