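test_that("identical configurations align with zero residuals", {
  set.seed(21)
  cfg <- random_config(18)
  fit <- gpa_align(dataset_from_matrices(rep(list(cfg), 5)))
  expect_true(fit$converged)
  expect_lte(fit$n_iterations, 2L)
  expect_lt(tail(fit$objective, 1), 1e-16)
})

test_that("alignment removes arbitrary rigid motion and scaling", {
  set.seed(22)
  cfg <- random_config(18)
  mats <- lapply(1:6, function(i) rigid_motion(cfg, scale = runif(1, 0.2, 5)))
  fit <- gpa_align(dataset_from_matrices(mats))
  al <- aligned_matrices(fit)
  for (i in 2:6) expect_lt(sqrt(sum((al[[1]] - al[[i]])^2)), 1e-8)
})

test_that("GPA objective is monotone and consensus equals rescaled mean", {
  set.seed(23)
  base <- random_config(18)
  mats <- lapply(1:20, function(i) base + matrix(rnorm(36, 0, 0.05), 18, 2))
  fit <- gpa_align(dataset_from_matrices(mats))
  expect_true(all(diff(fit$objective) <= 1e-12))
  al <- aligned_matrices(fit)
  mean_al <- Reduce(`+`, al) / length(al)
  mean_al <- mean_al / sqrt(sum(sweep(mean_al, 2, colMeans(mean_al))^2))
  cons <- cbind(fit$mean_shape$x, fit$mean_shape$y)
  expect_lt(sqrt(sum((mean_al - cons)^2)), 1e-9)
  # every aligned configuration is centred with unit centroid size
  for (m in al) {
    expect_lt(max(abs(colMeans(m))), 1e-9)
    expect_equal(sum(m^2), 1, tolerance = 1e-9)
  }
})

test_that("GPA is invariant to pre-transformation of the input", {
  set.seed(24)
  base <- random_config(18)
  mats <- lapply(1:10, function(i) base + matrix(rnorm(36, 0, 0.03), 18, 2))
  moved <- lapply(mats, function(m) rigid_motion(m, scale = runif(1, 0.5, 2)))
  f1 <- gpa_align(dataset_from_matrices(mats))
  f2 <- gpa_align(dataset_from_matrices(moved))
  # same shapes up to a global rotation: consensus shapes coincide
  expect_lt(procrustes_distance(cbind(f1$mean_shape$x, f1$mean_shape$y),
                                cbind(f2$mean_shape$x, f2$mean_shape$y)),
            1e-8)
  expect_equal(tail(f1$objective, 1), tail(f2$objective, 1), tolerance = 1e-8)
})

test_that("procrustes_distance is a similarity-invariant metric", {
  set.seed(25)
  a <- random_config(18)
  expect_equal(procrustes_distance(a, a), 0)
  rot90 <- matrix(c(0, 1, -1, 0), 2)
  expect_lt(procrustes_distance(a, 2 * a %*% rot90), 1e-12)
  b <- random_config(18)
  expect_equal(procrustes_distance(a, b), procrustes_distance(b, a),
               tolerance = 1e-12)
})

test_that("procrustes_distance matches rotation-grid minimization", {
  set.seed(26)
  for (rep in 1:10) {
    a <- random_config(18)
    b <- a + matrix(rnorm(36, 0, 0.2), 18, 2)
    expect_equal(procrustes_distance(a, b),
                 procrustes_distance_grid(a, b, n_grid = 1e6),
                 tolerance = 1e-6)
  }
})

test_that("residual variance conservation links GPA and repeatability", {
  set.seed(27)
  base <- random_config(18)
  mats <- lapply(1:15, function(i) base + matrix(rnorm(36, 0, 0.04), 18, 2))
  fit <- gpa_align(dataset_from_matrices(mats))
  al <- aligned_matrices(fit)
  cons <- cbind(fit$mean_shape$x, fit$mean_shape$y)
  ss <- sum(vapply(al, function(m) sum((m - cons)^2), numeric(1)))
  expect_equal(ss, tail(fit$objective, 1), tolerance = 1e-10)
})

test_that("byte-identical replicates give 100% repeatability", {
  set.seed(28)
  rows <- list()
  for (i in 1:5) {
    cfg <- random_config(18)
    for (r in 0:1) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        specimen = sprintf("w%d", i), species = "sp", replicate = r,
        landmark = 1:18, x = cfg[, 1], y = cfg[, 2])
    }
  }
  rr <- estimate_repeatability(dplyr::bind_rows(rows))
  expect_equal(rr$repeatability_pct, 100)
  expect_equal(rr$measurement_error_pct, 0)
  expect_equal(rr$repeatability_pct + rr$measurement_error_pct, 100,
               tolerance = 1e-6)
})

test_that("repeatability recovers a known variance ratio", {
  # within-specimen (digitizing) variance set equal to among-specimen
  # variance -> repeatability near 50%
  spec <- morpho_sim_spec(species = "sp", n_per_species = 40L,
                          target_d = matrix(0, 1, 1),
                          shape_noise_sd = 0.003, allometry_r2 = NULL,
                          digitizing_error_sd = 0.003, n_replicates = 1L,
                          seed = 29)
  rr <- estimate_repeatability(simulate_wings(spec))
  expect_equal(rr$repeatability_pct, 50, tolerance = 0.04)  # 50% +/- 2
  expect_error(
    estimate_repeatability(simulate_wings(
      morpho_sim_spec(species = "sp", n_per_species = 10L,
                      target_d = matrix(0, 1, 1), allometry_r2 = NULL,
                      seed = 30))),
    "digitizations")
})

test_that("repeatability recovery sharpens with specimen count", {
  err <- vapply(c(20L, 80L, 320L), function(n) {
    spec <- morpho_sim_spec(species = "sp", n_per_species = n,
                            target_d = matrix(0, 1, 1),
                            shape_noise_sd = 0.003, allometry_r2 = NULL,
                            digitizing_error_sd = 0.003, n_replicates = 1L,
                            seed = 31)
    abs(estimate_repeatability(simulate_wings(spec))$repeatability_pct - 50)
  }, numeric(1))
  expect_lt(err[3], err[1])
})
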