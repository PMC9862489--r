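test_that("generators are byte-reproducible from their seed", {
  w1 <- simulate_wings(morpho_sim_spec(n_per_species = c(5, 5, 5, 5), seed = 7))
  w2 <- simulate_wings(morpho_sim_spec(n_per_species = c(5, 5, 5, 5), seed = 7))
  expect_identical(w1, w2)
  w3 <- simulate_wings(morpho_sim_spec(n_per_species = c(5, 5, 5, 5), seed = 8))
  expect_false(identical(w1$x, w3$x))

  s1 <- simulate_barcodes(seq_sim_spec(seed = 5))
  s2 <- simulate_barcodes(seq_sim_spec(seed = 5))
  expect_identical(s1, s2)
  expect_false(identical(
    s1$sequence, simulate_barcodes(seq_sim_spec(seed = 6))$sequence))
})

test_that("zero noise collapses conspecifics to identical shapes", {
  spec <- morpho_sim_spec(species = c("a", "b"), n_per_species = c(4, 4),
                          target_d = matrix(c(0, 6, 6, 0), 2),
                          shape_noise_sd = 0, allometry_r2 = NULL,
                          digitizing_error_sd = 0, seed = 9)
  wings <- simulate_wings(spec)
  arr <- wingcoi:::as_landmark_array(wings)
  sp <- arr$info$species
  for (g in c("a", "b")) {
    idx <- which(sp == g)
    for (j in idx[-1]) {
      expect_lt(procrustes_distance(arr$coords[, , idx[1]],
                                    arr$coords[, , j]), 1e-9)
    }
  }
  # ...but the two species still differ
  expect_gt(procrustes_distance(arr$coords[, , which(sp == "a")[1]],
                                arr$coords[, , which(sp == "b")[1]]), 1e-4)
})

test_that("realized within-species shape variance matches the moment target", {
  sigma <- 0.003
  spec <- morpho_sim_spec(species = "sp", n_per_species = 200L,
                          target_d = matrix(0, 1, 1),
                          shape_noise_sd = sigma, allometry_r2 = NULL,
                          digitizing_error_fraction = 0, seed = 10)
  wings <- simulate_wings(spec)
  fit <- gpa_align(wings)
  arr <- wingcoi:::as_landmark_array(fit$aligned)
  cons <- cbind(fit$mean_shape$x, fit$mean_shape$y)
  msd <- mean(apply(arr$coords, 3, function(m) sum((m - cons)^2)))
  q <- 2 * 18 - 4
  expect_equal(msd, q * sigma^2, tolerance = 0.1)  # +/- 10% at n = 200
})

test_that("generated landmark data pass the dataset invariants", {
  wings <- simulate_wings(morpho_sim_spec(n_per_species = c(4, 4, 4, 4),
                                          n_replicates = 1, seed = 12))
  revalidated <- landmark_data(wings)
  expect_equal(nrow(revalidated), 16 * 2 * 18)
  expect_true(all(table(revalidated$specimen) == 2 * 18))
})

test_that("realized sequence divergences are unbiased for their targets", {
  # a single dataset's mean interspecific distance inherits the Monte-Carlo
  # noise of one ancestor-pair realization (sd ~ sqrt(d/L) ~ 0.7 pp), so
  # unbiasedness is checked on the mean over replicate datasets
  intra <- inter <- numeric(25)
  for (r in 1:25) {
    spec <- seq_sim_spec(species = c("x", "y"), n_per_species = 4,
                         intra_divergence = 0.005,
                         inter_divergence = matrix(c(0, 0.04, 0.04, 0), 2),
                         seed = 1300 + r)
    stats <- divergence_summary(simulate_barcodes(spec))$pair_stats
    intra[r] <- mean(stats$mean_pct[stats$type == "intra"])
    inter[r] <- stats$mean_pct[stats$type == "inter"]
  }
  expect_lt(abs(mean(intra) - 0.5), 0.15)
  expect_lt(abs(mean(inter) - 4), 0.45)  # ~3 se at 25 replicates
})

test_that("every generated barcode is a clean ORF in frame 0", {
  seqs <- simulate_barcodes(seq_sim_spec(seed = 14))
  passes <- vapply(seqs$sequence,
                   function(s) check_stop_codons(s, frame = 0)$pass,
                   logical(1))
  expect_true(all(passes))
})

test_that("the overlap pair is constructed below the intraspecific maxima", {
  spec <- seq_sim_spec(species = c("p", "q", "r"), n_per_species = 8,
                       intra_divergence = 0.01,
                       inter_divergence = 0.04,
                       overlap_pair = c("q", "r"),
                       overlap_divergence = 0.005, seed = 15)
  ds <- divergence_summary(simulate_barcodes(spec))
  gap <- barcoding_gap(ds)
  no_gap <- gap[!gap$gap_present, ]
  expect_equal(nrow(no_gap), 1L)
  expect_setequal(c(no_gap$species_a, no_gap$species_b), c("q", "r"))
})

test_that("saturated divergence targets are rejected", {
  expect_error(seq_sim_spec(species = c("a", "b"), inter_divergence = 0.9,
                            seed = 16), "saturated")
})
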