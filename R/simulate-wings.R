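#' Synthetic 18-landmark wing template
#'
#' A fixed 18-landmark 2-D configuration laid out like a culicid wing
#' (elongate outline with vein-intersection points along the long axis).
#' The exact coordinates are arbitrary synthetic values — they are *not*
#' digitized from any specimen — and serve only as the reference shape for
#' the landmark generator.
#'
#' @return An 18 x 2 numeric matrix.
#' @export
wing_template <- function() {
  matrix(c(
    0.00,  0.00,   0.40,  0.35,   0.90,  0.52,   1.60,  0.60,
    2.30,  0.52,   2.90,  0.30,   3.10,  0.05,   2.85, -0.18,
    2.40, -0.33,   1.80, -0.42,   1.10, -0.40,   0.50, -0.28,
    0.15, -0.10,   0.80,  0.10,   1.40,  0.15,   2.00,  0.10,
    1.60, -0.10,   1.00, -0.12
  ), ncol = 2L, byrow = TRUE)
}

# Default target Mahalanobis separations for 4 species groups: the distance
# scale congeneric mosquito wings show (D roughly 4-10, one species much
# more distinct than the rest).
default_target_d <- function() {
  sp <- c("chiangmaiensis", "fuscana", "halifaxii", "vorax")
  D <- matrix(0, 4L, 4L, dimnames = list(sp, sp))
  D["chiangmaiensis", "fuscana"] <- 4.55
  D["chiangmaiensis", "halifaxii"] <- 5.34
  D["chiangmaiensis", "vorax"] <- 8.45
  D["fuscana", "halifaxii"] <- 4.05
  D["fuscana", "vorax"] <- 10.25
  D["halifaxii", "vorax"] <- 9.99
  D + t(D)
}

#' Specification for the synthetic wing-landmark generator
#'
#' Bundles and pre-computes everything [simulate_wings()] needs. The
#' defaults are the study conditions the package's analyses assume: four
#' species groups of 40/50/42/25 specimens, 18 landmarks, species mean
#' shapes separated at Mahalanobis distances between about 4 and 10 (one
#' species far more distinct than the rest), a size–shape (allometric)
#' relation explaining about 22% of the variance of the first discriminant
#' axis with a negative slope, and digitizing error amounting to 4% of the
#' total shape variance.
#'
#' Species mean shapes are placed in the tangent space of the template by a
#' classical-MDS embedding of `target_d` scaled by the within-group shape
#' noise, so the generated groups hit the requested Mahalanobis distances
#' by construction. The between-species size structure is solved
#' analytically from `allometry_r2` (see the methods vignette for the
#' derivation); `digitizing_error_sd` is likewise solved from
#' `digitizing_error_fraction` unless given directly.
#'
#' @param species Species labels.
#' @param n_per_species Group sizes (same length as `species`, each >= 3).
#' @param target_d Symmetric matrix of target Mahalanobis distances between
#'   species mean shapes.
#' @param shape_noise_sd Isotropic within-species shape noise sd per
#'   tangent-space dimension (Procrustes units). Default 0.003, a typical
#'   within-species scale for mosquito wings.
#' @param allometry_r2 Target squared correlation between the first
#'   discriminant axis and centroid size across all specimens. Default
#'   0.22; `NULL` disables allometric structure.
#' @param allometry_coeff Within-species shape displacement (Procrustes
#'   units along the dominant discriminant direction) per unit log centroid
#'   size. Default gives a mild individual-level allometry on top of the
#'   species-level size–shape coupling.
#' @param size_meanlog Grand mean of log centroid size (image units).
#'   Default `log(3)` (about a 3 mm wing at unit scale).
#' @param size_sdlog_within Within-species sd of log centroid size.
#'   Default 0.06.
#' @param digitizing_error_fraction Fraction of total shape variance due to
#'   digitizing error. Default 0.04.
#' @param digitizing_error_sd Explicit digitizing noise sd per tangent
#'   dimension; overrides the fraction when given.
#' @param n_replicates Extra digitizations per specimen (0 = none).
#' @param template An `p x 2` base configuration. Default [wing_template()].
#' @param seed Integer seed (required; generation is fully reproducible).
#' @return An object of class `"morpho_sim_spec"`.
#' @export
morpho_sim_spec <- function(species = c("chiangmaiensis", "fuscana",
                                        "halifaxii", "vorax"),
                            n_per_species = c(40L, 50L, 42L, 25L),
                            target_d = NULL,
                            shape_noise_sd = 0.003,
                            allometry_r2 = 0.22,
                            allometry_coeff = NULL,
                            size_meanlog = log(3),
                            size_sdlog_within = 0.06,
                            digitizing_error_fraction = 0.04,
                            digitizing_error_sd = NULL,
                            n_replicates = 0L,
                            template = wing_template(),
                            seed) {
  if (missing(seed)) wc_abort("`seed` is required for reproducibility.")
  n_sp <- length(species)
  if (length(n_per_species) != n_sp) {
    wc_abort("`n_per_species` must match `species` in length.")
  }
  if (any(n_per_species < 3L)) wc_abort("Each group needs n >= 3.")
  if (shape_noise_sd < 0 || size_sdlog_within < 0) {
    wc_abort("Standard deviations must be >= 0.")
  }
  if (is.null(target_d)) {
    target_d <- if (n_sp == 4L && identical(species, c("chiangmaiensis",
                                                       "fuscana", "halifaxii",
                                                       "vorax"))) {
      default_target_d()
    } else {
      6 * (1 - diag(n_sp))  # generic equidistant groups at D = 6
    }
  }
  target_d <- as.matrix(target_d)
  if (!isSymmetric(unname(target_d)) || nrow(target_d) != n_sp) {
    wc_abort("`target_d` must be a symmetric species x species matrix.")
  }
  ref <- unit_config(template)
  p <- nrow(ref)
  sigma <- shape_noise_sd
  tau_w <- size_sdlog_within

  # --- embed target separations (units of within-group sd) ----------------
  k_emb <- min(3L, n_sp - 1L)
  if (n_sp > 2L) {
    z <- stats::cmdscale(stats::as.dist(target_d), k = k_emb)
  } else if (n_sp == 2L) {
    z <- matrix(c(0, target_d[1, 2]), ncol = 1L)
  } else {
    z <- matrix(0, 1L, 1L)
  }
  if (ncol(z) < 3L) z <- cbind(z, matrix(0, n_sp, 3L - ncol(z)))
  w_s <- n_per_species / sum(n_per_species)
  z <- sweep(z, 2L, colSums(z * w_s))     # weighted centroid at origin

  # --- within-species allometric coefficient -------------------------------
  beta <- allometry_coeff
  if (is.null(beta)) {
    beta <- if (!is.null(allometry_r2) && sigma > 0) {
      sqrt(0.1) * sigma / max(tau_w, 1e-12)  # mild individual allometry
    } else {
      0
    }
  }

  # --- digitizing noise solved from the target error fraction --------------
  # every digitization (the original included) carries digitizing noise, so
  # the realized within-group variance per tangent dimension is
  # sigma^2 + d^2 (+ the allometric term along axis 1); the offsets below
  # are scaled by those full within sds so the Mahalanobis targets hold.
  q <- 2L * p - 4L
  d2 <- if (is.null(digitizing_error_sd)) 0 else digitizing_error_sd^2
  f <- digitizing_error_fraction
  if (is.null(digitizing_error_sd)) {
    if (f < 0 || f >= 1) wc_abort("`digitizing_error_fraction` must be in [0, 1).")
    for (it in 1:10) {
      s1sq <- sigma^2 + beta^2 * tau_w^2 + d2
      s23sq <- sigma^2 + d2
      between_total <- sum(w_s * (z[, 1L]^2 * s1sq +
                                  (z[, 2L]^2 + z[, 3L]^2) * s23sq))
      among_total <- between_total + q * sigma^2 + beta^2 * tau_w^2
      d2_new <- f / (1 - f) * among_total / q
      if (abs(d2_new - d2) < 1e-20) { d2 <- d2_new; break }
      d2 <- d2_new
    }
    digitizing_error_sd <- sqrt(d2)
  }
  w1 <- sqrt(sigma^2 + beta^2 * tau_w^2 + d2)   # full within sd, axis 1
  s23 <- sqrt(sigma^2 + d2)                     # full within sd, axes 2-3
  if (s23 == 0) {
    # degenerate noise-free case: separations in Mahalanobis units are
    # unbounded, so offsets fall back to a fixed Procrustes scale per unit
    w1 <- s23 <- 0.003
  }

  # raw tangent offsets scaled by the within sds -> Mahalanobis = target_d
  offsets <- cbind(z[, 1L] * w1, z[, 2L] * s23, z[, 3L] * s23)

  # --- between-species size structure solved from the target r^2 -----------
  tau_b <- 0
  if (!is.null(allometry_r2) && sigma > 0) {
    if (allometry_r2 < 0 || allometry_r2 >= 1) {
      wc_abort("`allometry_r2` must be in [0, 1).")
    }
    v_z <- sum(w_s * z[, 1L]^2)
    rho2 <- allometry_r2 * (v_z + 1)
    if (v_z > 0) {
      if (rho2 >= v_z) {
        wc_abort("`allometry_r2` too large for the given separations.")
      }
      A <- sqrt(v_z)
      cc <- beta * tau_w^2 / w1
      # (A^2 - rho2) tau_b^2 - 2 A cc tau_b + cc^2 - rho2 tau_w^2 = 0
      disc <- (A * cc)^2 - (A^2 - rho2) * (cc^2 - rho2 * tau_w^2)
      if (disc < 0) wc_abort("No feasible size structure for `allometry_r2`.")
      tau_b <- (A * cc + sqrt(disc)) / (A^2 - rho2)
    }
  }

  # species mean log sizes: coupled (negatively) to the first shape axis
  sdz <- sqrt(max(sum(w_s * z[, 1L]^2), 1e-300))
  meanlog_s <- size_meanlog - tau_b * z[, 1L] / sdz

  out <- list(
    species = species, n_per_species = as.integer(n_per_species),
    target_d = target_d, shape_noise_sd = sigma,
    allometry_r2 = allometry_r2, allometry_coeff = beta,
    size_meanlog = size_meanlog, size_sdlog_within = tau_w,
    size_meanlog_species = meanlog_s, tau_b = tau_b,
    digitizing_error_sd = digitizing_error_sd,
    n_replicates = as.integer(n_replicates),
    template = ref, offsets = offsets, seed = as.integer(seed)
  )
  class(out) <- "morpho_sim_spec"
  out
}

#' Generate a synthetic wing-landmark dataset
#'
#' Draws, per specimen: a log-normal centroid size; a shape equal to the
#' species mean shape plus an allometric displacement proportional to the
#' specimen's log-size deviation plus isotropic Gaussian noise (all in the
#' tangent space of the template, so the specified variances are Procrustes
#' variances); and emits coordinates after a random rotation, translation
#' and scaling by the centroid size. Replicate digitizations re-emit the
#' same wing with digitizing noise only. Fully reproducible from the seed.
#'
#' @param spec A [morpho_sim_spec()] object.
#' @return A long-format landmark tibble (see [landmark_data()]).
#' @examples
#' wings <- simulate_wings(morpho_sim_spec(seed = 1))
#' dplyr::count(wings, species) # 18 rows per specimen
#' @export
simulate_wings <- function(spec) {
  if (!inherits(spec, "morpho_sim_spec")) {
    wc_abort("`spec` must come from morpho_sim_spec().")
  }
  set.seed(spec$seed)
  ref <- spec$template
  p <- nrow(ref)
  basis <- tangent_basis(ref)
  Tb <- cbind(basis$nonaffine, basis$uniform)   # 2p x (2p - 4)
  q <- ncol(Tb)
  # species mean shapes; guard against landmark collisions
  for (s in seq_along(spec$species)) {
    off <- Tb[, 1:3, drop = FALSE] %*% spec$offsets[s, ]
    ms <- ref + cbind(off[1:p], off[(p + 1):(2 * p)])
    if (min(stats::dist(ms)) < 1e-6) {
      wc_abort(sprintf("Species '%s': displacement collapses landmarks.",
                       spec$species[[s]]))
    }
  }
  rows <- list()
  for (s in seq_along(spec$species)) {
    n_s <- spec$n_per_species[[s]]
    for (i in seq_len(n_s)) {
      log_cs <- stats::rnorm(1L, spec$size_meanlog_species[[s]],
                             spec$size_sdlog_within)
      eps <- log_cs - spec$size_meanlog_species[[s]]
      t_coord <- c(spec$offsets[s, ], rep(0, q - 3L))
      t_coord[1L] <- t_coord[1L] + spec$allometry_coeff * eps
      t_coord <- t_coord + stats::rnorm(q, 0, spec$shape_noise_sd)
      theta <- stats::runif(1L, 0, 2 * pi)
      R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
      shift <- stats::runif(2L, 0, 10)
      cs <- exp(log_cs)
      id <- sprintf("%s_%03d", spec$species[[s]], i)
      for (r in 0:spec$n_replicates) {
        t_r <- t_coord + stats::rnorm(q, 0, spec$digitizing_error_sd)
        off <- Tb %*% t_r
        shape <- ref + cbind(off[1:p], off[(p + 1):(2 * p)])
        coords <- cs * shape %*% t(R)
        coords <- sweep(coords, 2L, shift, `+`)
        rows[[length(rows) + 1L]] <- tibble(
          specimen = id, species = spec$species[[s]], replicate = r,
          landmark = seq_len(p), x = coords[, 1L], y = coords[, 2L],
          scale = NA_real_)
      }
    }
  }
  landmark_data(bind_rows(rows))
}
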