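# --- low-level Procrustes machinery (p x 2 matrices, block-free) ---------

center_config <- function(x) sweep(x, 2L, colMeans(x))

# optimal rotation R (2x2, det +1: reflections disallowed -- all wings are
# the same side) minimizing |x %*% R - target|^2
procrustes_rotation <- function(x, target) {
  m <- crossprod(x, target)
  sv <- svd(m)
  d <- sign(det(sv$u) * det(sv$v))
  sv$u %*% diag(c(1, d)) %*% t(sv$v)
}

unit_config <- function(x) {
  x <- center_config(x)
  cs <- sqrt(sum(x^2))
  if (cs <= .Machine$double.eps * nrow(x)) {
    wc_abort("Degenerate configuration: all landmarks coincide.",
             class = "wingcoi_degenerate")
  }
  x / cs
}

#' Generalized Procrustes superimposition
#'
#' Iteratively removes translation, scale and rotation from a set of
#' landmark configurations, leaving pure shape: each configuration is
#' centred, scaled to unit centroid size, and optimally rotated (rotation
#' only — no reflection, as all wings are digitized on the same side) onto
#' the running consensus, which is then updated, until the consensus moves
#' by less than `tol`. The consensus is initialized from the first
#' configuration; the result is invariant to that choice up to a global
#' rotation.
#'
#' @param data Long-format landmark data frame with at least 2
#'   configurations.
#' @param tol Convergence tolerance on the root-mean-square consensus
#'   change. Default `1e-8`.
#' @param max_iter Iteration cap; non-convergence sets `converged = FALSE`
#'   with a warning rather than failing.
#' @return An object of class `"wing_gpa"` with components
#'   `aligned` (long tibble of superimposed coordinates, each configuration
#'   centred with unit centroid size), `mean_shape` (consensus tibble,
#'   centroid size 1), `centroid_sizes` (pre-scaling sizes per
#'   configuration), `n_iterations`, `converged`, and the per-iteration
#'   Procrustes sum of squares `objective`.
#' @examples
#' wings <- simulate_wings(morpho_sim_spec(n_per_species = c(5, 5), seed = 2))
#' fit <- gpa_align(wings)
#' glance(fit)
#' @export
gpa_align <- function(data, tol = 1e-8, max_iter = 100L) {
  arr <- as_landmark_array(data)
  if (arr$n < 2L) wc_abort("GPA needs at least 2 configurations.")
  confs <- vector("list", arr$n)
  sizes <- numeric(arr$n)
  for (j in seq_len(arr$n)) {
    x <- arr$coords[, , j]
    xc <- center_config(x)
    cs <- sqrt(sum(xc^2))
    if (cs <= .Machine$double.eps * arr$p) {
      wc_abort(sprintf("Degenerate configuration for specimen '%s' (replicate %d).",
                       arr$info$specimen[[j]], arr$info$replicate[[j]]),
               class = "wingcoi_degenerate")
    }
    sizes[j] <- cs
    confs[[j]] <- xc / cs
  }
  consensus <- confs[[1L]]
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (j in seq_len(arr$n)) {
      confs[[j]] <- confs[[j]] %*% procrustes_rotation(confs[[j]], consensus)
    }
    new_cons <- Reduce(`+`, confs) / arr$n
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    objective <- c(objective,
                   sum(vapply(confs, function(x) sum((x - new_cons)^2), numeric(1))))
    delta <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    rlang::warn(sprintf("GPA did not converge in %d iterations.", max_iter))
  }
  coords <- array(unlist(confs), dim = c(arr$p, 2L, arr$n))
  out <- list(
    aligned = landmark_long(coords, arr$info),
    mean_shape = tibble(landmark = seq_len(arr$p),
                        x = consensus[, 1L], y = consensus[, 2L]),
    centroid_sizes = arr$info |>
      transmute(.data$specimen, .data$species, .data$replicate, csize = sizes),
    n_iterations = iter,
    converged = converged,
    objective = objective,
    p = arr$p
  )
  class(out) <- "wing_gpa"
  out
}

#' @export
print.wing_gpa <- function(x, ...) {
  cat(sprintf(
    "Generalized Procrustes alignment: %d configurations, %d landmarks\n",
    nrow(x$centroid_sizes), x$p))
  cat(sprintf("  iterations: %d (%s), Procrustes SS = %.6g\n",
              x$n_iterations,
              if (x$converged) "converged" else "NOT converged",
              tail(x$objective, 1)))
  invisible(x)
}

#' @method tidy wing_gpa
#' @export
tidy.wing_gpa <- function(x, ...) x$aligned

#' @method glance wing_gpa
#' @export
glance.wing_gpa <- function(x, ...) {
  tibble(
    n = nrow(x$centroid_sizes),
    n_landmarks = x$p,
    n_iterations = x$n_iterations,
    converged = x$converged,
    procrustes_ss = tail(x$objective, 1)
  )
}

#' Procrustes distance between two configurations
#'
#' Root summed squared difference between two landmark configurations after
#' centring, scaling to unit centroid size, and optimal (rotation-only)
#' superimposition. Zero exactly when the shapes are identical up to a
#' similarity transform; symmetric in its arguments.
#'
#' @param a,b Numeric `p x 2` coordinate matrices with the same landmark
#'   count (landmarks in corresponding order).
#' @return A non-negative number (the full Procrustes distance).
#' @export
procrustes_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) {
    wc_abort("Configurations must share the same landmark count.")
  }
  au <- unit_config(a)
  bu <- unit_config(b)
  # partial Procrustes: both at unit centroid size, rotation only; the
  # residual norm is computed explicitly (not via sqrt(2 - 2*gamma), which
  # loses half the significant digits near zero)
  R <- procrustes_rotation(bu, au)
  sqrt(sum((bu %*% R - au)^2))
}

#' Digitizing repeatability from replicate landmark configurations
#'
#' Quantifies how much of the observed shape variance reflects true
#' among-specimen differences rather than digitizing error. All replicate
#' digitizations are jointly superimposed by [gpa_align()], then the aligned
#' coordinates are partitioned by a one-way specimen-effect decomposition
#' pooled across all landmark coordinates: with mean squares `MS_among` and
#' `MS_within` and (average) replicate number r, the among-specimen variance
#' component is `(MS_among - MS_within)/r` (clipped at zero) and
#'
#'   repeatability = 100 * among / (among + within).
#'
#' Only specimens with at least two digitizations enter the decomposition.
#'
#' @param data Long-format landmark data with `replicate > 0` rows present
#'   for at least two specimens.
#' @return An object of class `"wing_repeatability"`: a list with
#'   `repeatability_pct`, `measurement_error_pct` (summing to 100),
#'   `n_specimens`, `n_configurations` and the underlying mean squares.
#' @examples
#' spec <- morpho_sim_spec(n_per_species = c(10, 10), n_replicates = 1,
#'                         seed = 7)
#' estimate_repeatability(simulate_wings(spec))
#' @export
estimate_repeatability <- function(data) {
  data <- landmark_data(data)
  reps <- data |>
    distinct(.data$specimen, .data$replicate) |>
    count(.data$specimen, name = "r") |>
    filter(.data$r >= 2L)
  if (nrow(reps) < 2L) {
    wc_abort(paste0(
      "Repeatability needs >= 2 specimens with >= 2 digitizations each; ",
      "re-digitize a subset of images (replicate > 0) and retry."))
  }
  sub <- semi_join(data, reps, by = "specimen")
  fit <- gpa_align(sub)
  arr <- as_landmark_array(fit$aligned)
  flat <- t(apply(arr$coords, 3L, as.vector))          # n_config x 2p
  spec_of <- arr$info$specimen
  grand <- colMeans(flat)
  specs <- unique(spec_of)
  ss_among <- 0; ss_within <- 0
  r_s <- integer(length(specs))
  for (k in seq_along(specs)) {
    rows <- flat[spec_of == specs[[k]], , drop = FALSE]
    r_s[k] <- nrow(rows)
    m <- colMeans(rows)
    ss_among <- ss_among + r_s[k] * sum((m - grand)^2)
    ss_within <- ss_within + sum(sweep(rows, 2L, m)^2)
  }
  s_n <- length(specs)
  n_tot <- sum(r_s)
  ms_among <- ss_among / (s_n - 1L)
  ms_within <- ss_within / (n_tot - s_n)
  # unbalanced one-way coefficient for the among component
  r0 <- (n_tot - sum(r_s^2) / n_tot) / (s_n - 1L)
  var_among <- max(0, (ms_among - ms_within) / r0)
  rep_pct <- 100 * var_among / (var_among + ms_within)
  out <- list(
    repeatability_pct = rep_pct,
    measurement_error_pct = 100 - rep_pct,
    n_specimens = s_n,
    n_configurations = n_tot,
    ms_among = ms_among,
    ms_within = ms_within
  )
  class(out) <- "wing_repeatability"
  out
}

#' @export
print.wing_repeatability <- function(x, ...) {
  cat(sprintf(
    "Digitizing repeatability: %.1f%% (measurement error %.1f%%)\n  %d specimens, %d digitizations\n",
    x$repeatability_pct, x$measurement_error_pct,
    x$n_specimens, x$n_configurations))
  invisible(x)
}

#' @method glance wing_repeatability
#' @export
glance.wing_repeatability <- function(x, ...) {
  tibble(
    repeatability_pct = x$repeatability_pct,
    measurement_error_pct = x$measurement_error_pct,
    n_specimens = x$n_specimens,
    n_configurations = x$n_configurations
  )
}
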