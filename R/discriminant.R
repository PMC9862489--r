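# pooled within-group covariance (unbiased, n - g denominator)
pooled_within_cov <- function(x, groups) {
  g <- unique(groups)
  ss <- matrix(0, ncol(x), ncol(x))
  for (lab in g) {
    rows <- x[groups == lab, , drop = FALSE]
    ss <- ss + crossprod(sweep(rows, 2L, colMeans(rows)))
  }
  ss / (nrow(x) - length(g))
}

group_means <- function(x, groups) {
  g <- sort(unique(groups))
  m <- t(vapply(g, function(lab) colMeans(x[groups == lab, , drop = FALSE]),
                numeric(ncol(x))))
  rownames(m) <- g
  m
}

# guard against near-singular pooled covariance: truncate to the leading
# principal subspace of the total covariance with condition number < cond_max;
# max_keep additionally caps the dimension (degrees-of-freedom guard)
truncate_for_conditioning <- function(x, groups, cond_max = 1e8,
                                      max_keep = Inf) {
  keep <- min(ncol(x), max_keep)
  repeat {
    W <- pooled_within_cov(x[, seq_len(keep), drop = FALSE], groups)
    ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
    if (ev[keep] > 0 && ev[1] / ev[keep] < cond_max) break
    keep <- keep - 1L
    if (keep == 0L) {
      wc_abort("Pooled within-group covariance is singular in every subspace.")
    }
  }
  if (keep < ncol(x)) {
    rlang::inform(sprintf(
      "Pooled covariance ill-conditioned: retaining the %d leading shape components.",
      keep))
  }
  keep
}

mahalanobis_matrix <- function(means, Winv) {
  g <- nrow(means)
  D <- matrix(0, g, g, dimnames = list(rownames(means), rownames(means)))
  for (i in seq_len(g - 1L)) {
    for (j in (i + 1L):g) {
      d <- means[i, ] - means[j, ]
      D[i, j] <- D[j, i] <- sqrt(drop(t(d) %*% Winv %*% d))
    }
  }
  D
}

check_groups <- function(species, min_per = 3L) {
  if (is.null(species) || all(is.na(species))) {
    wc_abort("Species labels are required for discrimination.")
  }
  tab <- table(species)
  if (length(tab) < 2L) wc_abort("At least 2 species groups are required.")
  small <- names(tab)[tab < min_per]
  if (length(small)) {
    wc_abort(paste0("Group(s) with fewer than ", min_per, " members: ",
                    paste(small, collapse = ", "), "."))
  }
  invisible(tab)
}

#' Canonical discriminant analysis of shape variables
#'
#' Computes the canonical (discriminant) axes maximizing between-group
#' relative to pooled within-group shape variance, and the pairwise
#' Mahalanobis distances between group means using the pooled within-group
#' covariance. Distances are reported as D (the square root), the scale on
#' which wing-shape divergences of congeneric mosquitoes typically fall
#' between about 4 and 10.
#'
#' If the pooled covariance is ill-conditioned (condition number above
#' 1e8), the trailing shape components are dropped with a message before
#' fitting.
#'
#' @param shape A `"shape_scores"` object from [shape_variables()], or a
#'   data frame with a `species` column and numeric score columns.
#' @param species Optional explicit label vector overriding the one in
#'   `shape`.
#' @return An object of class `"wing_cva"`: `canonical_scores` (tibble with
#'   `CV1..CV(g-1)`), `mahalanobis` (g x g symmetric matrix of D),
#'   `means`, `pooled_cov`, `axes`, `groups`, `eigenvalues`.
#' @examples
#' wings <- simulate_wings(morpho_sim_spec(seed = 4))
#' cva <- discriminant_analysis(shape_variables(gpa_align(wings)))
#' tidy(cva)
#' @export
discriminant_analysis <- function(shape, species = NULL) {
  sm <- score_matrix(shape)
  labels <- species %||% sm$species
  check_groups(labels)
  keep <- truncate_for_conditioning(
    sm$x, labels, max_keep = length(labels) - length(unique(labels)) - 1L)
  x <- sm$x[, seq_len(keep), drop = FALSE]
  g <- sort(unique(labels))
  means <- group_means(x, labels)
  W <- pooled_within_cov(x, labels)
  Winv <- solve(W)
  # between-group covariance (group-size weighted)
  grand <- colMeans(x)
  B <- matrix(0, ncol(x), ncol(x))
  for (lab in g) {
    n_l <- sum(labels == lab)
    d <- means[lab, ] - grand
    B <- B + n_l * tcrossprod(d)
  }
  B <- B / length(labels)
  # canonical axes via symmetric eigenproblem in the whitened metric
  eW <- eigen(W, symmetric = TRUE)
  Wih <- eW$vectors %*% diag(1 / sqrt(eW$values), ncol(x)) %*% t(eW$vectors)
  eM <- eigen(Wih %*% B %*% Wih, symmetric = TRUE)
  n_axes <- min(length(g) - 1L, ncol(x))
  A <- Wih %*% eM$vectors[, seq_len(n_axes), drop = FALSE]
  # orientation convention: largest-|coefficient| positive
  for (j in seq_len(n_axes)) {
    i_max <- which.max(abs(A[, j]))
    if (A[i_max, j] < 0) A[, j] <- -A[, j]
  }
  cvs <- sweep(x, 2L, grand) %*% A
  colnames(cvs) <- paste0("CV", seq_len(n_axes))
  canonical_scores <- bind_cols(
    tibble(specimen = sm$specimen %||% as.character(seq_along(labels)),
           species = labels,
           csize = sm$csize %||% NA_real_),
    as_tibble(cvs)
  )
  out <- list(
    canonical_scores = canonical_scores,
    mahalanobis = mahalanobis_matrix(means, Winv),
    means = means,
    pooled_cov = W,
    axes = A,
    groups = g,
    eigenvalues = pmax(eM$values[seq_len(n_axes)], 0),
    k_used = keep
  )
  class(out) <- "wing_cva"
  out
}

#' @export
print.wing_cva <- function(x, ...) {
  cat(sprintf("Canonical discriminant analysis: %d groups, %d shape variables\n",
              length(x$groups), x$k_used))
  cat("Pairwise Mahalanobis distances (D):\n")
  print(round(x$mahalanobis, 2))
  invisible(x)
}

#' @method tidy wing_cva
#' @export
tidy.wing_cva <- function(x, ...) {
  pairs <- utils::combn(x$groups, 2L)
  tibble(
    species_a = pairs[1L, ],
    species_b = pairs[2L, ],
    mahalanobis_d = apply(pairs, 2L, function(p) x$mahalanobis[p[1], p[2]])
  )
}

#' @method glance wing_cva
#' @export
glance.wing_cva <- function(x, ...) {
  tibble(
    n = nrow(x$canonical_scores),
    n_groups = length(x$groups),
    k_used = x$k_used,
    d_min = min(x$mahalanobis[upper.tri(x$mahalanobis)]),
    d_max = max(x$mahalanobis[upper.tri(x$mahalanobis)])
  )
}

# observed pairwise Mahalanobis D restricted to two groups' specimens
pair_mahalanobis <- function(x, labels, a, b) {
  rows <- labels %in% c(a, b)
  xs <- x[rows, , drop = FALSE]
  ls <- labels[rows]
  W <- pooled_within_cov(xs, ls)
  d <- colMeans(xs[ls == a, , drop = FALSE]) - colMeans(xs[ls == b, , drop = FALSE])
  sqrt(drop(t(d) %*% solve(W, d)))
}

#' Permutation test for pairwise shape divergence
#'
#' For every pair of species, specimen labels are permuted within the
#' pair's pooled sample and the Mahalanobis distance recomputed; the
#' p-value is the add-one Monte-Carlo estimate
#' `(1 + #\{permuted D >= observed D\}) / (n_perm + 1)` (never exactly
#' zero). Bonferroni correction multiplies each p by the number of pairs
#' before comparison with `alpha`.
#'
#' @inheritParams discriminant_analysis
#' @param n_perm Number of permutations (default 1000; fewer than 100
#'   triggers a warning).
#' @param alpha Significance level after correction. Default 0.05.
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @param seed Integer seed; required, every stochastic step in the
#'   pipeline is explicitly seeded.
#' @return A tibble with one row per species pair: `species_a`,
#'   `species_b`, `mahalanobis_d`, `p_value` (raw), `p_adjusted`,
#'   `significant`.
#' @export
mahalanobis_permutation_test <- function(shape, species = NULL,
                                         n_perm = 1000L, alpha = 0.05,
                                         correction = c("bonferroni", "none"),
                                         seed) {
  correction <- match.arg(correction)
  if (missing(seed)) wc_abort("`seed` is required for reproducibility.")
  if (n_perm < 100L) rlang::warn("n_perm < 100 gives very coarse p-values.")
  sm <- score_matrix(shape)
  labels <- species %||% sm$species
  check_groups(labels)
  keep <- truncate_for_conditioning(
    sm$x, labels, max_keep = length(labels) - length(unique(labels)) - 1L)
  x <- sm$x[, seq_len(keep), drop = FALSE]
  g <- sort(unique(labels))
  pairs <- utils::combn(g, 2L)
  n_pairs <- ncol(pairs)
  set.seed(seed)
  res <- vector("list", n_pairs)
  for (q in seq_len(n_pairs)) {
    a <- pairs[1L, q]; b <- pairs[2L, q]
    rows <- which(labels %in% c(a, b))
    xs <- x[rows, , drop = FALSE]
    ls <- labels[rows]
    keep_pair <- truncate_for_conditioning(xs, ls,
                                           max_keep = length(ls) - 3L)
    xs <- xs[, seq_len(keep_pair), drop = FALSE]
    obs <- pair_mahalanobis(xs, ls, a, b)
    exceed <- 0L
    for (r in seq_len(n_perm)) {
      perm <- sample(ls)
      d_perm <- pair_mahalanobis(xs, perm, a, b)
      if (d_perm >= obs) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (n_perm + 1)
    res[[q]] <- tibble(species_a = a, species_b = b,
                       mahalanobis_d = obs, p_value = p)
  }
  out <- bind_rows(res)
  out$p_adjusted <- if (correction == "bonferroni") {
    pmin(1, out$p_value * n_pairs)
  } else {
    out$p_value
  }
  out$significant <- out$p_adjusted < alpha
  out
}

#' Leave-one-out cross-validated reclassification
#'
#' Each specimen is removed in turn, group means and the pooled
#' within-group covariance are refit on the remaining specimens (full
#' cross-validation, not a reuse of the global covariance), and the
#' specimen is assigned to the group with the smallest Mahalanobis
#' distance. Returns the confusion matrix and per-group / total percentages
#' of correct identification.
#'
#' @inheritParams discriminant_analysis
#' @return An object of class `"wing_loo"`: `confusion` (g x g integer
#'   matrix, rows = true group, columns = assigned), `per_group_pct`,
#'   `total_pct`, `assignments` tibble.
#' @examples
#' wings <- simulate_wings(morpho_sim_spec(seed = 5))
#' loo <- loo_classification(shape_variables(gpa_align(wings)))
#' loo$total_pct
#' @export
loo_classification <- function(shape, species = NULL) {
  sm <- score_matrix(shape)
  labels <- species %||% sm$species
  tab <- table(labels)
  if (length(tab) == 1L) {
    rlang::warn("Single group: leave-one-out classification is trivially 100%.")
    g1 <- names(tab)
    conf <- matrix(as.integer(tab), 1L, 1L, dimnames = list(g1, g1))
    out <- list(confusion = conf, per_group_pct = setNames(100, g1),
                total_pct = 100,
                assignments = tibble(specimen = sm$specimen, species = labels,
                                     assigned = labels, correct = TRUE))
    class(out) <- "wing_loo"
    return(out)
  }
  check_groups(labels)
  keep <- truncate_for_conditioning(
    sm$x, labels, max_keep = length(labels) - length(unique(labels)) - 2L)
  x <- sm$x[, seq_len(keep), drop = FALSE]
  g <- sort(unique(labels))
  n <- nrow(x)
  assigned <- character(n)
  for (i in seq_len(n)) {
    xi <- x[-i, , drop = FALSE]
    li <- labels[-i]
    means <- group_means(xi, li)
    Winv <- solve(pooled_within_cov(xi, li))
    d2 <- vapply(g, function(lab) {
      d <- x[i, ] - means[lab, ]
      drop(t(d) %*% Winv %*% d)
    }, numeric(1))
    assigned[i] <- g[which.min(d2)]
  }
  conf <- table(factor(labels, levels = g), factor(assigned, levels = g))
  conf <- matrix(as.integer(conf), length(g), length(g),
                 dimnames = list(g, g))
  per_group <- 100 * diag(conf) / rowSums(conf)
  out <- list(
    confusion = conf,
    per_group_pct = per_group,
    total_pct = 100 * sum(diag(conf)) / n,
    assignments = tibble(
      specimen = sm$specimen %||% as.character(seq_len(n)),
      species = labels, assigned = assigned,
      correct = labels == assigned)
  )
  class(out) <- "wing_loo"
  out
}

#' @export
print.wing_loo <- function(x, ...) {
  cat(sprintf("Leave-one-out reclassification: %.2f%% correct overall\n",
              x$total_pct))
  print(x$confusion)
  invisible(x)
}

#' @method tidy wing_loo
#' @export
tidy.wing_loo <- function(x, ...) {
  as_tibble(as.data.frame.table(x$confusion, stringsAsFactors = FALSE)) |>
    setNames(c("species", "assigned", "n")) |>
    mutate(n = as.integer(.data$n))
}

#' @method glance wing_loo
#' @export
glance.wing_loo <- function(x, ...) {
  tibble(total_pct = x$total_pct,
         min_group_pct = min(x$per_group_pct),
         max_group_pct = max(x$per_group_pct),
         n = sum(x$confusion))
}

#' Allometry: regression of shape on size
#'
#' Ordinary least squares of the first discriminant-axis score (or, for a
#' plain score matrix, its first column) on centroid size, with the
#' coefficient of determination r² quantifying the size effect on shape
#' and a permutation p-value obtained by shuffling sizes across specimens.
#' The reported slope sign refers to the package's documented axis
#' orientation (largest-|coefficient| positive); only |r| and r² are
#' orientation-invariant.
#'
#' @param shape A `"wing_cva"` object (first canonical axis used), a
#'   `"shape_scores"` object, or a data frame of scores.
#' @param sizes Centroid sizes per specimen; taken from `shape` when it
#'   carries a `csize` column.
#' @param n_perm Number of size permutations for the p-value. Default 1000.
#' @param seed Integer seed (required).
#' @return An object of class `"wing_allometry"`: `r_squared`, `p_value`,
#'   `slope`, `slope_sign`, `n`, and the fitted values tibble `data`.
#' @export
allometry_regression <- function(shape, sizes = NULL, n_perm = 1000L, seed) {
  if (missing(seed)) wc_abort("`seed` is required for reproducibility.")
  if (inherits(shape, "wing_cva")) {
    y <- shape$canonical_scores$CV1
    sizes <- sizes %||% shape$canonical_scores$csize
  } else {
    sm <- score_matrix(shape)
    y <- sm$x[, 1L]
    sizes <- sizes %||% sm$csize
  }
  if (is.null(sizes) || all(is.na(sizes))) {
    wc_abort("Centroid sizes are required (supply `sizes`).")
  }
  if (length(sizes) != length(y)) {
    wc_abort("`sizes` must have one value per specimen.")
  }
  if (stats::sd(sizes) < .Machine$double.eps) {
    wc_abort("Zero size variance: allometry regression is undefined.")
  }
  fit <- stats::lm(y ~ sizes)
  r2 <- summary(fit)$r.squared
  set.seed(seed)
  exceed <- 0L
  for (r in seq_len(n_perm)) {
    r2_perm <- stats::cor(y, sample(sizes))^2
    if (r2_perm >= r2 - 1e-15) exceed <- exceed + 1L
  }
  slope <- unname(coef(fit)[2L])
  out <- list(
    r_squared = r2,
    p_value = (1 + exceed) / (n_perm + 1),
    slope = slope,
    slope_sign = if (abs(slope) < .Machine$double.eps) "zero"
                 else if (slope > 0) "positive" else "negative",
    n = length(y),
    data = tibble(csize = sizes, shape_score = y)
  )
  class(out) <- "wing_allometry"
  out
}

#' @export
print.wing_allometry <- function(x, ...) {
  cat(sprintf("Allometry: r^2 = %.3f (%s slope), permutation p = %.4g, n = %d\n",
              x$r_squared, x$slope_sign, x$p_value, x$n))
  invisible(x)
}

#' @method glance wing_allometry
#' @export
glance.wing_allometry <- function(x, ...) {
  tibble(r_squared = x$r_squared, p_value = x$p_value,
         slope = x$slope, slope_sign = x$slope_sign, n = x$n)
}
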