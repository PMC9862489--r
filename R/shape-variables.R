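# Thin-plate-spline bending-energy matrix of a p x 2 reference shape.
# K_ij = r^2 log r^2; the bending energy is the upper-left p x p block of
# the inverse of the bordered system [[K, Q], [Q', 0]], Q = [1 | ref].
bending_energy <- function(ref) {
  p <- nrow(ref)
  d2 <- as.matrix(stats::dist(ref))^2
  K <- ifelse(d2 > 0, d2 * log(d2), 0)
  Q <- cbind(1, ref)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3L, 3L)))
  if (rcond(L) < 1e-14) {
    wc_abort("Singular bending-energy system: reference has coincident landmarks.",
             class = "wingcoi_degenerate")
  }
  Linv <- solve(L)
  Be <- Linv[seq_len(p), seq_len(p), drop = FALSE]
  (Be + t(Be)) / 2
}

# Orthonormal basis (2p x 4) of the similarity transforms at a centred,
# unit-size reference, block layout c(x, y): translations, scaling, rotation.
similarity_basis <- function(ref) {
  p <- nrow(ref)
  cbind(
    c(rep(1, p), rep(0, p)) / sqrt(p),
    c(rep(0, p), rep(1, p)) / sqrt(p),
    c(ref[, 1L], ref[, 2L]),            # scaling (unit: |ref| = 1)
    c(-ref[, 2L], ref[, 1L])            # infinitesimal rotation
  )
}

# Tangent-space basis at the consensus split into non-affine (partial-warp)
# and uniform (affine) parts. Columns are orthonormal, jointly spanning the
# (2p - 4)-dimensional shape tangent space.
tangent_basis <- function(ref) {
  p <- nrow(ref)
  Be <- bending_energy(ref)
  eig <- eigen(Be, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-10
  E <- eig$vectors[, pos, drop = FALSE]       # p x (p - 3)
  zero2 <- matrix(0, p, ncol(E))
  nonaffine <- cbind(rbind(E, zero2), rbind(zero2, E))  # 2p x (2p - 6)
  S <- similarity_basis(ref)
  qrc <- qr(cbind(S, nonaffine))
  full <- qr.Q(qrc, complete = TRUE)
  uniform <- full[, (ncol(S) + ncol(nonaffine) + 1L):(2L * p), drop = FALSE]
  list(nonaffine = nonaffine, uniform = uniform, similarity = S,
       bending_values = eig$values[pos])
}

#' Shape variables from a Procrustes alignment
#'
#' Converts superimposed coordinates into the final shape variables used for
#' discrimination: the aligned residuals about the consensus are projected
#' into the shape tangent space, expressed as partial-warp scores (the
#' thin-plate-spline bending-energy eigenbasis of the consensus, i.e. the
#' non-affine components) plus the two uniform (affine) components, and then
#' rotated to principal components. Components are retained up to the
#' smallest dimension reaching `variance_retained` of the total shape
#' variance. Because the partial-warp + uniform basis is an orthonormal
#' basis of the tangent space, total variance is conserved and the retained
#' space coincides with principal components of the Procrustes residuals.
#'
#' Axis orientation is fixed by the convention that each component's largest
#' absolute loading is positive (principal-component signs are otherwise
#' arbitrary).
#'
#' @param alignment A `"wing_gpa"` object from [gpa_align()] (>= 3
#'   specimens).
#' @param variance_retained Fraction of total shape variance the retained
#'   components must reach, in (0, 1]. Default 0.99. The source study does
#'   not state its retained dimension, so this is deliberately a parameter.
#' @return An object of class `"shape_scores"`: `scores` (tibble: specimen
#'   metadata, centroid size `csize`, and columns `PC1..PCk`), `basis`
#'   (2p x k loadings on the c(x, y)-stacked coordinates), `explained`
#'   (per-component variance fractions), `k`, `consensus`.
#' @examples
#' wings <- simulate_wings(morpho_sim_spec(seed = 3))
#' sv <- shape_variables(gpa_align(wings))
#' sv$k
#' @export
shape_variables <- function(alignment, variance_retained = 0.99) {
  if (!inherits(alignment, "wing_gpa")) {
    wc_abort("`alignment` must come from gpa_align().")
  }
  if (variance_retained <= 0 || variance_retained > 1) {
    wc_abort("`variance_retained` must be in (0, 1].")
  }
  arr <- as_landmark_array(alignment$aligned)
  if (arr$n < 3L) wc_abort("Shape variables need >= 3 specimens.")
  ref <- cbind(alignment$mean_shape$x, alignment$mean_shape$y)
  basis <- tangent_basis(ref)
  flat <- t(apply(arr$coords, 3L, as.vector))               # n x 2p, c(x,y)
  resid <- sweep(flat, 2L, c(ref[, 1L], ref[, 2L]))
  S <- basis$similarity
  tang <- resid - resid %*% S %*% t(S)                      # tangent projection
  W <- tang %*% cbind(basis$nonaffine, basis$uniform)       # pw + uniform scores
  total_var <- sum(apply(W, 2L, stats::var))
  sizes <- alignment$centroid_sizes
  if (total_var < .Machine$double.eps) {
    rlang::warn("No shape variation present; zero shape variables returned.")
    scores <- bind_cols(arr$info[c("specimen", "species", "replicate")],
                        tibble(csize = sizes$csize))
    out <- list(scores = scores, basis = matrix(0, 2L * arr$p, 0L),
                explained = numeric(0), k = 0L, consensus = ref,
                total_variance = 0)
    class(out) <- "shape_scores"
    return(out)
  }
  pca <- stats::prcomp(W, center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2
  frac <- ev / sum(ev)
  k <- which(cumsum(frac) >= variance_retained - 1e-12)[1]
  keep <- seq_len(k)
  rot <- pca$rotation[, keep, drop = FALSE]
  sc <- pca$x[, keep, drop = FALSE]
  # orientation convention: largest-|loading| positive
  full_basis <- cbind(basis$nonaffine, basis$uniform) %*% rot
  for (j in seq_len(k)) {
    i_max <- which.max(abs(full_basis[, j]))
    if (full_basis[i_max, j] < 0) {
      full_basis[, j] <- -full_basis[, j]
      sc[, j] <- -sc[, j]
    }
  }
  colnames(sc) <- paste0("PC", seq_len(k))
  scores <- bind_cols(
    arr$info[c("specimen", "species", "replicate")],
    tibble(csize = sizes$csize[match(
      paste(arr$info$specimen, arr$info$replicate),
      paste(sizes$specimen, sizes$replicate))]),
    as_tibble(sc)
  )
  out <- list(scores = scores, basis = full_basis, explained = frac[keep],
              k = k, consensus = ref, total_variance = total_var)
  class(out) <- "shape_scores"
  out
}

#' @export
print.shape_scores <- function(x, ...) {
  cat(sprintf(
    "Shape variables: %d specimens x %d components (%.2f%% of shape variance)\n",
    nrow(x$scores), x$k, 100 * sum(x$explained)))
  invisible(x)
}

#' @method tidy shape_scores
#' @export
tidy.shape_scores <- function(x, ...) x$scores

#' @method glance shape_scores
#' @export
glance.shape_scores <- function(x, ...) {
  tibble(n = nrow(x$scores), k = x$k,
         variance_retained = sum(x$explained),
         total_variance = x$total_variance)
}

# internal: numeric score matrix + labels from a shape_scores object or a
# data frame whose numeric columns are the variables
score_matrix <- function(shape) {
  if (inherits(shape, "shape_scores")) {
    df <- shape$scores
  } else if (is.data.frame(shape)) {
    df <- shape
  } else {
    wc_abort("Expected a shape_scores object or a data frame of scores.")
  }
  pc_cols <- grep("^PC\\d+$", names(df), value = TRUE)
  if (!length(pc_cols)) {
    pc_cols <- names(df)[vapply(df, is.numeric, logical(1))]
    pc_cols <- setdiff(pc_cols, c("csize", "replicate", "landmark"))
  }
  if (!length(pc_cols)) wc_abort("No score columns found.")
  list(x = as.matrix(df[pc_cols]),
       species = if ("species" %in% names(df)) df$species else NULL,
       specimen = if ("specimen" %in% names(df)) df$specimen else NULL,
       csize = if ("csize" %in% names(df)) df$csize else NULL)
}
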