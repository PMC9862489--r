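# clamp a newly computed pair of sister branch lengths: a negative branch is
# set to zero and its deficit moved to the adjacent (sister) branch, so the
# path length between the two children is preserved
clamp_pair <- function(b) {
  if (b[1] < 0) { b[2] <- b[2] + b[1]; b[1] <- 0 }
  if (b[2] < 0) { b[1] <- max(0, b[1] + b[2]); b[2] <- 0 }
  b
}

newick_label <- function(x) gsub("[,;:()\\s]+", "_", x, perl = TRUE)

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou–Nei agglomeration: at each step the pair minimizing the
#' Q-criterion `Q_ij = (n-2) d_ij - r_i - r_j` is joined, branch lengths
#' follow the standard formulas, and the reduced matrix uses
#' `d_uk = (d_ik + d_jk - d_ij)/2`. Negative branch lengths are clamped to
#' zero with the deficit transferred to the sister branch (path lengths
#' between the joined children are preserved). On additive input matrices
#' the tree reproduces all pairwise distances exactly.
#'
#' @param dist A symmetric numeric matrix with zero diagonal, `n >= 3`.
#' @param taxa Tip names; defaults to the matrix dimnames.
#' @return An unrooted [ape::phylo] tree.
#' @examples
#' d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' nj_tree(d)
#' @export
nj_tree <- function(dist, taxa = NULL) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 3L) wc_abort("NJ needs at least 3 taxa.")
  if (!isSymmetric(unname(d)) || any(abs(diag(d)) > 1e-12)) {
    wc_abort("`dist` must be symmetric with zero diagonal.")
  }
  taxa <- taxa %||% rownames(d) %||% paste0("t", seq_len(n))
  nodes <- newick_label(taxa)
  active <- seq_len(n)
  while (length(active) > 3L) {
    m <- length(active)
    da <- d[active, active]
    r <- rowSums(da)
    Q <- (m - 2) * da - outer(r, r, `+`)
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)[1L, ]
    i <- ij[[1]]; j <- ij[[2]]
    if (i > j) { k <- i; i <- j; j <- k }
    bi <- da[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    b <- clamp_pair(c(bi, da[i, j] - bi))
    new_node <- sprintf("(%s:%.12g,%s:%.12g)",
                        nodes[active[i]], b[1], nodes[active[j]], b[2])
    du <- (da[i, ] + da[j, ] - da[i, j]) / 2
    ai <- active[i]; aj <- active[j]
    d[ai, active] <- du
    d[active, ai] <- du
    d[ai, ai] <- 0
    nodes[ai] <- new_node
    active <- setdiff(active, aj)
  }
  a <- active
  b1 <- (d[a[1], a[2]] + d[a[1], a[3]] - d[a[2], a[3]]) / 2
  b2 <- (d[a[1], a[2]] + d[a[2], a[3]] - d[a[1], a[3]]) / 2
  b3 <- (d[a[1], a[3]] + d[a[2], a[3]] - d[a[1], a[2]]) / 2
  bs <- c(b1, b2, b3)
  # clamp any negative terminal branch, moving the deficit to the largest
  for (q in seq_len(3L)) {
    if (bs[q] < 0) {
      big <- which.max(bs)
      bs[big] <- bs[big] + bs[q]
      bs[q] <- 0
    }
  }
  bs <- pmax(bs, 0)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 nodes[a[1]], bs[1], nodes[a[2]], bs[2], nodes[a[3]], bs[3])
  ape::read.tree(text = nwk)
}

#' Bootstrap supports for a neighbor-joining barcode tree
#'
#' Builds the full-data K2P + NJ tree, then resamples alignment columns
#' with replacement `n_boot` times, recomputing distances and tree per
#' replicate. Supports are the percentage of replicates containing each
#' bipartition of the full-data tree (the supports annotate the full-data
#' topology, not a consensus). Replicates whose resampled distances
#' saturate are skipped and counted; more than 1% skipped triggers a
#' warning.
#'
#' @param seqs A sequence tibble (>= 4 records).
#' @param n_boot Bootstrap replicates, default 1000.
#' @param outgroup Optional record id to root the display tree on.
#' @param seed Integer seed (required).
#' @inheritParams k2p_distance
#' @return An [ape::phylo] tree with node labels holding bootstrap
#'   percentages; attribute `"n_skipped"` counts saturated replicates.
#' @export
bootstrap_nj <- function(seqs, n_boot = 1000L, outgroup = NULL, seed,
                         deletion = c("pairwise", "complete")) {
  if (missing(seed)) wc_abort("`seed` is required for reproducibility.")
  deletion <- match.arg(deletion)
  seqs <- validate_seqs(seqs, min_records = 4L)
  m <- seq_int_matrix(seqs)
  if (deletion == "complete") {
    keep <- colSums(m == 0L) == 0L
    if (!any(keep)) wc_abort("Complete deletion leaves no sites.")
    m <- m[, keep, drop = FALSE]
  }
  full_d <- codes_to_k2p_matrix(m, seqs$id)
  phy <- nj_tree(full_d)
  set.seed(seed)
  boots <- list()
  skipped <- 0L
  L <- ncol(m)
  for (b in seq_len(n_boot)) {
    cols <- sample.int(L, L, replace = TRUE)
    db <- tryCatch(codes_to_k2p_matrix(m[, cols, drop = FALSE], seqs$id),
                   wingcoi_saturation = function(e) NULL,
                   wingcoi_no_sites = function(e) NULL)
    if (is.null(db)) { skipped <- skipped + 1L; next }
    boots[[length(boots) + 1L]] <- nj_tree(db)
  }
  if (skipped > 0.01 * n_boot) {
    rlang::warn(sprintf("%d of %d bootstrap replicates skipped (saturated distances).",
                        skipped, n_boot))
  }
  n_valid <- length(boots)
  counts <- ape::prop.clades(phy, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  phy$node.label <- as.character(round(100 * counts / max(n_valid, 1L)))
  if (!is.null(outgroup)) {
    og <- newick_label(outgroup)
    if (!og %in% phy$tip.label) wc_abort(paste0("Outgroup not found: ", outgroup))
    phy <- ape::root(phy, outgroup = og, resolve.root = TRUE,
                     edgelabel = TRUE)
  }
  attr(phy, "n_skipped") <- skipped
  phy
}

codes_to_k2p_matrix <- function(m, ids) {
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- k2p_from_codes(
        m[i, ], m[j, ], pair_name = paste(ids[i], "vs", ids[j]))
    }
  }
  D
}
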