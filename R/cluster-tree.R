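hclust_method <- function(linkage) {
  switch(linkage,
         upgma = "average",
         single = "single",
         complete = "complete",
         wc_abort("`linkage` must be one of 'upgma', 'single', 'complete'."))
}

#' Hierarchical clustering tree of shape similarity
#'
#' Builds an agglomerative tree on the pairwise Mahalanobis distance matrix
#' between species mean shapes (UPGMA by default) and, when raw scores are
#' supplied, attaches bootstrap supports: specimens are resampled with
#' replacement *within* species (so group sizes are preserved), the
#' Mahalanobis matrix and tree recomputed, and each internal partition's
#' support is the percentage of replicates reproducing it.
#'
#' @param shape A `"shape_scores"` object or score data frame (needed for
#'   bootstrapping); may be `NULL` to cluster a precomputed matrix without
#'   supports.
#' @param species Optional label vector overriding the one in `shape`.
#' @param mahalanobis Optional precomputed g x g distance matrix; computed
#'   from `shape` when `NULL`.
#' @param linkage `"upgma"` (default), `"single"`, or `"complete"`. The
#'   linkage behind published wing-shape trees is rarely stated; UPGMA is
#'   the conventional choice for ultrametric similarity displays.
#' @param n_boot Bootstrap replicates (default 1000); 0 disables supports.
#' @param seed Integer seed (required when bootstrapping).
#' @return An [ape::phylo] tree with species as tips, branch lengths from
#'   the linkage heights, and node labels holding bootstrap percentages
#'   (when computed). Write with [ape::write.tree()].
#' @export
shape_cluster_tree <- function(shape = NULL, species = NULL,
                               mahalanobis = NULL,
                               linkage = c("upgma", "single", "complete"),
                               n_boot = 1000L, seed = NULL) {
  linkage <- match.arg(linkage)
  if (is.null(mahalanobis)) {
    if (is.null(shape)) wc_abort("Supply `shape` or a precomputed `mahalanobis` matrix.")
    cva <- discriminant_analysis(shape, species = species)
    mahalanobis <- cva$mahalanobis
  }
  if (!isSymmetric(unname(mahalanobis)) || any(diag(mahalanobis) != 0)) {
    wc_abort("`mahalanobis` must be symmetric with zero diagonal.")
  }
  g <- nrow(mahalanobis)
  if (g < 3L) wc_abort("A clustering tree needs >= 3 groups.")
  hc <- stats::hclust(stats::as.dist(mahalanobis), method = hclust_method(linkage))
  phy <- ape::as.phylo(hc)
  if (n_boot > 0L && !is.null(shape)) {
    if (is.null(seed)) wc_abort("`seed` is required for bootstrapping.")
    sm <- score_matrix(shape)
    labels <- species %||% sm$species
    keep <- truncate_for_conditioning(
      sm$x, labels, max_keep = length(labels) - length(unique(labels)) - 1L)
    x <- sm$x[, seq_len(keep), drop = FALSE]
    set.seed(seed)
    boots <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(sort(unique(labels)), function(lab) {
        rows <- which(labels == lab)
        sample(rows, length(rows), replace = TRUE)
      }))
      xb <- x[idx, , drop = FALSE]
      lb <- labels[idx]
      # resampling duplicates rows, so re-check conditioning per replicate
      kb <- suppressMessages(truncate_for_conditioning(xb, lb))
      xb <- xb[, seq_len(kb), drop = FALSE]
      Db <- mahalanobis_matrix(group_means(xb, lb),
                               solve(pooled_within_cov(xb, lb)))
      hb <- stats::hclust(stats::as.dist(Db), method = hclust_method(linkage))
      boots[[b]] <- ape::as.phylo(hb)
    }
    counts <- ape::prop.clades(phy, boots, rooted = TRUE)
    counts[is.na(counts)] <- 0
    phy$node.label <- as.character(round(100 * counts / n_boot))
  }
  phy
}
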