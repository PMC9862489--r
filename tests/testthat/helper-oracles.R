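# Independent oracles used by the tests. Each is deliberately written along
# a different computational path than the package implementation it checks.

# random p x 2 configuration with landmarks spread out (non-degenerate)
random_config <- function(p = 18, spread = 1) {
  matrix(stats::runif(2 * p, -spread, spread), p, 2)
}

rigid_motion <- function(x, theta = stats::runif(1, 0, 2 * pi),
                         shift = stats::rnorm(2, 0, 5), scale = 1) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  sweep(scale * x %*% t(R), 2, shift, `+`)
}

# Procrustes distance by brute-force minimization over a dense grid of
# rotation angles (no SVD): d^2(theta) = |A - B R(theta)|^2 for unit-size
# centred A, B, minimized over the grid.
procrustes_distance_grid <- function(a, b, n_grid = 1e6) {
  centre_unit <- function(x) {
    x <- sweep(x, 2, colMeans(x))
    x / sqrt(sum(x^2))
  }
  a <- centre_unit(a); b <- centre_unit(b)
  # |A - B R|^2 = 2 - 2 (cos(t) * s1 + sin(t) * s2)
  s1 <- sum(a * b)
  s2 <- sum(a[, 1] * b[, 2] - a[, 2] * b[, 1])
  theta <- seq(0, 2 * pi, length.out = n_grid)
  d2 <- 2 - 2 * (cos(theta) * s1 + sin(theta) * s2)
  sqrt(max(0, min(d2)))
}

# K2P by explicit per-site classification on character vectors: an
# independent site-count route (string sets, no integer coding).
k2p_sitecount_oracle <- function(s1, s2) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  stopifnot(length(a) == length(b))
  purines <- c("A", "G")
  pyrimidines <- c("C", "T")
  nts <- c(purines, pyrimidines)
  n <- 0; ts <- 0; tv <- 0
  for (i in seq_along(a)) {
    if (!(a[i] %in% nts) || !(b[i] %in% nts)) next
    n <- n + 1
    if (a[i] == b[i]) next
    same_class <- (a[i] %in% purines && b[i] %in% purines) ||
      (a[i] %in% pyrimidines && b[i] %in% pyrimidines)
    if (same_class) ts <- ts + 1 else tv <- tv + 1
  }
  P <- ts / n; Q <- tv / n
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# random DNA string (optionally with gap/N contamination)
random_dna <- function(L, gap_frac = 0) {
  s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  if (gap_frac > 0) {
    k <- rbinom(1, L, gap_frac)
    if (k > 0) s[sample(L, k)] <- sample(c("-", "N"), k, replace = TRUE)
  }
  paste(s, collapse = "")
}

# mutate a sequence with fixed numbers of transitions and transversions at
# distinct sites
mutate_sites <- function(seq, n_ts = 0, n_tv = 0) {
  ch <- strsplit(seq, "")[[1]]
  sites <- sample(seq_along(ch), n_ts + n_tv)
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- c(A = "C", G = "T", C = "G", T = "A")
  if (n_ts > 0) for (i in sites[seq_len(n_ts)]) ch[i] <- ts_map[[ch[i]]]
  if (n_tv > 0) for (i in sites[n_ts + seq_len(n_tv)]) ch[i] <- tv_map[[ch[i]]]
  paste(ch, collapse = "")
}

# --- exhaustive least-squares topology search for small NJ checks --------

# brute force: enumerate all unrooted topologies (n = 4: 3; n = 5: 15),
# fit least-squares branch lengths via the path-indicator design matrix,
# return the topology with the smallest residual sum of squares
best_ls_topology <- function(d) {
  n <- nrow(d)
  taxa <- rownames(d)
  topos <- generate_unrooted_topologies(taxa)
  fits <- vapply(topos, function(nwk) {
    phy <- ape::read.tree(text = nwk)
    X <- path_design_matrix(phy, taxa)
    y <- d[t(combn(taxa, 2))]
    b <- stats::coef(stats::lm.fit(X, y))
    b[is.na(b)] <- 0
    sum((X %*% b - y)^2)
  }, numeric(1))
  best <- ape::read.tree(text = topos[[which.min(fits)]])
  list(tree = best, rss = min(fits), all_rss = fits)
}

# unrooted topologies as newick strings (n = 4 or 5 taxa)
generate_unrooted_topologies <- function(taxa) {
  n <- length(taxa)
  if (n == 4) {
    t_ <- taxa
    return(list(
      sprintf("((%s,%s),%s,%s);", t_[1], t_[2], t_[3], t_[4]),
      sprintf("((%s,%s),%s,%s);", t_[1], t_[3], t_[2], t_[4]),
      sprintf("((%s,%s),%s,%s);", t_[1], t_[4], t_[2], t_[3])
    ))
  }
  if (n == 5) {
    # every unrooted binary 5-taxon tree is two cherries plus a middle
    # taxon: 5 choices of middle x 3 pairings of the rest = 15 topologies
    out <- list()
    for (mid in seq_len(5)) {
      rest <- taxa[-mid]
      for (pairing in list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))) {
        out[[length(out) + 1L]] <- sprintf(
          "((%s,%s),%s,(%s,%s));",
          rest[pairing[1]], rest[pairing[2]], taxa[mid],
          rest[pairing[3]], rest[pairing[4]])
      }
    }
    return(out)
  }
  stop("only 4 or 5 taxa supported")
}

# design matrix mapping branch lengths to pairwise path lengths
path_design_matrix <- function(phy, taxa) {
  n_edge <- nrow(phy$edge)
  prs <- t(combn(taxa, 2))
  X <- matrix(0, nrow(prs), n_edge)
  for (r in seq_len(nrow(prs))) {
    i <- match(prs[r, 1], phy$tip.label)
    j <- match(prs[r, 2], phy$tip.label)
    # path between tips: edges on i->root and j->root, symmetric difference
    anc <- function(tip) {
      path <- integer(0)
      node <- tip
      repeat {
        e <- which(phy$edge[, 2] == node)
        if (!length(e)) break
        path <- c(path, e)
        node <- phy$edge[e, 1]
      }
      path
    }
    pi_ <- anc(i); pj <- anc(j)
    X[r, c(setdiff(pi_, pj), setdiff(pj, pi_))] <- 1
  }
  X
}

# simulate a plain Gaussian "shape score" data frame for null calibration
null_scores <- function(n_per_group, k, labels = c("g1", "g2"), shift = 0) {
  x <- matrix(rnorm(sum(n_per_group) * k), ncol = k)
  x[seq_len(n_per_group[1]), 1] <- x[seq_len(n_per_group[1]), 1] + shift
  df <- tibble::as_tibble(as.data.frame(x))
  names(df) <- paste0("PC", seq_len(k))
  df$species <- rep(labels, n_per_group)
  df$specimen <- sprintf("s%03d", seq_len(nrow(df)))
  df
}
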