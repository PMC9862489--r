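# Default per-pair interspecific K2P targets (substitutions/site): the
# divergence scale of congeneric COI barcodes, including one species pair
# whose separation sits below the intraspecific maxima (no barcoding gap).
default_inter_targets <- function(species) {
  stopifnot(length(species) == 4L)
  M <- matrix(0, 4L, 4L, dimnames = list(species, species))
  M[1, 2] <- 0.0186; M[1, 3] <- 0.0170; M[1, 4] <- 0.0511
  M[2, 3] <- 0.0048; M[2, 4] <- 0.0496
  M[3, 4] <- 0.0474
  M + t(M)
}

#' Specification for the synthetic COI barcode generator
#'
#' Defaults emulate a four-species congeneric barcode study: 10 sequences
#' per species, 658 bp coding sequences, intraspecific K2P divergences
#' between about 0.2% and 0.8%, interspecific divergences up to about
#' 5.6%, and one species pair (`fuscana`–`halifaxii` in the default
#' naming) whose interspecific divergence falls below the intraspecific
#' maxima, so the barcoding gap is absent for exactly that pair.
#'
#' @param species Species labels.
#' @param n_per_species Sequences per species (scalar or vector).
#' @param seq_length Alignment length in bp, default 658 (must be a
#'   multiple of 3 after trimming; trailing bases beyond the last full
#'   codon are allowed).
#' @param intra_divergence Target expected intraspecific K2P distance
#'   (substitutions/site), scalar or per-species vector. Default mirrors
#'   the congeneric scale: `c(0.0019, 0.0060, 0.0035, 0.0076)` for four
#'   species, 0.005 otherwise.
#' @param inter_divergence Target expected interspecific distances: a
#'   symmetric species x species matrix or a scalar applied to every pair.
#' @param overlap_pair Optional length-2 species vector whose pairwise
#'   target is overridden by `overlap_divergence` (the gap-less pair).
#' @param overlap_divergence Target for `overlap_pair`, default 0.0048.
#' @param kappa Transition/transversion rate ratio of the substitution
#'   process, default 4 (typical for insect mitochondrial coding genes).
#' @param base_freqs Root base composition (A, C, G, T). Default is an
#'   AT-rich insect mitochondrial composition.
#' @param seed Integer seed (required).
#' @return An object of class `"seq_sim_spec"`.
#' @export
seq_sim_spec <- function(species = c("chiangmaiensis", "fuscana",
                                     "halifaxii", "vorax"),
                         n_per_species = 10L,
                         seq_length = 658L,
                         intra_divergence = NULL,
                         inter_divergence = NULL,
                         overlap_pair = NULL,
                         overlap_divergence = 0.0048,
                         kappa = 4,
                         base_freqs = c(A = 0.299, C = 0.159,
                                        G = 0.154, T = 0.388),
                         seed) {
  if (missing(seed)) wc_abort("`seed` is required for reproducibility.")
  n_sp <- length(species)
  if (length(n_per_species) == 1L) n_per_species <- rep(n_per_species, n_sp)
  if (length(n_per_species) != n_sp) {
    wc_abort("`n_per_species` must be a scalar or match `species`.")
  }
  if (kappa <= 0) wc_abort("`kappa` must be > 0.")
  if (is.null(intra_divergence)) {
    intra_divergence <- if (n_sp == 4L) c(0.0019, 0.0060, 0.0035, 0.0076)
                        else rep(0.005, n_sp)
  }
  if (length(intra_divergence) == 1L) {
    intra_divergence <- rep(intra_divergence, n_sp)
  }
  if (any(intra_divergence < 0)) wc_abort("Divergence targets must be >= 0.")
  if (is.null(inter_divergence)) {
    inter_divergence <- if (n_sp == 4L) default_inter_targets(species)
                        else 0.04
  }
  if (length(inter_divergence) == 1L) {
    inter_divergence <- inter_divergence * (1 - diag(n_sp))
    dimnames(inter_divergence) <- list(species, species)
  }
  inter_divergence <- as.matrix(inter_divergence)
  if (!isSymmetric(unname(inter_divergence)) || nrow(inter_divergence) != n_sp) {
    wc_abort("`inter_divergence` must be a symmetric species x species matrix.")
  }
  if (!is.null(overlap_pair)) {
    if (length(overlap_pair) != 2L || !all(overlap_pair %in% species)) {
      wc_abort("`overlap_pair` must name two of the species.")
    }
    inter_divergence[overlap_pair[1], overlap_pair[2]] <- overlap_divergence
    inter_divergence[overlap_pair[2], overlap_pair[1]] <- overlap_divergence
  }
  if (any(inter_divergence > 0.7) || any(intra_divergence > 0.7)) {
    wc_abort("Divergence targets beyond 0.7 substitutions/site are saturated.")
  }
  out <- list(
    species = species, n_per_species = as.integer(n_per_species),
    seq_length = as.integer(seq_length),
    intra_divergence = intra_divergence,
    inter_divergence = inter_divergence,
    kappa = kappa, base_freqs = base_freqs / sum(base_freqs),
    seed = as.integer(seed)
  )
  class(out) <- "seq_sim_spec"
  out
}

# Expected proportion of differing sites between two sequences separated by
# K80 distance d (transition/transversion rate ratio kappa), split into the
# transition and (total) transversion parts -- the closed form of the
# rate-matrix exponential.
k80_diff_proportions <- function(d, kappa) {
  bt <- d / (kappa + 2)
  at <- kappa * bt
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv <- 0.5 - 0.5 * exp(-4 * bt)
  c(ts = p_ts, tv = p_tv)
}

# Mutate one site, drawing transition vs transversion with the weights
# implied by the branch, but never creating a frame-0 stop codon (TAA/TAG
# under the invertebrate mitochondrial code): purifying selection against
# nonsense mutations, so every sequence stays a clean ORF by construction.
mutate_site <- function(codes, s, w_ts, L) {
  ts_partner <- c(3L, 4L, 1L, 2L)
  tv1 <- c(2L, 1L, 2L, 1L)
  tv2 <- c(4L, 3L, 4L, 3L)
  targets <- c(ts_partner[codes[s]], tv1[codes[s]], tv2[codes[s]])
  weights <- c(w_ts, (1 - w_ts) / 2, (1 - w_ts) / 2)
  cod <- (s - 1L) %/% 3L
  if (3L * cod + 3L <= L) {
    ok <- vapply(targets, function(b) {
      c1 <- if (s == 3L * cod + 1L) b else codes[3L * cod + 1L]
      c2 <- if (s == 3L * cod + 2L) b else codes[3L * cod + 2L]
      c3 <- if (s == 3L * cod + 3L) b else codes[3L * cod + 3L]
      !(c1 == 4L && c2 == 1L && (c3 == 1L || c3 == 3L))
    }, logical(1))
    targets <- targets[ok]
    weights <- weights[ok]
  }
  if (length(targets) == 1L) return(targets)  # sample() scalar pitfall
  sample(targets, 1L, prob = weights)
}

# Branch evolution on a disjoint site budget: the generator hands every
# branch its own sites from one random site permutation (an infinite-sites
# approximation, appropriate at barcode divergences of a few percent), so
# path distances add exactly and a dataset's divergence pattern -- means,
# minima, maxima, and hence the barcoding-gap structure -- is pinned to its
# targets up to integer rounding. The per-branch substitution count inverts
# the K80 saturation curve (m = round(L x expected differing-site
# proportion)), so the K2P estimates measured on the generated data are
# unbiased for the requested distances. Randomness remains in the root
# sequence, the site permutation and the substitution types.
evolve_branch <- function(codes, d, kappa, pool) {
  if (d <= 0) return(codes)
  L <- length(codes)
  pp <- k80_diff_proportions(d, kappa)
  m <- round(L * sum(pp))
  if (m == 0L) return(codes)
  sites <- pool_take(pool, m)
  w_ts <- pp[["ts"]] / sum(pp)
  for (s in sites) codes[s] <- mutate_site(codes, s, w_ts, L)
  codes
}

new_site_pool <- function(L) {
  pool <- new.env(parent = emptyenv())
  pool$sites <- sample.int(L)
  pool$next_i <- 1L
  pool
}

pool_take <- function(pool, m) {
  if (pool$next_i + m - 1L > length(pool$sites)) {
    wc_abort(paste0("Divergence targets exhaust the alignment: more ",
                    "substitutions requested than sites available."))
  }
  out <- pool$sites[pool$next_i:(pool$next_i + m - 1L)]
  pool$next_i <- pool$next_i + m
  out
}

# deterministic within-species branch-length profile: individual distances
# to the species ancestor span 0 to ~2x the mean (two individuals identical
# to the ancestor), so realized intraspecific ranges mirror the 0-to-max
# spread barcode studies report while the mean stays on target
branch_profile <- function(n) {
  if (n == 1L) return(1)
  f <- 2 * (seq_len(n) - 1) / (n - 1)
  if (n > 2L) f[2L] <- 0
  f / mean(f)
}

codes_to_string <- function(codes) {
  paste(c("A", "C", "G", "T")[codes], collapse = "")
}

# re-roll any frame-0 stop codon (TAA/TAG under the invertebrate
# mitochondrial code) by redrawing its third position
fix_stop_codons <- function(codes, base_freqs) {
  L3 <- (length(codes) %/% 3L) * 3L
  repeat {
    firsts <- seq.int(1L, L3, by = 3L)
    is_stop <- codes[firsts] == 4L & codes[firsts + 1L] == 1L &
      codes[firsts + 2L] %in% c(1L, 3L)
    if (!any(is_stop)) break
    for (f in firsts[is_stop]) {
      codes[f + 2L] <- sample(c(2L, 4L), 1L)  # TAC / TAT: tyrosine
    }
  }
  codes
}

#' Generate a synthetic aligned COI barcode set
#'
#' Simulates sequences under a Kimura two-parameter substitution process:
#' a random in-frame, stop-free ancestral sequence is drawn from
#' `base_freqs`; species ancestors are evolved along a
#' neighbor-joining tree fitted to the target between-ancestor distances
#' (each pair's ancestor separation is the interspecific target minus the
#' two intraspecific half-targets, so expected pairwise distances between
#' individuals match the targets); individuals then evolve independently
#' for half their species' intraspecific target. Any stop codon arising in
#' frame 0 (invertebrate mitochondrial code) is re-rolled, keeping every
#' sequence a clean ORF. Fully reproducible from the seed.
#'
#' @param spec A [seq_sim_spec()] object.
#' @return A sequence tibble (`id`, `species`, `sequence`), aligned length
#'   in attribute `"alignment_length"`.
#' @examples
#' seqs <- simulate_barcodes(seq_sim_spec(seed = 11))
#' divergence_summary(seqs)
#' @export
simulate_barcodes <- function(spec) {
  if (!inherits(spec, "seq_sim_spec")) {
    wc_abort("`spec` must come from seq_sim_spec().")
  }
  set.seed(spec$seed)
  n_sp <- length(spec$species)
  L <- spec$seq_length
  root <- sample.int(4L, L, replace = TRUE,
                     prob = spec$base_freqs[c("A", "C", "G", "T")])
  root <- fix_stop_codons(root, spec$base_freqs)

  # ancestor separations: inter target minus the intra half-branches
  anc_d <- spec$inter_divergence
  for (i in seq_len(n_sp)) {
    for (j in seq_len(n_sp)) {
      if (i != j) {
        anc_d[i, j] <- max(0, spec$inter_divergence[i, j] -
                             (spec$intra_divergence[i] +
                              spec$intra_divergence[j]) / 2)
      }
    }
  }
  pool <- new_site_pool(L)
  ancestors <- evolve_ancestors(root, anc_d, spec$kappa, pool)

  rows <- list()
  for (s in seq_len(n_sp)) {
    half <- spec$intra_divergence[s] / 2
    profile <- branch_profile(spec$n_per_species[s])
    for (i in seq_len(spec$n_per_species[s])) {
      codes <- evolve_branch(ancestors[[s]], half * profile[i], spec$kappa,
                             pool)
      rows[[length(rows) + 1L]] <- tibble(
        id = sprintf("%s_%02d", spec$species[[s]], i),
        species = spec$species[[s]],
        sequence = codes_to_string(codes))
    }
  }
  out <- bind_rows(rows)
  attr(out, "alignment_length") <- L
  out
}

# evolve species ancestors so their pairwise expected distances match
# anc_d: single species trivial; two species along one branch; three or
# more along the NJ tree of anc_d (exact for additive targets)
evolve_ancestors <- function(root, anc_d, kappa, pool) {
  n_sp <- nrow(anc_d)
  if (n_sp == 1L) return(list(root))
  if (n_sp == 2L) {
    return(list(root, evolve_branch(root, anc_d[1, 2], kappa, pool)))
  }
  rownames(anc_d) <- colnames(anc_d) <- paste0("s", seq_len(n_sp))
  phy <- nj_tree(anc_d)
  n_tip <- length(phy$tip.label)
  n_node <- phy$Nnode
  seqs <- vector("list", n_tip + n_node)
  root_node <- n_tip + 1L
  seqs[[root_node]] <- root
  # assign each edge once its parent sequence is known (topology order)
  done <- rep(FALSE, nrow(phy$edge))
  while (!all(done)) {
    progressed <- FALSE
    for (e in which(!done)) {
      parent <- phy$edge[e, 1L]
      child <- phy$edge[e, 2L]
      if (!is.null(seqs[[parent]])) {
        seqs[[child]] <- evolve_branch(seqs[[parent]], phy$edge.length[e],
                                       kappa, pool)
        done[e] <- TRUE
        progressed <- TRUE
      }
    }
    if (!progressed) wc_abort("Internal error: disconnected ancestor tree.")
  }
  tips <- match(paste0("s", seq_len(n_sp)), phy$tip.label)
  lapply(tips, function(i) seqs[[i]])
}
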