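# core K2P from integer-coded site vectors (A=1, C=2, G=3, T=4, 0 = missing)
k2p_from_codes <- function(v1, v2, pair_name = "pair",
                           on_saturation = c("error", "na")) {
  on_saturation <- match.arg(on_saturation)
  comp <- v1 > 0L & v2 > 0L
  n <- sum(comp)
  if (n == 0L) {
    wc_abort(sprintf("No comparable sites for %s under the deletion policy.",
                     pair_name), class = "wingcoi_no_sites")
  }
  a <- v1[comp]; b <- v2[comp]
  diff <- a != b
  s <- a + b
  transitions <- sum(diff & (s == 4L | s == 6L))  # A<->G (1+3), C<->T (2+4)
  P <- transitions / n
  Q <- (sum(diff) - transitions) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    if (on_saturation == "na") return(NA_real_)
    wc_abort(sprintf("Saturated divergence for %s: K2P distance undefined.",
                     pair_name), class = "wingcoi_saturation")
  }
  -0.5 * log(arg1) - 0.25 * log(arg2)
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' With transition proportion P and transversion proportion Q over the
#' comparable sites, the K2P distance (substitutions/site) is
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`. Sites where either
#' sequence has a gap, `N` or other ambiguity are excluded pairwise
#' (`deletion = "pairwise"`, the default for barcode work) or an error is
#' raised if you request complete deletion and ambiguous columns remain
#' (for two sequences the two policies coincide). Saturation
#' (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) raises an error naming the pair —
#' silent infinities hide data problems — unless `on_saturation = "na"`.
#'
#' @param a,b Aligned DNA strings of equal length.
#' @param deletion Site-deletion policy, `"pairwise"` or `"complete"`.
#' @param on_saturation `"error"` (default) or `"na"`.
#' @return Non-negative distance in substitutions per site.
#' @examples
#' k2p_distance(strrep("ACGT", 25), strrep("ACGT", 25))        # 0
#' @export
k2p_distance <- function(a, b, deletion = c("pairwise", "complete"),
                         on_saturation = c("error", "na")) {
  deletion <- match.arg(deletion)
  seqs <- validate_seqs(tibble(id = c("a", "b"), sequence = c(a, b)))
  m <- seq_int_matrix(seqs)
  k2p_from_codes(m[1L, ], m[2L, ], pair_name = "a vs b",
                 on_saturation = match.arg(on_saturation))
}

#' Pairwise K2P distance matrix
#'
#' @param seqs A sequence tibble (>= 2 records, equal aligned lengths).
#' @inheritParams k2p_distance
#' @return A symmetric matrix of substitutions/site with zero diagonal,
#'   dimnames from record ids.
#' @export
k2p_matrix <- function(seqs, deletion = c("pairwise", "complete"),
                       on_saturation = c("error", "na")) {
  deletion <- match.arg(deletion)
  on_saturation <- match.arg(on_saturation)
  seqs <- validate_seqs(seqs)
  m <- seq_int_matrix(seqs)
  if (deletion == "complete") {
    keep <- colSums(m == 0L) == 0L
    if (!any(keep)) wc_abort("Complete deletion leaves no sites.")
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(seqs$id, seqs$id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- k2p_from_codes(
        m[i, ], m[j, ],
        pair_name = paste(seqs$id[i], "vs", seqs$id[j]),
        on_saturation = on_saturation)
    }
  }
  D
}

#' Intra- and interspecific divergence summary
#'
#' All pairwise K2P distances grouped into the Table-of-divergences layout
#' barcoding studies report: one cell per species (intraspecific, unordered
#' distinct pairs only) and per species pair (interspecific), each with
#' mean, minimum and maximum in percent, plus pooled overall intra- and
#' interspecific means. A species with a single sequence has an undefined
#' (`NA`) intraspecific cell, not zero.
#'
#' @param seqs A sequence tibble with species labels (>= 2 species).
#' @inheritParams k2p_distance
#' @return An object of class `"divergence_summary"`: tibble `pair_stats`
#'   with columns `species_a`, `species_b`, `type` (`"intra"`/`"inter"`),
#'   `mean_pct`, `min_pct`, `max_pct`, `n_comparisons`; scalars
#'   `overall_intra_mean_pct`, `overall_inter_mean_pct`.
#' @export
divergence_summary <- function(seqs, deletion = c("pairwise", "complete"),
                               on_saturation = c("error", "na")) {
  seqs <- validate_seqs(seqs)
  if (all(is.na(seqs$species))) {
    wc_abort("Species labels are required for a divergence summary.")
  }
  D <- k2p_matrix(seqs, deletion = deletion, on_saturation = on_saturation)
  sp <- seqs$species
  species <- sort(unique(sp))
  if (length(species) < 2L) {
    wc_abort("At least 2 species are required for interspecific cells.")
  }
  cells <- list()
  idx <- 1L
  for (i in seq_along(species)) {
    for (j in i:length(species)) {
      rows <- which(sp == species[[i]])
      cols <- which(sp == species[[j]])
      if (i == j) {
        if (length(rows) < 2L) {
          cells[[idx]] <- tibble(species_a = species[[i]], species_b = species[[j]],
                                 type = "intra", mean_pct = NA_real_,
                                 min_pct = NA_real_, max_pct = NA_real_,
                                 n_comparisons = 0L)
          idx <- idx + 1L
          next
        }
        pairs <- utils::combn(rows, 2L)
        vals <- D[cbind(pairs[1L, ], pairs[2L, ])]
        type <- "intra"
      } else {
        vals <- as.vector(D[rows, cols])
        type <- "inter"
      }
      cells[[idx]] <- tibble(
        species_a = species[[i]], species_b = species[[j]], type = type,
        mean_pct = 100 * mean(vals, na.rm = TRUE),
        min_pct = 100 * min(vals, na.rm = TRUE),
        max_pct = 100 * max(vals, na.rm = TRUE),
        n_comparisons = sum(!is.na(vals))
      )
      idx <- idx + 1L
    }
  }
  pair_stats <- bind_rows(cells)
  intra_vals <- inter_vals <- numeric(0)
  for (i in seq_len(nrow(D) - 1L)) {
    for (j in (i + 1L):nrow(D)) {
      if (sp[i] == sp[j]) intra_vals <- c(intra_vals, D[i, j])
      else inter_vals <- c(inter_vals, D[i, j])
    }
  }
  out <- list(
    pair_stats = pair_stats,
    overall_intra_mean_pct = 100 * mean(intra_vals, na.rm = TRUE),
    overall_inter_mean_pct = 100 * mean(inter_vals, na.rm = TRUE),
    n_sequences = nrow(seqs),
    distance_matrix = D
  )
  class(out) <- "divergence_summary"
  out
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat(sprintf(
    "K2P divergence summary (%d sequences): overall intra %.2f%%, inter %.2f%%\n",
    x$n_sequences, x$overall_intra_mean_pct, x$overall_inter_mean_pct))
  print(x$pair_stats, n = Inf)
  invisible(x)
}

#' @method tidy divergence_summary
#' @export
tidy.divergence_summary <- function(x, ...) x$pair_stats

#' @method glance divergence_summary
#' @export
glance.divergence_summary <- function(x, ...) {
  tibble(
    n_sequences = x$n_sequences,
    n_species = length(unique(c(x$pair_stats$species_a, x$pair_stats$species_b))),
    overall_intra_mean_pct = x$overall_intra_mean_pct,
    overall_inter_mean_pct = x$overall_inter_mean_pct
  )
}

#' Barcoding-gap report
#'
#' For every species pair, compares the smallest interspecific distance
#' with the largest intraspecific distance of the two species: the
#' barcoding gap is present when `min_inter > max_intra` strictly. A
#' missing gap means barcode identification cannot separate the pair. A
#' pair whose members lack an intraspecific cell (single sequence) is
#' reported indeterminate (`NA`).
#'
#' @param summary A `"divergence_summary"` object.
#' @return A tibble with one row per species pair: `species_a`,
#'   `species_b`, `max_intra_pct`, `min_inter_pct`, `gap_present`.
#' @export
barcoding_gap <- function(summary) {
  if (!inherits(summary, "divergence_summary")) {
    wc_abort("`summary` must come from divergence_summary().")
  }
  ps <- summary$pair_stats
  intra <- ps[ps$type == "intra", ]
  inter <- ps[ps$type == "inter", ]
  intra_max <- setNames(intra$max_pct, intra$species_a)
  inter |>
    rowwise() |>
    mutate(
      max_intra_pct = max(intra_max[[.data$species_a]],
                          intra_max[[.data$species_b]]),
      min_inter_pct = .data$min_pct,
      gap_present = .data$min_inter_pct > .data$max_intra_pct
    ) |>
    ungroup() |>
    select("species_a", "species_b", "max_intra_pct", "min_inter_pct",
           "gap_present")
}
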