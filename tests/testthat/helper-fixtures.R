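# shared fixture builders for landmark tests

dataset_from_matrices <- function(mats, species = NULL) {
  rows <- lapply(seq_along(mats), function(i) {
    tibble::tibble(specimen = sprintf("w%02d", i),
                   species = if (is.null(species)) NA_character_ else species[i],
                   replicate = 0L, landmark = seq_len(nrow(mats[[i]])),
                   x = mats[[i]][, 1], y = mats[[i]][, 2])
  })
  landmark_data(dplyr::bind_rows(rows))
}

aligned_matrices <- function(fit) {
  arr <- wingcoi:::as_landmark_array(fit$aligned)
  lapply(seq_len(arr$n), function(j) arr$coords[, , j])
}


# build an additive distance matrix from a tree with known branch lengths
additive_matrix <- function(nwk) {
  phy <- ape::read.tree(text = nwk)
  d <- ape::cophenetic.phylo(phy)
  d[sort(rownames(d)), sort(colnames(d))]
}
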