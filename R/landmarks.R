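#' Landmark data in long format
#'
#' wingcoi stores 2-D landmark data as plain long-format tibbles with one row
#' per digitized landmark and the columns
#'
#' * `specimen` — specimen identifier (character),
#' * `species`  — species label (character, free text, compared
#'   case-sensitively after whitespace trimming; may be `NA`),
#' * `replicate` — digitization replicate, integer `>= 0`
#'   (0 = original digitization),
#' * `landmark` — 1-based landmark index (the 1-based convention is used in
#'   all files and reports; internal matrix code is 0/1-based as R dictates),
#' * `x`, `y`  — coordinates in native digitizing units,
#' * `scale`   — optional image scale (units per mm), carried as metadata.
#'
#' `landmark_data()` validates such a data frame and returns it as a tibble;
#' every analysis function calls it internally, so handing any conforming
#' data frame straight to `gpa_align()` and friends works too.
#'
#' @param data A data frame with at least `specimen`, `landmark`, `x`, `y`.
#'   Missing `species`, `replicate` or `scale` columns are added (`NA`, 0,
#'   `NA`).
#' @param n_landmarks Expected landmarks per configuration. Default `NULL`
#'   infers it from the data and requires it to be identical across
#'   configurations.
#'
#' @return A validated tibble with the canonical columns, landmark count in
#'   attribute `"n_landmarks"`.
#' @examples
#' lm <- landmark_data(simulate_wings(morpho_sim_spec(seed = 1)))
#' attr(lm, "n_landmarks")
#' @export
landmark_data <- function(data, n_landmarks = NULL) {
  if (!is.data.frame(data)) {
    wc_abort("`data` must be a data frame of landmarks in long format.")
  }
  need <- c("specimen", "landmark", "x", "y")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    wc_abort(paste0("Landmark data is missing column(s): ",
                    paste(miss, collapse = ", "), "."))
  }
  out <- as_tibble(data)
  if (!"species" %in% names(out)) out$species <- NA_character_
  if (!"replicate" %in% names(out)) out$replicate <- 0L
  if (!"scale" %in% names(out)) out$scale <- NA_real_
  out$specimen <- as.character(out$specimen)
  out$species <- trimws(as.character(out$species))
  out$replicate <- as.integer(out$replicate)
  out$landmark <- as.integer(out$landmark)
  if (!all(is.finite(out$x)) || !all(is.finite(out$y))) {
    wc_abort("All landmark coordinates must be finite.")
  }
  counts <- out |>
    count(.data$specimen, .data$replicate, name = "p")
  if (length(unique(counts$p)) != 1L) {
    wc_abort("All configurations must share the same landmark count.")
  }
  p <- counts$p[[1]]
  if (!is.null(n_landmarks) && p != n_landmarks) {
    wc_abort(sprintf("Expected %d landmarks per configuration, found %d.",
                     n_landmarks, p))
  }
  idx_ok <- out |>
    group_by(.data$specimen, .data$replicate) |>
    summarise(ok = all(sort(.data$landmark) == seq_len(p)), .groups = "drop")
  if (!all(idx_ok$ok)) {
    wc_abort("Landmark indices must be exactly 1..n_landmarks in every configuration.")
  }
  out <- arrange(out, .data$specimen, .data$replicate, .data$landmark)
  attr(out, "n_landmarks") <- p
  out
}

# long tibble -> list(coords = p x 2 x n array, info = one row per config)
as_landmark_array <- function(data) {
  data <- landmark_data(data)
  p <- attr(data, "n_landmarks")
  info <- data |>
    distinct(.data$specimen, .data$replicate, .data$species, .data$scale)
  n <- nrow(info)
  coords <- array(NA_real_, dim = c(p, 2L, n))
  key <- paste(data$specimen, data$replicate, sep = "\r")
  ikey <- paste(info$specimen, info$replicate, sep = "\r")
  for (j in seq_len(n)) {
    block <- data[key == ikey[j], ]
    coords[, 1L, j] <- block$x
    coords[, 2L, j] <- block$y
  }
  list(coords = coords, info = info, p = p, n = n)
}

# inverse of as_landmark_array
landmark_long <- function(coords, info) {
  p <- dim(coords)[1]
  n <- dim(coords)[3]
  tibble(
    specimen = rep(info$specimen, each = p),
    species = rep(info$species, each = p),
    replicate = rep(info$replicate, each = p),
    landmark = rep(seq_len(p), times = n),
    x = as.vector(coords[, 1L, ]),
    y = as.vector(coords[, 2L, ]),
    scale = rep(if ("scale" %in% names(info)) info$scale else NA_real_,
                each = p)
  )
}

#' Centroid size of landmark configurations
#'
#' Centroid size is the square root of the summed squared distances of the
#' landmarks to their centroid — the standard geometric-morphometrics size
#' measure. It is invariant to translation and rotation and scales linearly
#' with the coordinates.
#'
#' @param x Either a numeric `p x 2` coordinate matrix (returns a single
#'   number) or a long-format landmark data frame (returns a tibble with one
#'   row per configuration).
#' @return A positive number, or a tibble with columns `specimen`,
#'   `species`, `replicate`, `csize`.
#' @examples
#' centroid_size(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # sqrt(2)
#' @export
centroid_size <- function(x) {
  UseMethod("centroid_size")
}

#' @export
centroid_size.default <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) != 2L) {
    wc_abort("A configuration needs >= 2 landmarks in 2 dimensions.")
  }
  centered <- sweep(x, 2L, colMeans(x))
  cs <- sqrt(sum(centered^2))
  if (cs <= .Machine$double.eps * nrow(x)) {
    wc_abort("Degenerate configuration: all landmarks coincide.",
             class = "wingcoi_degenerate")
  }
  cs
}

#' @export
centroid_size.data.frame <- function(x) {
  arr <- as_landmark_array(x)
  sizes <- vapply(seq_len(arr$n),
                  function(j) centroid_size.default(arr$coords[, , j]),
                  numeric(1))
  arr$info |>
    transmute(.data$specimen, .data$species, .data$replicate, csize = sizes)
}
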