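#' Read and write TPS landmark files
#'
#' `read_tps()` parses the TPS dialect emitted by common digitizing software:
#' `LM=<p>` starts a block of `p` whitespace-separated coordinate lines,
#' followed by optional `ID=`, `IMAGE=` and `SCALE=` records. Unknown keys
#' are skipped with a warning. `SCALE` is kept as metadata and is *not*
#' multiplied into the coordinates unless `physical = TRUE` (Generalized
#' Procrustes discards scale anyway, so native digitizing units are the
#' default). Species labels come from `label_map` when given.
#'
#' Replicate digitizations are encoded in the ID as a `__r<k>` suffix
#' (`wingA__r1` is replicate 1 of specimen `wingA`); `write_tps()` emits the
#' same convention, so write/read round trips preserve replicates.
#'
#' @param path Path to a TPS file.
#' @param label_map Optional data frame with columns `specimen` and
#'   `species` mapping IDs to species labels, or `NULL`.
#' @param physical If `TRUE`, divide coordinates by `SCALE` so they are in
#'   mm; requires every block to carry a `SCALE=` record.
#' @return A long-format landmark tibble (see [landmark_data()]).
#' @seealso [write_tps()], [read_landmarks_csv()]
#' @export
read_tps <- function(path, label_map = NULL, physical = FALSE) {
  if (!file.exists(path)) wc_abort(paste0("TPS file not found: ", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  blocks <- list()
  i <- 1L
  block_no <- 0L
  while (i <= length(lines)) {
    ln <- lines[[i]]
    if (!grepl("^LM\\s*=", ln, ignore.case = TRUE)) {
      wc_abort(sprintf("Line %d: expected an LM= record, got '%s'.", i, ln),
               class = "wingcoi_format")
    }
    block_no <- block_no + 1L
    p <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", ln, ignore.case = TRUE)))
    if (is.na(p) || p < 1L) {
      wc_abort(sprintf("Block %d: unreadable landmark count in '%s'.", block_no, ln),
               class = "wingcoi_format")
    }
    coords <- matrix(NA_real_, p, 2L)
    for (k in seq_len(p)) {
      i <- i + 1L
      if (i > length(lines) || grepl("^[A-Za-z]+\\s*=", lines[[i]])) {
        wc_abort(sprintf(
          "Block %d declares LM=%d but has only %d coordinate line(s).",
          block_no, p, k - 1L), class = "wingcoi_format")
      }
      xy <- suppressWarnings(as.numeric(strsplit(lines[[i]], "\\s+")[[1]]))
      if (length(xy) != 2L || anyNA(xy)) {
        wc_abort(sprintf("Line %d: non-numeric coordinate pair '%s'.",
                         i, lines[[i]]), class = "wingcoi_parse")
      }
      coords[k, ] <- xy
    }
    id <- NULL
    scale <- NA_real_
    while (i + 1L <= length(lines) &&
           !grepl("^LM\\s*=", lines[[i + 1L]], ignore.case = TRUE)) {
      i <- i + 1L
      kv <- lines[[i]]
      key <- toupper(sub("\\s*=.*$", "", kv))
      val <- sub("^[A-Za-z]+\\s*=\\s*", "", kv)
      if (key == "ID") {
        id <- val
      } else if (key == "SCALE") {
        scale <- suppressWarnings(as.numeric(val))
      } else if (key != "IMAGE") {
        rlang::warn(sprintf("Ignoring unknown TPS key '%s' (block %d).",
                            key, block_no))
      }
    }
    if (is.null(id)) id <- sprintf("specimen_%03d", block_no)
    rep_idx <- 0L
    if (grepl("__r\\d+$", id)) {
      rep_idx <- as.integer(sub("^.*__r", "", id))
      id <- sub("__r\\d+$", "", id)
    }
    if (physical) {
      if (is.na(scale)) {
        wc_abort(sprintf("Block %d ('%s') has no SCALE= record; cannot convert to mm.",
                         block_no, id), class = "wingcoi_format")
      }
      coords <- coords / scale
    }
    blocks[[block_no]] <- tibble(
      specimen = id, species = NA_character_, replicate = rep_idx,
      landmark = seq_len(p), x = coords[, 1L], y = coords[, 2L],
      scale = scale
    )
    i <- i + 1L
  }
  if (!length(blocks)) wc_abort("TPS file contains no LM blocks.",
                                class = "wingcoi_format")
  out <- bind_rows(blocks)
  if (!is.null(label_map)) {
    label_map <- as_tibble(label_map)
    out$species <- label_map$species[match(out$specimen, label_map$specimen)]
    out$species <- trimws(out$species)
  }
  landmark_data(out)
}

#' @rdname read_tps
#' @param data A long-format landmark data frame.
#' @export
write_tps <- function(data, path) {
  data <- landmark_data(data)
  arr <- as_landmark_array(data)
  con <- file(path, "w")
  on.exit(close(con))
  for (j in seq_len(arr$n)) {
    id <- arr$info$specimen[[j]]
    if (arr$info$replicate[[j]] > 0L) {
      id <- sprintf("%s__r%d", id, arr$info$replicate[[j]])
    }
    writeLines(sprintf("LM=%d", arr$p), con)
    writeLines(sprintf("%.12g %.12g", arr$coords[, 1L, j], arr$coords[, 2L, j]), con)
    writeLines(sprintf("ID=%s", id), con)
    if (is.finite(arr$info$scale[[j]])) {
      writeLines(sprintf("SCALE=%.12g", arr$info$scale[[j]]), con)
    }
  }
  invisible(path)
}

#' Read and write long-format landmark CSV
#'
#' The CSV layout is the package's canonical long format: one row per
#' landmark with columns `specimen`, `species`, `replicate`, `landmark`
#' (1-based), `x`, `y` and optional `scale`. Floats are written with
#' `%.12g`, so read/write round trips are byte-stable.
#'
#' @param data A long-format landmark data frame (non-empty).
#' @param path File path.
#' @return `read_landmarks_csv()` returns a validated landmark tibble;
#'   `write_landmarks_csv()` returns `path` invisibly.
#' @export
write_landmarks_csv <- function(data, path) {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    wc_abort("Refusing to write an empty landmark dataset.")
  }
  data <- landmark_data(data)
  out <- data
  out$x <- sprintf("%.12g", out$x)
  out$y <- sprintf("%.12g", out$y)
  out$scale <- ifelse(is.finite(data$scale), sprintf("%.12g", data$scale), "")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_csv <- function(path) {
  if (!file.exists(path)) wc_abort(paste0("CSV file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  landmark_data(df)
}
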