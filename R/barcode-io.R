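#' Read and write aligned COI barcode FASTA
#'
#' `read_barcode_fasta()` loads a FASTA file of DNA barcodes into the
#' package's canonical sequence tibble: one row per record with columns
#' `id`, `species`, `sequence` (uppercase, alphabet `A C G T - N`). All
#' sequences must share one aligned length — COI barcodes are in-frame and
#' indel-free within a genus, so unequal lengths indicate missing external
#' alignment and raise an error. IUPAC ambiguity codes beyond `N` are
#' rejected by default; `ambiguity = "missing"` converts them to `N`.
#'
#' @param path FASTA file path.
#' @param label_map Species labels: a data frame with columns `id` and
#'   `species`, or the path of a two-column CSV with those columns, or
#'   `NULL` (species stay `NA`).
#' @param ambiguity `"error"` (default) or `"missing"`.
#' @return A tibble with columns `id`, `species`, `sequence`; aligned
#'   length in attribute `"alignment_length"`.
#' @export
read_barcode_fasta <- function(path, label_map = NULL,
                               ambiguity = c("error", "missing")) {
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) wc_abort(paste0("FASTA file not found: ", path))
  dna <- ape::read.FASTA(path)
  if (!length(dna)) wc_abort("FASTA file contains no records.")
  seqs <- toupper(vapply(as.character(dna), paste, character(1), collapse = ""))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    wc_abort(paste0(
      "Sequences have unequal lengths (", paste(sort(unique(lens)), collapse = ", "),
      "); align them externally (e.g. mafft/ClustalW) before import."))
  }
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    if (ambiguity == "error") {
      wc_abort(paste0(
        "IUPAC ambiguity codes beyond N in record(s): ",
        paste(names(seqs)[bad], collapse = ", "),
        ". Use ambiguity = 'missing' to treat them as N."))
    }
    seqs <- gsub("[^ACGTN-]", "N", seqs)
  }
  out <- tibble(id = names(seqs), species = NA_character_, sequence = unname(seqs))
  if (!is.null(label_map)) {
    if (is.character(label_map) && length(label_map) == 1L) {
      label_map <- utils::read.csv(label_map, stringsAsFactors = FALSE)
    }
    if (!all(c("id", "species") %in% names(label_map))) {
      wc_abort("`label_map` needs columns `id` and `species`.")
    }
    out$species <- trimws(label_map$species[match(out$id, label_map$id)])
  }
  attr(out, "alignment_length") <- lens[[1]]
  out
}

#' @rdname read_barcode_fasta
#' @param seqs A sequence tibble with columns `id` and `sequence`.
#' @export
write_barcode_fasta <- function(seqs, path) {
  seqs <- validate_seqs(seqs, min_records = 1L)
  writeLines(paste0(">", seqs$id, "\n", seqs$sequence), path)
  invisible(path)
}

validate_seqs <- function(seqs, min_records = 2L) {
  if (!is.data.frame(seqs) || !all(c("id", "sequence") %in% names(seqs))) {
    wc_abort("Expected a sequence tibble with columns `id` and `sequence`.")
  }
  if (nrow(seqs) < min_records) {
    wc_abort(sprintf("At least %d sequence record(s) required.", min_records))
  }
  seqs <- as_tibble(seqs)
  if (!"species" %in% names(seqs)) seqs$species <- NA_character_
  seqs$sequence <- toupper(seqs$sequence)
  if (any(grepl("[^ACGTN-]", seqs$sequence))) {
    wc_abort("Sequences may only contain A, C, G, T, N and '-'.")
  }
  if (length(unique(nchar(seqs$sequence))) != 1L) {
    wc_abort("All sequences must share one aligned length.")
  }
  seqs
}

# integer-coded alignment matrix: A=1, C=2, G=3, T=4, gap/N/other = 0
seq_int_matrix <- function(seqs) {
  L <- nchar(seqs$sequence[[1]])
  m <- matrix(0L, nrow(seqs), L, dimnames = list(seqs$id, NULL))
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  for (i in seq_len(nrow(seqs))) {
    ch <- strsplit(seqs$sequence[[i]], "")[[1]]
    v <- code[ch]
    v[is.na(v)] <- 0L
    m[i, ] <- v
  }
  m
}

#' Mean nucleotide composition of a barcode set
#'
#' Per-sequence base fractions over unambiguous sites (gaps and N excluded
#' from denominators), averaged over sequences. The four percentages sum to
#' 100.
#'
#' @param seqs A sequence tibble (see [read_barcode_fasta()]).
#' @return A tibble with columns `base` (`A`, `T`, `G`, `C`) and `pct`.
#' @examples
#' nucleotide_composition(tibble::tibble(id = "s1", sequence = "ATGC"))
#' @export
nucleotide_composition <- function(seqs) {
  seqs <- validate_seqs(seqs, min_records = 1L)
  m <- seq_int_matrix(seqs)
  fracs <- t(apply(m, 1L, function(v) {
    v <- v[v > 0L]
    if (!length(v)) return(rep(NA_real_, 4L))
    tabulate(v, 4L) / length(v)
  }))
  empty <- apply(is.na(fracs), 1L, any)
  if (any(empty)) {
    rlang::warn(paste0("Excluding all-gap/ambiguous record(s): ",
                       paste(seqs$id[empty], collapse = ", ")))
    fracs <- fracs[!empty, , drop = FALSE]
    if (!nrow(fracs)) wc_abort("No sequence with unambiguous sites remains.")
  }
  mean_frac <- colMeans(fracs)  # order A, C, G, T
  tibble(base = c("A", "T", "G", "C"),
         pct = 100 * mean_frac[c(1L, 4L, 3L, 2L)])
}

#' Stop-codon (pseudogene) screen
#'
#' Translates a barcode sequence under the invertebrate mitochondrial
#' genetic code and reports whether the translation is stop-free —
#' the standard check that an amplified COI fragment is the functional
#' mitochondrial copy rather than a nuclear pseudogene (numt). With
#' `frame = "auto"` the screen passes if at least one forward reading frame
#' is stop-free, and reports the first passing frame.
#'
#' @param seq A single DNA string (gaps removed internally; ungapped length
#'   must be >= 3).
#' @param frame `"auto"` (default) or a fixed frame 0, 1, 2.
#' @param genetic_code A seqinr `numcode`; 5 = invertebrate mitochondrial
#'   (default).
#' @return A list with `pass` (logical), `frame` (the passing or requested
#'   frame; `NA` when no frame passes), `translation` (peptide of that
#'   frame), and `stops_per_frame` (named integer vector).
#' @export
check_stop_codons <- function(seq, frame = "auto", genetic_code = 5L) {
  if (!is.character(seq) || length(seq) != 1L) {
    wc_abort("`seq` must be a single DNA string.")
  }
  s <- toupper(gsub("-", "", seq))
  if (grepl("[^ACGTN]", s)) wc_abort("Non-DNA characters in sequence.")
  if (nchar(s) < 3L) wc_abort("Ungapped length must be >= 3.")
  chars <- strsplit(s, "")[[1]]
  frames <- if (identical(frame, "auto")) 0:2 else as.integer(frame)
  if (any(!frames %in% 0:2)) wc_abort("`frame` must be 'auto', 0, 1 or 2.")
  translations <- lapply(frames, function(f) {
    seqinr::translate(chars, frame = f, numcode = genetic_code, ambiguous = TRUE)
  })
  stops <- vapply(translations, function(p) sum(p == "*"), integer(1))
  names(stops) <- paste0("frame", frames)
  pass_idx <- which(stops == 0L)
  if (length(pass_idx)) {
    i <- pass_idx[[1]]
    list(pass = TRUE, frame = frames[[i]],
         translation = paste(translations[[i]], collapse = ""),
         stops_per_frame = stops)
  } else {
    list(pass = FALSE, frame = NA_integer_,
         translation = paste(translations[[1]], collapse = ""),
         stops_per_frame = stops)
  }
}
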