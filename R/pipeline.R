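#' Pipeline run configuration
#'
#' Collects the paths, seeds and tuning parameters the end-to-end runners
#' need. Every stochastic stage receives an explicit seed; the full
#' configuration is echoed verbatim into the output directory so a
#' completed run is re-derivable from the bundle alone.
#'
#' @param landmarks Path to a TPS or long-format landmark CSV file.
#' @param sequences Path to an aligned barcode FASTA file.
#' @param labels Path to a two-column CSV mapping ids to species (columns
#'   `specimen`/`species` for landmarks, `id`/`species` for sequences), or
#'   `NULL` when labels are embedded.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer master seed (required).
#' @param n_perm Permutations for shape tests, default 1000.
#' @param n_boot Bootstrap replicates for trees, default 1000.
#' @param variance_retained Retained shape variance, default 0.99.
#' @param deletion Site-deletion policy for K2P, default `"pairwise"`.
#' @param linkage Linkage for the shape similarity tree, default `"upgma"`.
#' @return A `"run_config"` list.
#' @export
run_config <- function(landmarks = NULL, sequences = NULL, labels = NULL,
                       out_dir, seed, n_perm = 1000L, n_boot = 1000L,
                       variance_retained = 0.99,
                       deletion = c("pairwise", "complete"),
                       linkage = c("upgma", "single", "complete")) {
  if (missing(seed)) wc_abort("`seed` is required for reproducibility.")
  if (missing(out_dir)) wc_abort("`out_dir` is required.")
  cfg <- list(landmarks = landmarks, sequences = sequences, labels = labels,
              out_dir = out_dir, seed = as.integer(seed),
              n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
              variance_retained = variance_retained,
              deletion = match.arg(deletion), linkage = match.arg(linkage))
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path Path of a YAML run-configuration file with the same keys.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) wc_abort(paste0("Config file not found: ", path))
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

start_bundle <- function(cfg, kind) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_plain <- unclass(cfg)
  yaml::write_yaml(cfg_plain[!vapply(cfg_plain, is.null, logical(1))],
                   file.path(cfg$out_dir, "config.yml"))
  log_path <- file.path(cfg$out_dir, "run.log")
  log_line <- function(...) {
    msg <- sprintf(...)
    message(msg)
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), msg, "\n",
        sep = "", file = log_path, append = TRUE)
  }
  log_line("wingcoi %s | %s pipeline | seed %d",
           as.character(utils::packageVersion("wingcoi")), kind, cfg$seed)
  log_line("%s", R.version.string)
  log_line("units: Mahalanobis distances as D; K2P summaries in percent")
  log_line
}

stage <- function(log_line, name, expr) {
  log_line("stage: %s", name)
  tryCatch(expr, error = function(e) {
    wc_abort(sprintf("Pipeline halted at stage '%s': %s", name,
                     conditionMessage(e)))
  })
}

write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = !is.null(rownames(x)) &&
                     !identical(rownames(x), as.character(seq_len(nrow(x)))))
  path
}

#' Run the wing geometric-morphometrics pipeline
#'
#' Executes the full shape workflow on a landmark file: Procrustes
#' superimposition, digitizing repeatability (when replicate digitizations
#' are present), shape variables, allometry, canonical discrimination with
#' permutation-tested Mahalanobis distances, the shape similarity tree with
#' bootstrap supports, and leave-one-out reclassification. All tables
#' (CSV), the tree (Newick), plots (PNG) and a run log are written to the
#' bundle directory.
#'
#' @param config A [run_config()] with `landmarks` set.
#' @return Invisibly, a named list of the stage results.
#' @export
run_morpho <- function(config) {
  if (!inherits(config, "run_config")) wc_abort("`config` must come from run_config().")
  if (is.null(config$landmarks)) wc_abort("`config$landmarks` is required.")
  log_line <- start_bundle(config, "morphometrics")
  od <- config$out_dir
  label_map <- NULL
  if (!is.null(config$labels)) {
    label_map <- utils::read.csv(config$labels, stringsAsFactors = FALSE)
  }
  lm_data <- stage(log_line, "read landmarks", {
    if (grepl("\\.tps$", config$landmarks, ignore.case = TRUE)) {
      read_tps(config$landmarks, label_map = label_map)
    } else {
      d <- read_landmarks_csv(config$landmarks)
      if (!is.null(label_map)) {
        d$species <- trimws(label_map$species[match(d$specimen, label_map$specimen)])
      }
      landmark_data(d)
    }
  })
  res <- list()
  res$repeatability <- NULL
  if (any(lm_data$replicate > 0L)) {
    res$repeatability <- stage(log_line, "repeatability", estimate_repeatability(lm_data))
    write_table(glance(res$repeatability), file.path(od, "repeatability.csv"))
    log_line("repeatability %.2f%%", res$repeatability$repeatability_pct)
  }
  originals <- filter(lm_data, .data$replicate == 0L)
  res$gpa <- stage(log_line, "Procrustes superimposition", gpa_align(originals))
  res$shape <- stage(log_line, "shape variables",
                     shape_variables(res$gpa, config$variance_retained))
  write_table(res$shape$scores, file.path(od, "shape_scores.csv"))
  res$cva <- stage(log_line, "discriminant analysis", discriminant_analysis(res$shape))
  write_table(as.data.frame(res$cva$mahalanobis), file.path(od, "mahalanobis.csv"))
  res$allometry <- stage(log_line, "allometry",
                         allometry_regression(res$cva, n_perm = config$n_perm,
                                              seed = config$seed + 1L))
  write_table(glance(res$allometry), file.path(od, "allometry.csv"))
  log_line("allometry r^2 = %.3f (p = %.4g)", res$allometry$r_squared,
           res$allometry$p_value)
  res$permutation <- stage(log_line, "permutation tests",
                           mahalanobis_permutation_test(
                             res$shape, n_perm = config$n_perm,
                             seed = config$seed + 2L))
  write_table(res$permutation, file.path(od, "mahalanobis_tests.csv"))
  res$tree <- stage(log_line, "shape similarity tree",
                    shape_cluster_tree(res$shape, linkage = config$linkage,
                                       n_boot = config$n_boot,
                                       seed = config$seed + 3L))
  ape::write.tree(res$tree, file.path(od, "shape_tree.nwk"))
  res$loo <- stage(log_line, "leave-one-out classification",
                   loo_classification(res$shape))
  write_table(as.data.frame(res$loo$confusion), file.path(od, "confusion.csv"))
  write_table(tibble(species = names(res$loo$per_group_pct),
                     correct_pct = unname(res$loo$per_group_pct),
                     total_pct = res$loo$total_pct),
              file.path(od, "classification.csv"))
  log_line("LOO total accuracy %.2f%%", res$loo$total_pct)
  stage(log_line, "plots", {
    ggplot2::ggsave(file.path(od, "discriminant_space.png"),
                    autoplot(res$cva), width = 7, height = 5, dpi = 150)
    ggplot2::ggsave(file.path(od, "allometry.png"),
                    autoplot(res$allometry), width = 6, height = 4, dpi = 150)
    ggplot2::ggsave(file.path(od, "mean_shapes.png"),
                    plot_mean_shapes(res$gpa), width = 7, height = 5, dpi = 150)
  })
  log_line("morphometrics pipeline complete")
  invisible(res)
}

#' Run the COI barcode pipeline
#'
#' Executes the barcoding workflow on an aligned FASTA: nucleotide
#' composition, stop-codon (pseudogene) screen, the K2P distance matrix,
#' the intra/interspecific divergence summary, the barcoding-gap report,
#' and the neighbor-joining tree with bootstrap supports. Tables, Newick
#' trees and a run log are written to the bundle directory.
#'
#' @param config A [run_config()] with `sequences` set.
#' @return Invisibly, a named list of the stage results.
#' @export
run_barcode <- function(config) {
  if (!inherits(config, "run_config")) wc_abort("`config` must come from run_config().")
  if (is.null(config$sequences)) wc_abort("`config$sequences` is required.")
  log_line <- start_bundle(config, "barcode")
  od <- config$out_dir
  seqs <- stage(log_line, "read sequences",
                read_barcode_fasta(config$sequences, label_map = config$labels))
  if (anyDuplicated(seqs$sequence)) {
    rlang::warn("Duplicate sequences present; their pairwise distances are 0.")
  }
  res <- list()
  res$composition <- stage(log_line, "nucleotide composition",
                           nucleotide_composition(seqs))
  write_table(res$composition, file.path(od, "composition.csv"))
  res$stop_codons <- stage(log_line, "stop-codon screen", {
    screens <- lapply(seqs$sequence, check_stop_codons)
    tibble(id = seqs$id,
           pass = vapply(screens, `[[`, logical(1), "pass"),
           frame = vapply(screens, `[[`, integer(1), "frame"))
  })
  write_table(res$stop_codons, file.path(od, "stop_codons.csv"))
  if (!all(res$stop_codons$pass)) {
    rlang::warn("Possible pseudogenes: stop codons found in some sequences.")
  }
  res$k2p <- stage(log_line, "K2P distances",
                   k2p_matrix(seqs, deletion = config$deletion))
  write_table(as.data.frame(res$k2p), file.path(od, "k2p_matrix.csv"))
  res$summary <- stage(log_line, "divergence summary",
                       divergence_summary(seqs, deletion = config$deletion))
  write_table(res$summary$pair_stats, file.path(od, "divergence_summary.csv"))
  log_line("overall intra %.2f%%, inter %.2f%%",
           res$summary$overall_intra_mean_pct, res$summary$overall_inter_mean_pct)
  res$gap <- stage(log_line, "barcoding gap", barcoding_gap(res$summary))
  write_table(res$gap, file.path(od, "gap_report.csv"))
  res$nj <- stage(log_line, "neighbor-joining tree", nj_tree(res$k2p))
  ape::write.tree(res$nj, file.path(od, "nj_tree.nwk"))
  res$boot <- stage(log_line, "bootstrap supports",
                    bootstrap_nj(seqs, n_boot = config$n_boot,
                                 seed = config$seed + 4L,
                                 deletion = config$deletion))
  ape::write.tree(res$boot, file.path(od, "nj_tree_bootstrap.nwk"))
  log_line("barcode pipeline complete")
  invisible(res)
}

#' Write synthetic study-mirror datasets to disk
#'
#' Generates a wing-landmark TPS file (plus a specimen-to-species label
#' CSV) and an aligned barcode FASTA (plus label CSV) from the two
#' generator specifications, and writes a manifest with MD5 checksums.
#'
#' @param out_dir Output directory.
#' @param morpho A [morpho_sim_spec()], or `NULL` to skip landmarks.
#' @param barcode A [seq_sim_spec()], or `NULL` to skip sequences.
#' @return Invisibly, the manifest tibble.
#' @export
run_simulate <- function(out_dir, morpho = NULL, barcode = NULL) {
  if (is.null(morpho) && is.null(barcode)) {
    wc_abort("Supply at least one of `morpho`, `barcode`.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  if (!is.null(morpho)) {
    wings <- simulate_wings(morpho)
    tps <- file.path(out_dir, "wings.tps")
    write_tps(wings, tps)
    lab <- file.path(out_dir, "wing_labels.csv")
    utils::write.csv(distinct(wings, .data$specimen, .data$species),
                     lab, row.names = FALSE)
    files <- c(files, tps, lab)
  }
  if (!is.null(barcode)) {
    seqs <- simulate_barcodes(barcode)
    fa <- file.path(out_dir, "barcodes_synthetic.fasta")
    write_barcode_fasta(seqs, fa)
    lab <- file.path(out_dir, "barcode_labels.csv")
    utils::write.csv(seqs[c("id", "species")], lab, row.names = FALSE)
    files <- c(files, fa, lab)
  }
  manifest <- tibble(file = basename(files),
                     md5 = unname(tools::md5sum(files)),
                     bytes = file.size(files))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Fetch deposited COI barcode accessions (requires network access)
#'
#' Downloads a set of GenBank nucleotide accessions as FASTA via NCBI
#' E-utilities and writes the FASTA plus an id-to-species label CSV next to
#' it. This is the only networked function in the package; it is never
#' called by the analysis stages or the tests, which run fully offline.
#' The default accessions are the deposited barcodes of the four Thai
#' *Lutzia* species (10 per species).
#'
#' @param dest_dir Directory to write `coi_accessions.fasta` and
#'   `coi_labels.csv` into.
#' @param accessions Named character vector: accession -> species label.
#'   Default: OP783906-OP783945 mapped to the four species.
#' @return Invisibly, the FASTA path.
#' @export
fetch_coi_accessions <- function(dest_dir,
                                 accessions = lutzia_accessions()) {
  dir.create(dest_dir, recursive = TRUE, showWarnings = FALSE)
  url <- paste0(
    "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi?",
    "db=nuccore&rettype=fasta&retmode=text&id=",
    paste(names(accessions), collapse = ","))
  fa <- file.path(dest_dir, "coi_accessions.fasta")
  utils::download.file(url, fa, quiet = TRUE)
  raw <- readLines(fa)
  headers <- grep("^>", raw, value = TRUE)
  ids <- sub("^>(\\S+).*$", "\\1", headers)
  ids <- sub("\\.\\d+$", "", ids)
  utils::write.csv(
    tibble(id = sub("^>(\\S+).*$", "\\1", headers),
           species = unname(accessions[match(ids, names(accessions))])),
    file.path(dest_dir, "coi_labels.csv"), row.names = FALSE)
  invisible(fa)
}

#' @rdname fetch_coi_accessions
#' @export
lutzia_accessions <- function() {
  acc <- sprintf("OP%06d", 783906:783945)
  setNames(rep(c("chiangmaiensis", "fuscana", "halifaxii", "vorax"),
               each = 10L), acc)
}
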