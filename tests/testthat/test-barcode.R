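test_that("FASTA round trip preserves sequences and labels map on", {
  set.seed(81)
  seqs <- tibble::tibble(
    id = c("s1", "s2"), species = c("sp1", "sp2"),
    sequence = replicate(2, random_dna(120)))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_barcode_fasta(seqs, fa)
  back <- read_barcode_fasta(fa, label_map = seqs[c("id", "species")])
  expect_identical(back$sequence, seqs$sequence)
  expect_identical(back$species, seqs$species)
  expect_equal(attr(back, "alignment_length"), 120L)

  writeLines(c(">a", "ACGT", ">b", "ACGTTT"), fa)
  expect_error(read_barcode_fasta(fa), "unequal lengths")
  writeLines(c(">a", "ACRT", ">b", "ACGT"), fa)
  expect_error(read_barcode_fasta(fa), "ambiguity")
  ok <- read_barcode_fasta(fa, ambiguity = "missing")
  expect_equal(ok$sequence[1], "ACNT")
})

test_that("nucleotide composition is exact on constructed sequences", {
  one <- tibble::tibble(id = "s", sequence = "ATGC")
  comp <- nucleotide_composition(one)
  expect_equal(comp$pct, rep(25, 4))
  all_a <- nucleotide_composition(tibble::tibble(id = "s", sequence = "AAAA"))
  expect_equal(all_a$pct[all_a$base == "A"], 100)
  set.seed(82)
  many <- tibble::tibble(id = c("a", "b", "c"),
                         sequence = replicate(3, random_dna(300, gap_frac = 0.1)))
  expect_equal(sum(nucleotide_composition(many)$pct), 100, tolerance = 1e-9)
  expect_warning(
    nucleotide_composition(tibble::tibble(id = c("a", "b"),
                                          sequence = c("----", "ACGT"))),
    "all-gap")
})

test_that("stop-codon screen detects constructed stops and clean ORFs", {
  bad <- check_stop_codons("ATTTAAGGC", frame = 0)
  expect_false(bad$pass)
  expect_gt(bad$stops_per_frame[["frame0"]], 0)

  clean <- check_stop_codons(strrep("ATT", 30))
  expect_true(clean$pass)
  expect_equal(clean$frame, 0L)

  # TGA is tryptophan (not a stop) in the invertebrate mitochondrial code
  expect_true(check_stop_codons("ATTTGAATT", frame = 0)$pass)
  expect_error(check_stop_codons("AXGTAA"), "Non-DNA")
  expect_error(check_stop_codons("AT"), ">= 3")

  set.seed(83)
  orf <- simulate_barcodes(seq_sim_spec(species = "sp", n_per_species = 1,
                                        seq_length = 657, intra_divergence = 0,
                                        inter_divergence = matrix(0, 1, 1),
                                        seed = 84))$sequence
  expect_true(check_stop_codons(orf, frame = 0)$pass)
})

test_that("K2P distance matches the closed form on constructed counts", {
  set.seed(85)
  a <- random_dna(100)
  expect_equal(k2p_distance(a, a), 0)
  b <- mutate_sites(a, n_ts = 10, n_tv = 0)
  expect_equal(k2p_distance(a, b), -0.5 * log(0.8), tolerance = 1e-12)
  c_ <- mutate_sites(a, n_ts = 0, n_tv = 10)
  expect_equal(k2p_distance(a, c_),
               -0.5 * log(1 - 0.1) - 0.25 * log(1 - 0.2), tolerance = 1e-12)
  expect_equal(k2p_distance(a, b), k2p_distance(b, a))
})

test_that("K2P matches the independent site-count oracle on random pairs", {
  set.seed(86)
  for (rep in 1:50) {
    a <- random_dna(200, gap_frac = 0.05)
    b <- random_dna(200, gap_frac = 0.05)
    ch <- strsplit(a, "")[[1]]
    idx <- sample(200, 150)  # mostly-shared backbone keeps divergence sane
    bch <- strsplit(b, "")[[1]]
    bch[idx] <- ch[idx]
    b <- paste(bch, collapse = "")
    expect_equal(k2p_distance(a, b), k2p_sitecount_oracle(a, b),
                 tolerance = 1e-10)
  }
})

test_that("gap columns are ignored under pairwise deletion", {
  set.seed(87)
  a <- random_dna(90)
  b <- mutate_sites(a, n_ts = 4, n_tv = 2)
  d0 <- k2p_distance(a, b)
  # append a gap column on each side
  expect_equal(k2p_distance(paste0(a, "-"), paste0(b, "A")), d0,
               tolerance = 1e-12)
  expect_equal(k2p_distance(paste0("N", a), paste0("C", b)), d0,
               tolerance = 1e-12)
})

test_that("saturation and empty-overlap raise informative errors", {
  expect_error(k2p_distance(strrep("A", 30), strrep("G", 30)),
               class = "wingcoi_saturation")
  expect_error(k2p_distance(strrep("-", 9), strrep("A", 9)),
               class = "wingcoi_no_sites")
  expect_true(is.na(k2p_distance(strrep("A", 30), strrep("G", 30),
                                 on_saturation = "na")))
})

test_that("divergence summary aggregates constructed datasets correctly", {
  set.seed(88)
  base <- random_dna(200)
  far <- mutate_sites(base, n_ts = 7, n_tv = 3)  # ~5% apart
  seqs <- tibble::tibble(
    id = c("a1", "a2", "b1", "b2"),
    species = c("spA", "spA", "spB", "spB"),
    sequence = c(base, base, far, far))
  ds <- divergence_summary(seqs)
  stats <- ds$pair_stats
  expect_equal(stats$mean_pct[stats$type == "intra"], c(0, 0))
  inter <- stats[stats$type == "inter", ]
  expect_equal(inter$mean_pct, 100 * k2p_distance(base, far), tolerance = 1e-9)
  expect_equal(sum(stats$n_comparisons), choose(4, 2))

  # single-sequence species -> undefined intra cell, not zero
  seqs3 <- dplyr::bind_rows(seqs,
                            tibble::tibble(id = "c1", species = "spC",
                                           sequence = base))
  ds3 <- divergence_summary(seqs3)
  c_cell <- ds3$pair_stats |>
    dplyr::filter(species_a == "spC", type == "intra")
  expect_true(is.na(c_cell$mean_pct))
  expect_equal(sum(ds3$pair_stats$n_comparisons), choose(5, 2))
})

test_that("barcoding gap uses a strict inequality and is monotone", {
  set.seed(89)
  base <- random_dna(300)
  seqs <- tibble::tibble(
    id = c("a1", "a2", "b1", "b2"),
    species = c("spA", "spA", "spB", "spB"),
    sequence = c(base,
                 mutate_sites(base, n_ts = 3),          # intra A = 1%
                 mutate_sites(base, n_ts = 12),          # inter >= ~3%
                 mutate_sites(base, n_ts = 12, n_tv = 3)))
  ds <- divergence_summary(seqs)
  gap <- barcoding_gap(ds)
  expect_true(all(c("max_intra_pct", "min_inter_pct") %in% names(gap)))

  # boundary: min_inter == max_intra -> no gap (strict rule)
  ds2 <- ds
  inter_rows <- ds2$pair_stats$type == "inter"
  max_intra <- max(ds2$pair_stats$max_pct[!inter_rows], na.rm = TRUE)
  ds2$pair_stats$min_pct[inter_rows] <- max_intra
  expect_false(any(barcoding_gap(ds2)$gap_present))

  # monotonicity: inflating every interspecific distance keeps the gap
  ds3 <- ds
  ds3$pair_stats$min_pct[inter_rows] <- ds3$pair_stats$min_pct[inter_rows] + 10
  before <- barcoding_gap(ds)$gap_present
  after <- barcoding_gap(ds3)$gap_present
  expect_true(all(after >= before))
})
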