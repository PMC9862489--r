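# wingcoi

Dual species identification for mosquitoes: landmark-based **wing
geometric morphometrics** and **COI DNA barcoding**, in one R package.

## The problem

Several mosquito genera contain species whose adults can only be keyed
out from multiple intact body parts; damaged field specimens defeat the
keys. Two complementary quantitative routes exist:

* **Wing shape.** Wing-vein landmarks carry a species-specific signal.
  After Generalized Procrustes Analysis (GPA) removes position, scale and
  rotation, canonical discriminant analysis separates species, and the
  pairwise Mahalanobis distance
  `D = sqrt((m_i - m_j)' W^{-1} (m_i - m_j))` (pooled within-group
  covariance `W`) quantifies shape divergence. Identification performance
  is measured by leave-one-out reclassification: remove each specimen,
  refit means and `W`, assign to the nearest group.
* **COI barcodes.** Kimura-2-parameter distances
  `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` (transition proportion `P`,
  transversion proportion `Q`) summarise intra- and interspecific
  divergence; identification works only where a **barcoding gap** exists,
  i.e. the smallest interspecific distance strictly exceeds the largest
  intraspecific one. Neighbor-joining trees with bootstrap supports
  visualise the clustering.

wingcoi implements both engines end to end — TPS/CSV/FASTA input,
repeatability estimation, partial-warp shape variables, permutation-tested
Mahalanobis distances, UPGMA shape trees, divergence tables, gap reports,
NJ bootstrap trees — plus synthetic generators that emulate the full
statistical structure of a four-species congeneric study, so every stage
is testable offline. Results are tibbles; fitted objects have `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

```r
library(wingcoi)

# a study-mirror synthetic dataset: 4 species, 157 wings (40/50/42/25)
wings <- simulate_wings(morpho_sim_spec(seed = 42))
sv    <- shape_variables(gpa_align(wings))
cva   <- discriminant_analysis(sv)
cva
#> Canonical discriminant analysis: 4 groups, 31 shape variables
#> Pairwise Mahalanobis distances (D):
#>                chiangmaiensis fuscana halifaxii vorax
#> chiangmaiensis           0.00    4.97      5.91  9.68
#> fuscana                  4.97    0.00      4.68 11.84
#> halifaxii                5.91    4.68      0.00 12.03
#> vorax                    9.68   11.84     12.03  0.00

loo_classification(sv)
#> Leave-one-out reclassification: 93.63% correct overall
#>                chiangmaiensis fuscana halifaxii vorax
#> chiangmaiensis             39       1         0     0
#> fuscana                     2      45         3     0
#> halifaxii                   1       3        38     0
#> vorax                       0       0         0    25
```

Every `D` is on the scale wing-shape studies report (roughly 4–10 between
congeners); the one species separated by `D ≈ 10–12` reclassifies
perfectly, the overlapping trio at 92–94%. The barcode side of the same
design:

```r
seqs <- simulate_barcodes(seq_sim_spec(seed = 42))
ds   <- divergence_summary(seqs)
glance(ds)
#> # A tibble: 1 × 4
#>   n_sequences n_species overall_intra_mean_pct overall_inter_mean_pct
#> 1          40         4                  0.481                   3.16

barcoding_gap(ds)
#> # A tibble: 6 × 5
#>   species_a      species_b max_intra_pct min_inter_pct gap_present
#> 1 chiangmaiensis fuscana           1.23           1.38  TRUE
#> 2 chiangmaiensis halifaxii         0.611          1.38  TRUE
#> 3 chiangmaiensis vorax             1.54           4.71  TRUE
#> 4 fuscana        halifaxii         1.23           0     FALSE
#> 5 fuscana        vorax             1.54           4.23  TRUE
#> 6 halifaxii      vorax             1.54           4.23  TRUE
```

One species pair overlaps (`gap_present = FALSE`): its interspecific
distances dip to 0% while intraspecific distances reach 1.2% — barcoding
cannot separate that pair, while wing shape can. That asymmetry is the
package's central use case.

End-to-end runners write inspectable bundles (CSV tables, Newick trees,
PNG figures, a run log with seeds):

```r
run_simulate("data", morpho = morpho_sim_spec(seed = 1),
             barcode = seq_sim_spec(seed = 2))
cfg <- run_config(landmarks = "data/wings.tps",
                  labels = "data/wing_labels.csv",
                  out_dir = "out_morpho", seed = 1)
run_morpho(cfg)
```

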