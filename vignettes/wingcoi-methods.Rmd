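---
title: "Methods behind wingcoi: wing shape discrimination and COI barcode divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind wingcoi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingcoi)
```

wingcoi implements the two complementary identification workflows used for
mosquitoes whose adults are hard to key out morphologically: landmark-based
wing geometric morphometrics and COI DNA barcoding. This vignette documents
the statistical models behind each stage, the tunable parameters and their
defaults, what the synthetic generators do and do not emulate, and the
design decisions taken where the methodology is genuinely open.

## 1. Wing geometric morphometrics

### Procrustes superimposition

A wing is recorded as 18 two-dimensional landmarks at vein intersections
and termini. Size is summarised by centroid size
$CS = \sqrt{\sum_i \lVert x_i - \bar x \rVert^2}$, the standard geometric
morphometrics size measure. `gpa_align()` performs full Generalized
Procrustes Analysis: configurations are centred, scaled to unit centroid
size, and iteratively rotated onto the running consensus until the
consensus root-mean-square change falls below `tol` (default `1e-8`, with a
100-iteration cap that flags rather than fails). Two choices deserve note:

* **No reflections.** The optimal rotation is constrained to determinant
  +1 because all wings are digitized on the same body side; allowing
  reflections could silently "repair" mirrored digitizing mistakes.
* **Tangent-space treatment.** Aligned coordinates are used as
  tangent-space coordinates about the consensus after orthogonal
  projection off the four similarity directions (two translations,
  scaling, infinitesimal rotation). For congeneric wings the shape
  dispersion is tiny (Procrustes distances of order 0.01–0.05), so the
  tangent approximation is excellent.

`procrustes_distance()` is the partial Procrustes distance: both
configurations at unit centroid size, rotation-only fit, explicit residual
norm. The residual is computed directly rather than through
$\sqrt{2-2\gamma}$, which loses half the significant digits near zero —
this matters when testing that two digitizations of one wing coincide.

### Digitizing repeatability

Landmark placement error is quantified by re-digitizing a subset of images
and partitioning the aligned-coordinate variance with a one-way
specimen-effect decomposition pooled across all coordinates. With mean
squares $MS_a$ (among specimens), $MS_w$ (within, i.e. among replicate
digitizations) and average replicate number $r$,

$$\hat\sigma^2_a = \frac{MS_a - MS_w}{r}, \qquad
  R = 100\,\frac{\hat\sigma^2_a}{\hat\sigma^2_a + MS_w}.$$

$R$ is the repeatability percentage and $100-R$ the measurement-error
percentage. The among-component is clipped at zero; the unbalanced-design
coefficient replaces $r$ when replicate numbers differ. This is the
standard Procrustes-ANOVA-style estimator; the literature this package
follows names only "Procrustes analysis" for this step, so the
decomposition had to be fixed here as a design decision.

### Shape variables

`shape_variables()` converts aligned coordinates into the "final shape
variables" used downstream: partial-warp scores — projections of the
tangent residuals onto the eigenvectors of the thin-plate-spline
bending-energy matrix of the consensus — plus the two uniform (affine)
components obtained as the orthonormal complement of the non-affine and
similarity subspaces. Because the combined basis is an orthonormal basis of
the $2p-4$-dimensional tangent space, total variance is conserved exactly
and the subsequent principal-component rotation spans the same space as a
PCA of the raw Procrustes residuals (both properties are tested).

The number of retained components is controlled by `variance_retained`
(default 0.99): the study design this package mirrors never states how many
components were kept, so the threshold is deliberately a user-facing
parameter. A dedicated test confirms that classification results are
unchanged when the threshold approaches 1.

Component signs are fixed by the convention *largest absolute loading is
positive*. Principal-component and canonical-axis orientations are
otherwise arbitrary, which is why only $|r|$ and $r^2$ of the allometric
regression are stable quantities; the reported `slope_sign` refers to this
package's orientation convention.

### Discrimination, permutation tests, classification

`discriminant_analysis()` computes canonical axes maximizing between-group
relative to pooled within-group variance, and between-group Mahalanobis
distances

$$D_{ij} = \sqrt{(\bar x_i - \bar x_j)^\top W^{-1} (\bar x_i - \bar x_j)},$$

with $W$ the pooled within-group covariance (denominator $n-g$). $D$ (not
$D^2$) is reported, the scale on which congeneric mosquito wings fall
roughly between 4 and 10. Two numerical guards apply: the score dimension
is capped at $n-g-1$ (degrees of freedom) and further truncated while the
condition number of $W$ exceeds $10^8$, with a message.

`mahalanobis_permutation_test()` permutes specimen labels within each
species pair and uses the add-one Monte-Carlo estimator
$p = (1+\#\{D^\ast \ge D\})/(n_{perm}+1)$, which can never return an exact
zero; Bonferroni correction multiplies by the number of pairs (6 for four
species). `loo_classification()` refits *both* the group means and the
pooled covariance in every leave-one-out fold — stricter than reusing the
global covariance, and the honest error rate; published tools sometimes
reuse the global fit, so accuracies here can be marginally more
conservative.

`allometry_regression()` regresses the first canonical-axis score on
centroid size and reports $r^2$ with a size-permutation p-value. The first
canonical axis matches the convention of plotting "wing shape (the
discriminant factor)" against CS; a multivariate shape-on-size regression
was considered and rejected as a primary statistic because the univariate
$r^2$ is what this literature reports.

`shape_cluster_tree()` builds a UPGMA tree (linkage configurable; the
published trees in this literature rarely name the linkage, and UPGMA is
the conventional choice for ultrametric similarity displays) on the
Mahalanobis matrix, with supports from bootstrap resampling of specimens
*within* species so that group sizes — and hence the covariance pooling —
are preserved.

## 2. COI barcode divergence

### K2P distances

`k2p_distance()` implements the Kimura two-parameter distance from the
transition proportion $P$ and transversion proportion $Q$ over comparable
sites:

$$d = -\tfrac12\ln(1 - 2P - Q) - \tfrac14\ln(1 - 2Q).$$

Sites with gaps or ambiguity in either sequence are deleted pairwise by
default (`deletion = "complete"` is available); pairwise deletion is the
common default of the software family used for barcode divergence tables.
Saturation ($1-2P-Q \le 0$ or $1-2Q \le 0$) raises an error naming the
pair rather than returning infinity — silent infinities hide alignment
problems — and can be downgraded to `NA` for summary robustness.
Distances are reported in substitutions/site in matrices and in percent in
summaries; every pipeline output labels its units.

Alignment itself is delegated: COI barcodes are indel-free and in-frame
within a genus, so the package requires equal-length input and points the
user to an external aligner otherwise, instead of bundling one.

### Divergence summary and the barcoding gap

`divergence_summary()` groups all pairwise distances into the standard
intra/inter table (mean, min, max in percent per cell; a species with one
sequence has an *undefined* intraspecific cell, never zero). The
barcoding gap for a species pair is present exactly when the smallest
interspecific distance strictly exceeds the larger of the two species'
intraspecific maxima. The strict inequality is the boundary rule: a tie is
no gap, because identification by barcode fails when ranges touch.

### Pseudogene screen

`check_stop_codons()` translates under the invertebrate mitochondrial code
(stops TAA/TAG; TGA is tryptophan) and passes when at least one forward
frame is stop-free (`frame = "auto"`), since the primer-relative reading
frame of an amplicon is not fixed a priori. A stop-free translation is the
standard evidence that the amplified fragment is the functional
mitochondrial locus rather than a nuclear copy.

### Neighbor joining and bootstrap

`nj_tree()` is a direct Saitou–Nei implementation: the pair minimizing
$Q_{ij} = (n-2)d_{ij} - r_i - r_j$ is joined, branch lengths follow the
standard formulas, and a negative branch is clamped to zero with its
deficit moved to the sister branch so path lengths are preserved. On
additive matrices the tree reproduces all input distances to machine
precision (tested against an exhaustive least-squares search over all 4-
and 5-taxon topologies, and against an independent implementation on
random matrices). `bootstrap_nj()` resamples alignment columns, recomputes
K2P + NJ per replicate, and annotates the *full-data* topology with the
percentage of replicates containing each bipartition — supports annotate
the estimate, not a consensus tree. Saturated replicates are skipped and
counted, with a warning above 1%.

## 3. The synthetic generators

The generators exist so that every stage of both pipelines can be
exercised end to end, at the study's scale, with no external data. Their
defaults *are* the study conditions the analyses assume.

### Wing landmarks (`morpho_sim_spec()` / `simulate_wings()`)

Four species groups of 40/50/42/25 specimens; 18 landmarks from a fixed
synthetic wing-like template (its coordinates are arbitrary and digitized
from no specimen). The generative model, per specimen of species $s$:

$$\log CS \sim N(\mu_s, \tau_w^2), \qquad
  t = \delta_s + \beta(\log CS - \mu_s)\,e_1 + \varepsilon,\quad
  \varepsilon \sim N(0, \sigma^2 I_{2p-4}),$$

with $t$ the tangent-space coordinates mapped back around the template and
emitted after a random rigid motion and scaling by $CS$; replicate
digitizations re-emit the same wing with digitizing noise only (and every
digitization, the original included, carries that noise). Defaults:
$\sigma = 0.003$ Procrustes units per tangent dimension (a typical
within-species scale for mosquito wings), $\tau_w = 0.06$, mean wing CS
$\approx 3$ units.

Three calibrations are solved at specification time, in closed form:

* **Separations.** The species mean offsets $\delta_s$ are the classical
  MDS embedding of the target Mahalanobis matrix (default: the 4.05–10.25
  range observed between congeneric species, with one species much more
  distinct), scaled axis-wise by the full within-group standard deviations
  — so realized Mahalanobis distances match the targets by construction.
* **Allometry.** The observed $r^2 \approx 0.22$ between the first
  discriminant axis and CS cannot come from within-species allometry
  alone: at separations of $D \approx 8$–10, the between-group variance on
  the first axis bounds the achievable pooled $r^2$ at about
  $1/(1+v_z) \approx 0.1$. The generator therefore couples the *species
  mean sizes* (negatively) to the dominant shape axis — biologically,
  interspecific allometry — with the between-species size spread $\tau_b$
  solved from
  $r^2 (v_z + 1)(\tau_b^2 + \tau_w^2) = (\tau_b\sqrt{v_z} - \beta\tau_w^2/w_1)^2$,
  where $v_z$ is the weighted variance of the first-axis embedding
  coordinates and $w_1$ the full within sd along that axis. The individual
  coefficient $\beta$ stays small (about 10% of the noise variance).
* **Digitizing error.** `digitizing_error_fraction` (default 0.04, i.e.
  repeatability 96%) is converted to a per-dimension noise sd through a
  short fixed-point iteration, because the between-species offset scale
  itself depends on the total within variance.

A single simulated dataset recovers the target $r^2$ with a sampling sd of
about 0.05 at $n = 157$, so the acceptance checks average a handful of
replicate datasets; the per-dataset spread is a property of the design
size, not of the generator.

### Barcodes (`seq_sim_spec()` / `simulate_barcodes()`)

Four species, 10 sequences each, 658 bp, intraspecific targets
0.19/0.60/0.35/0.76% and interspecific targets up to 5.1%, with the
`fuscana`–`halifaxii` pair at 0.48% — below the intraspecific maxima, so
exactly that pair lacks a barcoding gap. The root sequence is drawn from
an AT-rich insect mitochondrial composition (A 29.9, T 38.8, G 15.4,
C 15.9%) and made stop-free; species ancestors evolve along the
neighbor-joining tree of the between-ancestor targets
($d_{anc} = d_{inter} - (d_{intra,a}+d_{intra,b})/2$, clamped at zero);
individuals evolve along a deterministic within-species branch profile
spanning 0 to about twice the mean (two individuals per species remain
identical to their ancestor), which reproduces the 0-to-max intraspecific
ranges barcode tables report.

Substitution is a K80 process *conditioned on its event count*:
each branch receives $m = \mathrm{round}(L \times p_{\mathrm{diff}}(d))$
events, where $p_{\mathrm{diff}}$ is the closed-form expected
differing-site proportion at distance $d$, sites are allocated disjointly
across all branches from one random permutation (an infinite-sites
approximation, appropriate below ~6% divergence), and events that would
create a frame-0 stop codon are rejected (purifying selection), so every
sequence is a clean ORF with no post-hoc repair. Two consequences drive
this choice. First, measured K2P distances are unbiased for the targets
(the saturation inversion cancels the estimator's correction). Second, the
divergence table — including the minima and maxima that decide the
barcoding gap — is pinned to its targets up to integer rounding. Under
unconditioned per-site simulation each dataset's pairwise distances
carry $\sqrt{d/L} \approx 0.4$–0.7 percentage points of Monte-Carlo noise,
which is *larger than the gap margins being emulated* (min-inter 1.43 vs
max-intra 1.14 for the closest pair with a gap), so the designed gap
structure would be scrambled in a substantial fraction of seeds. The
randomness that remains — root sequence, site permutation, substitution
types — is what the downstream tree and bootstrap machinery consume.

### What the generators do not emulate

Real wings violate isotropy: landmark noise is spatially correlated and
vein-specific, and within-species covariance differs between species. Real
COI data contain rate variation among sites and codon positions,
composition drift, and occasionally indels or heteroplasmy. Passing tests
on synthetic data therefore demonstrate that the *algorithms* implement
their definitions and recover known structure at the study's scale — not
that any particular biological dataset will behave as cleanly.

## 4. Problem sizes and numerical choices in the tests

The test suite runs at the study scale where that is cheap (157 wings, 40
barcodes) and at reduced sizes where a property needs replication: the
type-I calibration uses 1000 two-group null datasets of 25 specimens and
10 shape variables with 199 permutations each; divergence-recovery
averages 150 small two-species datasets; tree bootstraps in tests use
29–100 replicates while the pipeline default stays at 1000. Degenerate
inputs (identical shapes, all-gap sequences, zero size variance,
coincident landmarks, saturated distances) raise typed errors that the
pipeline runners convert into stage-labelled failures.

## 5. Known limitations

* The landmark reader accepts the common TPS dialect (`LM=`, `ID=`,
  `IMAGE=`, `SCALE=`) and warns on unknown keys; curve/semilandmark
  records are out of scope.
* Mahalanobis distances at high retained dimension carry the usual upward
  small-sample bias (noticeably so when the score dimension approaches
  group sizes); the conditioning guard bounds the numerics but not the
  bias. Comparisons across studies should fix `variance_retained`.
* The barcoding engine assumes aligned, indel-free input and a single
  genetic code; model selection beyond K2P, and online database identity
  queries, are deliberately outside the package.
* `fetch_coi_accessions()` is the only networked function; nothing in the
  analyses or tests touches the network.
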