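---
title: "Methods and design notes for hypoxiaTME"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for hypoxiaTME}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypoxiaTME)
hxLogLevel("WARN")
```

`hypoxiaTME` quantifies how tumor hypoxia relates to the immune
microenvironment: signature scoring of a hypoxic state, spatial
delineation of the tumor boundary, deconvolution and co-localization of
ALCAM-high macrophages with exhausted T cells, immunophenoscore
computation, pseudotime-based transcription-factor screening, and
hypoxia-stratified survival and immunotherapy-response statistics. This
vignette documents the models, their parameters, the numerical choices,
and the places where the design was genuinely open.

## Signature scoring

Two single-sample scorers are provided.

**Rank-walk scorer** (`scoreRankEnrichment`), used for bulk samples and
spatial spots. Within each sample, genes receive average ranks (ties
averaged; the largest expression has rank N). Walking positions from the
highest to the lowest rank, signature genes ("hits") add
$r(g)^{\tau}/\sum_{hits} r(h)^{\tau}$ with weight exponent $\tau = 0.25$,
non-signature genes subtract $1/(N - N_g)$, and the score is the mean of
the running difference over all N positions. Two properties make this
scorer attractive for cross-sample comparison: it is invariant to any
strictly monotone per-sample transformation (normalization choices cannot
change it), and it is exactly checkable — the test suite compares it
against a brute-force transcription of the walk on randomized small
instances. The widely used gene-set variation approach (kernel-smoothed
expression CDFs) targets the same construct; we deliberately implement the
rank-walk form instead because it is fully specified by the walk above,
admits an exact small-instance oracle, and all downstream use only
compares scores *between* samples. The kernel choice and difference
statistic of the CDF-based approach are therefore out of scope.

**Mean-scaled scorer** (`scoreMeanScaled`), used when columns are single
cells: per-gene z-scores across cells (sample standard deviation with
$n-1$ denominator; zero-variance genes contribute 0), averaged over the
matched signature genes. It is linear, so planted shifts propagate
predictably — useful for recovery tests.

The 15-gene hypoxia signature ships as a packaged GMT
(`hypoxiaSignature()`). Gene matching is exact and case-sensitive
everywhere; signature genes absent from a matrix are logged. The Tex
marker set carries both the spelling "TGAE" found in published marker
lists and the standard symbol ITGAE, so whichever a matrix uses will
match.

`medianSplit` labels scores strictly above the median "high" and
everything else "low"; ties at the median deterministically go low, and
an all-constant vector is an error rather than an arbitrary split.

## Spatial slides and tumor-boundary delineation

Slides are `SpatialSlide` objects (a `SummarizedExperiment` whose
`colData` holds array and pixel coordinates). QC keeps genes detected in
at least 5 spots with total count at least 100, then keeps spots with at
least 500 transcripts, computed on the filtered gene set — the filters
are stated in that order and their interaction is not specified
elsewhere, so gene-then-spot is this package's fixed convention.

The neighbor graph connects spots whose center distance is at most 1.2
times the minimal pairwise distance; on a clean hexagonal lattice this is
exactly the six first-circle neighbors, and the 1.2 slack tolerates small
registration jitter without reaching the second circle (distance √3).

**Malignant core.** Spots are scored with a malignancy signature by the
rank-walk scorer; candidates are spots at or above the 0.90 score
quantile, restricted to the largest connected component of the neighbor
graph. This replaces copy-number-based malignancy calling: CNV inference
is out of scope here and synthetic slides carry no CNV signal, while a
marker-program score preserves the intent (find the contiguous
high-malignancy island). With uniform (tied) expression the quantile rule
keeps all tied spots and connectivity then applies — degenerate but
well-defined.

**Layer-wise extrapolation.** Spot expression is log-normalized
(counts-per-10k, log1p), per-gene centered, and embedded by SVD. Two
numerical choices matter:

* *Deterministic components.* Each component's sign is fixed by making
  its largest-magnitude loading positive, so results do not depend on
  LAPACK sign conventions.
* *Noise filtering.* Up to 10 components are used, but components whose
  singular value falls below the Gavish–Donoho optimal hard threshold
  (estimated from the spectrum median) are dropped. On slides whose
  expression is driven by a few composition axes, the trailing components
  are a flat noise bulk; including them adds a distance "noise floor"
  comparable to the malignant/boundary separation itself and destabilizes
  the acceptance rule below. The threshold is closed-form and
  deterministic.

Extrapolation starts from the core (layer 0). At each layer, frontier
neighbors are accepted as Mal when their Euclidean distance to the
centroid of the *current* malignant set is at most the 0.95 quantile of
the core spots' distances to that centroid; otherwise they are marked
Bdy. Two refinements proved necessary on recovery tests and are part of
the algorithm's definition here:

* the centroid is recomputed each layer from the current malignant set —
  with a hypoxia gradient across the tumor, outer malignant rings are
  systematically displaced in expression space, and a centroid frozen at
  the core rejects them;
* Bdy labels are provisional until extrapolation completes — a spot
  rejected early is re-tested when a later frontier reaches it, since the
  centroid may have moved toward it. Labels become final when a layer
  adds no malignant spot (those last frontier spots stay Bdy) or the
  layer cap (lattice diameter in spacing units) is reached; everything
  never reached is nMal.

If the core covers every spot there is no boundary; the function returns
an all-Mal assignment with a warning rather than failing.

`summarizeRegionScores` reports per-region means, a per-slide min–max
normalization of the three means to [0, 1], and two-sided Wilcoxon
rank-sum tests for Mal vs Bdy and Bdy vs nMal; empty regions yield
missing means and skipped tests.

## Deconvolution, gating, and co-localization

`buildReference` averages linear-scale normalized expression per labeled
cell type (at least 10 cells per type) and keeps the 50 most
type-specific genes per type by log fold change against the rest.
`deconvolveSpots` solves a non-negative least-squares problem per spot
over the union of marker genes and normalizes the weights to proportions;
an all-zero solution yields missing proportions. A log-normal measurement
model would be an alternative; linear-scale NNLS was chosen because
downstream logic consumes only the proportions and the linear model is
exactly recoverable on noiseless mixtures (the tests require recovery to
1e-6 there, and mean absolute error below 0.05 at 5% Gaussian noise).

`gateAlcamMacrophages` first requires a macrophage proportion of at least
`macThreshold` (default 0.1) — published descriptions of the ALCAM median
split do not state whether such a gate preceded it, so the gate is this
package's explicit, configurable addition — then median-splits
log-normalized ALCAM expression among those spots (ties low). Tex spots
are called by rank-walk enrichment of the Tex marker set at a score
quantile (default 0.75) with an optional minimum T-cell proportion of
0.05; both knobs are exposed because no canonical values exist.

`colocalize` flags a Tex spot when it is itself an ALCAM-high macrophage
spot or any first-outer-circle neighbor is one.
`compareColocalizedExhaustion` contrasts exhaustion scores between
flagged groups with a two-sided Wilcoxon rank-sum test, exact when the
pooled size is at most 25 without ties (the test suite checks exactness
against full permutation enumeration up to n = 10).
`regionEnrichment` reports per-region observed/expected ratios with
Fisher exact p-values.

## Immunophenoscore

`computeIPS` computes per-gene z-scores across samples, averages them
within each determinant (metagene), applies the determinant's ±1 weight,
averages determinants within each of the four categories, and sums the
four category values. The weight scheme is fixed and validated: +1 for
each MHC molecule, ICOS, CD27, and the four effector cell types; −1 for
PD-1, CTLA4, LAG3, TIGIT, TIM3, PD-L1, PD-L2, Tregs, and MDSCs. The
published scheme names "10 MHC-related molecules" and "10 checkpoints or
immunomodulators" without enumerating all of them, and does not print the
cell-type metagenes; the packaged defaults fill those gaps from the
original immunophenogram scheme and are flagged
(`"listed_in_source": false`) and fully overridable via
`loadIPSConfig()`. IPS is invariant under per-gene positive affine
transforms and is negated exactly when all weights are negated — both are
tested.

## Pseudotime and the TF screen

Trajectory reconstruction methods (tree-based dimensionality reduction)
are replaced by a transparent 1-D ordering: the first principal component
of log-normalized expression, oriented so the designated root state has
the minimal mean projection, min–max scaled to [0, 1]. The biological
claims this feeds — monotone marker trends along differentiation — only
require a faithful ordering, which the recovery tests verify (absolute
Spearman correlation with true pseudotime ≥ 0.8 under the generator's
signal strength). Externally computed pseudotime can be supplied
directly.

`trendTest` compares a natural cubic spline fit (df = 3) of expression on
pseudotime against the intercept-only model with an F-test — a
like-for-like stand-in for trajectory differential tests, with matched
significance thresholds. Direction is the sign of the difference between
the mean over the top pseudotime tercile and the mean over the bottom
tercile, "flat" below 1e-8; terciles are taken over all cells, which
makes direction well-defined even when state labels are noisy. The test
depends on pseudotime only through its values' order, so affine
rescalings leave p unchanged. p-values are BH-corrected across the tested
genes.

`filterDifferentiationTFs` keeps a TF when, in at least half of all
datasets (≥ n/2, ties at exactly half retained), it is significant (p < 0.05 and q < 0.05) and
higher at the end state than the start state. `classifyTfHypoxia` labels
each retained TF per dataset by the sign and significance of its Spearman
correlation with the per-cell hypoxia score, and `summarizeTfClasses`
aggregates class proportions across datasets. `subsetFoldChange` adds 0.5
pseudocells to every subset count before forming proportion ratios so
subsets absent from one hypoxia group stay finite.

## Survival and response statistics

`spearmanScreen` uses average-rank Spearman correlation; p-values come
from the t-approximation, except at n ≤ 9 where the full permutation
distribution is enumerated; q-values are BH across features, flagged at
q < 0.05 ("FDR" is implemented as BH throughout the package — the
standard default where only "FDR" is named). `groupCompare` is the
Wilcoxon machinery (rank-sum unpaired, signed-rank paired; exact at total
n ≤ 25 without ties, normal approximation with tie correction otherwise;
all-zero paired differences return p = 1).

`responseContrast` supports two poolings: responders = CR/PR vs
non-responders = PD (SD excluded), or the IMvigor-style pooling that adds
SD to the responders. Where paired pre/on-treatment profiles exist it
additionally contrasts per-patient on-minus-pre score changes between
responder groups.

`optimalCutpoint` scans every midpoint between consecutive distinct
scores whose split leaves each group at least 10% of samples (the
conventional minimum for maximally selected statistics; no value is
stated in the source descriptions), computes the standardized two-group
log-rank statistic (hypergeometric variance) at each, and returns the
argmax of the absolute statistic, breaking ties toward the smaller
cutpoint. The statistic is reported uncorrected — the cutpoint is used
for stratification, and the survival figure it feeds reports the log-rank
p of the resulting split, not a selection-corrected p. The scan is tested
for exact agreement with an independently written exhaustive oracle on
random cohorts. `kmLogrank` produces product-limit curves via the
survival package, medians as the earliest time the estimate drops to
≤ 0.5 (NA when it never does), and the two-group log-rank chi-square from
the package's own hypergeometric form, which is well-defined (statistic
0) even for degenerate zero-variance configurations; it is cross-checked
against `survival::survdiff` on non-degenerate inputs.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of their parameter objects (same
parameters, same output; the RNG state of the session is restored
afterwards).

**Slides** (`simulateSlide`). An axial hex lattice with unit spacing
(pixel centers $x = q + r/2$, $y = r\sqrt{3}/2$), so the six-neighbor
distance is exactly 1 and the distance-threshold neighbor rule is
exercised. Ground truth by ring index: rings up to `coreRadius` are Mal,
the next ring is Bdy, the rest nMal. Per-spot cell-type mixtures are
drawn from region-specific Dirichlet distributions over five cell types
(Malignant, Macrophage, TexT, EffectorT, Stromal), each carrying a
20-gene-scale expression program; every cell type also carries a stromal-,
immune- or malignancy-appropriate program so that no region is
systematically depleted of high-expressed genes (rank-based scores would
otherwise be compositionally confounded). Hypoxia-program means scale
with $\exp(\text{gradient} \cdot (1 - \text{ring}/n_\text{rings}))$ —
highest at the center, baseline at the slide edge. One global factor
scales mean library size; spot totals then vary naturally with
composition. Counts are negative binomial with variance
$\mu + \mu^2/\text{dispersion}$. Defaults: 600 genes, library size
20 000, dispersion 2 (strongly overdispersed, Visium-like),
`hypoxiaGradient` 1.5, `programMean` 10 against a 0.2 baseline.
"Strong program separation", the regime used by the recovery tests, is
`regionSharpness = 10` (Dirichlet concentrations scaled tenfold, giving
pure regional mixtures). `alcamBdyFactor` multiplies the ALCAM mean in
boundary spots to plant macrophage ALCAM elevation at the boundary.

**Bulk cohorts** (`simulateBulkCohort`). Latent hypoxia per sample is
`hypoxiaSlope` × stage plus Gaussian noise (sd 0.8, so a slope of 0.5
over 9 stages gives a clearly detectable but not deterministic
stage–score association); hypoxia-signature gene means scale with its
exponential. Survival is exponential with hazard
$\propto \exp(\text{HR} \cdot h)$ around a 720-day baseline, censored at
a uniform fraction of the event time with probability `censorRate`.
Response is Bernoulli with logit decreasing in latent hypoxia (responders
CR/PR, non-responders PD or occasionally SD so that both pooling rules
are exercised); 40% of samples carry a paired on-treatment profile whose
latent hypoxia is shifted down for responders and up for non-responders.

**T cells** (`simulateTcells`). Pseudotime uniform on [0, 1]; naive
markers decline, exhaustion markers and the hypoxia program rise along
it; subset labels are pseudotime quintiles (NaiveLike → Tex). A
designated TF can be made to rise in exactly k of n datasets to exercise
the consistency filter end to end.

The generators deliberately omit gene–gene correlation beyond the program
structure, batch effects, doublets, segmentation artifacts, and spatial
autocorrelation beyond the region model. Passing recovery tests therefore
demonstrates correctness of the algorithms under their stated model, not
performance on real tissue; on real data the boundary quantile, core
quantile, and gating thresholds are the knobs a user should expect to
revisit.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` use: 8-ring slides (217 spots,
600 genes) with 10 simulation seeds for region recovery; 9-stage cohorts
with 20 samples per stage; 100-spot deconvolution panels; 2000 null genes
for trend-test size; 50 random cohorts (n ≤ 60) for cutpoint/oracle
agreement; and the full CLI chain run twice from one seed with manifests
compared byte-for-byte. These sizes give stable statistics while keeping
a complete run in minutes on one CPU. All randomness flows from explicit
integer seeds; every stochastic operation logs its seed.

## Known limitations

* The boundary algorithm assumes the malignant region is a single
  connected territory; multifocal tumors would need per-component seeding.
* Rank-walk scores are comparable across samples of one matrix but are
  not calibrated across matrices with different gene universes.
* NNLS deconvolution has no uncertainty estimates; proportions near the
  simplex boundary are biased by the non-negativity constraint.
* The 1-D pseudotime cannot represent branching trajectories; branch
  analysis is out of scope.
* The maximally selected statistic is reported without a
  selection-adjusted p-value; treat the cutpoint as descriptive
  stratification, not a test.
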