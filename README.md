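# hypoxiaTME

Tumor hypoxia reshapes the immune microenvironment: hypoxic regions around
the tumor boundary recruit immunosuppressive *ALCAM*-high macrophages that
co-localize with exhausted CD8+ T cells (Tex), and a high hypoxic state
predicts worse survival and poorer response to immune-checkpoint blockade
(ICB). `hypoxiaTME` implements the computational chain needed to quantify
these relationships across bulk, single-cell, and spatial transcriptomics,
together with synthetic-data generators carrying full ground truth so every
step can be validated by parameter recovery.

It is aimed at computational biologists analyzing 10x-style spatial slides
(hexagonal spot lattices), bulk RNA-seq cohorts with staging / survival /
ICB-response annotation, and CD8+ T-cell single-cell datasets.

## What it computes

**Hypoxia score.** A single-sample enrichment score of a 15-gene
HIF1A-associated signature (*ACOT7, ADM, ALDOA, CDKN3, ENO1, LDHA, MIF,
MRPS17, NDRG1, P4HA1, PGAM1, SLC2A1, TPI1, TUBB6, VEGFA*). For bulk samples
and spots the score is a weighted Kolmogorov–Smirnov random walk over
within-sample expression ranks: with genes ordered by decreasing rank r(g),
hits (signature genes) contribute increments proportional to r(g)^0.25
(normalized to sum 1), misses decrement uniformly by 1/(N − N_g), and the
score is the mean of the running difference over all N positions. It
depends only on within-sample ranks, so any monotone per-sample transform
leaves it unchanged. For single cells the score is the mean per-gene
z-score (across cells) over the signature.

**Tumor boundary delineation.** Spots are QC-filtered (genes detected in
≥ 5 spots with total count ≥ 100; spots with ≥ 500 transcripts), a
hexagonal neighbor graph is built from spot centers, a malignant core is
seeded (malignancy-signature score ≥ the 0.90 quantile, largest connected
component), and the tumor is grown layer by layer: a frontier spot joins
the malignant region (Mal) when its distance to the malignant centroid in
denoised PCA space is at most the 0.95 quantile of the core spots' own
distances; otherwise it is provisionally boundary (Bdy). Extrapolation
completes when no frontier spot joins; remaining spots are non-malignant
(nMal).

**Deconvolution and co-localization.** Spot cell-type proportions by
non-negative least squares (min ‖y − S·w‖², w ≥ 0) against reference
cell-type profiles over marker genes; macrophage-containing spots are split
at the median of normalized *ALCAM* expression; Tex spots are called by
marker-set enrichment (*PDCD1, LAG3, HAVCR2, CD8A, CD8B, CD3E, ENTPD1,
ITGAE, BATF, NR4A1*); a Tex spot counts as co-localized with ALCAM-high
macrophages when it carries them itself or any first-outer-circle lattice
neighbor does, and exhaustion scores are contrasted between co-localized
and non-co-localized Tex spots by a two-sided Wilcoxon rank-sum test.

**Immunophenoscore (IPS).** Per sample, the sum over four categories
(effector cells, suppressor cells, MHC molecules, checkpoints) of averaged
±1-weighted per-gene sample z-scores; higher = more immunogenic.

**Pseudotime TF screen.** Cells ordered on a 1-D naive→exhausted axis
(first principal component, root-anchored); per-gene natural-spline F-tests
against pseudotime; transcription factors retained when significant
(p < 0.05 and BH q < 0.05) and rising toward the exhausted end in at least
half of all datasets; retained TFs classified by Spearman correlation with
the per-cell hypoxia score.

**Survival and ICB response.** Spearman screens with BH FDR control;
responder (CR/PR, optionally pooled with SD) vs non-responder (PD) score
contrasts including paired on-minus-pre treatment changes; maximally
selected log-rank cutpoints (exhaustive scan of admissible midpoints of the
standardized log-rank statistic) for hypoxia-high/low stratification, with
Kaplan–Meier curves and the log-rank test.

## Worked example

Simulate a slide with a malignant core, delineate the boundary, and
summarize the hypoxia score by region:

```r
library(hypoxiaTME)
hxLogLevel("WARN")

slide   <- simulateSlide(slideSimParams(regionSharpness = 10, seed = 1))
slide   <- qcFilter(slide)
graph   <- buildNeighborGraph(slide)
core    <- identifyMalignantCore(slide, defaultProgramGenes()$malignancy,
                                 graph)
regions <- delineateBoundary(slide, graph, core)
regions
#> RegionAssignment: 217 spots (Mal=37 Bdy=24 nMal=156), 4 extrapolation layer(s)

hyp <- scoreRankEnrichment(slide, hypoxiaSignature(),
                           signatureName = "hypoxia")
out <- summarizeRegionScores(hyp, regions)
out$summary
#>      region   n  mean normalized
#> Mal     Mal  37 0.454      1.000
#> Bdy     Bdy  24 0.417      0.463
#> nMal   nMal 156 0.384      0.000
out$tests
#>      contrast statistic        p
#> 1  Mal_vs_Bdy       845 3.36e-09
#> 2 Bdy_vs_nMal      2916 1.13e-05
```

The delineated regions here coincide with the simulation's ground truth
(37 Mal / 24 Bdy / 156 nMal spots), and the region means reproduce the
expected gradient: malignant spots carry the highest hypoxia score, the
boundary sits in between, and boundary spots are significantly more
hypoxic than non-malignant tissue.

A subcommand-style CLI wraps the same functions
(`simulate`, `score`, `regions`, `deconv`, `coloc`, `ips`, `tfs`,
`survive`):

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "hypoxiaTME.R", package = "hypoxiaTME"))') \
    simulate --config config.json --out out/
```

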