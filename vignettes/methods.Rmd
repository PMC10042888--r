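---
title: "Methods: consensus marker discovery, subcluster programs, and chromatin regulation in multi-omic ccRCC cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nephromics` implements the cross-sample consensus analyses of a multi-omic
clear cell renal cell carcinoma (ccRCC) cohort: single-nucleus RNA counts,
single-nucleus chromatin accessibility, and bulk expression/proteomics with
survival follow-up. This vignette records the statistical models, the
parameter choices and their rationale, the behavior of the synthetic cohort
generator the test suite scores against, and the design decisions taken
where the procedures left room.

## Statistical kernel

**Normalization.** Counts are depth-normalized per cell:
`value = ln(1 + count · s / total)` with scale factor `s = 10,000`. Zeros
map to zeros, so sparsity is preserved. Group averages are taken on the
de-logged scale (`expm1`), matching non-log dot-plot conventions.

**Rank-sum differential expression.** Two-sided Wilcoxon rank-sum on the
normalized values with the usual single-cell pre-filters: a gene is tested
only if detected in at least `min_pct = 0.1` of either group, and (for the
tumor-vs-cell-type comparisons) if the detection fractions differ by at
least `min.diff.pct = 0.1`. For untied samples with 30 or fewer cells the
exact Wilcoxon null distribution is used; larger or tied samples use the
normal approximation with tie and continuity correction. This keeps small
fixtures exact (the test suite checks agreement with full permutation
enumeration at n = 8+8 to within 10% relative) without sacrificing speed at
single-cell scale. Fold changes are `log2((mean_A + 1)/(mean_B + 1))` on
de-logged group means; log2 with a pseudocount of 1 is used everywhere, and
since all positivity thresholds in the pipeline are at zero, the choice of
base does not move any decision boundary. Bonferroni correction uses the
full number of genes (or peaks) in the matrix, not the post-filter count,
so adjusted p-values are comparable across differently filtered runs.

**Logistic likelihood-ratio test with latent covariates.** Accessibility
tests compare `group ~ feature + covariates` against `group ~ covariates`
(χ², 1 df). A covariate that fully explains a feature drives its p-value to
1 — this is precisely how copy-number correction works: when the per-peak
CNV value accounts for the accessibility difference, the peak is dropped.
Perfect separation is detected (diverging coefficient or fitted
probabilities at the boundary) and refitted by Firth-penalized likelihood;
such features are flagged rather than dropped, so degenerate synthetic
configurations cannot crash a run.

**Over-representation.** One-sided Fisher/hypergeometric upper-tail tests
against an explicit background universe (genes detected in ≥ 10% of either
population, or nearest genes of all peaks, depending on the analysis), with
BH correction across sets.

## Tiered marker consensus

Stage 1 runs per-sample comparisons (tumor vs each cell type, tumor vs the
combined non-tumor population) plus one pooled tumor-vs-NAT comparison, and
requires: (c1) significance against *every* other cell type in at least one
sample; (c2) a positive fold in ≥ 90% of samples and significance in ≥ 75%;
(c3) a positive fold against non-tumor cells of normal tissue. Fractions
are computed over samples with at least 3 cells on both sides and compared
with `>=` (9/10 passes 90%); cell types with fewer than 10 cells in a
sample are skipped in c1, since a rank test on fewer cells is noise. Cell
types absent from a sample are not required — the consensus is over the
evidence that exists. Stage 2 repeats the test against pooled NAT proximal
tubule cells (the presumed cell of origin) and each epithelial type; stage
3 requires a strictly greater-than-1 linear fold of mean gene activity in
tumor cells; stage 4 validates tumor-vs-NAT shifts in bulk RNA and protein
(BH q < 0.05), reported separately. `final_tier` counts consecutive stages
passed; a subcellular-location filter can be supplied as a plain gene table
rather than a bundled database.

## Subcluster programs and classification

Per-subcluster DEGs are one-vs-rest within sample, positive only, on
clusters with ≥ 50 cells. A pathway's score for a cluster is the mean over
the pathway's DEGs of the gene's z-scaled average expression across all
tumor clusters; zero-variance genes are dropped with a warning (their z is
undefined), and sets with no DEGs present score `NA`. Quantiles follow R's
type-7 (linear interpolation) convention throughout — the procedures name
quantiles without fixing a convention, so one is fixed and documented here.
Module enrichment requires a cluster to exceed the upper quantile (75%, or
90% for the strict mTOR-style rule) for *every* member set; the EMT rule
additionally requires an epithelial score below the 20% quantile.
Epithelial scores are z-scaled across tumor **and** proximal-tubule
clusters jointly (both populations anchor the scale), while pathway scores
scale over tumor clusters only; banding is Epi-H above the 70% quantile of
the tumor clusters' scores, Epi-M strictly between 40% and 70%, Epi-L
otherwise, and EMT-designated clusters take the EMT label regardless of
band — the four labels partition the tumor clusters. Stage association
takes each patient's maximum subcluster score and compares stage III/IV
vs I/II patients by two-sided rank-sum, BH-corrected across sets; fully
tied groups return p = 1, and groups with fewer than two patients are an
error.

## Signature and survival

The tumor-cell-intrinsic signature is built by comparing cells of the
clusters above the 90% score quantile against cells of those below the 10%
quantile, keeping genes up in the top group (adjusted p < 0.05), and
intersecting with the tumor-specific markers — the intersection is what
makes the bulk signature attributable to tumor cells rather than
infiltrating immune cells. "Samplewise-scaled" bulk scoring is read as
per-gene z across samples (mean over signature genes); the alternative
(per-sample z across genes) would make scores incomparable across samples
and is rejected. Survival stratification takes the `ceiling(n·q)` lowest
and highest scoring samples (q = 0.25 for the signature, 0.30 for single
markers), discards the middle, and compares the groups by Kaplan-Meier and
a two-sided log-rank test. The order-statistic group rule is deterministic
under ties (ordering by score, then sample id) and reproduces 26-per-tail
groups for a 103-sample cohort at 25%. No covariate-adjusted (Cox)
modeling is performed — only KM/log-rank is reported for these analyses.

## Chromatin accessibility

Peaks are resized to 501 bp centered on the summit and deduplicated by
greedy retention in descending signal order, so the final set is pairwise
non-overlapping; ties are broken by coordinates and peak id. Gene activity
sums fragment counts over the gene body extended 2 kb upstream
(strand-aware), then log-normalizes. The DACR consensus runs the logistic
LRT per mutant sample against pooled control tumor cells with FRiP as a
latent covariate, Bonferroni-adjusts over all peaks, and keeps peaks
significant in ≥ 50% of comparisons with the same fold direction in all of
them (the direction is the sign of the linear fold of de-logged
depth-normalized group means with a 0.01 pseudocount; a zero fold counts
as inconsistent). Peaks passing the consensus are re-tested pooled with
FRiP and the peak's CNV value as latent covariates and dropped if no
longer significant. Fold directions are computed on normalized counts, the
documented resolution of an otherwise open choice.

Promoters are (−1000, +100) around the TSS, strand-aware, 1-based
inclusive; peaks overlapping any promoter are promoter-class, and the
nearest gene is by TSS distance with gene-id tie-break. Motif scanning
computes log2-odds against the background (probabilities clamped at −20
bits to keep zero-probability columns finite) over both strands, with the
reporting threshold computed exactly by dynamic programming over the score
distribution discretized to 1e-3-bit bins (exceedance probability
≤ 5e-5 by default, the conventional scanning threshold); windows containing
`N` are skipped. Reverse-complement-palindromic consensi legitimately
produce a matching hit on both strands at the same offset. Motif-to-gene
edges exist only for genes whose promoter overlaps a DACR; hits are
promoter or distant motifs by their absolute genomic position relative to
the promoter window, and peaks co-accessible with a promoter peak at
≥ 0.25 are labeled enhancers (co-accessibility is consumed as an input
table; the method that generates it is out of scope). The motif deviation
score is a simplified re-implementation of the bias-corrected deviation
idea: expected counts are proportional to peak "popularity" (fraction of
cells with a nonzero count), backgrounds are 50 peak sets sampled within
popularity deciles, and GC matching is not attempted — sequences are not
always available, and the consistency-tier filtering downstream (≥ 50% of
samples, all-samples strict tier) is rank-based and robust to the
simplification.

## Copy number

Segments are called gain/loss at log2 copy ratio strictly above 0.2 /
below −0.2 (boundary values are neutral). Arm-level summaries are
length-weighted means `Σ len·log2CR / Σ len` over an arm's segments
(half-open intervals, `len = end − start`), called with the same
thresholds; the weighting is exactly invariant to splitting segments into
contiguous equal-ratio pieces. The cluster-CNV/pathway-score association
test is not named by the source procedure, so both a point-biserial
Pearson correlation (two-sided t p-value, BH across loci) and a rank-sum
p-value are reported side by side; neither is presented as canonical.

## The synthetic cohort generator

The generator emulates the study conditions every validation experiment
runs under: 12 tumor samples (plus 2 NAT samples), 2000 genes, ~6500
cells, negative-binomial counts (dispersion `size = 2`, so variance
µ + µ²/2, typical of UMI data) with per-cell log-normal(0, 0.3) size
factors to exercise depth normalization; 50 planted tumor markers at
log2 FC 1.5 in all samples; per-type identity-gene blocks so cell types
are separable (tumor cells deliberately carry *no* identity block beyond
the planted markers, so a null cohort has no built-in tumor-specific
genes); three tumor subclusters per sample with a planted program; a
5000-peak chromatin layer with 100 peaks at log2 FC −1 in a 4-mutant vs
8-control design, 200 tumor cells per sample; planted motif instances
embedded verbatim in 501-bp peak sequences; bulk expression with a 1-log2
tumor-vs-NAT shift, a protein layer that tracks expression with
N(0, 0.3) measurement noise and 10% of genes missing; exponential
survival with log hazard `log(3)` per standard deviation of the latent
signature score and uniform censoring on [0, 20]; and per-sample CNV
segments on a toy genome of 4 chromosomes × 2 arms × 10 Mb, with planted
arm events and segment noise truncated at ±0.05.

Two realism choices matter for interpretation. Planted markers, program
genes and differential peaks draw their base means from the expressed
range (log-normal around twice the global median) rather than the full
gene-wide distribution: the effects being emulated are, by construction,
detectable genes (CA9-class markers) and reproducibly covered peaks, and
planting a 1.5-log2 fold on a gene observed in 3% of cells would test the
sampling floor rather than the consensus logic. Second, the generator
omits doublets, ambient contamination, batch effects and GC bias, so
passing tests demonstrate the correctness and calibration of the
consensus procedures under a faithful count model — not robustness to
every artifact of real single-nucleus data.

Determinism: each generator draws from a named substream derived from the
master seed, so layers are reproducible independently of execution order,
and the pipeline's subcommands are byte-identical under a fixed seed.

## Validation problem sizes

The test suite scores: stage-1 marker recall/precision on the default
cohort; 20-seed null calibration for stage 1 and for the DACR consensus
(the null chromatin layer uses 1000 peaks with 100 tumor cells per sample —
the false-positive behavior of a Bonferroni-gated consensus does not need
the full 5000-peak layer, which is reserved for the recovery experiment);
DACR recovery and direction-flip rejection at full size; exact oracles for
the rank-sum, hypergeometric, BH/Bonferroni, Kaplan-Meier, log-rank,
peak-dedup, gene-activity, promoter, motif-scan and arm-weighting kernels;
log-rank power (200 simulations at HR 3, n = 160) and size (500 null
simulations); and end-to-end byte-level determinism of every subcommand.

## Known limitations

- The rank-sum normal approximation is used for all tied samples; only
  untied small samples take the exact path.
- The motif deviation score is a deliberate simplification (no GC-matched
  backgrounds) and should be read as a consistency screen, not a calibrated
  effect size.
- Cluster-level CNV status and peak co-accessibility are inputs; the
  package neither infers CNVs from expression nor computes co-accessibility.
- The logistic LRT treats cells as independent within a comparison, as the
  underlying procedures do; patient-level pseudoreplication is handled by
  the ≥ 50%-of-samples consensus layer, not by a mixed model.
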