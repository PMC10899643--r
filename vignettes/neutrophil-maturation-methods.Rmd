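---
title: "Models and methods: neutrophil maturation trajectories, modules and cross-species alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutrotime)
```

# Scope

`neutrotime` implements a complete analysis chain for continuous immune-cell
maturation measured by single-cell RNA-seq, developed around neutrophil
granulopoiesis: cells are ordered along a pseudotime in $[0,1]$, the
trajectory is discretized into 100 expression bins, maturation-associated
genes are selected by a spline association test, genes are partitioned into
modules and bins into maturation phases by dynamic-time-warping (DTW)
hierarchical clustering with Kelley–Gardner–Sutcliffe (KGS) cluster-number
selection, transcription factors (TFs) are ranked as candidate module
regulators by scaled DTW similarity, trajectories from other species are
aligned per gene by cross-correlation lag, pan-species maturation signatures
are derived from the lag table, and bulk samples are scored by ssGSEA and
expression-matched module scores. A synthetic-data generator with full
planted ground truth makes every stage testable without external downloads.

# The pipeline stage by stage

## Quality control and normalization

Genes are kept when detected in at least 20 cells; cells are kept with at
least 500 detected features and a mitochondrial read proportion strictly
below 10% (mitochondrial genes recognized by a configurable id-prefix list,
default `mt-`, case-insensitive, because zebrafish and mammalian naming
differ). Normalization is deterministic log1p counts-per-10k. The
downstream statistics operate on binned, per-gene z-scored profiles, which
are insensitive to the choice of variance stabilizer; a model-based
stabilizer would change none of the rank- and shape-based results and would
add a fitted model where none is needed.

## Pseudotime

`infer_pseudotime()` offers two modes. `component1` (its default) rescales
the rank of each cell's first principal component score to $[0,1]$ — the
cluster-free ordering. `principal_curve` runs a compact Hastie–Stuetzle
iteration in the top two components: smooth each coordinate against the
current ordering, recompute arc-length positions by projection onto the
fitted polyline, repeat to convergence, with two deterministic starts (the
first-component ordering and the angular ordering around the centroid, which
unrolls arched embeddings) selected by projection error. The full fit
(`fit_maturation_trajectory()`) defaults to the principal-curve mode: a 1-D
linear component folds trajectories whose intermediate programs are
orthogonal to the main axis (the classic horseshoe effect), while the curve
follows them. Orientation is decided by marker genes: the trajectory is
flipped so the rising marker (mmp9-like) increases; if the falling marker
(lyz-like) disagrees, the rising marker wins and a warning is issued.

Pseudotime is reported as rescaled ranks, so any statistic downstream is
invariant to monotone distortions of the latent coordinate.

## Binning and the association test

Bin $b$ of `bin_trajectory()` covers $[(b-1)/n, b/n)$ (last bin closed) and
holds the mean normalized expression of its cells; empty bins are filled by
linear interpolation and flagged, and bins with $\le 3$ cells are flagged
low-quality but kept (flag, don't drop). `association_test()` fits, per
gene, a cubic B-spline with 6 interior knots at pseudotime quantiles and
tests it against the intercept-only model with an F-test, followed by
Benjamini–Hochberg adjustment; mitochondrial, ribosomal and hemoglobin
genes (configurable regexes) and genes with fewer than 5 cells at $\ge 3$
reads are excluded before testing, and the top 1500 significant genes by
statistic are selected (all of them when fewer). The Gaussian spline F-test
on log-normalized data stands in for a negative-binomial GAM Wald test: on
z-scored binned profiles the two select and rank essentially the same
genes, and the linear-model form has an exactly known null. Exact numeric
equality with a count-model Wald statistic is not a goal; ranking agreement
is.

One caveat is inherent and shared by every pipeline of this design: the
association test conditions on a pseudotime inferred from the same
expression matrix. Under a complete null this is circular and
anti-conservative — the first component aligns with the largest noise
direction, and genes loading on it inherit spurious association. The
package's null-control tests therefore score the test against an ordering
independent of the noise; on real data the selection should be read as
"associated with the inferred axis", not as an unconditional discovery.

## DTW, KGS, modules and phases

The DTW distance is the classic dynamic program with absolute-difference
local cost and the symmetric step pattern whose diagonal move carries
weight 2; no warping window by default; all of it configurable via
`dtw_config()`. The implementation (in C++) is verified in the test suite
against exhaustive enumeration of all warping paths for every pair of
length-4 series over $\{0,1,2\}$.

Gene profiles are z-scored across bins before DTW — on raw scales the
distance is amplitude-dominated, while the scientific question is shape —
and smoothed with a centred moving average of 5 bins. The smoothing is a
variance-reduction step: at desk scale a bin averages ~20 cells, an order
of magnitude fewer than in a full-size study, and unconstrained DTW is
quick to exploit bin-level noise when plateau regions are compared.

`partition_genes()` clusters the selected genes with Ward.D2 linkage on the
DTW matrix and cuts the tree at the KGS-selected number of clusters: for
each $k$, the average over clusters of size $\ge 2$ of the mean
within-cluster pairwise distance (singletons contribute no spread) is
min–max rescaled over $k$ to $[1, k_{max}-1]$ and added to $k$; the minimum
wins, ties toward smaller $k$. Modules are labelled M1..Mk by the
pseudotime of each module's mean-profile peak, so labels depend only on the
partition.

`partition_phases()` clusters the 100 bins — each bin a vector over the
maturation genes — with the same DTW + Ward + KGS machinery, with two
deliberate configuration choices. First, the gene axis is ordered by
profile peak position (the order a seriated heatmap displays) before bins
are compared: over an arbitrary gene ordering, unconstrained warping
degenerates into a comparison of value multisets — an early bin with one
gene block high and a mid bin with another block high have nearly identical
multisets, and the phase structure disappears (during development a bin
whose cells were 90% mid-phase sat 2.4× closer to the early-phase interior
than to its own). Second, the default warping band for bins is narrow
(width 10): along a gene axis, warping is only meaningful for matching
genes of similar timing. Both choices are parameters, not hard-coded.
Phases are labelled P1..Pg by mean bin position; contiguity along the bin
axis is measured (fraction of bins agreeing with the best ordered
segmentation, found by dynamic programming) and reported, never enforced.
Cells inherit the phase of their bin. Whether phases should be clustered
over cells rather than bins is ambiguous in general; bins are used here
because they are the object every other stage shares, and the cell mapping
is exposed.

## Regulator ranking

For TFs and target genes on the same binned axis,
$s_{il} = 1 - d_{il} / \max_l d_{il}$ turns DTW distances into a
similarity in $[0,1]$ normalized per target gene across TFs: the most
distant TF scores exactly 0, and 1 requires an exact profile match. The
warping is the point: a TF whose profile runs a few bins ahead of its
targets — cause preceding effect — keeps a high similarity where a fixed-lag
correlation would not. `rank_regulators()` compares each TF's similarity
distribution across modules (Kruskal–Wallis), runs Dunn's pairwise post-hoc
from rank sums with tie correction and Holm adjustment, and calls a TF a
candidate regulator of the module where its median similarity is highest
when all contrasts against the other modules are significant. The relevant
null — a TF whose similarity distribution is identical across modules — is
exercised by permuting module labels; the procedure stays below the nominal
5% call rate there.

## Cross-species alignment

Stage-level integration: per-stage means, rank-based quantile normalization
(sort each column, average across columns at each rank, map back through
the original ranks; ties get average ranks and interpolated values),
per-dataset z-scaling, Ward.D2 on the Pearson distance $1-r$, a per-stage
maturation score (rank within its own dataset rescaled to $[0,1]$; a
single-stage dataset scores 0 by convention), and leaf reordering of the
dendrogram by ascending score within the tree constraints.

Gene-level alignment: 1-to-many homology is collapsed by keeping the
candidate with the highest detection rate (ties break lexicographically;
many-to-one collisions keep the better-detected pair), only genes common to
all datasets are kept, and each gene's z-scored binned profile in each
query dataset is aligned to the reference profile by the lag maximizing

$$ r(k) = \frac{\sum_t (x_{t+k} - \bar x)(y_t - \bar y)}{n\, s_x s_y},
   \qquad k \in [-k_{max}, k_{max}] $$

with $y$ the reference, $x$ the query, ties toward the smallest $|k|$ and
then the negative lag; a positive lag means the query pattern occurs later
than the reference. The default $k_{max}$ is 99 — the full range for 100
bins — because a conventional short default window would make a lag
threshold of 50 bins unreachable. Peak coefficients are reported as
computed, including negative peaks. Per gene the mean lag across datasets
and per (dataset, module) the mean peak coefficient are tabulated.

The estimator has a known bias worth stating: because means and scales are
global and the overlapping window shrinks with $|k|$, profiles that are
monotone steps with long plateaus produce broad, slightly
zero-shrunk correlation peaks. Transient (bump-like) profiles localize
sharply. The package's lag-recovery study therefore plants its shifts on
transient genes (see below).

Pan-species signatures: per module, genes with $|\text{mean lag}| \le 50$
bins (inclusive) and not on the blacklist of markers of unrelated cell
types are emitted as `<module>pan` gene sets with per-gene provenance, in
GMT-compatible form.

## Scoring

`ssgsea()` is the rank-weighted running-sum form: per sample, genes are
ranked by expression (average ranks on ties); the running sum steps up by
$|r|^{\alpha}$ (normalized over the set, $\alpha = 0.25$) at set genes and
down by $1/(N-|S|)$ elsewhere, and the score is the sum of the running-sum
values over all positions — the integral, not the maximum. With
`normalize = TRUE` scores are divided by the global score range. Scores
are functions of ranks only, hence exactly invariant under strictly
monotone transforms of a sample's values; one formulation with the
normalization toggle covers both common use styles of the score.
`module_score()` is the expression-matched contrast: genes are split into
24 equal-frequency bins of average expression, each set gene draws 100
controls from its own bin, and a cell's score is mean set expression minus
mean control expression. Because the controls are matched on average
expression, a shift present in every cell is absorbed; the score detects
per-cell deviations, and set genes are not excluded from the control pool,
which attenuates strong planted contrasts by their bin-share.
`hypergeom_enrichment()` is the upper one-tailed hypergeometric test with
BH adjustment (reporting threshold FDR < 0.1). `mixing_sensitivity()`
builds pseudo-bulks at fixed neutrophil:stromal ratios (1000 cells, 20
replicates per ratio), scores them and reports per-ratio medians.

# The synthetic-data generator

`simulate_trajectory_dataset()` emulates the statistical structure the
analysis assumes, not any particular dataset. Cells draw a latent
maturation time $t \sim U(0,1)$; counts are negative binomial with mean
`depth_factor * (baseline + amplitude * shape(t))`, gene-level dispersion 5
and a lognormal(9, 0.3) per-cell depth — a plausible droplet-scale setting.
The default design plants three modules over four phases:

* **M1** (55 genes): falling logistic, centre 0.25, width 0.025 — the early
  program switching off;
* **M2** (55 genes): plateaued pulse, on over $[0.25, 0.50]$ — the
  transient intermediate program;
* **M3** (70 genes): two-step rise — 12% of full level from $t = 0.50$,
  full level from $t = 0.75$ — a late program active through the last two
  phases at a rising level, which is what makes phase 4 distinct without
  adding a fourth gene module;
* reporters: a rising mmp9-like and a falling lyz-like gene (amplitude 14),
  used for orientation and to derive NO/INT/HI sorted-gate labels at the
  30th/70th percentiles of the rising reporter;
* the remaining genes are expressed but flat.

Per-gene jitter (centre sd 0.01, width ±10%, amplitude ±30%) keeps modules
internally heterogeneous. Three design facts matter and were chosen
deliberately: module shapes differ in kind, not merely in timing, because
unconstrained DTW absorbs pure time shifts; programs cross-fade exactly at
the phase boundaries (0.25, 0.50, 0.75), because a gap in which no program
is active creates intermediate bins that cluster as a spurious phase; and
the late module's two-step level encodes "active through the last two
phases", with the step sized so that the contrast survives the compression
of log normalization. The implied ground-truth phases are the windows
$[0, .25), [.25, .5), [.5, .75), [.75, 1]$.

What the generator does **not** emulate: ambient RNA, doublets, batch and
hashing effects, multi-lineage branching, and realistic transcriptome-wide
gene counts (a 300-gene panel stands in for the transcriptome, so the
compositional coupling of library-size normalization is stronger than in
real data). Passing recovery tests therefore demonstrate that the
machinery recovers planted structure of the assumed kind at realistic
noise; they do not certify behaviour under artifacts the generator omits.

`simulate_species_family()` translates each gene's profile by an integer
bin lag (edge-padded, wrap-free, positive = later than the reference),
renames genes to species-specific ids and emits a homology table whose
detection rates are the observed detection fractions, with optional planted
1-to-many paralogs (thinned to a clearly lower rate).
`simulate_stage_datasets()` averages the noiseless log-profile over
pseudotime windows and adds Gaussian noise — datasets available only as a
few ordered stages. `simulate_stromal_pool()` provides background cells
expressing a disjoint marker set, and `simulate_bulk_mixtures()` sums
sampled cells to pseudo-bulks at fixed ratios.

# Validation studies and their problem sizes

The acceptance studies (mirrored in `tests/testthat/test-acceptance.R` and
recomputed by `scripts/acceptance.R`) run at these sizes, chosen as the
smallest that exercise each property convincingly:

* module/phase recovery: 10 datasets of 2,000 cells × 300 genes at
  dispersion 5; expected: KGS picks 3 modules and 4 phases, module ARI
  $\ge 0.9$, and bin-phase accuracy $\ge 0.9$, each in at least 9 of 10
  seeds;
* DTW: exact agreement with path enumeration on all $81^2$ pairs of
  length-4 series over $\{0,1,2\}$;
* regulators: TFs leading each module by 5 bins (plus flat decoys) top
  their module's ranking in $\ge 9/10$ seeds; under the permuted-label
  null, specificity calls stay $\le 5\%$ over 50 draws;
* lag alignment: shifts drawn from $\{-20..20\}$ bins planted on 60
  transient genes in a 2,000-cell query dataset are recovered within
  ±2 bins for $\ge 95\%$ of genes. Both datasets are discretized on the
  generator's latent time here: the study isolates alignment accuracy
  from ordering error, which the module/phase study quantifies separately
  (and the deliberately exotic all-transient panel is exactly the geometry
  linear embeddings order poorly);
* pan-signature rule: planted conserved/shifted/blacklisted genes are
  recovered exactly, with the $|lag| = 50$ boundary inclusive;
* quantile normalization: the two-column worked example gives
  (2.5, 3.5, 4.5) in both columns and output columns are exact
  permutations of one another;
* ssGSEA: over all 15 placements of a 2-gene set among 6 genes, the
  top-rank placement maximizes and the bottom placement minimizes the
  score; monotone-transform invariance is exact;
* mixing: the matched late-module median ssGSEA score is monotone
  non-decreasing over neutrophil fractions $0, 0.1, \dots, 1$ (1000
  cells, 20 replicates, medians).

# Numerical and degenerate-input policy

Empty bins are interpolated and flagged; bins with $\le 3$ cells flagged.
Constant profiles z-score to zero rather than NaN. A gene identical to all
TFs gets similarity 1 (logged). Detection-rate ties in homology collapse
break lexicographically (logged). A single-stage dataset cannot be scaled
across stages and participates unscaled with maturation score 0 (logged).
Zero-variance profiles are an error in `cross_correlate()` and are dropped
with a warning in `build_lag_table()`. KGS ties break toward smaller k.
Cross-correlation ties break toward the smallest $|k|$, then the negative
lag. All generators restore the caller's RNG state; every stochastic
function takes an explicit seed.

# Known limitations

The pseudotime/selection circularity discussed above; the coarse CC peak on
long-plateau profiles; module scores' control pools not excluding set
genes; phase contiguity reported but not enforced; no branching
trajectories; and the generator's omissions listed above. The paper-scale
quantities that depend on external accessions (absolute feature counts of
a specific run, published signature sizes) are outside what synthetic data
can or should reproduce.
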