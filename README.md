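# neutrotime

Tools for analysing continuous immune-cell maturation from single-cell
RNA-seq, built around neutrophil granulopoiesis: pseudotime ordering and
binning of cells, selection of maturation-associated genes, discovery of
gene modules and maturation phases by dynamic-time-warping (DTW)
clustering, ranking of transcription factors as candidate module
regulators, alignment of maturation trajectories across species by
cross-correlation lag, derivation of pan-species maturation signatures,
and signature scoring of bulk samples. A negative-binomial synthetic-data
generator with planted ground truth makes the whole chain testable without
any external download.

## Who this is for

Computational biologists who have a single-cell expression matrix of a
maturing cell population (and possibly matching datasets from other
species, or bulk samples to score) and want a tested, scriptable
implementation of the trajectory → modules → regulators → cross-species →
signatures analysis style, with every statistical step exposed as a plain
R function.

## The methods in brief

- **Pseudotime**: rank of the first principal component, or arc-length
  along a Hastie–Stuetzle principal curve in the top components
  (deterministic, marker-oriented so a rising *mmp9*-like gene increases
  and a falling *lyz*-like gene decreases).
- **Binning**: 100 equal-width pseudotime bins of mean normalized
  expression; empty bins interpolated and flagged, bins with ≤ 3 cells
  flagged low-quality.
- **Association**: per gene, cubic B-spline (6 interior knots) vs
  intercept F-test, BH-adjusted; top 1500 significant genes selected.
- **Modules / phases**: DTW distance (|Δ| local cost, symmetric step
  pattern with diagonal weight 2) on z-scored smoothed profiles, Ward.D2
  linkage, cluster count by the Kelley–Gardner–Sutcliffe penalty; modules
  labelled by profile peak order, phases by position, with contiguity
  reported.
- **Regulators**: scaled DTW similarity `s = 1 − d / max(d)` per target
  gene across TFs; Kruskal–Wallis across modules with Dunn/Holm post-hoc;
  candidates ranked by median similarity.
- **Cross-species**: homology collapsed by detection rate, per-gene
  cross-correlation lag (positive = later than the reference), per-gene
  mean lags and per-(dataset, module) coefficients; pan signatures =
  genes with |mean lag| ≤ 50 bins, minus a blacklist.
- **Scoring**: rank-based ssGSEA (running-sum integral, α = 0.25),
  expression-matched per-cell module scores, hypergeometric
  over-representation, and a pseudo-bulk mixing sensitivity analysis.

See the methods vignette
(`vignettes/neutrophil-maturation-methods.Rmd`) for formulas, defaults,
design decisions and limitations.

## Worked example

```r
library(neutrotime)

sim <- simulate_trajectory_dataset(n_cells = 2000, n_genes = 300, seed = 1)
fit <- fit_maturation_trajectory(sim$expr, min_features = 100, top_n = 180)
fit
#> Neutrophil maturation trajectory fit
#>   cells: 2000  bins: 100
#>   maturation genes: 180 of 300 tested
#>   modules: 3 (KGS)  phases: 4 (KGS, contiguity 1.00)

summary(fit)
#> Maturation trajectory summary
#>   2000 cells; 300 genes tested, 180 selected
#>   module sizes:
#>   M1 M2 M3
#>   56 55 69
#>   bins per phase:
#>   P1 P2 P3 P4
#>   23 29 19 29
#>   phase contiguity: 1.00
#>   mean z-scored expression per module x phase:
#>       P1    P2    P3    P4
#> M1  1.59 -0.19 -0.52 -0.73
#> M2 -0.59  1.38 -0.14 -0.82
#> M3 -0.89 -0.82  0.29  1.33
```

The generator planted three gene modules (an early falling program, a
transient intermediate pulse, a two-step late program) across four phase
windows; the fit re-discovers 3 modules and 4 contiguous phases by KGS,
and the module × phase table shows the diagonal activation pattern — M1
high only in P1, M2 in P2, M3 rising through P3 into P4. `plot(fit)` draws
the module mean profiles with phase boundaries. From a fit, downstream
stages are plain calls: `scaled_dtw_similarity()` + `rank_regulators()`
for TF ranking, `bin_trajectory()` + `build_lag_table()` +
`derive_pan_signature()` for cross-species alignment, `ssgsea()` /
`module_score()` / `mixing_sensitivity()` for scoring.

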