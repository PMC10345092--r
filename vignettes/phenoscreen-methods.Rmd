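---
title: "Methods: gene-set scoring, phenotype screens and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-set scoring, phenotype screens and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoscreen)
```

# The analysis model

phenoscreen implements a cell-level association analysis for Patch-seq-style
data: the same neuron contributes a transcriptome (read counts per gene), a
morphology summary (total dendritic length, TDL, in µm), an
electrophysiology summary (action-potential rise speed, in V/s), and
metadata (donor, cortical area, cell class, t-type, relative depth within
L2/L3). Five statistical components sit on top of that data model.

## Normalization and gene-set scores

Counts are scaled within each cell to counts per million
(`cpm_normalize()`), then transformed to log10(CPM + 1)
(`log_transform()`). Normalizing within the cell removes differences in
sequencing depth and overall transcriptional output, at the price of making
expression *compositional*: a strong change in one group of genes slightly
shifts all the others in the opposite direction. That trade-off is inherent
to CPM and is inherited by everything downstream, including the synthetic
benchmarks (see *Known limitations*).

A gene set's score in a cell is the arithmetic mean of log10(CPM + 1) over
the set's genes (`gene_set_score()`). Before scoring, `prevalence_filter()`
removes genes with zero expression in **more than** a threshold fraction of
a designated reference population (default 0.95 of all cells; the reference
can be a smaller companion dataset). The inequality is strict: with 276
reference cells, a gene zero in 263 cells is excluded (263 > 0.95 × 276 =
262.2) while 262 zeros keeps it. "Zero" is tested on the stored value in
any normalization state, with no epsilon, because 0 counts, 0 CPM and 0
log10(CPM + 1) coincide exactly. Cells in which every retained gene is zero
score 0, not missing.

The per-cell mean is computed on the log scale rather than on CPM-then-log;
with sets of hundreds of genes spanning orders of magnitude of abundance the
log-scale mean weights genes more evenly and matches the scale on which the
scores are later z-scored and compared.

## Two-level group comparisons

Cells are strongly nested within donors, so group comparisons run at two
levels:

* **Cell level** — tie-corrected Kruskal–Wallis (`kruskal_wallis()`), H
  computed from average ranks with the standard correction
  1 − Σ(t³ − t)/(N³ − N), p from chi-square with k − 1 df. Post-hoc pairwise
  Dunn tests (`dunn_holm()`) use pooled average ranks with the tie-adjusted
  variance N(N+1)/12 − T/(12(N−1)), two-sided normal p values, Holm
  step-down adjusted. The pair family defaults to all k(k−1)/2 pairs
  (conservative); a `reference` argument restricts the family to pairs
  involving designated reference groups, for designs where only comparisons
  against particular types are of interest.
* **Donor level** — observations are collapsed to one median per donor and
  condition (`donor_collapse()`; donors missing any condition are dropped,
  never imputed), then the Friedman chi-square
  12/(nk(k+1)) ΣRⱼ² − 3n(k+1) with average within-donor ranks is computed
  (`friedman()`). For tiny designs an exact permutation p over all (k!)ⁿ
  within-donor orderings is available; at n = 3 donors and k = 3 conditions
  the maximum attainable statistic is 6.0 with exact p = 6/216. The classic
  (untied) chi-square formula is used with average ranks; note that
  `stats::friedman.test` additionally applies a tie correction to the
  denominator, so the two agree exactly only on tie-free data.

Degenerate inputs are defined, not errors: identical values across all
groups give H = 0 and p = 1.

## Per-gene phenotype screens and FDR

`per_gene_association()` regresses expression (log10(CPM + 1), the dependent
variable) on the phenotype by OLS, per gene, over the cells that have both
measurements. Cells lacking a phenotype are excluded from that screen only —
the reconstructed and recorded subsets of a Patch-seq study differ, and each
screen uses its own subset. The two-sided p for zero slope is algebraically
the Pearson correlation t-test with n − 2 df; having expression on the left
side only affects the units of the reported slope. Genes with zero variance
over the screened cells cannot be tested and are dropped with a report.
Donor identity is *not* adjusted for, matching the pooled-cells design of
the screens; treating it as a covariate is possible in principle but changes
the estimand and is deliberately not the default.

`benjamini_hochberg()` implements the step-up rule explicitly because the
screen reports the **critical p** — the largest sorted p(i) with
p(i) ≤ (i/m)q — in addition to flags; flags use p ≤ critical p (the ≤ at
p(i) itself is forced by the step-up definition; it differs from strict <
only at exact ties).

## Set overlap and over-representation

`overlap_enrichment()` asks whether the phenotype-correlated members of a
gene set belong to a reference set (e.g. HAR genes) more often than its
other members. The 2×2 table is rows = correlated / not-correlated members
of the full set, columns = in / not-in the reference; the one-sided p
(alternative: greater) is the exact hypergeometric upper tail, identical to
a one-sided Fisher test. This table construction is the only one consistent
with reporting "x% of correlated genes vs y% of the full set" alongside a
one-sided test. The odds ratio reported is the unconditional sample OR, with
Inf when an off-diagonal margin cell is zero.

`over_representation()` runs hypergeometric ORA of a foreground list against
a GMT annotation catalog: for each term, p = P(X ≥ k) with population N
(universe size), K (term size in the universe) and sample n (foreground size
in the universe); P(X ≥ k) rather than P(X > k), matching the one-sided
Fisher convention. Terms and foreground are intersected with the universe
first; terms with k = 0 are reported with p = 1 rather than dropped. No
term-size filters are applied by default (configurable). Significance uses
the triple rule: raw p, BH-adjusted p and q all below 0.05.

The q value is a Storey-style positive-FDR estimate with π₀ estimated at
λ = 0.5 (π₀ = #\{p > 0.5\} / (m/2), capped at 1), so
q = min(1, π₀ · BH-adjusted p). With fewer than 20 tested terms the π₀
estimate is too noisy to be useful and is pinned at 1, making q equal the
BH-adjusted p. This estimator is fully reproducible from the definition
above; it is not a re-implementation of any particular external package.

## AP rise speed

`detect_aps()` registers an AP at each upward crossing of a dV/dt threshold
(default 10 V/s) that is followed by a voltage peak of at least −10 mV
within 5 ms, merging crossings within 1 ms. The detector parameters are
conventional values and fully configurable; the downstream quantity — peak
dV/dt over the rising phase — is insensitive to them for clean suprathreshold
spikes, because any threshold below the peak slope selects the same rising
segment. The derivative is a central difference (one-sided at the ends),
with no smoothing by default; 1 mV/ms ≡ 1 V/s. `cell_rise_speed()` takes the
*first* AP of each suprathreshold sweep and averages across sweeps, so cells
firing many APs late in a step do not bias the estimate. The one-sided
threshold makes detection direction-sensitive: a time-reversed recording of
a realistic AP (fast rise, slow decay) contains no fast upstroke and yields
no detections.

# The synthetic-data generator

`generate_dataset()` emulates the structure the analysis assumes, with full
ground truth:

* **Cells** belong to t-types with configured relative-depth ranges and
  cycle deterministically over donors. Each cell carries a latent size
  factor z ~ Normal(type effect, 1). Default type effects make the deep-L3
  analogue (CARM1P1 = +0.8) largest and the superficial L2 type (LTK = −0.6)
  smallest, mirroring the depth gradient of real L2/L3 data.
* **Phenotypes** couple through z: TDL = 6000·exp(0.35 z)·(1 + ε) µm
  (log-linear, multiplicative noise SD 0.15, so TDL spans roughly 3–12 mm as
  in reconstructed L2/L3 pyramidal cells) and AP rise speed = 350 + 60 z + ε
  V/s (noise SD 30 V/s, values ~200–500 V/s). The shared factor makes the
  two phenotypes positively correlated, as in real deep-L3 types; an
  uncoupled mode gives TDL its own latent factor.
* **Counts** are negative binomial (dispersion 0.5, i.e. size 2) with
  log-normal library sizes (mean 5e5 counts over the simulated universe, CV
  0.3, a Patch-seq-like depth). Per-gene baselines are drawn log-normally
  and then shifted so total abundance is exactly 1e6 — baselines are
  therefore true expected log10 CPM. A fraction (default 10%) of genes is
  shifted 3 log units down, emulating genes the cell type barely expresses;
  these produce >95% zeros and exercise the prevalence filter naturally,
  without a zero-inflation component.
* **Planted effects**: each set plants genes whose abundance responds as
  exp(β z). β is calibrated so the gene's log10(CPM+1) correlation with the
  AP phenotype hits the configured target r: a β = 0 pilot simulation (300
  cells) measures each planted gene's residual SD σₑ, and
  β = ln(10)·(r′/√(1−r′²))·σₑ/sd(z) with r′ = target r divided by the
  latent–phenotype correlation. A target exceeding that correlation is
  impossible at any β, and the generator refuses it, stating the bound.
  Planted genes are re-drawn to baselines of 10–316 CPM (log10 U(1, 2.5)) so
  they are comfortably expressed, like the retained genes of a real screen.
* **Gene sets** realize configured pairwise/triple overlap counts exactly
  (regions are sized by rounding, then sampled without replacement), with
  defaults shaped like the published GWAS/HAR sets (~14–25% pairwise
  overlap). Planting can be biased toward one set's members to create a
  detectable enrichment signal for the overlap chain.
* **Traces**: spikes are Gaussian depolarizations with closed-form maximum
  derivative A·e^(−1/2)/s; the default width s = 0.3 ms gives ~200 V/s at
  100 mV amplitude and keeps the central-difference estimate within 1% of
  the analytic value at 50 kHz sampling and within 5% at 10 kHz.

All randomness flows from one master seed through keyed substreams (a
deterministic hash of seed and component key), so enlarging a config — more
cells, more genes — leaves the draws of existing components untouched.

What the generator does **not** emulate: per-donor batch effects beyond
additive type shifts, gene–gene correlation beyond the shared latent factor
and compositional coupling, zero-inflation beyond what the negative binomial
produces, realistic GO term hierarchies, and mapping noise in t-type labels.
Passing tests on this generator therefore validate the statistical
machinery and its calibration, not robustness to every artifact of real
Patch-seq data.

# Numerical and design choices

* Gene symbols match case-sensitively after whitespace trimming; a
  case-folding option would be easy but silently merging symbols is worse
  than failing loudly on case mismatches.
* Matrix orientation on disk must be declared (`cells_x_genes` default);
  auto-detection is refused because the square case is ambiguous.
* FREM3 cells exactly at the depth boundary (0.3) are assigned to L2,
  because L3 is defined by the strict inequality depth > 0.3; the boundary
  is configurable.
* CPM conservation: per-cell CPM sums to 1e6 exactly (up to floating
  error) when the matrix holds the full gene universe; subsetted matrices
  intentionally do not re-normalize.
* Correlations are clamped to [−1, 1] before the t transform so exact fits
  yield p = 0 rather than NaN.
* Heatmap z-scores use the population SD (divide by n, not n − 1), so each
  displayed row has SD exactly 1; constant genes are excluded earlier by
  the zero-variance drop.
* Ties in heatmap column order break by cell id; gene rows order by raw p,
  then gene id — all outputs are bit-reproducible.
* Friedman's exact permutation mode is guarded to (k!)ⁿ ≤ 1e6.
* `write_results()` serializes floats with 10 significant digits so
  delimited round-trips reproduce values to numerical noise.

# Problem sizes used by the test suite

The suite validates each statistic against independent brute-force oracles
(rank-variance identities for Kruskal–Wallis and Dunn, centered rank sums
for Friedman, threshold scans for BH, explicit term enumeration for the
hypergeometric tails — exhaustively for all tables of total size ≤ 30, ~46k
tables) on 500 random instances each, at 1e-10 agreement. Screen calibration
runs 200 all-null replicates (1000 genes × 150 cells) for the
false-discovery proportion and 200 planted replicates (target r = 0.6) for
sensitivity; smaller replicate counts are used for the generator-level
properties (planted-correlation accuracy, enrichment-chain detection) to
keep the default run compact. The K-W null calibration check uses 1000
simulated three-group datasets of 20 cells each.

# Known limitations

* CPM makes expression compositional: a strong planted module induces a
  small opposite-signed association in every other gene. The screen's
  false-discovery proportion on planted (non-null) simulations therefore
  sits slightly above the nominal q when effects are large and abundant —
  visible in the simulation results, and equally a property of any CPM-based
  analysis of real data.
* The per-gene screen pools cells across donors; with few donors and strong
  donor effects the effective sample size is smaller than the cell count,
  and p values can be optimistic. The donor-level Friedman path exists
  precisely to check conclusions at the donor scale.
* The q-value estimator is a simple λ = 0.5 Storey plug-in; with very few
  terms it degenerates (by design) to the BH-adjusted p.
* ORA treats annotation terms as flat sets; no GO-graph propagation or
  redundancy trimming is attempted.
* AP detection assumes clean somatic current-clamp traces; no artifact
  rejection or access-resistance quality control is included.
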