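---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
what each stage computes, the assumptions behind it, which knobs matter,
what the synthetic cohort does and does not emulate, and where the design
was genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Event data and gating

Cytometry events are cells × markers matrices of nonnegative ion-count-like
intensities. All gating and marker-level statistics operate on the
variance-stabilized scale `asinh(x / c)` with cofactor `c = 5`, the standard
choice for mass cytometry; the raw matrix is always retained, because the
anchor-threshold cytokine analysis thresholds raw intensities (a config
switch moves it to the arcsinh scale).

The gating hierarchy is a list of nodes, each a conjunction of threshold
comparisons on named markers intersected with its parent's membership.
Exclusive siblings must be disjoint; each level may carry a *complement*
node (the parent cells captured by no exclusive sibling), which makes every
exclusive family a partition of its parent — the property the composition
stage relies on. Event (row) indices are stable through every mask, so a
selection produced by the signature learner can be intersected with any
gate (`|So| / |Sc|`).

**Thresholds.** The source analyses gate manually from supplementary plots,
which are not machine-readable. Defaults are therefore data-driven:
`estimate_gate_thresholds()` places each marker's threshold halfway between
the 2nd and 98th percentile of the pooled healthy-control transformed
intensities (method `"midpoint"`). The midpoint of a wide quantile bracket
lands in the valley of a bimodal marker even when the positive mode holds
only a few percent of cells, where a pooled median would not. A plain
quantile method (`"quantile"`) and per-marker overrides are provided; "hi"
gates (PD-1hi) use the 90th percentile of the parent population (CD4 T
cells), matching the convention that "hi" is the top decile of the parent.

Two printed-versus-conventional ambiguities are configuration switches
rather than silent choices: the memory-quadrant naming
(`memory_convention = "as_printed"` keeps TCM = CD45RA+CD27−,
TEM = CD45RA−CD27+ exactly as printed; `"conventional"` swaps them) and the
IgM cut of the anergic Bnd gate (`bnd_igm_ref`, low versus negative).

**FCS.** No FCS parser is available in the supported dependency set, and a
binary cytometry parser is infrastructure this package should buy, not
write. Events are read and written as delimited tables (CSV/TSV, optionally
gzipped, header = marker names); `format = "fcs"` errors with guidance.

## 2. Anchor-referenced cytokine positivity

Each processing batch includes anchor aliquots of a single healthy donor.
For a cytokine and a gated population, the positivity threshold is the
0.95 quantile (linear interpolation, R type 7 — the convention is stated
because the source does not state one) of the anchor's T0 cells in that
population, computed per batch. A subject's readout is
`Δ% = %above(T6) − %above(T0)`; negative values are genuine (fewer
above-threshold cells after incubation) and preserved. Positivity is
strictly greater than the threshold; the tie convention only matters for
discrete data. Thresholding defaults to the same population being scored.

Group comparison uses Welch two-sample t-tests by default with
pooled-variance and Mann-Whitney options — the source methods cite t-tests
in one subsection and Mann-Whitney in figure legends, so both are exposed
and the choice is recorded in results. Degenerate zero-variance-in-both-
groups input returns p = 0 or 1 (documented) instead of erroring.

## 3. Gene-module and IFN-1 scores

Normalized expression is
`log2(height_g) − mean_h log2(height_h)` over housekeeping genes
{ACTB, GAPDH, TFRC}; only ratios matter, so the height unit is arbitrary
and per-subject global scaling cancels. A module score is the arithmetic
mean of its genes' normalized values — hence bounded by the constituent
extremes. IFN-1 is the mean of HERC5, IFI27, IFIT1 and RSAD2, classified
high when the score exceeds −0.5; the constant equals mean + 2 SD of a
healthy reference panel, and `derive_ifn_cutoff()` reproduces that
construction from any healthy score vector.

The commercial panel's full 51-gene membership is not public. The bundled
module map (`default_module_defs()`) is a *synthetic stand-in*: the four
IFN-1 genes are exact, the ten module names and the 51-gene total are
exact, the remaining memberships are plausible placeholders. Analyses that
depend only on module structure (scoring, testing, clustering) are
unaffected; gene-level claims would not be.

Group tests are two-sided Mann-Whitney U: exact via the null distribution
when the combined sample is ≤ 30 without ties, otherwise the tie-corrected
normal approximation with continuity correction. The exact path is verified
against exhaustive enumeration of labelings in the test suite. BH
correction is applied within the module family.

**Clustering and branch enrichment.** Subjects are clustered with Ward's
minimum-variance criterion (`hclust(method = "ward.D2")`, i.e. the
Lance-Williams update family) on Euclidean distances — Aitchison distances
for compositions. "Branch level k" is operationalized as removing the top
k − 1 merges and keeping the two largest resulting clusters. The
enrichment test is the one-sided hypergeometric tail for the labelled
count in the more-enriched branch. The source does not name its branch
test and its printed branch p-values are not reproducible from the printed
counts under any standard 2×2 test; the hypergeometric is this package's
documented choice, not a reproduction.

## 4. Compositional statistics

Counts of mutually exclusive types under a declared denominator are closed
to proportions summing to 1. Zeros get multiplicative replacement with
δ = 0.5 pseudo-counts (`δ / denominator`), then re-closure; δ is
configurable. Requested types are checked structurally against the gating
tree (no type may be an ancestor of another; every pair must diverge at
exclusive siblings) and, when masks are supplied, at the cell level — this
is why overlapping subsets like DN2 or cTfh are excluded from composition
tests and handled by the per-type models instead.

The association test is a CODAK-style kernel distance covariance: Gaussian
kernel on Aitchison distances with the median-heuristic bandwidth, delta
kernel on labels, biased HSIC statistic `tr(KHLH)/n²`, permutation p-value
`(1 + #{perm ≥ obs})/(B + 1)`. The reference method's exact kernel and
bandwidth are defined outside the source text, so these choices are
declared substitutes and recorded in the result object. Ties at floating-
point resolution count as ≥, which keeps the degenerate all-identical case
at p = 1.

Per-type follow-up is a binomial logistic GLMM
(`cbind(k, n−k) ~ group + (1 | subject)`, `lme4::glmer`) with Wald p-values
and BH across types. With one observation per subject the random-intercept
variance is estimated at the boundary and the fit reduces to ordinary
logistic regression (verified to 1e-3 against `glm` in the suite).
Separation and convergence problems are flagged in the result, not fatal.

## 5. Longitudinal models and clinical rules

Within-group repeated-measures correlation follows the rmcorr
construction: `lm(y ~ subject + x)`, with r the signed square root of the
post-subject variance fraction explained by x. With exactly one visit per
subject the subject intercepts are dropped and the measure is ordinary
Pearson correlation (oracle-checked). Differential correlation fits
`y ~ x * group + (1 | subject)` by ML; the differential p tests the
interaction. Both a likelihood-ratio test and a Wald z test are
implemented; the LRT is the default on calibration evidence. On null
cohorts with 3 visits per subject the measured type-I level at α = 0.05
was 0.077 ± 0.007 (Wald, 16 subjects; 0.067 ± 0.006 at the study-sized
24 subjects / 7 LN) versus 0.062 ± 0.008 (LRT) — both asymptotic and
liberal at these sizes, the Wald markedly more so. Random structure is
an intercept only, the smallest structure consistent with "linear mixed
model"; slopes are out of scope.

LLDAS and renal-response classifiers are pure functions over visit rows.
Missing inputs yield indeterminate (NA / "indeterminate"), never false.
The renal "sediment" parameter is summarized as the worse of WBC/hpf and
RBC/hpf — the source defines no scalar, so this is a documented choice —
and renal-function improvement counts a ≥ 50% eGFR rise or normalization
(> 90) from an abnormal baseline.

## 6. The signature learner

A multiple-instance convolutional learner over bags of cells: per cell and
filter, response `relu(w·x + b)`; per filter, the pooled response is the
mean of the top `⌈k% · bag⌉` cell responses (k from
{0.1, 1, 5, 20, 100}%); the output layer is a weighted sum plus softmax.
Filters and output weights initialize from U[−0.05, 0.05]; training is
mini-batch Adam on categorical cross-entropy with early stopping on
validation loss; hyperparameters (3–10 filters, k, learning rate, dropout
on the pooled layer) are random-searched; each candidate is evaluated by
5-fold CV with folds split at the *source-sample* level so cells from one
sample never straddle train and validation. The single trained
(candidate, fold) model with the lowest validation loss is returned — the
most literal reading of "the model with the lowest validation loss"; the
alternative (refit the best configuration on all data) was considered and
not taken, to keep the selected weights exactly those that achieved the
selected loss. Relu is used at the convolution layer (the source is silent;
relu matches the CellCnn lineage and keeps scores nonnegative).

Per-cell scores are the response of the disease-associated filter(s) —
those whose output weights favour the positive class — computed on whole
samples, independent of bag membership; the default aggregates by max over
positive filters. Cell selection thresholds at the 85th percentile of
scores pooled across samples (strictly above; per-sample thresholds are an
option since the source phrasing is ambiguous). Selected cells are
characterized by per-marker two-sample KS distances against the whole
population and mapped onto gated populations by |Sc ∩ gate| / |Sc|.

A property worth knowing: when *two* well-separated populations are
spiked, top-k pooling can reach near-zero loss from the dominant one alone
and never learn the second (observed in development: the plasmablast-like
spike recovered with AUROC 1.0, the DN2-like spike ignored). Rare-cell
discovery with this architecture finds *a* discriminative subset, not
necessarily *all* of them.

## 7. The synthetic cohort: what it emulates, what it does not

Each population is a Gaussian on the arcsinh scale per marker
(inverse-transformed via `sinh(·)·5`, clipped at 0), with mixing weights
per group. Defaults mirror the study design: 30 HC (cross-sectional), 24
SLE with 3 visits (7 LN), paired T0/T6 samples, batches with anchor
aliquots of a fixed pseudo-subject plus a small per-batch marker offset
(sd 0.05). Spiked plasmablast-like and DN2-like populations total 5% of
cells in LN and 0.5% in no-LN subjects (baseline 0.4% when spiking is
off); all-zero effects make HC and SLE draws identical by construction.
Subject- and visit-level mixing weights vary around group weights via a
Dirichlet with concentration 200 (≈ ±1.5 pp for a 5% population). Cytokine
channels of monocytes shift by 1.5 arcsinh units at T6 in SLE subjects.
Expression heights are log2-normal with housekeeping at log2 ≈ 12 and the
IFN-1 genes 2.5 log2 units below — so healthy IFN-1 scores centre at −2.5
with the −0.5 cutoff two healthy SDs above, and SLE IFN genes shift by
2^`ifn_shift` (default 2). SLEDAI and C3 are linear in each visit's
realized spiked-cell percentage with LN-specific slopes (defaults 0.5 vs
0; C3 at −5× those), subject random intercepts (sd 1) and noise (sd 0.3);
SLEDAI is kept continuous so that the zero-noise world is an exact line —
round it if an integer score is needed. `cells_per_sample = 1000` and
4 batches are desk-scale defaults, not printed values.

Not emulated: spillover/isotope interference, doublets, batch drift beyond
a constant offset, marker correlations within populations (populations are
axis-aligned Gaussians), realistic visit-schedule irregularity, and any
cohort-specific median or p-value that would require the real patient
data. A green test therefore establishes that the pipeline recovers the
stated generative structure at the stated sizes — not that it reproduces
the study's clinical numbers. Bnd2-like and aNAV-like cells are nearly
absent from the default world (no dedicated generative population), so
those gates are exercised structurally, not statistically.

## 8. Determinism and numerical conventions

One integer seed determines everything; child seeds are derived
arithmetically (kept below 2³¹) and applied via `withr::with_seed`, so no
global RNG state leaks. Quantiles are linear-interpolation type 7
throughout (anchor thresholds, selection percentiles, box summaries).
Median of an even count is the midpoint. BH families follow the figure
groupings (modules; cytokines × population; composition types; marker ×
population), never pooled across families. Permutation p-values carry the
+1 correction and are bounded below by 1/(B+1).
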