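---
title: "Methods: autoantibody repertoire analysis for protein microarray serology"
author: "SeroRepertoire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autoantibody repertoire analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SeroRepertoire)
```

# Scope and data model

SeroRepertoire analyses serum IgG screens on planar protein microarrays of
the ProtoArray type: thousands of purified proteins printed on a slide,
probed with patient and control sera, and scanned to per-spot fluorescence
intensities. The pipeline takes GenePix-style scan tables and produces an
autoantigen repertoire per patient, together with association,
longitudinal and enrichment statistics over that repertoire.

Probe-level data live in a `ScanSet` (layout plus foreground/background
intensity matrices); gene-level matrices are `SummarizedExperiment`
objects whose `metadata()$stage` records the processing stage, which
advances strictly `raw_log` → `normalized` → `zscore`. Stage checks in
every entry point prevent, for example, z-scoring a raw matrix.

# Probe summarization

Per spot the background is subtracted from the foreground; the net value
is floored at 1 a.u. before `log2` so that negative nets (possible when
local background exceeds signal) map to 0 rather than to an undefined
logarithm, and floored spots are flagged in the `floored` assay.
Replicate spots of a gene are combined by the mean of log2 values (median
available). Control probes are summarized per class — series (hIgG or V5)
× concentration level — because the normalization model treats each class
as one probe with constant expected signal across arrays.

# Robust control-probe normalization

Raw intensities are not comparable across arrays: printing, labeling and
scanning shift whole arrays on the log scale. Control-probe series printed
at fixed concentrations are assumed to have constant positive signal on
every array, so on the control classes we fit the two-way additive model

$$ y_{ij} = b_i + a_j + \varepsilon_{ij}, \qquad \textstyle\sum_j a_j = 0 $$

with class effects $b_i$, per-array effects $a_j$, by iteratively
reweighted least squares under a robust loss. Defaults: Huber loss with
tuning constant $1.345\,\hat\sigma$ (95% Gaussian efficiency),
$\hat\sigma$ re-estimated each iteration as the MAD of residuals about
zero, convergence when the largest parameter change falls below $10^{-8}$
log2 units, at most 50 iterations; Tukey's bisquare ($4.685\,\hat\sigma$)
is available as a redescending alternative, with weights floored at
$10^{-8}$ so the weighted design never loses rank. The zero-sum
constraint, rather than a reference array, keeps the parameterization
symmetric across cohorts. Normalization subtracts $\hat a_j$ from every
probe of array $j$; control rows are retained for diagnostics. When all
residuals fall inside the Huber threshold the fit coincides with ordinary
least squares, and refitting on normalized controls returns effects of
essentially zero (idempotence); both properties are under test.

# Print-contamination filtering

Two artifact filters run on the *normalized* matrix, before z-scoring (on
raw values, shared array effects would inflate every correlation):

* **Template correlation** — any gene whose profile across all samples has
  Pearson $r > 0.6$ with a user-supplied known autoantigen is flagged,
  with the rule applied to the signed correlation (anti-correlated
  profiles are biology, not carryover).
* **Neighbor correlation** — for gene pairs printed in adjacent wells of
  one block (queen 8-neighborhood by default, since print pins deposit to
  diagonal wells too; rook available), a correlation above 0.6 flags the
  member with the smaller *robust amplitude*, defined as the mean of the
  three largest deviations from the gene's median. A raw max or range is
  decided by single outlier spots and then misflags the true antigen about
  half the time under heavy-tailed noise; averaging the top three
  deviations makes the comparison reflect the reactivity amplitude, which
  for a carryover copy is the carryover coefficient times the source's.

Flagged genes are removed from all downstream matrices but preserved in a
`ContaminationReport`; report plus retained matrix always partition the
input gene set, and the flag set is invariant to gene ordering.

# Z-scores and autoantigen calling

Normalized signals are standardized per gene against the healthy cohort —
unrelated controls plus healthy relatives: $z_{ij} = (x_{ij} - m_i)/s_i$
with $m_i, s_i$ the control mean and sample SD ($n-1$ denominator; the
within-cohort SD of a finite sample, matching the worked example of two
SD units for a value of 4 against controls 1, 2, 3). Genes constant across
controls have no defined scale and are dropped with a warning.

A call is $z > 3$, strictly (a z of exactly 3 is negative). One serum per
patient represents that patient — the sample with the maximal number of
positive hits, ties resolved towards the later sampling age — and a gene
is an *autoantigen* when at least 3 distinct patients' representative
samples call it. Counting patients rather than samples prevents a single
patient's longitudinal replicates from promoting a private reactivity.
Calling is monotone in the threshold by construction.

# Association statistics

* **Moderated t** per clinical manifestation, implemented from the
  empirical-Bayes closed forms: per-gene two-group residual variance
  $s^2_g$ with $d_g = n-2$ df is shrunk to
  $\tilde s^2_g = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, with $(d_0,
  s_0^2)$ from moment matching on $\log s^2_g$ via Newton inversion of the
  trigamma function; $t = \Delta/(\tilde s_g\sqrt{1/n_1+1/n_2})$ on
  $d_0 + d_g$ df. The implementation is in-package (the adjustment
  universe must be configurable — e.g. the 900 most reactive proteins
  versus the whole platform — via `testSet`); the limma fit serves as an
  independent cross-check in the test suite, and the $d_0 = 0$ / $d_0 =
  \infty$ limits are verified against ordinary- and pooled-t oracles.
  Degenerate inputs (all $s^2_g = 0$) fall back to complete pooling with a
  warning.
* **Benjamini–Hochberg** adjustment over whichever gene universe was
  tested, significance at adjusted $p < 0.05$.
* **Per-sample dispersion**: SD over all probes per sample, patients vs
  controls compared by Wilcoxon rank-sum (the published contrast reports a
  p-value without naming the test; the rank-sum is the conventional choice
  for such a two-cohort spread comparison and is the package's default,
  two-sided).
* **PCA** over the top-k (default 50) most commonly positive reactivities,
  centered, no scaling; explained-variance ratios sum to at most 1.
* **Hierarchical clustering** of patients × top-k reactivities (default:
  Euclidean distance, complete linkage — the defaults of the heatmap tools
  conventional in this field; correlation distance and average linkage are
  options), deterministic given its inputs.
* **Manifestation regression**: ordinary least squares of the number of
  manifestations on $\log_2(\text{hits}+1)$, with Pearson r; a constant
  response is reported as slope 0, r 0, flagged degenerate.
* **Mutation-group comparison**: Nemenyi (Tukey–Kramer on ranks) pairwise
  test on log2 hit counts — joint midranks, statistic
  $q = (\bar R_i - \bar R_j)\big/\sqrt{\tfrac{N(N+1)}{12}(\tfrac1{n_i} +
  \tfrac1{n_j})}$, p from the studentized range with $k$ groups and
  infinite df under the $q\sqrt2$ convention. Midranks make the test
  invariant to monotone transforms (doubling all observations changes
  nothing); groups with fewer than 2 patients are excluded with a warning.

# Longitudinal dynamics

All samples of multi-sample patients (no representative collapsing) form
all within-patient ordered pairs. Each pair's positive calls split into
early-specific, shared, and late-specific, with proportions over their
total; pairs aggregate per gap category as the unweighted mean of per-pair
proportions (each pair is one observation of repertoire turnover,
regardless of its repertoire size). The gap boundary is 10 years, with a
gap of exactly 10.0 assigned to the long category. The trend summary
compares each patient's first and last samples and classifies strictly:
only a net gain counts as increased, equality falls in
decreased-or-unchanged.

# Enrichment

* **Categorical terms**: upper-tail hypergeometric $P(X \ge k)$ for
  $X \sim HG(N, K, n)$ with the platform content as universe (the
  standard over-representation convention; the strict tail would exclude
  the observed table), BH across all terms tested together. The
  implementation delegates the tail probability to `phyper`; the test
  suite checks it against exhaustive enumeration of all draws for every
  $N \le 12$.
* **Continuous properties** (SNP densities normalized by gene-span and
  exon lengths; per-taxon evolutionary rates): the observed query mean is
  compared with `R = 10000` same-size groups drawn *without* replacement
  from the platform universe, $p = (\#\{\text{as or more extreme}\} +
  1)/(R+1)$ — ties count as extreme, the minimal attainable p is
  $1/(R+1)$, and the statistic is super-uniform under its own null.
  Direction defaults to `less` for SNP density and evolutionary rate (the
  hypotheses are depletion and conservation); both the raw-count and the
  density statistic are available since either may be the comparison of
  interest.
* **External list overlap** after TR/NTR partitioning and ortholog
  mapping: one-to-many mappings keep a target gene if any query ortholog
  reaches it, duplicates collapse before counting, and the universe is the
  mappable platform content.

# The synthetic experiment generator

`simConfig()`/`simulateExperiment()` generate complete, ground-truth
labelled inputs: scans, metadata, annotations, DE lists. The log2 net
signal of gene $i$ on array $j$ is

$$ y_{ij} = \mu_i + a_j + \delta\sigma_{\mathrm{mix}}
   \mathbf{1}[\text{reactive}] + \text{carryover} + \varepsilon_{ij} $$

with gene baselines $\mu_i \sim N(8, 1)$ log2 a.u., zero-sum array
effects of SD 0.5 log2, and contaminated-normal noise
$\varepsilon \sim (1-f)N(0,\sigma^2) + fN(0,(k\sigma)^2)$ with
$\sigma = 0.35$ log2, $f = 0.05$, $k = 5$ — heavy tails chosen to
exercise the robust normalization. Reactivity effects are expressed in
control-SD units, where the control cohort's SD is the full mixture SD
$\sigma_{\mathrm{mix}} = \sigma\sqrt{1-f+fk^2} \approx 1.48\sigma$ (that
is what z-scoring divides by), so a planted $\delta = 6$ lands near
$z = 6$. Control classes follow a concentration ladder (base 6 log2, step
0.4 per level, V5 offset 0.2) that is exactly constant across arrays
before array effects. Contaminated wells receive the carryover
coefficient times the source's signal deviation plus their own noise, and
are placed in the well adjacent to a shared antigen. The cohort default
mirrors a realistic screen: 50 patients, 12 unrelated controls, 8 healthy
relatives, 1000 genes, 2 control series × 10 levels; shared antigens have
per-patient prevalence 0.1–0.6 (or exactly `sharedPatientsEach` carriers
when a fixed reactivity count is wanted), private reactivities arrive at
Poisson rate 5 per patient scaled per mutation group (1.6/1.4/0.6), and
manifestations are drawn per patient with probability
$\mathrm{logit}^{-1}(-3 + 0.6\log_2(\text{hits}+1))$ — the positive
hits–manifestations coupling is a generative assumption of this
simulator, not an estimate. Longitudinal patients receive a second sample
whose repertoire grows by Poisson(rate × gap) acquisitions and never
loses reactivities; gaps are drawn half short (1–8 y) and half long
(12–30 y).

What the generator does *not* emulate: spatial intensity gradients and
scratches (outliers are iid per cell, not spatially clustered), batch/lot
structure, isotype differences, titer saturation, or antigens with
correlated biological co-occurrence beyond shared prevalence. Passing
recovery tests on this generator therefore demonstrates that each stage
inverts the generative structure it assumes — not that real arrays
satisfy those assumptions.

# Numerical and design notes

* Floors and ties: intensity floor 1 a.u. before log2; representative-
  sample ties break towards later age, then lexicographic sample id;
  neighbor-flag tie-break by robust amplitude as above.
* `fitControlModel` treats an exact fit (robust scale below machine
  tolerance) as converged; non-convergence returns the fit with
  `converged = FALSE` and a warning rather than an error.
* Empirical p-values always carry the +1 correction; `R < 100` warns.
* All clustering and PCA outputs are deterministic given input order;
  the only seeded stage is the resampling null, and `runPipeline()`
  threads one seed through it so a rerun reproduces every result file
  byte for byte (the manifest differs only in its timestamp).
* Problem sizes used by the test suite and the verification script —
  e.g. 30 arrays × 20 control classes for effect recovery (squared errors
  pooled over 5 replicates to keep the Monte-Carlo error of the RMSE
  estimate well below the tolerance), 24 × 5 planted reactivities over
  524 genes for calling recovery, 1000 genes for the null calibration,
  and R = 500–10000 for resampling — were chosen so each check has
  adequate statistical resolution while the whole suite stays fast.

# Known limitations

The z > 3 in ≥ 3 patients rule is not noise-free under heavy-tailed
intensity noise: with 5% of cells drawn at 5σ while the control-cohort SD
is only ≈1.48σ, roughly 1% of null gene×patient cells exceed z = 3, and
with 30–50 patients a few null genes per ~500 cross the 3-patient bar.
On the default generator this yields calling precision of ≈0.8–0.9 (at
perfect recall of well-shared antigens) and an occasional spurious
neighbor-correlation flag from coincident outliers (~2–3 per 500 clean
genes at 40 samples). These are properties of the published decision rule
under realistic noise, not implementation artifacts; the corresponding
recovery tests assert the stricter idealized bounds and the two that
exceed them are documented failures, with per-cell rates derivable in
closed form. Practitioners wanting higher precision should raise the
z threshold or the patient minimum, at a recall cost.

The moderated-t calibration assumes approximate normality of log
intensities; heavy-tailed cells inflate its type-I error slightly, which
is why the calibration check runs on Gaussian nulls. Finally, the Nemenyi
implementation uses the infinite-df studentized range approximation
(appropriate for the rank statistic), not a permutation null; a
permutation oracle backs it in the tests.
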