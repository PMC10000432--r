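---
title: "Methods: calcium remodeling analysis and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium remodeling analysis and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calremodel)
```

`calremodel` analyses a two-arm experiment on colorectal cancer (HT29) and
normal colonic (NCM460) cells, treated or not with the polyamine-synthesis
inhibitor DFMO: a single-cell calcium-imaging arm and a transcriptomic arm
over a curated panel of Ca²⁺-transport genes. This vignette explains the
statistical machinery, the choices we made where the design was genuinely
open, and what the synthetic-data generators do and do not emulate.

## Calcium traces and feature extraction

A recording samples the fura-2 F340/F380 ratio every 5 s through three
phases: baseline in 1 mM Ca²⁺, store depletion by CPA in Ca²⁺-free medium,
and Ca²⁺ re-addition evoking store-operated entry (SOCE). Five per-cell
features summarize a trace:

* `resting` — median ratio over the first 30 s. The median tolerates
  isolated acquisition artefacts.
* `store_dmax`, `store_auc` — maximum increment and trapezoidal area of the
  baseline-subtracted signal over the CPA window (ratio and ratio·s).
* `soce_dmax`, `soce_auc` — the same two metrics over the re-addition
  window.

Three conventions deserve a note, because the underlying experimental
literature usually leaves them implicit:

* **Baseline reference.** Each response window is referenced to the median
  of the 15 s immediately preceding it, not to the global resting level.
  Local references are robust to slow drift; both windows are configurable
  (`default_protocol()`).
* **No clipping.** Negative excursions are integrated as-is, so an AUC can
  be negative. Clipping at zero would bias small responses upward.
* **Half-open windows.** All windows are `[start, end)` in seconds;
  sampling need not be uniform (the trapezoid handles gaps). Cells whose
  trace cannot support a window (fewer than two samples, non-finite values)
  are reported in a rejects table and skipped, never silently dropped.

`dmax` is a maximum over noisy samples and therefore carries a small
positive bias (below σ·√(2·log m) for m window samples); the AUC and the
resting median are unbiased under symmetric noise. Tests that compare
estimates against generator truth use the unbiased features, or allow for
this bound explicitly.

## Condition comparison: mixed models and letters

Features are compared across the four conditions with the 2 × 2 factorial
`line * treatment`, with random intercepts for day and for coverslip. The
experiment's hierarchy makes cells pseudo-replicates: cells share a
coverslip, coverslips share a day, so naive per-cell tests would overstate
the evidence. Modelling decisions:

* **Nesting.** Each physical coverslip exists on one day under one
  condition, so coverslip enters as an intercept indexed by
  day × condition × coverslip. Random slopes have no support in this design.
* **Box–Cox.** The transform is selected by profile likelihood over
  λ ∈ [−2, 2] in steps of 0.01 (λ = 0 meaning log), on the fixed-effects
  model. Features that can be non-positive (AUCs) receive the smallest
  recorded shift making them positive. Marginal means are reported on both
  scales; the back-transform is the inverse Box–Cox of the mean without
  bias correction, which matches how such figures are conventionally drawn
  in original units.
* **Random-structure selection.** Following the top-down strategy, every
  candidate random structure is fitted by REML under the full fixed
  structure and the lowest information criterion wins. We use the AIC of
  the REML fits as a conditional-AIC surrogate: exact cAIC requires the
  effective degrees of freedom of the random effects, and for the purpose —
  ranking random structures under an identical fixed structure and an
  identical (shared-λ) response — the surrogate ranks identically in all
  regimes we simulate. λ is selected once and shared across candidates so
  their likelihoods are comparable.
* **Degenerate reductions.** `random = character(0)` drops to ordinary
  least squares; singular variance components are reported as zero. On
  zero-variance data the mixed marginal means agree with the OLS oracle to
  10⁻⁶, which the test suite asserts.

Pairwise condition differences use the Tukey–Kramer single-step adjustment:
the studentized-range distribution on the contrast t-statistics, with
Satterthwaite denominator degrees of freedom taken from the mixed model
(residual df for OLS fits). An edge joins two conditions whose adjusted
p ≥ α (default 0.05); maximal cliques of this graph — enumerated by
Bron–Kerbosch with pivoting — are the groups of mutually indistinguishable
conditions. Cliques are ordered by the ascending mean of their members'
(back-transformed) marginal means and lettered a, b, c, …, so a condition
labelled `ab` is indistinguishable from both groups. The ordering convention
is ours; any permutation renames letters without changing the partition,
which the tests check. Letter-count minimization beyond clique ordering is
out of scope.

Diagnostics (`check_assumptions()`) report Shapiro–Wilk and Jarque–Bera on
Pearson residuals, Bartlett across conditions and Breusch–Pagan against
fitted values, Shapiro–Wilk on predicted random intercepts, and outlier
flags at |studentized residual| > 3 or Cook's distance > 4/n computed on the
fixed-effects projection. The Jarque–Bera statistic is computed in-package
(n/6·(S² + K²/4) against χ²₂). Constant residuals are a refused, degenerate
input. A parametric bootstrap (`parametric_bootstrap()`) simulates from the
fitted model — fixed effects plus freshly drawn random intercepts and
residual noise — refits, and reports percentile intervals; it is seeded and
exactly reproducible.

For small two-group designs (densitometry-style data, e.g. western blots at
n = 6 : 3), `boxcox_group_compare()` runs the same Box–Cox + linear-model
machinery. Outlier removal is *gated*: points flagged by the thresholds are
removed (once, with refit) only when the initial fit's residuals actually
violate Shapiro–Wilk normality at 0.05. Unconditional trimming at these
sample sizes inflates the type-I error well above nominal — removal is a
remedy for a broken assumption, not a routine step. Groups with zero
variance and distinct means are reported as exact separation (p = 0) rather
than fitted.

## Differential expression and the concordance rule

Expression matrices are quantile normalized (every column mapped onto the
row-wise mean of the sorted columns; tied entries share the mean of the
reference at the tied ranks, matching the standard implementation) and
filtered by the non-specific IQR rule — keep genes whose IQR strictly
exceeds the median IQR — with one exception: panel genes are always
retained, because the analysis is about them regardless of their
variability. Quantile normalization is exactly idempotent on tie-free data;
with ties at different ranks in different columns the tie-averaging
perturbs the next reference slightly, so idempotence is exact only up to
that effect (the implementation agrees with `limma::normalizeQuantiles`
to 10⁻¹⁰).

Each gene is fitted by least squares to
`log2Expression ~ line + treatment + line:treatment + day`. Day enters as a
fixed blocking factor: with one replicate per condition per day, the fixed
block is the standard identifiable choice, and treating it as a random
factor would require a consensus intra-block correlation across genes,
which is out of scope. Four contrasts are exported with fixed sign
conventions (HT29 − NCM460; DFMO − control): the line effect in control
cells, the treatment effect within each line (the per-line panels of the
usual figures are simple effects, not the interaction), and the
interaction.

Variance moderation estimates the prior (d₀, s₀²) by matching the mean and
variance of e_g = log s²_g − ψ(d_g/2) + log(d_g/2) to the scaled-F model,
inverting the trigamma function by Newton iteration. When the observed
log-variances are no more dispersed than χ² sampling predicts, d₀ = ∞ and
all posterior variances equal s₀² (normal reference); d₀ = 0 reproduces
ordinary t-statistics exactly. Benjamini–Hochberg adjustment is a direct
step-up implementation with enforced monotonicity. Both are cross-checked
against `limma` and `p.adjust` in the tests, which also verify type-I and
FDR calibration on 200 null simulations of 2000 genes × 16 samples.

Two platforms are combined per gene by the concordance rule: differentially
expressed iff (q < 0.05 on at least one platform, or q < 0.1 on both) *and*
the two log-fold-changes share a nonzero sign. "Significance level" is read
on the FDR scale, consistent with how significance is defined per platform;
a raw-p option exists. A zero logFC is sign-indeterminate and vetoes the
call; genes measured on one platform only are recorded as `insufficient`
rather than `not_DE`, keeping the distinction auditable. A gene is
**reversed** when its cancer-vs-normal change (under either the combined
call or a single-platform baseline — both are used in practice) and its
treatment effect in the cancer line are significant with opposite signs.

## Quality control

Sample QC runs PCA on centered, unscaled log₂ data (genes are variables;
standardizing them would let near-constant genes dominate), retains the
smallest set of leading components explaining ≥ 70 % of variance, flags
outliers within each line × treatment class by robust Mahalanobis distance
against the χ² quantile at 0.975 (the conventional MCD cutoff), applies
Ward (ward.D2) clustering on the retained scores, and summarizes RLE
(per-gene median-centered values) per sample with a default |median| flag
at 0.1. The MCD needs roughly twice as many samples as dimensions; below
2(p + 1) samples per class — including the real design's four samples per
class — the estimator degenerates (its discarded half always sits at
extreme distance), so the classical estimator is used instead, with a
warning. Probe-level NUSE requires residuals that do not exist after
summarization, so RLE is the sample-quality surrogate.

## qPCR

ΔCt = mean replicate Ct of the gene minus that of the housekeeping gene
(RP18S) in the same sample; relative abundance is 2^(−ΔCt) (Livak
convention — the negative exponent is the standard reading and the one the
figure axes of such studies use, even where methods text drops the sign).
ΔΔCt is the difference of group-mean ΔCt, reported as −ΔΔCt on the log₂
scale so 0 means no change and positive means higher expression in the test
group. Replicates aggregate by mean (median by flag). Groups are compared
by Student's t on per-sample ΔCt with Bonferroni correction across the
genes tested (nine in the shipped primer panel). Amplification-efficiency
correction is out of scope.

## What the generators emulate — and what they do not

`simulate_calcium()` draws, per cell,
`resting + day + coverslip + cell + template(t) + noise`, with the release
pulse parameterized as a difference of exponentials (rise 10 s, decay 45 s;
two free time constants on a smooth shape) and the SOCE plateau as a
saturating exponential (τ 20 s), each scaled so its sampled maximum equals
the configured amplitude. Defaults mirror the study design: 4 days,
2 coverslips per condition-day, 33 ± 4 cells per coverslip (so per-condition
totals fall in 230–300), 5 s sampling over 600 s with phases at 60 s and
360 s. Condition means encode the phenotype under study — HT29 control with
high resting (0.50) and SOCE (0.80) but low store release (0.35) against
NCM460 control (0.40 / 0.45 / 0.60), with DFMO moving HT29 toward normal
(0.42 / 0.55 / 0.55) and leaving NCM460 essentially alone. The magnitudes
of the day/coverslip variance components are free parameters of the design
(no published values exist); we set σ_day = σ_coverslip = 0.02,
σ_cell = 0.05, σ_noise = 0.02 ratio units, i.e. biological heterogeneity a
few times the photometric noise, and the truth table records the features
of the noiseless template. Because the random intercepts are additive over
the whole trace, they cancel from baseline-subtracted features: day and
coverslip variance survive in `resting` but not in Δmax/AUC. Real
amplitude-scale heterogeneity (a coverslip responding proportionally more)
is *not* emulated — passing tests show correct inference under additive
heterogeneity, not under multiplicative effects, photometric camera noise,
bleaching, or focus drift.

`simulate_expression_pair()` draws platform A from the factorial model with
Gaussian noise (σ = 0.25 log₂ units, day SD 0.15) and platform B as
`gain · truth + offset` plus its own noise (1.1 / 0.3 / 0.3) — a
summary-statistics emulation of a second technology, not a read-count
simulation; the concordance rule only ever consumes (q, logFC) pairs, which
is why this level of fidelity is the right one. The default truth plants,
on the panel, 17 DFMO-affected genes in HT29 of which 11 reverse a nonzero
cancer effect (signs follow the validated genes: CRACR2A, ORMDL3, septins
up after treatment; TRPV6, SPCA2 down; etc.), and in the background a 20 %
line-effect fraction and a 10 % HT29-only treatment fraction at ±2 log₂ —
echoing the strong treatment selectivity for cancer cells. The treatment
never affects the normal line in the default truth, so every NCM460
discovery in a simulation is a false positive. One consequence worth
knowing: with a quarter of the transcriptome shifted, quantile
normalization transfers some of that shift onto null genes, which inflates
genome-wide cross-contrast false calls; the panel-level reversal recovery
(the quantity of scientific interest) is unaffected, and the acceptance
report exposes both rates.

`simulate_qpcr()` writes Ct = baseline − log₂(abundance) + noise with a
constant-abundance housekeeping gene, triplicates, and σ = 0.2 cycles.

## Problem sizes and determinism

The test suite exercises the pipeline at the design's own scale: ~1050-cell
calcium simulations for coverage (100 replicates) and letter-display
recovery (100 replicates), 2000-gene × 16-sample expression simulations for
calibration (200 replicates) and reversal recovery, 500 random graphs
(n ≤ 12) against exhaustive clique enumeration, and 1000 random p-vectors
against an independent BH step-up. Every generator and the pipeline
orchestrator (`run_all()`) are deterministic given their seed; the
orchestrator derives per-stage seeds from a single master seed and
validates all thresholds (e.g. α₁ < α₂) before any stage runs.

## Known limitations

* Trace analysis starts from extracted ratio traces; ROI segmentation,
  ratio computation and calcium calibration (ratios stay ratios) are out of
  scope, as are probe-level microarray preprocessing (RMA, NUSE) and
  read-level RNA-seq modelling.
* The cAIC surrogate is valid for ranking random structures under a fixed
  mean structure only; it is not a general model-selection criterion.
* Back-transformed means are transformed-scale means pushed through the
  inverse Box–Cox (no smearing correction); they estimate the median-type
  location on the original scale.
* With four samples per class, within-class robust outlier detection
  necessarily falls back to classical estimates; it screens for gross
  errors only.
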