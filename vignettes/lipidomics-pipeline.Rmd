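---
title: "Methods: class-resolved HILIC lipidomics from feature tables to Dunnett statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: class-resolved HILIC lipidomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidhilic)
```

This vignette is the package's own account of its methods: the models and
assumptions behind each stage, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical choices made where the design was
genuinely open.

## The identification model

HILIC chromatography separates phospholipids by headgroup, not by acyl
chains, so all species of one class co-elute in a narrow window while MS1
m/z resolves the species within a class. Identification is therefore a
two-step gate, in this order:

1. **class by retention time** — a peak inside exactly one configured
   class window is assigned that class; outside all windows it is left
   unassigned (and is only matched against the full database when the
   class gate is explicitly disabled);
2. **species by m/z** — the peak is compared against the in silico
   database restricted to its class and the active ionization mode; the
   candidate with the smallest absolute ppm error wins.

The database enumerates species as (class, total acyl carbons c, total
double bonds d). Elemental formulas are affine in (c, d) per class — for
example PC is C~c+8~H~2c−2d+16~NO~8~P — and masses are monoisotopic sums
with C = 12 exactly. Two consequences are used as internal accuracy
checks: a CH~2~ ladder (adding one carbon pair adds 28.031300 Da) and a
double-bond ladder (each double bond removes H~2~, 2.015650 Da), both of
which hold to ~1e-7 Da across the full grid (limited only by floating
arithmetic).

Sphingomyelin is enumerated at the same (c, d) resolution, summing the
sphingoid base and the N-acyl chain (d18:1;16:0 becomes SM 34:1): MS1
m/z cannot resolve the backbone split, so a finer parameterisation would
claim information the measurement does not carry.

**Adduct policy.** The mobile phase is a formate/formic-acid buffer, so
negative mode forms [M+HCOO]⁻ for the zwitterionic classes PC and SM and
[M−H]⁻ for PE/PG/PI/PS; positive mode forms [M+H]⁺ for all phospholipids.
Cholesterol is a fixed species (C27H46O) detected as [M+H−H₂O]⁺ at
m/z 369.35 — at unit-decimal precision, the 369.3 precursor monitored in
SRM assays. The acquisition literature for this design does not state
which adducts its database used; this policy is the package's documented
assumption and is configurable.

**Enumeration range.** Defaults are even total carbons 24–44 and 0–8
double bonds inside the m/z 450–950 scan window. Mammalian diacyl lipids
have predominantly even totals; odd totals (real but rarer) are enabled
by `include_odd_carbons`. The pipeline default enables them because the
default species inventory contains odd-carbon PE (see below).

**Tolerances.** 5 ppm is the high-resolution default (Orbitrap-class
acquisition at resolution 120,000); 0.3 Da is the recommended setting
for ion-trap data. Both are arguments, never hard-coded.

**Ambiguity.** If two or more database entries fall within tolerance the
annotation is flagged and, by default, excluded from the abundance table:
reported species lists contain only uniquely named species, and
keep-nearest is an explicit opt-in.

## C13 de-isotoping

A species with n carbons carries natural ¹³C, producing satellites at
+1.003355 and +2.006710 Th whose intensity ratios to the monoisotopic
peak follow the binomial model B(n, p, k)/B(n, p, 0) with p = 0.0107
(≈ 0.45 and ≈ 0.10 at n = 42). Scanning peaks in ascending m/z, a peak
is merged into a lighter parent when the spacing matches within `mz_tol`
(default 0.005 Th), the retention times agree within `rt_tol` (default
10 s — satellites co-elute), and the mean intensity ratio lies within a
multiplicative band (default [0.5, 2]) of the binomial expectation. The
band is deliberately wide because measured intensities are noisy; the
carbon count is estimated as round(0.055 × m/z) — a linear fit adequate
over this mass range — unless a database hint pins it exactly. Merging
*adds* satellite intensity to the parent by default, conserving total
signal row-for-row; `drop` mode exists for parity with tools that discard
satellites. Only k ≤ 2 is considered: M+3 is below noise at ≤ 50
carbons. Chains (a satellite of a satellite) resolve to the lowest-m/z
retained parent because satellites are never themselves eligible parents.

## The synthetic-data generator

No raw LC-MS data are deposited for this study design, so the generator
is the package's primary test substrate. It is first-class, seeded code,
not a stored fixture.

* **Design**: 2 time points (12, 24 h) × 3 doses (0, 12.5, 25 μM) × 4
  replicates — 24 samples.
* **Inventory**: 306 species — 72 PC, 129 PE, 15 PG, 27 PI, 34 PS,
  29 SM. The per-class counts follow the reported inventory arithmetic
  of the profiled lipidome; 129 PE exceeds the 99-species even-carbon
  grid, so 30 odd-carbon PE species are included.
* **Effect template**: species with d = 0 or c = 32 decrease; species
  with d ∈ {1, 4} or c ∈ {36, 38} increase (the "down" rule wins when
  both apply). The maximum effect is |log2FC| = 1 at 25 μM and 24 h,
  scaled linearly by dose and attenuated ×0.6 at 12 h. The magnitude is
  a package choice: a two-fold change at the strongest condition is a
  realistic scale for treatment-induced membrane remodelling and gives
  the statistics something detectable but not trivial at n = 4.
* **Intensities**: per-species log-normal baselines (sdlog 1, arbitrary
  units) times 2^log2FC times log-normal replicate noise with CV 0.2 —
  standard LC-MS biological-plus-technical error; the unit-mean
  parameterisation keeps expected intensities equal to baseline × 2^FC.
* **Mass error**: the acquisition-level 5 ppm accuracy specification is
  treated as a 3σ bound, i.e. Gaussian calibration error with σ = 5/3
  ppm, drawn once per species and shared by its isotopologues (peaks
  read off one calibrated spectrum shift together). An optional
  independent per-peak centroiding error (`ppm_sd_indep`, default 0)
  perturbs the isotope spacing and is used to probe de-isotoping
  tolerance behaviour.
* **Retention**: classes elute in the order PG, PE, PI, PS, PC, SM at
  centres 50…550 s over a 0–600 s gradient with ±45 s windows and 5 s
  Gaussian jitter. Real gradients are instrument-specific; only the
  class-clustered structure matters downstream.
* **Noise peaks**: uniform in (m/z, rt) at 20% of signal-row density,
  with intensities drawn from the lowest decile of signal — enough to
  stress the annotator without overwhelming it.

What the generator does **not** emulate: chromatographic peak shapes,
profile spectra, cross-run retention drift, ion suppression, adduct
competition, in-source fragmentation, or missingness beyond a simple
low-intensity dropout flag (default off). Passing tests on synthetic
data therefore demonstrate the correctness of the computations under the
stated error model, not robustness to every artefact of real instrument
data.

The packaged `synthetic_reference_abundance()` table is different in
kind: a fixed, internally seeded percent-abundance table over the same
306-species inventory, constructed so that 90 species are near-constant
(CV ≈ 0.02) and 216 variable (CV ≈ 0.3). It stands in for the study's
species/abundance spreadsheet, which is not programmatically available,
and it is what the shipped variance-filter default is calibrated on.

## Statistics

**Percent normalization.** Figures of this kind plot "percentage of
abundance" without defining the basis; both bases are implemented and
reported explicitly — percent of total identified lipid signal (default,
whole-lipidome summaries) and percent of class (per-class species
panels). Percentages are compositional: a raw increase in one species
necessarily depresses the percentages of all others, which is why ground
truth for effect-direction checks is defined on the percent scale.

**Variance filter.** The filtering rule behind the reported 306 → 216
species reduction is not stated anywhere, only its outcome. The package
uses CV on percent abundance with a shipped threshold of 0.10, which
retains exactly 216 of the 306 reference species; the threshold is a
documented calibration, not a universal constant, and both metric
(CV/variance) and threshold are arguments.

**PCA.** Samples are observations, species are variables, centred and
unit-variance scaled by default, via `prcomp`. Components are sign-fixed
so each component's largest-magnitude loading is positive — PCA is
sign-indeterminate and a deterministic convention makes scores
reproducible. Rank-deficient inputs return fewer components with a
warning.

**Two-way ANOVA + Dunnett.** Each species is fit with fixed effects
dose × time (both categorical, with interaction; error df = 18 at the
default design). Within each time point, each non-zero dose is compared
against control using the pooled residual error — a Dunnett many-to-one
family of k = 2 comparisons per time point, matching the per-panel
significance marks of this figure style. The family-per-time-point
definition is a package choice (the alternative, one family across both
times, is stricter; the per-panel reading is the natural one). The
adjusted p-value is P(max_j |T_j| ≥ |t|) under the equicorrelated
k-variate t with ρ = 0.5 (balanced designs sharing a control mean),
computed by seeded Monte Carlo (200,000 draws by default, one shared
sorted sample per (k, df) so thousands of species cost one draw), with a
nested-quadrature integration backend as a cross-check. Adjusted
p-values are clamped from below by the raw two-sided t p-value — the
inequality is exact analytically, the clamp only absorbs Monte-Carlo
noise — and are monotone in |t|. Degenerate species (zero residual
variance) report p = 1 when the contrast is also zero, p = 0 under
perfect separation. Stars: 0.05 / 0.01 / 0.001, with `#` marking a
p < 0.1 trend.

**Fatty-acyl aggregation** sums per-sample percentages over species
sharing a double-bond count or carbon total, then reports mean ± SD per
(time, dose) cell; per-sample bin totals are exactly 100 for either
grouping, which is asserted as an invariant.

## Auxiliary quantitation

Cholesterol is quantified against an external calibration line fit by
ordinary least squares; the slope is the response factor. The intercept
is estimated rather than forced through origin (the "response factor"
wording is ambiguous on this; forcing is a flag). Inversion floors
negative estimates at zero with a flag.

qPCR relative expression uses the Rotor-Gene comparative model,
expression = amplification^(mean calibrator takeoff − takeoff), taking
per-sample amplification from the input records — raw fluorescence
curves are not refit. Housekeeping normalization follows geNorm: the
stability of gene j is the mean SD across samples of its pairwise log2
ratios to the other reference genes, and the per-sample normalization
factor is the geometric mean of the housekeeping expressions. With only
two housekeeping genes (GAPDH and YWHAZ here) the stepwise-exclusion
ranking of full geNorm is skipped: two genes admit no ranking.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed; there is no hidden RNG
state (`withr::local_seed` restores the caller's RNG). The test suite
and the acceptance script use the full 306-species inventory with 24
samples for pipeline checks, a 1,000–2,000-species null simulation for
the familywise-error calibration of the Dunnett procedure, and a 10⁶-draw
brute-force Monte Carlo as the independent oracle for the adjustment
itself — sizes chosen so each check has adequate statistical resolution
(e.g. the null familywise SE is ≈ 0.005 at 2,000 families) while the
whole suite runs in minutes on one core.

## Known limitations

* Isomers are not resolved: annotations are at the (class, c, d) level;
  sn-positions, double-bond positions, and ether/plasmalogen or lyso
  species are out of scope (a config hook exists for extending the
  enumeration templates).
* MS2 evidence is not used; annotation rests entirely on retention class
  and MS1 mass.
* Retention-time alignment across batches is not implemented; a
  single-batch design is assumed.
* At ion-trap tolerances (0.3 Da), the M+2 satellite of a species and
  the monoisotopic peak of its one-fewer-double-bond neighbour are only
  ~0.009 Th apart; the binomial ratio band is then the only guard, and
  high-resolution data are strongly preferred.
* The variance-filter threshold is calibrated on the packaged synthetic
  reference; on other data it is a starting point, not a rule.
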