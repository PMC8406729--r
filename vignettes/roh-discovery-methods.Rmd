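---
title: "Discovering unique ROH genotypes with unfavorable effects: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering unique ROH genotypes with unfavorable effects: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical machinery inside `rohclass`: the
discovery procedure and its assumptions, the tunable parameters and why
their defaults are what they are, what the synthetic-data generator does
and does not emulate, and the numerical and design decisions taken where
more than one reasonable choice existed.

## The discovery procedure

A *unique ROH genotype* is the exact homozygote allele string that a group
of animals shares across a window of consecutive SNPs.  Distinct strings
over the same window are distinct classes, because different homozygous
haplotypes may carry different recessive load.  The procedure has three
steps.

**Step 1 — windowed classing and screening.**  Starting from a window of
`initial_window` SNPs (default 60) at the beginning of each chromosome,
the window slides by `slide_step` (default 1) SNP at a time.  An animal is
a carrier in a window when the window lies inside one of its homozygous
runs: at least `min_run` (default 15) consecutive homozygous calls with no
heterozygote — and, in this implementation, no missing call — inside.
Carriers are grouped by their homozygote string; groups whose carrier
frequency strictly exceeds `min_class_frequency` (default 0.0075) are ROH
classes, everything else is the non-ROH class.  A class is stored when the
raw phenotype mean of its carriers lies strictly on the unfavorable side
of an empirically calibrated cut-off (below).  Windows at adjacent starts
whose class partitions — the assignment of animals to classes — are
identical are aggregated into one record spanning their union.  The window
is then shrunk by `window_decrement` (default 5) SNPs and the scan
repeats, down to `min_window` (default 50) SNPs, a length chosen to
capture recent inbreeding, which is the more detrimental kind.

**Step 2 — the animal mixed model.**  Each candidate window's classes are
fitted as a fixed class effect (reference level: non-ROH) in

$$ y = Xb + Za + \textstyle\sum_{j=1}^{4} W c_j + e, $$

with $a \sim N(0, A\sigma^2_a)$ the additive animal effect ($A$ the
pedigree numerator relationship matrix), four i.i.d. non-genetic random
factors $c_j \sim N(0, I\sigma^2_j)$ (herd-year, herd-region-year-season,
service-sire and technician in the dairy application; generic
user-declared factors here), and $e \sim N(0, I\sigma^2_e)$.  Centered
allele-count covariates for every SNP inside the window correct for the
additive effects of the SNPs, so the class contrast isolates the
non-additive (dominance/recessive-load) deviation of the diploid
homozygote class — the partial-dominance signal that drives inbreeding
depression.  Variance components are treated as known and held fixed
across windows, reflecting the null hypothesis of no ROH effect; they
normally come from a routine evaluation, and `estimate_variance_components()`
provides an in-package EM-REML to produce them once per trait.  The
contrast of each class against non-ROH is tested one-tailed in the
trait's unfavorable direction (lower is unfavorable for milk, fat and
protein yield and the non-return rate; higher for number of services,
age at first service, and first-service-to-conception).

**Step 3 — redundancy removal and FDR.**  Candidates whose SNP interval is
contained in another candidate with identical per-class carrier sets are
discarded (ties on identical intervals keep the larger-window record).
Per trait, the family of all one-tailed p-values from fitted, screened
classes is controlled genome-wise at `fdr_q` (default 0.01) with the
Benjamini–Hochberg step-up rule.

**The empirical cut-off.**  `threshold_samples` (default 1000) windows are
sampled uniformly over (chromosome, valid start) at the initial window
size; each is classed and fitted exactly as in step 2.  The cut-off is the
mean raw carrier mean of the classes whose one-tailed p-value falls in
`threshold_sig_range` (default 0.05–0.10): phenotype levels typical of
*marginally* unfavorable classes.  If fewer than 20 classes land in the
band it widens symmetrically in 0.01 steps (logged); if classes exist but
the band never fills — e.g. a constant phenotype makes every p-value
identical — the mean over all sampled class means is used, which reduces
to the constant itself in the degenerate case.  The minimum of 20 and the
widening rule are this package's choices; the published procedure does not
specify the sparse-band case.

## Parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `initial_window` | 60 | SNPs | published default window |
| `window_decrement` | 5 | SNPs | published reduction step |
| `min_window` | 50 | SNPs | captures recent inbreeding |
| `slide_step` | 1 | SNPs | exhaustive scan |
| `min_run` | 15 | SNPs | minimum stored homozygous run; inert at default window sizes (50 > 15) but kept as a knob |
| `min_class_frequency` | 0.0075 | fraction | published class-frequency floor (strict) |
| `fdr_q` | 0.01 | fraction | genome-wise FDR level |
| `threshold_samples` | 1000 | windows | cut-off calibration draws |
| `threshold_sig_range` | (0.05, 0.10) | p | marginal-significance band |

QC thresholds (call rate 0.95, MAF 0.01, heterozygosity deviation 0.15)
follow the published wording with strict inequalities, so boundary SNPs
are removed; the heterozygosity deviation is taken as an absolute value,
the published text not stating a sign.

## What the simulator emulates — and what it does not

`simulate_roh_dataset()` builds the desk-scale study on which the package
validates itself: an overlapping-generation pedigree (default 120
founders, 8 generations of ~240 animals each, ~2,000 animals total) in
which only ~5% of available males sire offspring, mimicking intense
AI-driven selection; this yields mean pedigree inbreeding around 5–7% in
the last generation and makes shared homozygous diplotypes (ROH classes)
common, as they are in real dairy data.  Genotypes arise by gene dropping:
founder haplotypes are drawn in linkage equilibrium with minor allele
frequencies uniform on (0.05, 0.5); gametes recombine as a Poisson process
at 1 cM/Mb (Haldane, no interference) over 5 chromosomes × 600 SNPs at
50 kb spacing — about a 20-fold size reduction from a 43K-SNP array.  ROH
therefore emerge *only* through identity by descent, the mechanism the
discovery procedure targets.  Gene dropping was chosen over coalescent
simulation because recent, pedigree-driven autozygosity — not ancient
haplotype sharing — is the phenomenon of interest.

Phenotypes come from the same mixed model the analysis fits: additive
values by the Mendelian-sampling recursion (founders $N(0,\sigma^2_a)$,
offspring mid-parent plus a deviation with variance
$\sigma^2_a(0.5 - 0.25(F_s+F_d))$), one categorical fixed factor with
random level means, four i.i.d. random factors, and a Gaussian residual.
The default variance budget for each trait divides the squared observed
trait SD into 30% additive (h² = 0.3), 10% fixed-factor spread, 5% for
each of the four random factors, and 40% residual — a realistic split for
yield traits where herd-management explains a large share of variance.
Trait scales reproduce the observed descriptives (e.g. milk yield mean
9074, SD 1732.2 kg).  The binary non-return rate is emitted by
thresholding a latent Gaussian at its 0.69 incidence and the number of
services by rounding a latent Gaussian capped to 1..10, because the
analysis treats these traits with the same linear model as continuous
ones.

**Planted truth.**  `plant_roh_effects()` records ground-truth unfavorable
classes.  In force mode it *copies an existing homozygote string* — one
with at most two pre-existing homozygous animals — onto randomly chosen
animals until the target carrier fraction (default 3%) is reached, and the
planted carrier sets of different windows are drawn disjointly.  Two
design constraints drive this:

* the planted string must be a *real haplotype*.  A synthesized random
  string is biologically impossible and is identified almost perfectly by
  the within-window additive SNP covariates, which inflates the contrast
  standard error several-fold — something no naturally arising class
  exhibits;
* the realized carriers must be *essentially random animals*.  Planting
  onto a common existing class recruits a related family whose
  co-inherited flanking segments carry the planted effect into other
  windows, so the rest of the genome is no longer effect-free and
  false-discovery accounting against the planted intervals becomes
  meaningless.

What the simulator does **not** emulate: linkage disequilibrium among
founder haplotypes, genotyping-array ascertainment, missing genotype
patterns of real arrays (simulated genotypes are complete; the scan's
missing-call handling is exercised by constructed fixtures), selection on
phenotype during the simulation, and non-Gaussian residuals.  Passing
tests therefore demonstrate the pipeline's internal correctness and its
statistical calibration under the stated generative model, not performance
on any particular real population.

## Numerical choices

* **A-inverse** is assembled directly by Henderson's rules with the
  inbreeding adjustment, F coming from the Meuwissen–Luo recursion
  (compiled); the test suite inverts it against the tabular-method A to
  1e-8.
* **Window fits** solve Henderson's mixed-model equations by absorbing
  the random-effect block: one sparse Cholesky factorization of
  $U'U + \sigma^2_e G^{*-1}$ per trait, after which every window fit is a
  small dense solve over the fixed-effect block (base factors, class
  indicators, window SNP covariates).  This is algebraically exact — the
  suite checks equality with dense GLS on $V$ to 1e-8 — and makes the
  1000-window cut-off calibration affordable.
* **Rank handling**: fixed-effect columns are admitted in the order base
  factors, class indicators, SNP covariates, through an ordered
  rank-revealing Cholesky with relative pivot tolerance 1e-8.  Collinear
  SNP covariates are therefore dropped before any class indicator, because
  the class contrast is the estimand; a class indicator that is itself
  confounded is skipped with a message, never silently repaired.
* **Degrees of freedom** for the one-tailed t-test are N records minus the
  rank of the fixed-effect block; at the sample sizes involved this is
  indistinguishable from a normal reference.
* **EM-REML** iterates the standard expectation-maximisation updates on
  the mixed-model equations, declaring convergence when the largest
  absolute component change per round falls below `tol` (default 1e-6)
  *relative to the total variance* — a criterion that does not stall when
  a component decays to the zero boundary, where EM is known to slow
  geometrically.  Components are clamped at 1e-12 and flagged;
  non-convergence within `max_iter` is an error carrying the iteration
  trace.  The implementation inverts the coefficient matrix densely each
  round and is intended for producing components once per trait at
  moderate size, not for routine per-window use.
* **Classing at scale** groups carriers by a two-chunk sliding hash of
  the homozygote string (each chunk ≤ 30 bits, exact in doubles), with a
  brute-force string-grouping oracle in the tests; candidate sets from the
  optimized scan are checked for exact equality with an exhaustive
  (size, start) brute force.
* **Coordinates**: SNP windows are half-open 0-based index intervals;
  genomic spans are reported as 1-based bp of the first/last SNP and Mb to
  two decimals.  Gene annotation intersects intervals under the half-open
  rule, so a gene merely abutting an interval end is not reported.
* **Allele coding**: PLINK text input is recoded per SNP with the
  lexicographically later observed allele as the alternate.  The scan is
  invariant to this convention because classing works on homozygote
  strings, not allele polarity.

## Design decisions on ambiguous points

* Missing calls break a homozygous run, like heterozygotes: the published
  rule forbids heterozygotes inside a run and says nothing about missing
  calls, and upstream imputation makes them rare; breaking is the
  conservative reading.
* "Windows with the same set of animals carrying the same set of unique
  ROH genotypes except for the first and last SNP were aggregated" is
  implemented as merging *adjacent-start windows with identical class
  partitions*; the strings may differ at the shifted boundary SNPs, the
  partition may not.
* Aggregation operates within one window size; redundancy across sizes is
  handled only by the nested-window discard, which requires identical
  carrier sets and interval containment.
* All SNPs inside the window are fitted as additive covariates (the
  superset reading of "the SNPs present in the unfavorable ROH
  genotypes").
* The FDR family is all tested classes per trait genome-wise; cross-trait
  pleiotropy grouping happens after per-trait FDR, and requires
  overlapping intervals on the same chromosome plus carrier sets
  re-derived from the genotypes that match exactly.
* The cut-off averages *carrier* means of band classes (not all phenotypes
  of qualifying windows), and is calibrated at the initial window size
  only.
* All qualifying classes of a window are fitted as separate fixed levels
  even when only some passed the screen, so the non-ROH reference is a
  genuine non-ROH group; only screened classes enter the FDR family.
* Age at first service is treated as higher-unfavorable by default, like
  the other interval fertility traits.

## Known limitations and calibration behavior

The raw-mean screen of step 1 selects which classes are tested in step 2
on a statistic correlated with the test itself, so the realized
false-discovery rate of the full procedure can exceed the nominal BH
level; validation on simulations with planted truth shows the genome-wise
false-discovery proportion near, and occasionally above, the nominal 1%,
dominated by rare replicates in which one long IBD-family haplotype
produces many overlapping near-duplicate records (real-data scans show the
same near-duplicate structure among reported discoveries).  The
acceptance script quantifies exactly this.  Other limitations: no
gap-tolerant ROH definition (a single heterozygote splits a run), no
genomic relationship matrices, single-trait models only, and a linear
model for the binary and count fertility traits.

## Problem sizes used in the validation suite

The test suite runs the full pipeline on 25 replicate simulations of the
reference desk-scale study (~1,900 animals, 3,000 SNPs, three planted
classes) for the false-discovery and power checks, and the acceptance
script on 50; brute-force scan equality is checked on ~300 animals × 600
SNPs over window sizes 60/55/50; A-inverse is validated on twenty
300-animal pedigrees; EM-REML recovery runs at a few hundred animals.
These sizes are the package's validation choices, selected so the whole
suite exercises every claim at meaningful scale.
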