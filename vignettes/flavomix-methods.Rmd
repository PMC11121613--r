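---
title: "Models and methods behind flavomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flavomix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavomix)
```

`flavomix` implements the computational arc of a UV-B / abscisic-acid
(ABA) stress study on a three-treatment, three-replicate plant design:
PAM fluorescence statistics, the JIP-test on fast fluorescence induction
transients, OPLS-DA-based differential-metabolite screening,
differential-gene screening, pathway over-representation, and correlation
networks. This vignette explains each model, its assumptions, the
tunable parameters, and the design decisions taken where the underlying
methodology is conventionally left unstated.

## The synthetic-data generator

Every stage is exercised against simulated data with planted ground
truth, generated by pure functions of a master seed (per-stream child
seeds are derived deterministically, so stages can be re-run in
isolation).

### OJIP transients

A measured OJIP transient rises from the minimal fluorescence F_O to the
maximal F_P through the named inflections K (300 µs), J (2 ms) and I
(~30 ms). The generator models the noise-free curve as a sum of three
saturating-exponential rises standing in for the O–J, J–I and I–P phases:

F(t) = F_O + (F_M − F_O) · Σ_i w_i (1 − e^(−t/τ_i)),

with weights `phase_weights` (default 0.5 / 0.3 / 0.2, summing to 1) and
strictly increasing time constants `phase_timescales` (default 0.5 ms,
8 ms, 80 ms — placing the half-rises in the J and I regions of a
plant-fluorometer trace). Two treatment effects can be planted:

* `j_step_shift` multiplies the O–J weight (weights are renormalized, so
  the P level is preserved); values > 1 raise the J step and make the
  treatment-minus-control ΔJ statistic positive, the signature of
  acceptor-side electron-transport blockage.
* `k_band_amp` adds a Gaussian-in-log-time bump centred at 300 µs
  (σ = 0.15 decades), the K-band signature of donor-side (OEC) damage; it
  makes ΔK positive. At 2 ms the bump has decayed by e^(−15), so it does
  not contaminate the J-step.

This is deliberately the *minimal* shape that carries every landmark the
JIP-test reads; it makes no claim about photosystem biophysics beyond
landmark fidelity. Sampling is logarithmic — 120 points from 10 µs to
1 s, the span of a 1-second saturating-pulse measurement — because
induction fluorometers sample log-densely and all landmark reads are
interpolations linear in log10(t). The two grid points nearest 300 µs
and 2 ms are snapped onto those exact times so that landmark extraction
on generator output carries no interpolation error. Noise is
multiplicative lognormal (`noise_sd`, default 0.02), keeping fluorescence
positive.

### PAM records

`simulate_pam()` draws per-replicate Fv/Fm, Y(II) and Fo values around
per-treatment targets (defaults: a strong Fv/Fm drop under UV-B partly
restored by ABA, a milder Y(II) response, essentially unchanged Fo) and
back-solves the raw record, Fm = Fo / (1 − Fv/Fm) and
F = Fm′ (1 − Y(II)), so the derived parameters reproduce the targets in
expectation.

### Omics matrices and planted truth

Both omics layers share one generative scheme: per-feature log-normal
baselines (metabolite intensities around e^13 a.u.; FPKM around e^3),
multiplied per group by 2^(planted log2FC), with multiplicative lognormal
replicate noise of coefficient of variation `cv`. The default `cv = 0.1`
describes tight biological replicates of a widely-targeted LC-MS assay
and is also the condition under which the parameter-recovery tests run.
Planted effects are declared per comparison ("MvsN" means the fold
change of N over M) and chain through the design order, so a feature
planted in both comparisons has its Q mean scaled by the product of both
effects. A configurable number of features is shared between the first
comparison's up set and the second's down set — the pattern of
metabolites that rise under stress and fall back under a mitigating
treatment. Planted metabolite effects are spread randomly across the
flavonoid subclasses (41% flavones, 29% flavonols, 9% flavanones by
default, remainder over six smaller classes).

The default transcriptome plants |log2FC| = 3 rather than 2. The reason
is statistical, not biological: the per-gene Welch t-test at n = 3 has a
p-value floor of roughly 10^−4 (df ≈ 4), and Benjamini–Hochberg
correction across ~48,000 genes with only ~150 true positives demands
p-values at or below that floor. Planting 4-fold changes in the
transcriptome produces a screen that can never reject — a property of
small-sample genome-wide testing, not an implementation defect — so the
generator plants 8-fold changes, well within the range of strong
stress-response genes. Even so, recall of a small planted set (~150
genes) remains partial at these sample sizes; the metabolite screen, with
only 2,148 features and the VIP×FC rule, does not suffer from this.

### Annotations

`simulate_annotations()` assigns transcription-factor family labels
(default sizes led by MYB 154, AP2-EREBP 93, mTERF 89, bHLH 82, C3H 75)
and KEGG-style pathway memberships, including ko00941 (flavonoid
biosynthesis) and ko00944 (flavone and flavonol biosynthesis). Caller-
supplied `prefer_ids` (typically the planted differential features) are
placed into the two flavonoid pathways without reuse across pathways, so
downstream enrichment has a known, disjoint signal.

## PAM statistics

Fv/Fm = (Fm − Fo)/Fm and Y(II) = (Fm′ − F)/Fm′ are scale-invariant
ratios; both are computed with domain checks (Fm > 0, Fo ≤ Fm, F ≤ Fm′).
Group summaries run one-way ANOVA followed by Tukey's HSD at α = 0.05
and convert the significant pairs into a compact-letter display by
insert-and-absorb, with letters assigned alphabetically in the order
groups appear. The choice of Tukey HSD is a convention: the
letter-display contract (significant pairs share no letter,
non-significant pairs share at least one) is what the tests verify. When
the residual variance is exactly zero (identical replicates), no pair is
called significant and all groups share "a".

## The JIP-test

F_O is taken as the minimum over the whole trace — the literal reading
of "minimum fluorescence" — rather than the first sample, which protects
against a noisy first point. F_K and F_J are read at exactly 300 µs and
2 ms by log-linear interpolation; F_P is the trace maximum. V_t
normalizes between O and P (V_t(O) = 0, V_t(P) = 1); W_t normalizes
between O and J (W_t(2 ms) = 1). W_t is the standard O–J double
normalization — the choice matters because the treatment-minus-control
difference ΔW_t read at 300 µs is the K-band statistic. Both
normalizations are invariant under affine rescaling of the raw
fluorescence, which is the point of normalizing: instrument gain and
offset drop out.

Group difference curves average the *per-replicate normalized* curves
and then subtract (replicate-first ordering, the conservative choice —
normalizing a mean raw curve would let bright replicates dominate).
Mismatched time grids are aligned by log-linear interpolation onto the
control grid. ΔJ is the ΔV_t value at 2 ms, ΔK the ΔW_t value at
300 µs; both are read off the difference curve by the same
interpolation. Difference curves are antisymmetric under swapping
treatment and control, and identically zero for a group against itself.

V_t is bounded in [0, 1] only for the noise-free ideal transient; with
noise, excursions outside the band are left untouched (never clipped) so
that averaging remains unbiased.

## OPLS-DA, Q² and VIP

The discriminant model is fitted from scratch by NIPALS. Raw intensities
are log2-transformed and column-mean centered (no unit-variance or
Pareto scaling by default — centering-only after log2 is the literal
convention for widely-targeted metabolomics; both alternatives are
available via `scaling`). The two classes are coded −1/+1 and centered.
Each orthogonal component is found by the orthogonal-signal-correction
step — project the X-loading of the current predictive direction off the
predictive weight, score, deflate — and the single predictive component
is then a one-component PLS1 fit on the filtered matrix. With
`n_ortho = 0` the model is *exactly* one-component PLS1, which is how
the implementation is cross-checked against an independent iterative
NIPALS oracle. Predictive scores are oriented so the second class level
has positive mean score.

Reported diagnostics: R²Y (in-sample fit of the class variable),
per-component explained X-variation, and the cross-validated
Q² = 1 − PRESS/TSS over held-out class predictions. Cross-validation is
stratified by class with 7 folds by default; with n = 3 per class
(6 samples) the fold count exceeds the sample count and the procedure
falls back to leave-one-out, with a message. Preprocessing, the
orthogonal filter and the predictive component are all re-estimated
inside each training fold — anything less would leak the held-out
samples into the filter. A model is "valid" iff Q² strictly exceeds 0.5.

VIP is computed over the predictive component only:
VIP_j = sqrt(p)·|w_j| with the unit-norm predictive weight vector, so
ΣVIP² = p and the mean squared VIP is 1. (With a single predictive
component the SSY weighting of the general VIP formula cancels.)
Features that are constant after centering are dropped with a warning
and receive no VIP; the screening layer treats them as unselectable.

## Screening rules

* **Differential flavonoids (DFs):** selected iff VIP > 1 (strict) and
  the linear-scale fold change of group means satisfies FC ≥ 1.5 or
  FC ≤ 0.67 (inclusive, exactly as conventionally printed). FC is
  computed on raw intensities, not logs.
* **Differential genes (DEGs):** per-gene two-sided Welch t-test on
  log2(FPKM + 1), BH adjustment, q < 0.05, plus a fold-change rule. The
  conventional statement "FC > 1" is ambiguous (read literally it admits
  any up-regulation); the default rule here is |log2FC| ≥ 1 with
  direction by the sign, and `fc_rule = "literal"` restores the literal
  reading. Genes with zero variance in both groups, or a zero
  denominator mean, are skipped with a warning.

Both screens are monotone in their thresholds (raising VIP, FC or
lowering q never adds hits), directions satisfy "up iff FC > 1", and
class tallies conserve the hit count — these conservation laws are what
`ledger_check()` verifies on every pipeline report (up + down = total,
Venn counts bounded by set sizes, tallies summing to hit counts).

## Enrichment

Pathway over-representation is the upper-tail hypergeometric test
P(X ≥ k) with k hits among n selected, K pathway members, N background
features, BH-adjusted across pathways. The background is all detected
features of the relevant omics layer — the natural universe when the
selection was made from that same matrix. Only over-representation is
tested (flavonoid-pathway enrichment is a one-sided question), and the
implementation is verified against exhaustive enumeration of all
C(N, n) draws for small universes.

## Correlation networks

All cross pairs between two profile matrices (sharing the same nine
ordered samples by default — correlations pool all three groups) are
tested with Pearson r and the exact t transform
t = r·sqrt((n−2)/(1−r²)), df = n − 2. An edge is kept iff r² ≥ 0.8 and
p < 0.05; with n = 9 the r² threshold (|r| ≥ 0.894) is the binding
constraint. Edges carry signs (positive iff r > 0); no multiple-testing
correction is applied across edges, matching the stated raw-p
convention. Edge sets are symmetric in the argument order, and
thresholding is monotone. TF–enzyme "chords" are the same computation
with nodes labelled by TF family and enzyme symbol; individual TF genes
(not family aggregates) enter the correlation.

In the orchestrated pipeline the DF–DEG network is restricted to hits
mapped to the two flavonoid pathways — the targeted-integration reading —
which keeps the edge list interpretable; the full cross-product is
available by calling `correlation_network()` directly.

## Pipeline problem sizes and determinism

`run_config()` defaults encode the emulated study: 3 × 3 design, 2,148
metabolites (487 flavonoids), 47,598 genes, planted DF splits 83/30
(MvsN) and 18/30 (NvsQ) with 17 shared, planted DEG splits 1288/627 and
18/130 with 10 shared, UV-B OJIP effects (J-step ×1.4, K-band 400 a.u.)
partly reversed under ABA (×1.2, 150 a.u.). A full `run_all()` takes a
few seconds on one core. The orchestration tests use a reduced
configuration (400 metabolites, 2,000 genes) because they exercise
structure, not power. All outputs are byte-identical given the same
configuration and seed.

## What passing tests do and do not show

The generator produces lognormal, independent features with exchangeable
replicates and exactly multiplicative group effects. Real widely-
targeted metabolomes and de novo transcriptomes violate all of this:
feature correlations, heteroscedastic low-intensity noise, missing
values, batch structure, and count-based error for low-expression genes.
Passing the recovery tests therefore shows that the *statistical
machinery* is implemented correctly and calibrated under its own
assumptions — not that real data of this design would yield comparable
recall. Two known limitations follow directly: the Welch-based DEG
screen is underpowered for small planted sets at n = 3 (see the
generator section), and OPLS-DA Q² values obtained on strongly planted
synthetic separations are higher than typical field data would give.
Landmark-faithful OJIP simulation likewise says nothing about chloroplast
biophysics between the landmarks; only the landmark reads and curve
normalizations are load-bearing.
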