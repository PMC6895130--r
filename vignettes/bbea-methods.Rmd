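---
title: "Methods: from bead fluorescence to epitope statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from bead fluorescence to epitope statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbea)
```

This vignette explains what the package computes and why each choice was
made: the quantification model and its assumptions, the batch-correction and
reliability machinery, the parameters that matter, what the simulator does
and does not emulate, and the numerical corner cases.

## Quantification

A bead-array plate reader reports, per well and bead region, the median
fluorescence intensity (MFI) over the beads it counted. Two facts shape the
quantification:

* raw MFI is strongly right-skewed and heteroscedastic, so all modeling is
  done on the log2 scale: `Y = log2(MFI + 0.5)`. The 0.5 shift keeps zero
  MFI finite (`Y = -1`) and is configurable, but there is rarely a reason to
  change it;
* the secondary antibody binds beads and peptides to some degree on its
  own. Each plate therefore carries buffer-only (NSB) wells, and the
  per-epitope background is the **mean of the log-transformed** NSB signals
  of that plate — not the log of the mean MFI. The two differ by Jensen's
  inequality; the package follows the definition on the log scale because
  the background model, like everything downstream, is additive in `Y`.

Binding scores floor the background-corrected signal at zero:
`B = max(0, Y - baseline)`. A negative difference means "no evidence of
binding above background", and propagating negative background noise into
downstream statistics would manufacture spurious variance at blank
epitopes. Floored cells are flagged (`$floored`) so QC can distinguish a
true zero from a subtracted value. Flooring happens **once**, at
quantification: model residuals and batch-adjusted values may legitimately
be negative and are never re-floored, otherwise adjustment would distort
within-plate contrasts.

Bead-count QC runs **before** the baseline is computed: wells whose count
averaged across epitopes is strictly below 30 are excluded (30.0 is kept),
and an NSB well that fails QC never contributes to the baseline. The
threshold reflects the common observation that fewer than ~25-30 beads per
region makes the median unstable; a stricter per-epitope minimum-count mode
is available (`min_per_epitope`). Where all of a sample's wells fail, the
sample is listed as excluded.

`distribution_diagnostics()` reports sample skewness and excess kurtosis
with bootstrap replicates (default 100), the ingredients of a
skewness-vs-kurtosis plot: raw MFI sits far from the normal point, binding
scores land near the normal/log-normal region, which is what justifies the
parametric modeling that follows. Constant input has undefined shape and is
reported as NA with a warning rather than a number.

## Plate (batch) effects

Each microplate run is a batch: technician, temperature, incubation timing
all shift an entire plate additively on the log scale. Per epitope the
package fits `Y ~ 1 + plate + <experimental terms>` by least squares, or
with a subject random intercept (REML via lme4) when samples repeat across
visits — a random intercept induces exactly the compound-symmetric
correlation a repeated-measures design calls for. Model fitting is per
epitope, with no information sharing: strongly bound epitopes show larger
plate shifts than blank ones, so a shared batch coefficient would be wrong.

The reference plate is the first in sorted order; coefficients are shifts
relative to it. Adjustment subtracts **only** the plate coefficients
(`Y* = Y - Z gamma_hat`): experimental-factor estimates stay in the data
because removing fitted biology would bias every downstream contrast
toward zero. Consequences worth knowing: reference-plate rows are returned
unchanged, within-plate differences are invariant, and adjusting twice is
a no-op (the refitted coefficients are numerically zero).

Estimability requires that plate is not confounded with any experimental
term. This is checked by a rank test on the combined design matrix and
reported as an error naming the aliased columns — if all cases sit on one
plate and all controls on another, no model can say how much is batch and
how much is biology; the fix is experimental (randomize samples to
plates), not statistical. The simulator's `allocation = "confounded"` mode
exists to exercise exactly this path.

### Well position

Reading order (A1..A12, then B1.., down to H12) leaves later rows
incubating longer, and edge wells evaporate faster, so the package includes
a positional diagnostic: a 95-coefficient well model (reference A1) fitted
jointly with sample and plate effects, returned in reading order with 95%
CIs. It requires a design whose replicates were randomized across wells of
at least two plates — with one observation per well, position is
indistinguishable from residual noise, and the function says so. Well
coefficients are a diagnostic only and are never subtracted: adjusting for
96 positions estimated from small designs would add more variance than it
removes, and a well-run assay shows no systematic position effect (the
null-calibration test asserts ~5% of CIs exclude zero when the truth is
zero).

### PVCA

Principal variance component analysis answers "what fraction of overall
variance does each factor explain": (1) center epitopes and
eigen-decompose the between-unit **correlation** matrix (correlation, not
covariance, so high-dynamic-range epitopes do not dominate; a flag
switches); (2) retain the smallest leading PC set reaching a cumulative
eigenvalue share of 0.8 (the conventional threshold, configurable);
(3) regress each retained PC on random intercepts for every factor
(pairwise interactions optional, off by default — with the typical factor
counts the interaction components are rarely estimable and mostly add
singular fits); (4) truncate negative variance components at zero,
normalize with the residual to proportions; (5) eigenvalue-weight across
PCs. The result (WAPV) sums to one and is invariant to factor order. A
scalar shift common to all epitopes is invisible to a correlation across
epitopes; batch effects show up in PVCA through their epitope-profile
component (e.g. per-plate baseline wiggle), which matches how batch
structure actually contaminates profiles.

## Reliability

Two-way single-measure ICCs from the ANOVA decomposition of a subjects x
raters matrix: consistency `(MSR-MSE)/(MSR+(k-1)MSE)` and agreement, which
adds `(k/n)(MSC-MSE)` to the denominator and therefore punishes a constant
shift in one replicate. Single-measure forms are the default because the
question is "how reliable is one measurement"; average-measure forms are a
flag away. CIs are the exact F interval (consistency) and the
Satterthwaite approximate-F interval (agreement), alpha fixed at 0.05.
Qualitative bands are closed on the left: 0.75 is "excellent", 0.60 is
"good", 0.40 is "fair".

Arrangements: replicate reliability treats **epitopes as subjects and
replicates as raters**, one ICC per sample — with 50-66 epitopes and 3
replicates this is the only arrangement that yields a stable per-sample
estimate. Center reproducibility uses epitopes x centers per sample (or
samples x centers per epitope) on replicate-averaged binding, and defaults
to **consistency**, because an additive center shift is a batch effect: it
is removable (`remove_plate_effects()` with center as the batch), after
which agreement is the relevant metric. A degenerate case to expect in
practice: a non-reactive control has binding pinned near the zero floor,
so its between-epitope variance is mostly noise and its ICC is low or
undefined — the package flags it rather than failing, because a poor ICC
on a blank sample is correct behavior, not an assay failure.

Clustering uses `1 - Spearman rho` (average ranks on ties) with UPGMA
linkage; technical replicates should form clades. Trees serialize to
Newick through ape.

## Detection and differential binding

With a handful of replicate pairs, per-epitope variance estimates are too
noisy for a plain t-test. The moderated test shrinks each variance toward
a prior shared across epitopes: the prior `(d0, s0^2)` is estimated by
matching the mean and variance of `log(s^2)` to their theoretical
digamma/trigamma moments under a scaled-F model — the trigamma equation is
inverted by Newton iteration to `|delta| < 1e-8` — and
`s_tilde^2 = (d0 s0^2 + df s^2)/(d0 + df)`, with `df + d0` degrees of
freedom for the p-value (capped at a large finite value when `d0` is
infinite). One prior per experiment/isotype: moderation means borrowing
strength across epitopes; a per-epitope prior would be vacuous. Setting
`d0 = 0` reproduces the classical test exactly, which the tests exploit as
an oracle bridge.

Two deliberate modes mirror two different questions:

* **detection** (paired positive-pool vs negative-control): two-sided
  p < 0.05 with **no multiplicity adjustment** — appropriate for a small
  benchmarking panel where the cost of a miss dominates; BH-adjusted
  values are reported alongside. The effect size is `mean(delta)/SD(delta)`,
  which equals the classical `t/sqrt(n)` for the paired design.
* **differential binding** (two groups of samples): moderated t per
  epitope with optional covariates, Benjamini-Hochberg FDR across
  epitopes, and a **conjunctive** gate: fold change `2^|delta| >= 1.5`
  **and** FDR < 0.05. The fold-change threshold is applied to the
  magnitude (`|delta| >= log2 1.5`); a tiny-p, small-fold epitope is not
  called.

The IgG4-IgE comparison is a difference on the log2 binding scale, never a
quotient: the field calls it a "ratio", but on log-transformed data the
difference is the meaningful contrast.

## The microarray comparator

Peptide microarrays are quantified as robust z-scores within slide:
`S = log2(spot/background)`, `Z = (S - median(S_blank))/MAD(S_blank)` with
`MAD = median(|Y - median(Y)|)` — deliberately **without** the 1.4826
normal-consistency factor, following the definition as used for this assay
(a flag enables the scaled variant). Blank spots have median Z of exactly
zero by construction, and Z is invariant to location shifts and overall
intensity scaling. Replicate spots (up to 6 per peptide) collapse by the
median; the collapse statistic is not standardized in the field, so the
mean is available by flag.

## The simulator

`simulate_study()` draws from the same additive log2 model the pipeline
assumes:

    Y = nsb_mean + reactivity_i * (mu_j + a_i + profile_ij + Delta_j g_i)
        + gamma_plate + omega_well + eps,     eps ~ N(0, noise_sd)
    MFI = round(max(0, 2^Y - 0.5))

Defaults encode a realistic study: epitope means `mu_j` spread over 3-8
log2 units (weak to strong binders over background), scalar sample effect
SD 1, sample-by-epitope profile SD 0.5 (each sample's own epitope
signature — the biologically meaningful signal), replicate noise SD 0.3,
background mean 1 (MFI ~1.5) with SD 0.2, three NSB wells per plate, bead
counts negative-binomial with mean 50 (lower the mean to exercise the
bead-QC path), integer-rounded MFI. A scaled-t noise option reproduces the
heavy-tailed raw-MFI shape. Samples are allocated to plates by blocked
randomization (each group dealt round-robin across plates); replicates sit
in adjacent wells unless `randomize_wells = TRUE`, the layout needed for
well-position diagnostics. Two modeling choices deserve justification:

* the plate shift is applied to serum wells only, not to buffer wells. If
  NSB wells carried the full batch shift, background subtraction would
  silently remove the plate effect and the batch machinery would have
  nothing to do; in practice the dominant run-to-run variation enters
  through sample handling, and background drift enters through the NSB
  wells' own noise.
* a non-reactive control is modeled by `reactivity = 0` (signal collapses
  to background), which reproduces the near-zero binding and poor
  replicate ICC expected of a negative control.

What the simulator does **not** emulate: bead aggregation and carryover,
intensity-dependent (heteroscedastic) noise, spatial edge gradients beyond
the additive per-well term, non-additive batch distortions (scale
effects), and cross-reactivity structure between epitopes. Passing tests
on simulated data therefore demonstrate that the estimators recover the
additive model they assume at realistic sizes and noise levels — not that
real plates obey that model.

## Numerical choices and degenerate inputs

* Problem sizes in the tests and acceptance script: plate-effect recovery
  uses 96 samples x 4 plates x 50 epitopes in triplicate; well diagnostics
  use the 2-plate fully randomized design (62 samples x 3 replicates = all
  186 wells); detection calibration uses 10,000 null epitopes; prior
  recovery uses 5,000 variances; ICC coverage uses 1,000 replicate
  matrices. These sizes keep every run deterministic under a seed and
  complete in seconds to minutes.
* Coverage checks for the plate model are run with iid noise on the
  unsubtracted log signal: background subtraction adds a per-plate,
  per-epitope offset (the baseline's own sampling noise) that a per-epitope
  OLS standard error cannot see, so CI calibration is asserted where the
  model's assumptions hold, and recovery/adjustment behavior is asserted
  separately under the full realistic generator.
* Seeds: every stochastic routine takes or derives from an explicit seed;
  `distribution_diagnostics()` and the simulator save and restore the
  caller's RNG state.
* Zero variances entering the shrinkage estimator are offset by a small
  positive constant with a warning; fewer than two distinct variances give
  `d0 = Inf` (complete pooling). Constant ratings matrices give an
  undefined ICC with an explanation, not a number. Constant rows are
  dropped from Spearman clustering with a warning. A zero MAD among blank
  spots is an error with guidance, since no standardization is possible.
* Ties in Spearman correlations use average ranks; ICC band boundaries
  fall into the higher band; BH adjustment preserves ties and restores
  input order.
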