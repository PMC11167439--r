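---
title: "Models and methods behind synergyscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind synergyscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergyscope)
```

synergyscope quantifies synergy between two stimuli at three layers:
transcript counts (an expected-additivity score with outlier calling),
pharmacology (four-parameter logistic fits and a Poisson interaction GLM
for inhibitor pairs), and chromatin accessibility (synergy-specific
accessible elements). This vignette explains each model, its assumptions,
the tunable parameters, the synthetic-data generators that back the test
suite, and the numerical choices that were genuinely open.

## The expected-additivity score

For a gene with log2 fold changes `fA`, `fB`, `fAB` of the two single
stimuli and their combination, all against the unstimulated reference, the
score is `D = fAB − (fA + fB)`. On the count scale, `D = 0` means the
combination multiplies the two single-stimulus effects — the natural null
for independently acting signals on a log-linear readout. `D` is invariant
to a global rescaling of all counts (a sequencing-depth change), because
each fold change is a ratio; note that rescaling *only the reference
samples* is not an invariance (it shifts each fold change and hence `D`),
which is why contrasts must share one consistently normalized reference.

Outliers of the `D` distribution are called with the interquartile-range
rule: positive if `D > Q3 + k·IQR`, negative if `D < Q1 − k·IQR`, with
`k = 1.5` (the conventional fence) and type-7 linear-interpolation
quantiles — the default definition of the R `stats` environment, fixed
and tested explicitly because quantile conventions differ across software.
Inequalities are strict, so a degenerate all-equal vector yields no
outliers. The rule is deliberately distribution-light: it assumes only
that the bulk of genes is additive, so the central quartiles estimate the
additive noise scale. It will over-call if most genes are truly
synergistic, and the fence has no formal error-rate guarantee.

By default the outlier universe is gated to genes differentially expressed
in the combination-vs-unstimulated contrast (|fold change| ≥ 2 and
FDR-adjusted p ≤ 0.05), the contrast the score is about; gating on all
three contrasts is available behind `gate_all_contrasts` but off by
default. On synthetic counts, fold changes are the naive mean-ratio
estimator with a pseudocount (default 1, needed whenever a reference mean
can be zero) and the gate's p-values come from a Welch t test on
log-counts with Benjamini–Hochberg correction; real studies should supply
shrunken fold changes and adjusted p-values from a dedicated
differential-expression fit instead — the contrast table is the interface.

## Plate normalization

The three-stage procedure assumes a multiplicative error model for counted
hybridization plates:

    observed = truth × lane(column) × plex(gene, plex set) × content(well) × noise

* **Stage 1 (positive controls).** Each well's positive-control geometric
  mean is scaled to its column's reference (the geometric mean of the
  per-well values), factor = column reference / well value — the
  orientation that scales low-signal wells up and provably equalizes
  positive-control signal within a column. "The positive control of a
  well" is interpreted as the geometric mean over that well's several
  positive probes. This stage removes within-column hybridization
  variation; a column-wide factor survives to stage 3.
* **Stage 2 (plex calibration).** Each plex set carries the same
  calibration sample; for gene *g* the cross-plex reference `G(g)` is the
  geometric mean of *g*'s calibration counts over plex sets, and every
  measurement of *g* in plex set *s* is multiplied by `G(g)/cal(g, s)`.
  This equalizes each gene across plex sets but leaves a per-gene constant
  (the geometric mean of that gene's plex factors) that no calibration
  scheme can remove — it cancels in any cross-sample comparison, which is
  what the normalization exists for. Positive controls, which are spiked
  identically into every plex, are not plex-corrected.
* **Stage 3 (housekeepers).** With housekeeper true abundance constant
  across samples, the factor `M/h(p)` (arithmetic mean of geometric means
  over positions) equalizes each position's housekeeper geometric mean,
  removing whatever per-position scale survives stages 1–2. "Position"
  means a well. The canonical housekeeper trio (GUSB, HPRT1, NOL7) is used
  when present, else all housekeeping-class probes.

Geometric means are computed in log space; zero counts in positives,
calibration samples or housekeepers are hard errors rather than silently
offset, because no zero-handling rule is defensible without knowing the
assay floor. Zeros elsewhere pass through unchanged (normalization never
alters the zero pattern). Each stage is idempotent, which the tests assert
at 1e-12. Because the residual plex constant and the noise are
multiplicative, recovery of planted truth is measured as the Pearson
correlation of log2 counts; the linear-scale correlation is dominated by
the few highest-abundance probes and fluctuates across simulation seeds
without reflecting any property of the method.

The plate generator emulates a 96-well layout (12 columns × 8 rows), three
plex sets occupying contiguous column blocks whose last column carries the
calibration sample, a six-probe positive-control ladder, the housekeeper
trio, and 12 endogenous genes log-spaced over 30–30,000 counts — the
dynamic range a counted chemokine panel spans. Default factor spreads are
lognormal with sd 0.3 (lane), 0.3 (plex), 0.2 (content) and 2% measurement
noise. What it does not emulate: background counts (no negative-control
modeling, matching the normalization's own scope), probe-specific
saturation, or well failures.

## Dose-response fitting

The inhibition model is `y(d) = Imax + (I0 − Imax)/(1 + (d/IC50)^HC)` with
`I0` the zero-dose response (percent of maximal expression), `Imax` the
response remaining at infinite dose, `IC50` in the dose's own units (nM or
ng/mL), and the Hill coefficient `HC` unitless — values above ~2 indicate
ultrasensitivity. Vehicle observations (dose 0) enter through the exact
zero-dose limit of the model rather than a log-dose plotting offset; the
`log_x` flag is cosmetic. The activation form
`y(d) = bottom + (top − bottom)/(1 + (EC50/d)^HC)` is the same surface
with relabeled asymptotes and shares the optimizer.

Fitting is unweighted least squares over replicate-level points (matching
mean ± SD, n = 4 per dose designs), by Levenberg–Marquardt in the
transformed space (I0, Imax, log IC50, log HC), with HC box-bounded to
[0.1, 10] and a multi-start over seven log-spaced IC50 initializations
spanning the dose range; the best residual sum of squares wins. The
objective trace is recorded and is non-increasing. `fix_lower_at = 0` pins
the lower asymptote, mirroring fits that constrain full inhibition at
saturation; the default leaves it free, and both modes are tested. At
least four distinct positive doses are required — below that the four
parameters are not identifiable. Non-convergence is flagged in the result,
not raised.

## The Poisson interaction GLM

For an inhibitor pair dosed on a grid, responses are modeled as
`log μ = β0 + βA·a + βJ·j + βAJ·a·j` where `a` and `j` are ordinal dose
indices (0 = vehicle, +1 per successive experimental dose). Index coding
makes `exp(βJ)` the rate ratio "per experimental dose", the unit in which
titrations of this kind are reported; concentration-linear coding is
available behind a flag. The interaction `βAJ` is the synergy parameter:
negative values mean each inhibitor deepens the per-dose effect of the
other beyond multiplicativity.

The fit is iteratively reweighted least squares on the Poisson
score equations (so non-integer normalized counts are handled as a
quasi-likelihood mean model), converging when the relative deviance change
drops below 1e-8 (at most 50 iterations), with the covariance from the
inverse Fisher information. Per-term Wald statistics `(β/se)²` are referred
to chi-square with 1 df; the interaction's p-value is the synergy test,
with the direction constraint applied at the calling step. Marginal trends
`slope_J(a) = βJ + βAJ·a` carry delta-method errors, and
`100·(1 − exp(slope))` converts a trend to the percent decrease per dose
step.

One design choice deserves emphasis: replicate rows are kept by default
rather than averaged per cell. Fitting cell means in a Poisson model
understates the variance (the mean of n counts has variance μ/n), which
makes Wald tests anticonservative; keeping replicates preserves the
variance model, and the package's null-calibration test (2000 simulated
no-interaction grids) shows the interaction test's type-I error within
[0.035, 0.065] at α = 0.05 under that default. `average_replicates = TRUE`
reproduces the averaged-counts workflow for comparison. No overdispersion
correction is applied — a Pearson dispersion estimate is reported so users
can judge whether plain Poisson inference is trustworthy — and multi-gene
batches can opt into Benjamini–Hochberg adjustment. Coefficient-recovery
checks compare per-dose effects on the rate-ratio scale (`exp(β)`), the
scale on which the method reports effects and on which a 1% tolerance is
meaningful for coefficients near zero.

## Synergy-specific accessible elements

Differential accessibility between two conditions is assessed per peak
with a one-sided depth-scaled Poisson test: the comparator count is scaled
to the target depth (`λ = count_c × depth_t/depth_c`), the fold change is
`count_t/λ`, and the p-value is the exact Poisson upper tail
`P(X ≥ count_t)`. This is an explicit reconstruction of the tag-count test
used by common peak tools, validated against the summed-pmf CDF to 1e-12 —
not a claim of bit-compatibility with any tool (whose internal tag
thresholds and normalizations are not reproducible from their outputs).
A peak passes at fold ≥ 1.5 and p < 1e-4 (strict), the conventional gates
for this analysis.

SSAEs are the costimulated-condition peaks that pass all three pairwise
comparisons (vs unstimulated and vs each single stimulus); the intersection
is by peak id over a shared universe, so it is order-invariant and can only
shrink the survivor set. Survivors are *de novo* when they overlap no
called peak in either single-stimulus set (half-open, ≥1 bp overlap —
book-ended peaks do not touch) and *enhanced* otherwise; a stricter
variant additionally requires positive single-condition signal. TSS
proximity uses the SSAE midpoint on the 0-based half-open scale against a
±500 kb window, boundary inclusive. BED coordinates are 0-based half-open
throughout, converted to 1-based GRanges internally.

The landscape generator plants 5000 background peaks (equal Poisson means
across conditions, 50–500 counts), 20 enhanced elements (4-fold combo
enrichment over a preserved baseline) and 20 de novo elements (near-silent,
mean 2, outside the combination), on disjoint intervals across five
chromosomes with equal depths. It does not emulate overlapping or nested
peaks, depth imbalance (supported by the test, just not defaulted),
fragment-length structure, or spatially correlated background — so passing
tests demonstrate the set logic and test calibration, not robustness to
those real-data complications.

## Synthetic counts and what passing tests mean

Expression counts are negative binomial (variance `μ + φμ²`, dispersion
φ = 0.05) around condition means `baseline × 2^log2FC`, with baselines
log-uniform over 20–2000, single-stimulus log2 fold changes N(0, 1), four
replicates per condition, 2000 genes, and 30 positive / 10 negative
planted outliers at |D| = 4 log2 units — the design scale of a
four-condition costimulation experiment with a minority of strongly
synergistic genes. The NB choice matches the mean-variance behaviour the
downstream contrast assumes; the generators deliberately mirror each
model's assumptions so that parameter recovery is well-posed. Passing
recovery tests therefore show the estimators are correct under their own
model, not that the models fit arbitrary real data; model criticism
(dispersion estimates, residuals) remains the analyst's job on real
inputs.

All generators are pure functions of their parameters and a seed (RNG
state is saved and restored), and every stochastic test fixes its seed.

## Problem sizes and numerics

The test and acceptance suites run at: 2000 genes × 16 samples (outlier
recovery), a 96-well × 21-probe plate, 9-dose × 4-replicate curves with a
200-replication noise sweep at 5% CV, 3×3×3 inhibitor grids with 2000
null-calibration and 500 recovery simulations, and a 5040-peak landscape —
sizes chosen so each property is measured with comfortable Monte-Carlo
margin while the whole suite stays interactive. Tolerances: 1e-12 for
algebraic identities and oracle agreement, 1e-6 relative for noiseless
nonlinear-fit recovery (the optimizer's own precision), and pre-registered
statistical bands elsewhere (e.g. type-I error in [0.035, 0.065]).

## Known limitations

* The mean-ratio log2FC estimator has no shrinkage; near-zero reference
  means with small pseudocounts give unstable fold changes.
* The IQR fence controls no formal error rate and assumes an additive
  majority.
* The plate normalization cannot remove the per-gene cross-plex constant;
  absolute cross-gene comparisons remain unit-dependent.
* Poisson inference ignores overdispersion by design (it is reported, not
  corrected); strongly overdispersed grids need a quasi-Poisson or NB
  extension.
* The peak test assumes independent Poisson tag counts per peak; the three
  pairwise tests share the costimulated count and are positively
  correlated, so no closed-form three-way null expectation exists — the
  null is bounded, not computed, in the tests.
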