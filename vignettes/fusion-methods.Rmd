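---
title: "Two-block infrared data fusion for origin classification: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-block infrared data fusion for origin classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Medicinal-plant material from different growing regions carries subtly
different chemical fingerprints. Two vibrational-spectroscopy modalities see
different parts of that chemistry: FT-MIR (4000-650 cm^-1, fundamental
vibrations; here only the informative windows 3700-2620 and 1800-650 cm^-1
are analysed, 1150 variables) and NIR (10000-4000 cm^-1, overtone and
combination bands, 1545 variables). `irfuse` implements the complete
chemometric protocol for classifying the geographic origin of samples from
paired FT-MIR/NIR absorbance spectra, and for asking the question the
protocol exists for: at which level -- raw signal, selected features, or
model decisions -- should the two blocks be combined?

The pipeline stages are: pretreatment selection, per-class Kennard-Stone
splitting, PLS-DA and random-forest classification, three variable-selection
routes, and three fusion levels. Every stage is a package function; the
`analysis/` scripts narrate one full run and `run_experiment()` orchestrates
everything from a single config and seed.

## Models and procedures

**Pretreatment.** Six candidates: raw, SNV, first and second Savitzky-Golay
derivative (FD/SD), and SNV followed by either derivative (composite names
read left to right). SNV standardises each spectrum to mean 0, sd 1 (n-1
denominator), exactly inverting an affine scatter corruption `a*y + b`.
Derivatives use Savitzky-Golay filtering with window 15 and polynomial
degree 2 by default; these values are not dictated by any instrument
convention, so they are exposed and recorded. The filter output keeps the
input shape (asymmetric polynomial fits at segment edges), and the FT-MIR
grid's two segments are filtered separately so the filter never bridges the
excised 2620-1800 cm^-1 gap. `rank_pretreatments()` scores every candidate
by a PLS-DA on the calibration set -- R2, Q2 (7-fold CV), RMSEE, RMSECV,
calibration accuracy -- and aggregates by rank sum with accuracy as the
tie-break. One caveat found while validating this stage: the resubstitution
criteria (R2, RMSEE) structurally favour raw data, which retains the most
fittable variance, so when drift is low-rank the raw route can win the rank
sum even though a derivative wins every cross-validated criterion. The test
suite pins down the cross-validated half of that statement.

**Region exclusion.** The FT-MIR baseline region (4000-3700) and the ATR
crystal region (2620-1800) are removed before modelling. Boundary
wavenumbers belong to the retained side when one exists (the intervals are
open at shared endpoints, so 3700, 2620 and 1800 stay); a boundary at the
grid edge has no retained side and is claimed by the excluded region.

**Splitting.** Kennard-Stone max-min selection runs independently inside
every class, on the per-variable autoscaled concatenation of both
pretreated blocks, taking `floor(2n/3)` samples per class for calibration.
`floor` (not `round`) is what reproduces the canonical per-class counts
(26, 26, 24, 26, 26) from class sizes (40, 40, 36, 40, 40). The feature
space for the distances is a design choice -- the protocol needs one split
reused by every model, and the concatenated space is the only one that is
neutral between the blocks. Class members are processed in sample-id order
and distance ties break on the lowest index, so the assignment is
deterministic and invariant to row order.

**PLS-DA.** PLS2 regression of the one-hot class indicators on the
mean-centered spectra; each component is the dominant singular vector of
the current X'Y cross-covariance with both blocks deflated, which is the
NIPALS solution computed deterministically (signs fixed by the largest
weight entry). Class scores clip negative indicator predictions at zero and
renormalise rows to sum 1; the hard class is the arg-max. The component
count is chosen by 7-fold stratified cross-validation: the smallest A whose
Q2 is within 0.01 of the curve maximum, capped at 15. An earlier rule --
stop at the first gain below 0.01 -- was rejected after it underfitted
visibly (fused-matrix Q2 curves often have an early flat spot and then keep
climbing; the first-gain rule stopped at A = 2 where the maximum sat at
A = 15 with validation accuracy 0.97 instead of 0.37). Overfitting is
screened by a permutation test: labels permuted, model refit, R2 and Q2
regressed on the correlation between permuted and original indicator
columns per class; a Q2 intercept at or above 0.05 flags overfit. The
package default of 200 permutations is scaled to 50 in the test suite.

**Random forest.** `randomForest` CART bagging. Tuning follows the two-step
OOB protocol: fit 2000 trees at `m_try = floor(sqrt(p))`, read the
cumulative OOB error curve, and take the earliest exact-minimum tree count
inside the longest run of counts whose error stays within `1/(2 n_cal)` of
the minimum -- a "smooth region" rule made operational, since half a
misclassification is the smallest meaningful error difference. Then rescan
`m_try` over a 12-point geometric grid between `sqrt(p)/4` and `4 sqrt(p)`
at the chosen tree count. OOB error excludes samples that were never out of
bag (relevant only for very small forests).

**Selection routes.** (i) `pca_extract`: correlation-matrix PCA (the Kaiser
eigenvalue > 1 rule is only calibrated for autoscaled data) keeping
components with eigenvalue above 1, with a projector for new samples.
(ii) `rfe_select`: variables ranked once by scaled permutation importance of
a tuned forest, dropped five at a time; at each retained size a stratified
10-fold CV error of a forest refit is recorded; the selected size is the
smallest within one standard error of the curve minimum, and the curve is
annotated with irrelevant/interference/important regions (the initial
plateau, scanning downward, is "irrelevant"). The one-standard-error rule
replaces a by-eye partition of the error curve. (iii) `boruta_select`:
Boruta (shadow features, hits against the best shadow, two one-sided
binomial tests with Holm step-down at the full-problem multiplicity,
alpha = 0.01); confirmed plus tentative variables are retained, since
all-relevant selection is the point. One deliberate departure from the
textbook formulation: shadows are fresh permutations of *every* original
column at every iteration rather than only of the still-active ones.
Shrinking the shadow pool together with the active set collapses the
max-shadow bar late in the run, and surviving chance-correlated variables
then ratchet up hits and get spuriously confirmed -- on small pure-noise
matrices (n = 60, p = 50) the shrinking-pool variant confirmed several
null variables across seeds, while the stationary bar confirms none on
typical draws. Boruta is implemented in the package; forests inside RFE and Boruta
run on `ranger` for speed, while `fit_rf`/`tune_rf` use `randomForest` for
its per-tree OOB error curve. (iv) `vip_select`: variables with VIP
strictly above 1 from a PLS-DA on the low-level fused matrix, where
`VIP_j = sqrt(p * sum_a SSY_a (w_aj/||w_a||)^2 / sum_a SSY_a)`.

Scope matters: for mid-level fusion the selections run on the full sample
set, which follows the reference protocol but leaks validation information
into the selection -- `run_experiment()` emits an explicit warning in its
manifest whenever that scope is used. High-level selections run on the
calibration set only.

**Fusion.** Low level concatenates the two pretreated blocks (1150 + 1545 =
2695 columns, provenance retained). Mid level concatenates the per-block
selected columns or kept component scores. High level fuses decisions: for
each sample the two models' class-score vectors are combined element-wise
by four fuzzy aggregation operators (minimum, maximum, product, average);
each operator votes for its maximal class, widened by any class within
`eps = 0.01` of the maximum (near-ties count as maxima; the comparison is
strict, so a difference of exactly `eps` is not a tie, and the product
operator applies the rule to the product scores, not the inputs). The final
class set is the plurality winner across the four vote sets, with tied
pluralities returning the union -- the voting semantics are under-determined
by a 3-vs-1 worked example alone, and plurality-with-union-ties is the
reconstruction that matches it; it is therefore stated here and embedded in
the report output rather than hidden. A final set larger than one is
"multiple discrimination": it never lowers accuracy (the sample is correct
if its true class is in the set) but every extra class collects a false
positive, which depresses that class's efficiency
`sqrt(sensitivity * specificity)`.

## The synthetic generator

No instrument data ships with the package, so `simulate_blocks()` generates
paired blocks with the statistical structure the analysis assumes: a shared
Gaussian-peak backbone per modality (centers at the bands a powdered
botanical sample shows -- O-H/C-H stretches, carbonyl, the carbohydrate
fingerprint; NIR overtone bands), class profiles that perturb designated
peaks by 5-20% height multipliers and center shifts up to 4 cm^-1, and a
noise model with four realistic ingredients: per-sample per-peak height
jitter (3% by default -- natural composition variability, the source of the
dominant smooth covariance every real spectral dataset has), a per-sample
polynomial baseline (degree 2 by default, amplitude 0.03), affine scatter
`a*y + b` with `a ~ U(0.9, 1.1)` and `b ~ U(-0.02, 0.02)` (chosen so SNV is
its exact inverse), and iid Gaussian noise (sd 0.005). Peaks are Gaussian,
not Lorentzian: the tests need realistic correlation structure, not line
shapes. All randomness fans out from one master seed through named
substreams, so changing one stage's stochasticity does not perturb another
stage.

The height jitter deserves a note: without it, autoscaled synthetic spectra
are iid-noise dominated, the correlation-matrix eigenvalue bulk sits far
above 1, and the Kaiser rule keeps essentially every component while class
directions fall below the random-matrix bulk edge and become unrecoverable
-- a regime no real spectral dataset is in. With jitter and baseline
dominating the per-column variance, the eigenvalue spectrum concentrates
the way real data does and the PCs route behaves sensibly.

`make_complementary_scenario()` builds the two-block test bed: FT-MIR
resolves classes 1-3 (two markers per pair plus two group markers against
classes 4-5), NIR resolves class 4 vs 5 and the group, and each block sees
only a 1-2% echo of the other block's contrasts -- so neither block alone
can resolve all five classes while the fused problem is easy, by
construction. The markers are single grid columns (bands narrower than one
grid step, snapped onto the grid, centered in low-backbone windows so
composition jitter does not sit on top of them), giving an exact six-column
ground-truth mask per block for selection-recovery scoring. Scenario noise
is additive sd 0.002 with baseline amplitude 0.01 -- instrument-scale noise
well below the structured variability, which keeps each marker column
individually strong (class contrast about 2-3 noise sd) and keeps the class
eigendirections above the correlation-PCA noise bulk. One-column marker
bands are spectroscopically idealised (real NIR bands are broad); the
scenario trades that realism for an unambiguous ground truth, and broad
realistic bands are exactly what the default scenario provides.

What passing tests on this generator do show: the pipeline's bookkeeping,
determinism, voting semantics, selection recovery under a known truth, and
the qualitative fusion orderings. What they do not show: that any of this
holds on real rhizome spectra -- instrument artefacts (water vapour,
detector nonlinearity, ATR penetration depth) and real between-region
chemistry are not modelled, and accuracies on synthetic data say nothing
quantitative about accuracies on real data.

## Problem sizes and runtime

The test suite runs the study-sized dataset (n = 196, 1150 + 1545
variables) for the split bookkeeping, fusion-width, selection-recovery,
fusion-benefit and permutation checks; RFE is the slow piece (its error
curve refits a 10-fold CV forest at 230 and 309 retained sizes
respectively, a few minutes per block with 100-tree `ranger` refits), so
unit tests of RFE/Boruta internals use planted-signal matrices of a few
hundred columns, and the permutation test runs at 50 permutations. The
analysis scripts state their own sizes inline.

## Known limitations

- The fuzzy-vote plurality/union rule is a reconstruction (see above); any
  downstream comparison of "multiple discrimination" rates depends on it.
- Mid-level selection scope leaks by design fidelity; treat mid-level
  validation metrics as optimistic and read the manifest warning.
- `rank_pretreatments` inherits the resubstitution bias discussed above;
  with low-rank drift it can legitimately prefer raw data.
- The RF calibration-set report rows are resubstitution by default, with an
  "RF (OOB)" row alongside, because which of the two a reference table
  means is generally ambiguous; the two can differ by a lot.
- Replicate handling is the caller's business: the pipeline accepts one row
  per sample, and `average_replicates()` exists for the common
  three-scans-per-sample case without guessing at any particular study's
  choice.
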