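---
title: "Models and methods behind memtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind memtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memtrace)
```

# The scientific problem

Episodic memories are thought to undergo *systems consolidation*: with time,
retrieval comes to depend less on the hippocampus and more on neocortical
regions such as the inferior frontal gyrus (IFG). A pharmacological elevation
of noradrenergic arousal shortly after encoding (for example with the
alpha-2-adrenoceptor antagonist yohimbine) can modulate — and possibly
reverse — this trajectory. Testing that idea requires a fairly long analysis
chain: recognition-memory behaviour scored with signal-detection theory,
first-level fMRI GLMs, multivoxel encoding–retrieval similarity (ERS),
psychophysiological-interaction (PPI) connectivity, and a 2×2
between-subjects (drug × delay) group analysis with small-volume
familywise-error control.

`memtrace` implements that chain end to end at desk scale, together with a
**synthetic cohort generator** whose planted effects make every stage
testable: the package can always answer the question "if the data really
contained effect X, would this pipeline find it, and does it stay quiet when
nothing is there?".

# The simulated experiment

The generator reproduces the design of a two-day pharmacological fMRI study:

* a fully crossed between-subjects design, drug (PLAC vs. YOH) × delay
  (1 d vs. 28 d), default 26 subjects per cell with sex balanced 13/13;
* 60 old pictures (30 emotionally negative, 30 neutral), each shown once in
  each of three encoding runs; a recognition test over three runs mixing the
  60 old with 60 emotion-matched new pictures;
* 3-s picture events, jittered 4 ± 1 s fixation intervals, TR = 2 s;
* recognition responses on a four-point confidence scale
  ("definitely new" … "definitely old").

The voxel grid defaults to 24×24×24 at a nominal 3 mm — far smaller than an
acquisition grid, but large enough for three disjoint cubic ROIs
(hippocampus-like target, IFG-like neocortical region that doubles as the
PPI seed, and a null control region) each surrounded by room for a 3-voxel
searchlight. The experiments shipped in `R/experiments.R` use a 16³ grid and
20 items to keep simulation loops fast; the vignette quotes those sizes
below wherever they matter.

## Forward model for BOLD data

For every trial the generator adds, inside each ROI, a uniform amplitude
(condition-specific, in arbitrary BOLD units) plus a multivoxel *item
pattern*, and convolves the resulting trial amplitude train with the
canonical double-gamma HRF. On top of the signal it adds

* two slow cosine drift components per run with per-voxel random amplitudes,
  drawn from the discrete-cosine components below the 128-s cutoff, so the
  high-pass filter is genuinely exercised and can in principle remove them
  completely; and
* AR(1) Gaussian scan noise (default marginal SD 0.3, lag-1 coefficient
  0.3).

Item patterns are unit-norm Gaussian vectors over ROI voxels. The
recognition-phase pattern of an old item is constructed as
$r \cdot \text{enc} + \sqrt{1-r^2} \cdot \text{indep}$, which gives an
expected encoding–recognition Pearson correlation of exactly $r$ — the
planted reinstatement strength. New items get independent patterns, so the
planted encoding–new similarity is zero. This analytic construction is what
lets the acceptance checks compare recovered ERS against `atanh(r)` without
any reference dataset.

During recognition runs the IFG-like seed region additionally carries a
smooth latent fluctuation $s(t)$ (an AR(1) process with coefficient 0.85);
the target ROI receives `gain * s(t)` gated by the HRF-convolved old-trial
train, plus a small context-independent coupling. That is the planted PPI
effect: coupling between seed and target that is stronger during old trials.

## Behavioural model

Recognition evidence is drawn from $N(d', 1)$ for old items and $N(0, 1)$
for new items. The decision criterion sits at $\lambda = d'/2 + c$; two
confidence criteria at $\lambda \pm 0.5$ map evidence onto the four response
levels (the generating study does not specify a confidence model, so the
symmetric offset is a package choice and is configurable). Subjects get a
latent trait deviation on $d'$ (SD 0.35) and on the criterion (SD 0.1).

The default cell parameters were fixed once, before any recovery experiment
was run, so that the planted cohort reproduces the aggregate statistics the
package's validation quotes: cell means $d'$ = 3.15 / 3.15 / 1.71 / 2.35
(PLAC-1d / YOH-1d / PLAC-28d / YOH-28d) give a grand mean of 2.59, a
1d→28d decline of 1.12 and a drug × delay interaction contrast of 0.64,
with criterion $c = 0.35$ placing hit and false-alarm rates near 0.82 and
0.05. An emotion × delay modulation of ±0.21 at 28 d encodes the slower
decline of emotionally negative material. Because the per-cell hit rates are
a concave function of $d'$, the simulated grand-average hit rate (~81%)
sits slightly below what a single homogeneous $d'$ of 2.59 would give; this
is a property of the heterogeneous design, not a calibration target.

# Analysis methods

## First-level GLM

`build_design()` constructs the subject design across concatenated runs:
condition mode uses one regressor per encoding run and emotion plus one per
emotion and oldness category at recognition, and trialwise mode gives every
trial its own regressor (the beta-series model). All task regressors are
3-s boxcars convolved with the canonical double-gamma HRF (response gamma
shape 6, undershoot shape 16, ratio 1/6, 32-s support, unit peak), sampled
via a fine grid (TR/16) so onsets are honoured to ~0.1 s. Each run
contributes a constant and a block of discrete-cosine drift regressors with
periods above the 128-s cutoff.

`fit_glm()` runs OLS per voxel; with `ar1 = "global"` it estimates a single
lag-1 autocorrelation from the pooled in-mask OLS residuals (lags never
cross run boundaries), applies the AR(1) square-root (Prais–Winsten) filter
to data and design, and refits. One pooled coefficient rather than
voxel-wise estimates is a deliberate stability choice at desk scale. The
estimate is clipped to ±0.97 and falls back to 0 when residual variance is
numerically zero (noiseless forward-model checks).

Trialwise betas are converted to t-statistics (`trial_patterns()`), the
noise-normalised patterns used by the similarity analysis; condition-level
contrasts are computed from data smoothed with an 8-mm FWHM mask-aware
Gaussian kernel, while everything multivariate uses unsmoothed data.

## Searchlight ERS

`build_searchlight()` enumerates integer offsets with
$\|o\|^2 \le \text{radius}^2$ (radius 3 → 123 voxels for an interior
sphere), clips spheres to the grid and mask, and drops spheres with fewer
than 10 in-mask voxels. For each sphere, `ers_map()` computes Pearson
correlations between the final-run encoding pattern of each old item and
(a) its own recognition pattern — encoding-old similarity, EOS — and (b) its
matched new item's pattern — encoding-new similarity, ENS. Correlations are
Fisher z-transformed *before* averaging over items (z-then-average keeps
the statistic additive; the alternative order is a documented open choice),
and the reinstatement index ERS = EOS − ENS is written at the sphere
centre. A cross-trial variant replaces the matched pairings with all
non-corresponding old (EOS) and all new (ENS) pairings. Correlations are
clipped to $1 - 10^{-7}$ before `atanh` so degenerate spheres stay finite.

Subtracting ENS matters in practice: any shared activation profile (for
instance the ROI-shaped mean response that all items share) inflates raw
pattern correlations for matched and non-matched pairs alike; the EOS − ENS
difference cancels it and isolates item-specific reinstatement.

## PPI

`first_eigenvariate()` extracts the leading left singular vector of the
column-centred ROI time-series matrix, sign-fixed to correlate positively
with the region and standardised. `build_ppi_design()` assembles
`[seed, psych, seed * psych, drifts, constants]`, where `psych` is the
old/new contrast-coded event train convolved with the HRF and the
interaction is the literal element-by-element product at scan resolution.
No haemodynamic deconvolution of the seed is applied — the implementation
follows the plain-product formulation; the psychological vector is
HRF-convolved so both factors live on the BOLD time scale. With the
generator's ±1 context coding, a planted old-trial gain $g$ is recovered as
an interaction beta of about $g/2$, and the recovery experiments test sign
and group-level significance rather than the absolute scale.

## Group inference

Within-subject 2-level factors (old vs. new, EOS vs. ENS) are collapsed to
per-subject difference maps, so the between-subjects 2×2 ANOVA on those maps
tests the three-way pattern of interest. `interaction_map()` reports the
signed t of the cell-mean contrast
$(\text{PLAC}: 1d - 28d) - (\text{YOH}: 1d - 28d)$ with the pooled
within-cell error; for the highest-order term this equals the standard
two-way ANOVA interaction test (verified against `aov` in the test suite).

`permutation_fwe()` is the package's analogue of small-volume correction:
subject cell labels are permuted (simple relabelling of the purely
between-subjects assignment), the maximum |t| inside each ROI is recorded
per permutation, and the observed ROI peak is ranked in that max-statistic
null; when fewer distinct relabellings exist than requested permutations
the null is enumerated exhaustively and p-values gain resolution
1/#arrangements. Max-statistic permutation is exactly valid at any ROI size
and needs no smoothness estimation, which is why it replaces random-field
theory here; the substitution is visible in the output metadata. Clusters
are formed among ROI voxels exceeding the two-sided p < 0.005 threshold
(6-connectivity); peak-level inference is primary and extent is reported
descriptively. Bonferroni across ROIs is applied on request, and post-hoc
cell comparisons use Welch t-tests on per-subject cluster means.

## Behavioural statistics

`d_prime()` computes $d' = \Phi^{-1}(H) - \Phi^{-1}(FA)$ and criterion
$c = -(\Phi^{-1}(H) + \Phi^{-1}(FA))/2$. Extreme rates default to the
log-linear correction (+0.5 to both counts, +1 to both totals) — continuous,
standard, and finite for perfect scores; a clamp rule and an error-raising
"none" mode are available. Confidence weighting multiplies each "old"
response by a weight (`definitely` = 1, `rather` = 0.5 by default; the
weighting scheme is configurable because no canonical map exists).
`welch_t()`, `pearson_cor_test()` (with Tukey-fence outlier trimming) and
`factorial_interaction()` (two-way ANOVA via `aov`, with the interaction
contrast and partial eta squared) wrap the standard tests the group analysis
needs. The subject-level factorial ANOVA replaces trial-level mixed models
deliberately: the interaction contrast is the quantity of interest, and the
cell-mean formulation makes its permutation analogue straightforward.

# Numerical and design choices

* **Seeds.** Every stochastic stage takes an explicit integer seed; stage
  seeds derive deterministically from one master seed, so a configuration
  reproduces byte-identical reports.
* **Coordinates.** All indexing is voxel-based and 1-based internally;
  cluster tables report voxel coordinates directly since the synthetic grid
  has an identity affine.
* **Degenerate inputs.** Zero-variance samples, all-zero contrasts, empty
  masks, missing pairings, out-of-window events and rank-deficient designs
  raise classed validation errors naming the offending columns or ids.
* **Smoothing.** Separable Gaussian with mask-aware renormalisation, so
  constants stay constant at mask edges and no signal leaks outside the
  mask; measured FWHM of a delta input is within 5% of the request.
* **Trial allocation.** The split of old/new items across recognition runs
  is uniform at random — the generating design leaves it unspecified.

# Validation experiments and their problem sizes

The functions in `R/experiments.R` define the package's standing
validation battery (also driven by `scripts/acceptance.R`):

* `ers_recovery_experiment()` — 8 subjects per planted r ∈ {0, 0.3, 0.6},
  16³ grid, 20 items, pattern noise 0 and scan noise 0.02, univariate
  amplitudes disabled so the multivariate channel is isolated. Recovered
  ROI-mean ERS tracks `atanh(r)` within ±0.1.
* `reversal_experiment()` — cohorts of 8 subjects per cell on the 16³ grid
  carrying the full qualitative reversal structure (hippocampal ERS and
  old>new amplitude rising 1d→28d under YOH, falling under PLAC; mirrored
  in the IFG ROI; nothing in the control ROI). The permutation interaction
  test should be significant with the planted sign in the target ROIs in at
  least 80% of cohorts and stay near the nominal error rate in the control.
* `fwe_null_experiment()` — 500 null cohorts of 16 subjects, 200
  permutations each: corrected rejections at 0.05 stay within [0.03, 0.08].
* `ppi_recovery_experiment()` — 12-subject cohorts on a 12³ grid;
  a planted gain of 0.6 yields a positive group-mean interaction beta in
  ≥90% of cohorts, and the zero-gain null stays calibrated.
* `behav_null_experiment()` / `behav_power_experiment()` — 2000-replicate
  type-I calibration of the factorial interaction and ≥80% detection power
  for the default planted attenuation at 26 subjects per cell.

These sizes are the package's documented desk-scale study conditions; the
full-size design (26 subjects/cell, 60 items, 24³ grid) runs through the
same code paths via `run_pipeline()`.

# What passing these tests does and does not show

The generator is a forward model, not real fMRI: it contains no motion, no
physiological (cardiac/respiratory) noise, no spatial autocorrelation
outside the smoothing step, no susceptibility artefacts, and its item
patterns are exactly Gaussian with exactly planted correlations. Passing
recovery tests therefore demonstrates that the estimators are correct and
calibrated *under the stated model*, and that the pipeline's inference is
valid for between-subjects permutation under exchangeability. It does not
certify preprocessing (realignment, normalisation are out of scope), nor
performance under real-data noise structure, nor the biological claims of
any particular study.

# Known limitations

* AR(1) is pooled per subject, not voxel-wise; strongly heterogeneous
  autocorrelation would be mis-whitened.
* The flexible-factorial error structure of classic neuroimaging packages is
  replaced by difference maps plus a between-subjects ANOVA; for 2-level
  within factors these target the same interaction, but the error model is
  not a bit-level reproduction.
* Only plain Pearson ERS is implemented — no cross-validated distances, no
  representational model comparison.
* The confidence-generation model (symmetric ±0.5 criteria) is a
  convention; weighted-d' results depend on the chosen weight map.
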