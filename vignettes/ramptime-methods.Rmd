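---
title: "ramptime: models, parameters, and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ramptime: models, parameters, and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ramptime)
```

This vignette is the package's own account of its methods: what each model
assumes, which tunable parameters matter and why their defaults were chosen,
what the synthetic generator does and does not emulate, and the numerical
conventions adopted where the underlying procedures left choices open. It
states no empirical result that the test suite or `scripts/acceptance.R` do
not themselves compute.

## The task and its data

A self-timed movement trial is: houselamp off, a uniform random delay
(0.4–1.5 s), a 100-ms start-timing cue, and then a self-timed wait. The
first lick after the cue determines the outcome — a *reaction* before
0.5 s, *early* before the criterion time (3.333 s in the standard task),
*reward* up to the 7-s trial end, an *ITI lick* up to 17 s, or *no lick*.
Bins are half-open `[lo, hi)`, so a lick exactly at the criterion is
rewarded. Continuous channels (signal fluorophore, control fluorophore,
EMG, accelerometer) are sampled at a configurable rate, 1 kHz by default.

## The synthetic session generator

The generator exists so that every downstream stage can be validated
against known ground truth. Its defaults describe the study conditions the
package targets:

* **First-lick times** are log-normal with moments matched to a mean of
  3.3 s and a Weber fraction (CV) of 0.30, truncated below at 0.05 s. The
  log-normal is a choice of convenience: timing distributions in this class
  of task are broad and right-skewed but no parametric family is canonical.
  A CV of 0.3 is typical of rodent interval timing.
* **The latent timing signal** is, per trial with movement time $T$, either
  a linear ramp from `ramp_onset_lag` (0.2 s, just after the cue transient)
  to the lick, rising to the common endpoint `ramp_peak_amplitude` (5 a.u.
  on a 100 a.u. resting fluorescence, i.e. a 5% dF/F ramp), so slope
  $\propto 1/(T - 0.2)$; or, in step mode, a single step of the same
  amplitude at a time uniform on $(0, T)$.
* **The baseline offset** is $g/T$ with gain $g = 3$, active from 3 s
  before lamp-off until the lick, multiplied by log-normal trial-to-trial
  jitter (`baseline_noise = 0.3`). The jitter matters: a noiseless $g/T$
  baseline would make pre-cue signals a *perfect* decoder of movement time,
  which no real recording is, and would leave nothing for the
  threshold-crossing predictor to absorb in the decoding model.
* **Transients** (cue, lick, reward) are first-order rise/decay kernels;
  the lick kernel's decay constant is set so its half-decay is ≈75 ms,
  matching fast extracellular dopamine sensors.
* **Bleaching** is a single exponential per channel (τ = 2000 s for the
  signal channel, 0.8× that for the control), applied multiplicatively.
* **Artifacts** are Poisson events (0.05/s) injected identically into both
  fluorescence channels and as bursts into EMG/accelerometer, emulating the
  logic of a calcium-insensitive control fluorophore.
* **Optogenetics**: a fraction (30%) of trials is flagged and their lick
  time redrawn from the empirical distribution of the base sample with its
  discrete hazard multiplied by $m$; sampled atoms are smeared uniformly
  over the gap to the previous atom so redraws are continuous and, at
  $m = 1$, equal in law to the base sample. Multiplied-hazard mass not
  exhausted by the atoms (when $m < 1$) becomes a no-lick trial.

What the generator does **not** emulate: hemodynamic or pH artifacts,
sensor nonlinearity and saturation, slow behavioural nonstationarity
(satiety, disengagement), correlated noise, or lick *bouts* (only first
licks drive transients). Tests passing on synthetic sessions therefore
validate the estimators' correctness and discriminative logic, not their
robustness to every failure mode of real photometry.

Test and acceptance runs synthesise sessions at 250 Hz rather than 1 kHz;
the sampling rate only sets the rendering resolution of the continuous
channels (all model fitting happens at 100 Hz or below), and 250 Hz keeps
the simulations comfortably sized. The rate is configurable throughout.

## dF/F conditioning

Four baseline estimators are provided; `moving_average` (a centred 200-s
window, shrunk symmetrically at the session edges) is the default used by
the pipeline. The per-trial `normalized_baseline` method is retained
deliberately as the cautionary contrast: when baseline activity carries
decision-relevant signal, normalising each trial by its own pre-trial mean
erases that signal and distorts within-trial dynamics. The **Distortion
Index** makes this quantitative: over windows around consecutive
early/rewarded trial pairs (ER and RE orderings, ±20 s around the second
trial's cue), both the raw fluorescence and the dF/F are min-max normalised
and their pointwise absolute difference is averaged over pairs. DI is zero
exactly when the dF/F is an affine rescale of the raw trace, so a large DI
flags artifactual rescaling. Two profiles are returned: the mean per-pair
distortion (`di`), and the distortion of the pair-averaged normalised
traces (`di_avg`), in which per-pair noise cancels so the systematic
component stands out; method comparisons use `di_avg`. On baseline-coupled
synthetic sessions the acceptance suite verifies DI(normalized baseline) >
DI(moving average) on the timing interval.

The whole-session low-pass baseline (`fc = 5e-5` Hz) is realised as an FFT
zero-phase filter with a raised-cosine transition from `fc` to
`10^(2(1-steepness))·fc`. The conventional meaning of "steepness" for this
filter family maps to a transition band far too wide to serve as a baseline
estimator at these cutoffs, so the package defines the transition on a
logarithmic frequency axis and validates the filter only by its attenuation
at 10× the cutoff, which the tests check directly. The filter's startup
behaviour is not corrected; the first window is reported as-is.

Singularities are single points (runs of ≤3 samples) beyond 15 SD of the
trace mean, replaced by linear interpolation; longer excursions are left
untouched and counted.

## Hazard functions

The raw first-lick histogram is biased by survival: late bins can only be
reached by trials that have not yet licked. The hazard corrects this by
dividing each 250-ms bin's count by the remaining opportunities (licks in
that bin or later). Bins with zero remaining opportunities are *undefined*
(`NA`), never zero, and all plots and fits mask them. The inverse transform
(`hazard_to_counts`) reconstructs the histogram exactly and serves as an
integrity check. Hazards can be computed per session and averaged, or on
pooled trials; per-session-then-average is the default, matching how
multi-animal summaries are usually displayed.

## The nested encoding model

The encoding model asks how much of the single-trial fluorescence is
explained by task events alone versus timing-dependent structure. The
signal from lamp-off to first lick is concatenated across trials (at a
100-Hz fitting rate) and regressed on nested predictor groups, in order:
null offset; control channel; cue kernels (24, raised cosines log-spaced
over 0–0.5 s post-cue); first-lick kernels (28, linear over −0.5–0 s);
nuisance-movement kernels (44, −0.5–+0.5 s around thresholded
EMG/accelerometer events); a lamp-off→lick constant offset scaled by the
trial's movement time; and 500 stretch predictors, each an indicator for
one contiguous 1/500 of the cue-to-lick interval. The stretch basis encodes
*percentages* of the interval, so it can only produce a ramp if ramping is
present and temporally scales with the interval — that is its point. The
stretch predictors tile the full interval at 0.2% each; a printed fraction
of 0.05% per predictor is arithmetically inconsistent with 500 predictors
covering the interval, and full tiling is the only self-consistent reading.

Every predictor is scaled to maximum absolute amplitude 1, making fitted
predictions invariant to raw predictor scaling. Ridge coefficients follow
the convention $\hat\Theta = (X^\top X + \lambda I)^{-1} X^\top Y$; λ is
chosen per nest from a 13-point grid (10⁻³–10³) by five-fold
cross-validation *blocked by trial* — blocking by timepoint would leak
within-trial autocorrelation across folds. λ selection minimises the
penalised test loss as printed; nest-to-nest improvement is reported on the
unpenalised held-out MSE (both are stored). Coefficient uncertainty is
simulated from the Gaussian sandwich covariance
$\sigma^2 A^{-1} X^\top X A^{-1}$, $A = X^\top X + \lambda I$.

PCA of ramping intervals interpolates each cue+0.7→lick−0.6 segment to the
maximum possible interval length — $(7 - 0.7 - 0.6)\,\text{s} \times f_s$,
i.e. 5700 samples at 1 kHz — runs PCA across trials, and down-samples the
3-PC reconstruction back to each trial's duration. Intervals shorter than
0.1 s are excluded.

## Threshold decoding

Crossing times are *debounced*: the signal must cross the level from low to
high and stay at or above it through the interval's end. Trials that start
and end above the level never cross; a trial starting exactly at the level
and staying above counts as crossing at its first sample. Non-crossing
trials are encoded as 0; if no trial crosses, the predictor becomes a
constant-ones column (penalising the extra predictor without information).
100 candidate levels span the pooled min–max; `mid` is the lowest level
with the maximum number of crossings, `min`/`max` are the lowest/highest
levels with ≥50 crossings, and the relaxed mode used for control channels
drops the 50-trial floor. Signals are smoothed with a 100-ms Gaussian
kernel truncated at ±3σ before crossing analysis.

The decoder regresses log first-lick time on nested predictors (previous
lick time; previous outcome indicators; median signal over the 10 s before
lamp-off; median lamp-off→cue signal; control crossing; signal crossing),
each min-max normalised, with the same trial-blocked ridge/CV machinery.
Medians, not means, summarise the ITI and lamp-off windows. The
slope-vs-threshold analysis regresses *absolute* crossing time on first-lick
time per level: ramps to a common endpoint give slopes rising toward 1 with
level; a latent step gives level-independent slopes.

## Ramp-vs-step classification

Each trial's ramping interval is min-max normalised (so the Beta noise
prior lives on (0,1) and classification is affine-invariant) and classified
by 20 independent traces of 50 retain-the-best importance-resampling
rounds. Each round flips a fair coin for the class, draws a data-driven
proposal, scores it by log prior + iid Gaussian log-likelihood, and keeps
the best hypothesis seen. `p(ramp)` is the fraction of traces ending on a
ramp.

Proposals: ramp slopes and intercepts are Gaussian around RANSAC consensus
fits — a per-trial pool of 50 candidates from minimal two-point samples,
each refined on its inlier set with an inlier band of 2× the median
absolute residual (re-estimated per candidate); drawing a pool member per
proposal preserves the data-driven randomness of per-proposal RANSAC at a
fraction of its cost. The slope spread is `maxslope` (signal range over
duration, the largest slope the data supports) and the intercept spread the
magnitude of the intercept at `maxslope`, both floored at 0.1 so no
proposal density degenerates. Step times are uniform over the points whose
derivative is strictly above its 95th percentile (all interior points when
the derivative is flat, as for a pure line); segment amplitudes are
Gaussian around the segment means. Noise SDs are Beta with mode equal to
the relevant signal SD; a mode alone does not fix a Beta, so the
concentration is set to ν = α + β = 10, weakly informative and
mode-preserving. Scores use a fixed broad prior (slope ~ N(0, maxslope),
amplitudes ~ N(signal mean, 1)) rather than the proposal densities, so the
two model classes are compared on the same footing; the class coin is
re-flipped every round, which keeps the two classes symmetric within a
trace. Classification accuracy on labelled synthetic trials at SNR ≥ 10 is
asserted at ≥80% per class in the acceptance suite.

Two population diagnostics complement per-trial classification:
step-aligned averaging (true steps give a clean step; true ramps leave a
transient on a *rising background*) and the cross-trial variance profile in
10% increments of pooled, truncated intervals (uniform step times give an
inverted-U; common-endpoint ramps with baseline noise give variance falling
toward the lick). The variance profile operates on signals in their
original units — per-trial normalisation would delete the baseline-offset
variance it is designed to expose.

## Movement-state decoding

Movement is modelled as a discrete-time hazard: at 100 Hz, every timepoint
from the cue to 160 ms before the lick is a non-movement state, and the
single point 150 ms before the lick is the movement state (excluding
peri-movement samples). The logistic model predicts the state from the
current signal and nine 200-ms history means reaching 2 s back, nested most
distant first so proximal signals can absorb distal variance. Timepoints
closer than 2 s to the cue get zeroed history bins plus a mask indicator
rather than being dropped. Class balance is enforced by down-sampling the
non-movement states to the movement count; each nest is refit on 100
balanced sets and the coefficients averaged. The logistic solver carries a
tiny ridge (10⁻³) that guards against separation and against coefficient
blow-up when smooth signals make the history bins nearly collinear.

Because balanced training inflates predicted probabilities by the
down-sampling prior, the fitted hazard applies the standard case-control
intercept correction (−log n₀/n₁) before binning, putting the fitted curve
on the true hazard scale; plain (0,1) normalisation without the correction
is available behind a flag but leaves a monotone nonlinear compression that
caps well-specified recovery far below its ceiling. The fitted hazard is
the per-bin mean predicted probability across trials; it is compared to the
empirical hazard of the same trials' licks by an *opportunity-weighted*
squared correlation over bins with ≥10 remaining opportunities. The
weighting matters: tail bins rest on a handful of trials, and with plain
correlation their sampling noise dominates — under a label shuffle the flat
fitted curve plus tail noise can fake R² up to ~0.3, while the weighted
statistic stays near zero. An unweighted absolute-scale SSE R² is reported
alongside. `cv_fitted_hazard()` evaluates everything out-of-sample via
trial-blocked folds, which is what the shuffle control and the acceptance
suite use; the in-sample variant is retained for exploration. Time-slice
BIC model selection (500-ms slices, one point per trial per slice) compares
signal-only against trial-history predictor sets.

## Optogenetic statistics

Stimulated and unstimulated first-lick pools are compared by (1) the
two-sample unsigned KS test; (2) the paired-draw bootstrap: one trial from
each pool, difference taken, 10⁵ draws by default (10⁶ is configuration),
summarised by the median or mean of the difference distribution with a
percentile 95% interval; and (3) dAUC, the integral of the difference
between the two empirical cdfs over 0.7–7 s, with a two-sided permutation
test (10⁴ shuffles) and the add-one p estimator (b+1)/(n+1). The sign
convention is stimulated − unstimulated, so an early shift (activation) is
*positive* dAUC; the opposite convention is a pure sign flip available via
`legacy_sign`. The null calibration of these tests (type-I error at
α = 0.05 over 200 simulated null sessions) is asserted in the acceptance
suite within ±0.04.

## Numerical conventions and degenerate inputs

* Hazard bins with zero opportunities: `NA`, masked everywhere.
* Flat windows in the Distortion Index: skipped with a warning.
* Constant predictors in the decoder: retained (ridge handles them) and
  visible in the coefficient table.
* Empty nuisance channels: zero events, an empty kernel block.
* Trials lacking 5 s of pre-trial data for trial-based dF/F: flagged and
  excluded; their spans are `NA`.
* All statistical null checks in the test suite run at α = 0.01 or with
  Bonferroni-corrected simultaneous bands: with dozens of bins or trials a
  raw per-element 3σ rule would fail by construction ~10% of the time.
* Seeds: every stochastic entry point takes a `seed`; identical seeds give
  bit-identical sessions, fits, and resampling results.

## Problem sizes

The test suite and acceptance script use: 10⁴ draws for distributional
checks; 150–500-trial sessions at 250 Hz for pipeline-level properties;
200 labelled trials per class for classification accuracy; a 500-trial
logistic-hazard session for movement-state recovery; 10⁵ bootstrap draws
and 10⁴ permutations for the opto statistics; and 200 simulated null
sessions for calibration. These sizes were chosen so each property is
measured well inside its Monte-Carlo error at desk scale.

## Known limitations

* The encoding model is Gaussian; non-Gaussian observation noise (photon
  shot noise at low light) is approximated, not modelled.
* Basis shapes are fixed raised cosines; kernel *shape* learning is out of
  scope.
* The ramp-vs-step comparison considers linear ramps and single steps only;
  nonlinear (e.g. exponential) ramp families are not implemented.
* The movement-state model is plain discrete-time logistic regression, not
  a survival-analysis formulation; that is deliberate, matching the
  construction it implements.
* The Zenodo-deposited experimental sessions are not bundled; the optional
  loader surface is the session store (`read_session`/`write_session`), and
  all tests run on synthetic data.
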