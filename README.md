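# ramptime

Analysis of slowly ramping neural signals recorded during self-timed
movement tasks.

In these experiments a head-fixed animal receives a start-timing cue and
must withhold its response (a lick) for a criterion interval — 3.3 s in the
standard task — before moving to earn reward. Movement times are broadly
distributed from trial to trial, and fiber-photometry recordings of
dopaminergic activity show two low-dimensional signals that predict them: a
pre-cue **baseline offset** (higher baselines precede earlier movements) and
a slow **ramp** between cue and movement whose slope is inversely
proportional to the timed interval, terminating at a nearly common
amplitude. `ramptime` implements the full quantitative pipeline around these
observations, with a ground-truth synthetic session generator so every stage
is testable offline:

* **Synthetic sessions** — scalar-property (Weber's law) first-lick times,
  GCaMP-like traces with bleaching, cue/lick/reward transients, shared
  movement artifacts, baseline offsets `∝ 1/T`, cue-to-lick ramps with a
  common endpoint (or latent steps), a timing-free control fluorophore
  channel, and optogenetic hazard modulation on 30% of trials.
* **dF/F conditioning** — four baseline (F₀) methods: per-trial normalized
  baseline, whole-session ultra-low-pass, multi-trial baseline, and a 200-s
  moving average, `dF/F = (F − F₀)/F₀`; singularity removal; a Distortion
  Index quantifying artifactual rescaling on paired early/rewarded trials;
  transient half-decay kinetics; lick-transient-normalized dF/F.
* **Behaviour** — outcome classification, 250-ms timing histograms, and the
  hazard function `h(b) = count(b) / Σ_{b'≥b} count(b')` (the IRT/Op
  correction of survival bias), event-aligned averages, baseline-signal ×
  movement-time correlations, Weber CV summaries.
* **Nested encoding GLM** — `Y = ΘX` on concatenated lamp-off→lick spans:
  null offset, control channel, raised-cosine cue/lick/nuisance kernels, a
  movement-time-proportional baseline-offset predictor, and 500 "stretch"
  predictors tiling fixed fractions of the cue-to-lick interval; ridge
  penalty per nest chosen by five-fold CV blocked by trial; coefficient
  uncertainty by sandwich-covariance redraws; PCA of ramping intervals.
* **Threshold decoding** — debounced threshold crossings on the ramping
  interval (cue + 0.7 s to lick − 0.6 s), unbiased low/mid/high threshold
  selection, crossing-time-vs-movement-time slope profiles (slopes rise with
  threshold level for ramps, stay flat for steps), and a nested ridge
  decoder of log first-lick time.
* **Ramp-vs-step classification** — per-trial hierarchical Bayesian model
  comparison by retain-the-best importance resampling (20 traces × 50
  rounds) with data-driven RANSAC ramp proposals and derivative-peak step
  proposals; step-aligned averaging and cross-trial variance profiles as
  population-level diagnostics.
* **Movement-state decoding** — discrete-time logistic hazard model of the
  per-timepoint movement probability from the current signal and nine 200-ms
  history bins, class-balanced refits, fitted-vs-empirical hazard R², label
  shuffle controls, and time-slice BIC model selection.
* **Optogenetic statistics** — two-sample KS test, 10⁵–10⁶-draw
  bootstrapped median/mean shifts, and a dAUC (difference of cdf areas over
  0.7–7 s) permutation test.

Everything takes and returns tidy tables, composes with the pipe, and has
`tidy()`/`glance()`/`autoplot()` methods for the fitted objects.

## Worked example

```r
library(ramptime)

s   <- simulate_session(generative_params(n_trials = 150),
                        task_config(sampling_rate = 250), seed = 7)
fs  <- s$config$sampling_rate
dff <- s$channels$gcamp |> remove_singularities() |>
  compute_dff("moving_average", s$trials, fs = fs)

baseline_timing_correlation(dff, s$trials, "baseline", fs = fs)
#> # A tibble: 1 × 5
#>   window        r  ci_lo  ci_hi     n
#> 1 baseline -0.588 -0.697 -0.454   115

iv <- ramping_intervals(s, dff, out_rate = 100)
threshold_slope_analysis(iv, select_thresholds(iv))
#> # A tibble: 3 × 7
#>   level_name   level     n slope ci_lo ci_hi r_squared
#> 1 low        0.00326    52 0.193 0.146 0.240     0.575
#> 2 mid        0.0224    148 0.667 0.633 0.701     0.912
#> 3 high       0.0381     63 0.989 0.950 1.03      0.976
```

The negative baseline correlation says trials with higher pre-trial
fluorescence moved earlier. The slope table regresses the absolute
threshold-crossing time on the first-lick time at three threshold levels:
the slope rising from 0.29 toward 1 with threshold height is the signature
of single-trial *ramps* converging on a common endpoint — a single latent
step would cross every threshold at the same moment and give identical
slopes at all levels.

A full pipeline run (`run_pipeline()`) chains preprocessing, behaviour,
encoding, decoding, classification, state decoding, and opto statistics with
per-stage provenance hashes. A thin CLI over the same functions lives at
`inst/cli/ramptime`.

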