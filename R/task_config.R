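#' Task configuration for a self-timed movement session
#'
#' Describes the temporal structure of the behavioural task: a houselamp-off
#' event, a random delay, a start-timing cue, and windows that map the latency
#' of the first lick after the cue onto a trial outcome. Defaults reproduce the
#' 3.3-s variant of the task (criterion at 3.333 s, trial interval to 7 s,
#' intertrial period to 17 s after the cue); the 5-s variant uses
#' `criterion_time = 4.95, trial_end = 10, iti_end = 20`.
#'
#' @param criterion_time Seconds after the cue at which licks begin to earn
#'   reward.
#' @param trial_end End of the reward window, seconds after the cue.
#' @param iti_end End of the intertrial interval, seconds after the cue; the
#'   next trial's lamp-off event follows immediately.
#' @param lampoff_delay_range Two-element numeric, low/high bounds (seconds) of
#'   the uniform random delay between lamp-off and cue.
#' @param cue_duration Cue duration in seconds.
#' @param reaction_cutoff Licks earlier than this (seconds post-cue) are
#'   classified as reactive, not self-timed.
#' @param sampling_rate Sampling rate of the continuous channels, Hz.
#'
#' @return A list of class `task_config`.
#' @export
#' @examples
#' task_config()
task_config <- function(criterion_time = 3.333,
                        trial_end = 7,
                        iti_end = 17,
                        lampoff_delay_range = c(0.4, 1.5),
                        cue_duration = 0.1,
                        reaction_cutoff = 0.5,
                        sampling_rate = 1000) {
  stopifnot(
    criterion_time > 0,
    criterion_time < trial_end,
    trial_end < iti_end,
    length(lampoff_delay_range) == 2,
    lampoff_delay_range[1] < lampoff_delay_range[2],
    lampoff_delay_range[1] >= 0,
    sampling_rate > 0
  )
  structure(
    list(
      criterion_time = criterion_time,
      trial_end = trial_end,
      iti_end = iti_end,
      lampoff_delay_range = lampoff_delay_range,
      cue_duration = cue_duration,
      reaction_cutoff = reaction_cutoff,
      sampling_rate = sampling_rate
    ),
    class = "task_config"
  )
}

#' Generative parameters for synthetic photometry sessions
#'
#' Parameters of the synthetic-session generator. The signal-channel model is
#' `bleach(t) * (F_rest + baseline_offset(T) + latent(t; T) + kernels * events +
#' artifact + noise)`, where `T` is the trial's first-lick latency. The latent
#' timing term is either a linear ramp from `ramp_onset_lag` after the cue to
#' the first lick, terminating at the common endpoint `ramp_peak_amplitude`
#' (so per-trial slope is inversely proportional to the timed interval), or, in
#' step mode, a single step of the same amplitude at a time drawn uniformly on
#' the cue-to-lick interval. The per-trial baseline offset is
#' `baseline_gain / T`, reproducing the empirical association of elevated
#' baselines with earlier movements. The control channel shares the bleaching,
#' artifact and noise processes but carries no timing-dependent terms.
#'
#' @param n_trials Number of trials.
#' @param weber_fraction Coefficient of variation of the first-lick times
#'   (scalar timing property).
#' @param mean_move_time Mean first-lick latency in seconds.
#' @param dynamics_mode `"ramp"` or `"step"` single-trial latent dynamics.
#' @param ramp_peak_amplitude Common endpoint amplitude of the latent term,
#'   in raw fluorescence units (a.u.).
#' @param baseline_gain Baseline offset gain: per-trial offset is
#'   `baseline_gain / move_time` (a.u. * s).
#' @param baseline_noise SD of the log-normal trial-to-trial jitter on the
#'   baseline offset, so baselines predict move time imperfectly (0 disables).
#' @param ramp_onset_lag Seconds after the cue at which the latent ramp starts.
#' @param cue_kernel,lick_kernel,reward_kernel Transient shapes, lists with
#'   `amplitude` (a.u.), `rise` and `decay` time constants (seconds).
#' @param bleach_tau Photobleaching time constant, seconds (single
#'   exponential, independent per channel).
#' @param f_rest Resting fluorescence of the signal channel, a.u.
#' @param noise_sd White-noise standard deviation, a.u.
#' @param artifact_rate Rate of shared movement artifacts, events/s.
#' @param artifact_amplitude Artifact amplitude, shared across the two
#'   fluorescence channels.
#' @param opto `NULL`, or a list `list(fraction =, hazard_multiplier =)`
#'   marking a random subset of trials whose first-lick hazard is multiplied
#'   during stimulation.
#'
#' @return A list of class `generative_params`.
#' @export
generative_params <- function(n_trials = 500,
                              weber_fraction = 0.3,
                              mean_move_time = 3.3,
                              dynamics_mode = c("ramp", "step"),
                              ramp_peak_amplitude = 5,
                              baseline_gain = 3,
                              baseline_noise = 0.3,
                              ramp_onset_lag = 0.2,
                              cue_kernel = list(amplitude = 8, rise = 0.02, decay = 0.10),
                              lick_kernel = list(amplitude = 10, rise = 0.05, decay = 0.108),
                              reward_kernel = list(amplitude = 12, rise = 0.03, decay = 0.25),
                              bleach_tau = 2000,
                              f_rest = 100,
                              noise_sd = 0.5,
                              artifact_rate = 0.05,
                              artifact_amplitude = 2,
                              opto = NULL) {
  dynamics_mode <- match.arg(dynamics_mode)
  if (weber_fraction <= 0) abort("`weber_fraction` must be positive.")
  if (mean_move_time <= 0) abort("`mean_move_time` must be positive.")
  if (ramp_peak_amplitude < 0) abort("`ramp_peak_amplitude` must be >= 0.")
  if (!is.null(opto)) {
    opto$fraction <- opto$fraction %||% 0.3
    opto$hazard_multiplier <- opto$hazard_multiplier %||% 1
    stopifnot(opto$fraction > 0, opto$fraction <= 1, opto$hazard_multiplier > 0)
  }
  structure(
    list(
      n_trials = n_trials, weber_fraction = weber_fraction,
      mean_move_time = mean_move_time, dynamics_mode = dynamics_mode,
      ramp_peak_amplitude = ramp_peak_amplitude, baseline_gain = baseline_gain,
      baseline_noise = baseline_noise,
      ramp_onset_lag = ramp_onset_lag, cue_kernel = cue_kernel,
      lick_kernel = lick_kernel, reward_kernel = reward_kernel,
      bleach_tau = bleach_tau, f_rest = f_rest, noise_sd = noise_sd,
      artifact_rate = artifact_rate, artifact_amplitude = artifact_amplitude,
      opto = opto
    ),
    class = "generative_params"
  )
}
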