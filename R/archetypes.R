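#' Archetype specification for the synthetic cohort
#'
#' An archetype bundles the generative parameters of one latent participant
#' phenotype: the shape of its pupil trajectory across the task, its
#' cardiac-autonomic level (mean NN interval, beat-to-beat jitter, LF/HF
#' modulation depths), its oculomotor event rates, and its behavioral profile
#' (response time, error probability per difficulty level, self-esteem bias).
#'
#' The two default archetypes mirror the phenotypes the clustering is designed
#' to separate:
#' * **archetype 0** — "early responder": elevated pupil size at each block
#'   onset that declines within the block; high vagally-mediated HRV (long
#'   MeanNN, large RMSSD, strong HF modulation); sparser eye events; fast but
#'   error-prone responding with lower self-esteem.
#' * **archetype 1** — "deception reactor": low pupil size at block onset
#'   rising with difficulty, plus an additive pupil peak when deceptive
#'   feedback starts; low HRV with relatively stronger LF modulation; denser
#'   saccade/fixation/blink activity; slow, accurate responding with higher
#'   self-esteem.
#'
#' @param label Archetype label, 0 or 1.
#' @param block_start Pupil shape offset at each block onset (z-shape units).
#' @param within_block_slope Linear pupil drift across a block (z-shape units
#'   from block start to block end).
#' @param deception_peak Amplitude of the additive pupil peak centered on the
#'   first deceptive level (z-shape units; 0 disables).
#' @param mean_nn_ms Mean NN (RR) interval in ms; must lie in (300, 1500).
#' @param rmssd_target_ms Target RMSSD in ms; beat-to-beat Gaussian jitter SD
#'   is `rmssd_target_ms / sqrt(2)`.
#' @param lf_mod_amp,hf_mod_amp Amplitudes (ms) of the sinusoidal NN
#'   modulation at the 0.1 Hz (LF) and 0.25 Hz (HF) carriers.
#' @param saccade_rate_hz,fixation_rate_hz,blink_rate_hz Poisson event rates.
#' @param saccade_amp_deg,saccade_vel_deg_s Median saccade amplitude and mean
#'   velocity (lognormal medians).
#' @param fixation_dur_ms,blink_dur_ms Median event durations (ms).
#' @param rt_mean_ms Mean response time at level 1 (ms); grows by
#'   `rt_level_slope_ms` per level.
#' @param rt_level_slope_ms Added mean RT per difficulty level (ms).
#' @param error_prob_by_level Probability of an incorrect response at levels
#'   1..n_levels.
#' @param self_esteem_bias Additive offset on the 1-5 self-esteem rating.
#' @param ess_mean,ess_sd Epworth Sleepiness Scale distribution.
#' @param smoking_prob Probability of smoker status.
#' @return A list of class `archetype_spec`.
#' @export
archetype_spec <- function(label,
                           block_start,
                           within_block_slope,
                           deception_peak,
                           mean_nn_ms,
                           rmssd_target_ms,
                           lf_mod_amp,
                           hf_mod_amp,
                           saccade_rate_hz,
                           fixation_rate_hz,
                           blink_rate_hz,
                           saccade_amp_deg = 1.6,
                           saccade_vel_deg_s = 95,
                           fixation_dur_ms = 240,
                           blink_dur_ms = 160,
                           rt_mean_ms,
                           rt_level_slope_ms = 240,
                           error_prob_by_level,
                           self_esteem_bias = 0,
                           ess_mean = 9,
                           ess_sd = 3.6,
                           smoking_prob = 0.35) {
  if (!label %in% c(0L, 1L)) rlang::abort("label must be 0 or 1")
  if (mean_nn_ms <= 300 || mean_nn_ms >= 1500) {
    rlang::abort("mean_nn_ms must lie in (300, 1500)")
  }
  if (any(error_prob_by_level < 0 | error_prob_by_level > 1)) {
    rlang::abort("error probabilities must lie in [0, 1]")
  }
  rates <- c(saccade_rate_hz, fixation_rate_hz, blink_rate_hz)
  if (any(rates <= 0)) rlang::abort("event rates must be > 0")
  structure(
    list(
      label = as.integer(label),
      block_start = block_start,
      within_block_slope = within_block_slope,
      deception_peak = deception_peak,
      mean_nn_ms = mean_nn_ms,
      rmssd_target_ms = rmssd_target_ms,
      lf_mod_amp = lf_mod_amp,
      hf_mod_amp = hf_mod_amp,
      saccade_rate_hz = saccade_rate_hz,
      fixation_rate_hz = fixation_rate_hz,
      blink_rate_hz = blink_rate_hz,
      saccade_amp_deg = saccade_amp_deg,
      saccade_vel_deg_s = saccade_vel_deg_s,
      fixation_dur_ms = fixation_dur_ms,
      blink_dur_ms = blink_dur_ms,
      rt_mean_ms = rt_mean_ms,
      rt_level_slope_ms = rt_level_slope_ms,
      error_prob_by_level = error_prob_by_level,
      self_esteem_bias = self_esteem_bias,
      ess_mean = ess_mean,
      ess_sd = ess_sd,
      smoking_prob = smoking_prob
    ),
    class = "archetype_spec"
  )
}

#' Default archetype pair
#'
#' @return A list of two `archetype_spec` objects (archetypes 0 and 1).
#' @export
default_archetypes <- function() {
  list(
    archetype_spec(
      label = 0L,
      block_start = 1.3, within_block_slope = -1.5, deception_peak = 0,
      mean_nn_ms = 850, rmssd_target_ms = 45,
      lf_mod_amp = 15, hf_mod_amp = 25,
      saccade_rate_hz = 1.6, fixation_rate_hz = 1.8, blink_rate_hz = 0.25,
      saccade_amp_deg = 1.5, saccade_vel_deg_s = 90,
      fixation_dur_ms = 260, blink_dur_ms = 150,
      rt_mean_ms = 2000,
      error_prob_by_level = c(0.05, 0.08, 0.12, 0.18, 0.25, 0.32),
      self_esteem_bias = -0.5,
      ess_mean = 9.8, ess_sd = 3.4, smoking_prob = 0.5
    ),
    archetype_spec(
      label = 1L,
      block_start = -0.8, within_block_slope = 1.2, deception_peak = 1.3,
      mean_nn_ms = 750, rmssd_target_ms = 30,
      lf_mod_amp = 20, hf_mod_amp = 10,
      saccade_rate_hz = 2.0, fixation_rate_hz = 2.2, blink_rate_hz = 0.35,
      saccade_amp_deg = 1.8, saccade_vel_deg_s = 100,
      fixation_dur_ms = 210, blink_dur_ms = 180,
      rt_mean_ms = 2600,
      error_prob_by_level = c(0.02, 0.04, 0.06, 0.10, 0.14, 0.18),
      self_esteem_bias = 0.3,
      ess_mean = 8.0, ess_sd = 3.8, smoking_prob = 0.25
    )
  )
}

#' Default noise configuration for the cohort generator
#'
#' All components scale linearly with `scale`; `scale = 0` yields a
#' deterministic cohort in the pupil channel (identical vectors within an
#' archetype).
#'
#' @param scale Global multiplier applied to every noise component.
#' @return A list with elements `trial_sd_mm` (per-trial pupil noise, mm),
#'   `baseline_sd_mm` (between-participant baseline pupil SD, mm),
#'   `shape_jitter` (between-participant SD of the shape parameters, z-shape
#'   units), `ecg_noise_sd` (ECG baseline noise, fraction of QRS amplitude).
#' @export
default_noise <- function(scale = 1) {
  list(
    trial_sd_mm = 0.15 * scale,
    baseline_sd_mm = 0.30 * scale,
    shape_jitter = 0.12 * scale,
    ecg_noise_sd = 0.05 * scale
  )
}
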