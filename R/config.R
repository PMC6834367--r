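#' Task configuration
#'
#' Describes the offer structure of the safe-vs-risky choice task: reward
#' volumes, the grid of risky reward probabilities, cue mappings, laser
#' scheduling and the inter-trial-interval (ITI) model.
#'
#' Cues follow the task's conventions: the number of light flashes conveys the
#' risky probability (`n_flashes = round(flash_max * p)`, so 0--10 flashes for
#' p in steps of 0.1) and the auditory click rate conveys the water volume
#' (rate in Hz numerically equal to the volume in microliters by default, both
#' spanning 6--48).
#'
#' @param volumes Possible water volumes (uL) offered on each side.
#' @param prob_grid Allowed risky reward probabilities; must be a subset of
#'   `seq(0, 1, by = 0.1)` up to floating-point tolerance.
#' @param p_safe_side_right Probability that the safe port is the right port.
#' @param flash_max Flash count conveying p = 1.
#' @param click_rate_range Range (Hz) of click rates mapped linearly onto the
#'   volume range.
#' @param laser_frac_cue Fraction of trials with laser during the cue period.
#' @param laser_frac_choice Fraction of trials with laser during the choice
#'   report (center-poke exit onward).
#' @param iti_meanlog,iti_sdlog Log-normal ITI parameters (seconds); the
#'   default median is `exp(iti_meanlog)` = 3 s.
#' @param laser_min_iti Minimum ITI (s) imposed after a choice-report-laser
#'   trial, covering the laser illumination that persists into the ITI.
#' @return An object of class `task_config` (a validated list).
#' @examples
#' cfg <- task_config(laser_frac_choice = 0.15)
#' cfg$volumes
#' @export
task_config <- function(volumes = c(6, 12, 24, 48),
                        prob_grid = seq(0, 1, by = 0.1),
                        p_safe_side_right = 0.5,
                        flash_max = 10L,
                        click_rate_range = c(6, 48),
                        laser_frac_cue = 0,
                        laser_frac_choice = 0,
                        iti_meanlog = log(3),
                        iti_sdlog = 0.6,
                        laser_min_iti = 4) {
  if (length(volumes) < 1L || any(volumes <= 0)) {
    stop("`volumes` must be a non-empty set of positive volumes (uL)")
  }
  if (length(prob_grid) < 1L) stop("`prob_grid` must be non-empty")
  grid <- seq(0, 1, by = 0.1)
  if (any(vapply(prob_grid, function(p) min(abs(p - grid)), 0) > 1e-9)) {
    stop("`prob_grid` must be a subset of {0, 0.1, ..., 1}")
  }
  if (p_safe_side_right < 0 || p_safe_side_right > 1) {
    stop("`p_safe_side_right` must be in [0, 1]")
  }
  if (laser_frac_cue < 0 || laser_frac_choice < 0 ||
      laser_frac_cue + laser_frac_choice > 1) {
    stop("laser fractions must be in [0, 1] and sum to at most 1")
  }
  if (laser_min_iti < 0) stop("`laser_min_iti` must be >= 0")
  structure(list(
    volumes = sort(unique(as.numeric(volumes))),
    prob_grid = sort(unique(as.numeric(prob_grid))),
    p_safe_side_right = p_safe_side_right,
    flash_max = as.integer(flash_max),
    click_rate_range = as.numeric(click_rate_range),
    laser_frac_cue = laser_frac_cue,
    laser_frac_choice = laser_frac_choice,
    iti_meanlog = iti_meanlog,
    iti_sdlog = iti_sdlog,
    laser_min_iti = laser_min_iti
  ), class = "task_config")
}

#' Agent parameters for the generative choice rule
#'
#' Weights of the five-term logistic rule the simulated agent uses to choose
#' between the two ports, matching the regressor coding of
#' [build_design_matrix()] exactly (the simulator and the fitted model share
#' one coding function, so planted weights are recoverable):
#' \deqn{p(\mathrm{right}) = \mathrm{lapse}/2 + (1 - \mathrm{lapse})\,
#'   \sigma(w_{ev}\Delta EV + w_{rs} x_{rs} + w_{rws} x_{rws}
#'          + w_{lr} x_{lr} + w_{bias})}
#' The lapse is a uniform mixture outside the logistic, so the weights remain
#' identifiable from simulated data.
#'
#' @param w_ev Weight per uL of expected-value difference (right minus left).
#' @param w_rs_hyst Safe/risky category repetition (hysteresis) weight.
#' @param w_risky_winstay Weight toward the risky side after a rewarded risky
#'   choice (the risky win-stay bias).
#' @param w_lr_hyst Left/right side repetition weight.
#' @param w_lr_bias Constant side bias (positive = rightward).
#' @param lapse Probability of a uniform random choice, in [0, 0.5].
#' @return An object of class `agent_params`.
#' @examples
#' agent_params(w_ev = 0.15, w_risky_winstay = 0.8)
#' @export
agent_params <- function(w_ev = 0.15, w_rs_hyst = 0, w_risky_winstay = 0,
                         w_lr_hyst = 0, w_lr_bias = 0, lapse = 0) {
  w <- c(w_ev, w_rs_hyst, w_risky_winstay, w_lr_hyst, w_lr_bias)
  if (!all(is.finite(w))) stop("all weights must be finite")
  if (lapse < 0 || lapse > 0.5) stop("`lapse` must be in [0, 0.5]")
  structure(list(w_ev = w_ev, w_rs_hyst = w_rs_hyst,
                 w_risky_winstay = w_risky_winstay, w_lr_hyst = w_lr_hyst,
                 w_lr_bias = w_lr_bias, lapse = lapse),
            class = "agent_params")
}

#' Neural population configuration
#'
#' Parameters of the synthetic orbitofrontal-like population: a trial-start
#' transient whose amplitude carries reward history, choice-report selectivity
#' for side / risk / reward receipt, and a rank-1 across-trial gain that is
#' reduced on trials following reward.
#'
#' @param n_units Number of simulated units.
#' @param baseline_hz Baseline firing rate (Hz).
#' @param transient_amp_hz Amplitude (Hz) of the trial-initiation transient.
#' @param frac_history Fraction of units whose transient is modulated by the
#'   previous trial's outcome.
#' @param history_gain Multiplicative boost of the transient after an
#'   unrewarded previous trial (0.5 means 50% larger).
#' @param frac_side,frac_risk,frac_reward Fractions of units selective, at the
#'   choice report, for chosen side, risky-vs-safe choice, and reward receipt.
#' @param select_amp_hz Amplitude (Hz) of choice-report selectivity bumps.
#' @param trial_gain_gamma Reduction of the shared across-trial gain on trials
#'   after a rewarded trial (the planted rank-1 trial factor), in [0, 1).
#' @param trial_gain_sd S.d. of multiplicative trial-gain noise.
#' @return An object of class `neural_config`.
#' @export
neural_config <- function(n_units = 40L, baseline_hz = 5,
                          transient_amp_hz = 10, frac_history = 0.35,
                          history_gain = 0.5, frac_side = 0.4,
                          frac_risk = 0.1, frac_reward = 0.3,
                          select_amp_hz = 8, trial_gain_gamma = 0,
                          trial_gain_sd = 0.05) {
  fr <- c(frac_history, frac_side, frac_risk, frac_reward)
  if (any(fr < 0 | fr > 1)) stop("selectivity fractions must be in [0, 1]")
  if (baseline_hz < 0 || transient_amp_hz < 0 || select_amp_hz < 0) {
    stop("rates must be >= 0")
  }
  if (trial_gain_gamma < 0 || trial_gain_gamma >= 1) {
    stop("`trial_gain_gamma` must be in [0, 1)")
  }
  structure(list(n_units = as.integer(n_units), baseline_hz = baseline_hz,
                 transient_amp_hz = transient_amp_hz,
                 frac_history = frac_history, history_gain = history_gain,
                 frac_side = frac_side, frac_risk = frac_risk,
                 frac_reward = frac_reward, select_amp_hz = select_amp_hz,
                 trial_gain_gamma = trial_gain_gamma,
                 trial_gain_sd = trial_gain_sd),
            class = "neural_config")
}

#' Waveform drift-simulation configuration
#'
#' @param n_samples Samples per tetrode channel (>= 8).
#' @param amp_drift_sd Per-session, per-channel log-amplitude drift s.d.
#' @param shape_jitter_sd S.d. of additive shape noise, relative to the peak
#'   amplitude of the base template.
#' @return An object of class `waveform_sim_config`.
#' @export
waveform_sim_config <- function(n_samples = 32L, amp_drift_sd = 0.08,
                                shape_jitter_sd = 0.02) {
  if (n_samples < 8L) stop("`n_samples` must be >= 8")
  if (amp_drift_sd < 0 || shape_jitter_sd < 0) stop("s.d. values must be >= 0")
  structure(list(n_samples = as.integer(n_samples),
                 amp_drift_sd = amp_drift_sd,
                 shape_jitter_sd = shape_jitter_sd),
            class = "waveform_sim_config")
}
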