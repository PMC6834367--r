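#' Generate task offers
#'
#' Draws a sequence of safe-vs-risky offers. Volumes on the two sides are
#' drawn uniformly and independently from `config$volumes`, the risky
#' probability uniformly from `config$prob_grid`, and the safe side is
#' Bernoulli(`config$p_safe_side_right`). Flash counts and click rates are
#' derived deterministically from the cue mappings recorded in the config.
#' Choice-related columns are returned unset (`NA`); [simulate_agent()] fills
#' them in.
#'
#' @param n_trials Number of trials (>= 1).
#' @param config A [task_config()].
#' @param seed Integer seed; identical seeds give identical offer sequences.
#' @return A data.frame with one row per trial: `trial_index`, `safe_side`,
#'   `safe_volume`, `risky_volume`, `risky_prob`, `n_flashes_risky`,
#'   `click_rate_left`, `click_rate_right`, and unset `choice_side`,
#'   `chose_safe`, `rewarded`, `reward_volume`, `laser_epoch`, `iti_s`.
#' @examples
#' offers <- generate_offers(5, task_config(), seed = 1)
#' offers$risky_prob
#' @export
generate_offers <- function(n_trials, config = task_config(), seed = NULL) {
  stopifnot(inherits(config, "task_config"))
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop("`n_trials` must be >= 1")
  with_seed(seed, {
    safe_side <- ifelse(
      stats::runif(n_trials) < config$p_safe_side_right, "right", "left")
    safe_volume <- sample(config$volumes, n_trials, replace = TRUE)
    risky_volume <- sample(config$volumes, n_trials, replace = TRUE)
    risky_prob <- sample(config$prob_grid, n_trials, replace = TRUE)
    n_flashes <- as.integer(round(config$flash_max * risky_prob))
    # click rate conveys volume: linear map from the volume range onto the
    # click-rate range (identical ranges by default, so rate == volume)
    vr <- range(config$volumes)
    cr <- config$click_rate_range
    rate_of <- function(v) {
      if (diff(vr) == 0) return(rep(mean(cr), length(v)))
      cr[1] + (v - vr[1]) / diff(vr) * diff(cr)
    }
    rate_safe <- rate_of(safe_volume)
    rate_risky <- rate_of(risky_volume)
    right_is_safe <- safe_side == "right"
    data.frame(
      trial_index = seq_len(n_trials),
      safe_side = safe_side,
      safe_volume = safe_volume,
      risky_volume = risky_volume,
      risky_prob = risky_prob,
      n_flashes_risky = n_flashes,
      click_rate_left = ifelse(right_is_safe, rate_risky, rate_safe),
      click_rate_right = ifelse(right_is_safe, rate_safe, rate_risky),
      choice_side = NA_character_,
      chose_safe = NA,
      rewarded = NA,
      reward_volume = NA_real_,
      laser_epoch = NA_character_,
      iti_s = NA_real_,
      stringsAsFactors = FALSE
    )
  })
}
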