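# Shared fixtures and independent oracles for the test suite.

# Six-trial hand-coded session. Post-risky-reward trials (2, 3) both choose
# risky; post-safe-reward trials (5, 6) both choose safe; trial 4 follows an
# unrewarded risky choice and enters no conditional estimator.
fixture_trials <- function() {
  data.frame(
    trial_index = 1:6,
    safe_side   = c("right", "left", "right", "right", "left", "right"),
    safe_volume = c(12, 24, 12, 6, 48, 12),
    risky_volume = c(24, 48, 24, 12, 24, 48),
    risky_prob  = c(0.5, 0.8, 0.5, 0.2, 0.5, 0.9),
    n_flashes_risky = c(5L, 8L, 5L, 2L, 5L, 9L),
    click_rate_left = c(24, 24, 24, 12, 48, 48),
    click_rate_right = c(12, 48, 12, 6, 24, 12),
    choice_side = c("left", "right", "left", "right", "left", "right"),
    chose_safe  = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    rewarded    = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    reward_volume = c(24, 48, 0, 6, 48, 12),
    laser_epoch = "none",
    iti_s = 3,
    stringsAsFactors = FALSE
  )
}

# Brute-force conditional-frequency oracle: a plain loop over the trial
# sequence, independent of the package's estimator code.
oracle_cond_freqs <- function(trials) {
  n <- nrow(trials)
  post_safe_safe <- post_safe_n <- 0
  post_risky_safe <- post_risky_n <- 0
  rep_win <- win_n <- 0
  sw_loss <- loss_n <- 0
  rep_all <- all_n <- 0
  for (i in 2:n) {
    all_n <- all_n + 1
    repeated <- trials$choice_side[i] == trials$choice_side[i - 1]
    rep_all <- rep_all + repeated
    if (trials$rewarded[i - 1]) {
      win_n <- win_n + 1
      rep_win <- rep_win + repeated
      if (trials$chose_safe[i - 1]) {
        post_safe_n <- post_safe_n + 1
        post_safe_safe <- post_safe_safe + trials$chose_safe[i]
      } else {
        post_risky_n <- post_risky_n + 1
        post_risky_safe <- post_risky_safe + trials$chose_safe[i]
      }
    } else {
      loss_n <- loss_n + 1
      sw_loss <- sw_loss + !repeated
    }
  }
  list(
    p_safe_post_safe = post_safe_safe / post_safe_n,
    n_post_safe = post_safe_n,
    p_safe_post_risky = post_risky_safe / post_risky_n,
    n_post_risky = post_risky_n,
    p_repeat_win = rep_win / win_n, n_win = win_n,
    p_switch_loss = sw_loss / loss_n, n_loss = loss_n,
    p_repeat_all = rep_all / all_n, n_all = all_n
  )
}

# Independent re-implementation of the generative choice rule, written as a
# direct per-trial loop with its own regressor arithmetic (no calls into the
# package's coding function).
oracle_simulate_agent <- function(offers, w_ev, w_rs, w_rws, w_lr, w_bias,
                                  lapse = 0, seed = 1) {
  set.seed(seed)
  n <- nrow(offers)
  ev_safe <- offers$safe_volume
  ev_risky <- offers$risky_prob * offers$risky_volume
  safe_right <- offers$safe_side == "right"
  ev_right <- ifelse(safe_right, ev_safe, ev_risky)
  ev_left <- ifelse(safe_right, ev_risky, ev_safe)
  choice_right <- logical(n)
  chose_safe <- logical(n)
  rewarded <- logical(n)
  for (i in 1:n) {
    eta <- w_ev * (ev_right[i] - ev_left[i]) + w_bias
    if (i > 1) {
      eta <- eta + w_lr * (if (choice_right[i - 1]) 1 else -1)
      cat_sign <- if (chose_safe[i - 1]) 1 else -1
      eta <- eta + w_rs * cat_sign * (if (safe_right[i]) 1 else -1)
      if (rewarded[i - 1] && !chose_safe[i - 1]) {
        eta <- eta + w_rws * (if (safe_right[i]) -1 else 1)
      }
    }
    p_right <- lapse / 2 + (1 - lapse) / (1 + exp(-eta))
    choice_right[i] <- runif(1) < p_right
    chose_safe[i] <- choice_right[i] == safe_right[i]
    rewarded[i] <- if (chose_safe[i]) TRUE else runif(1) < offers$risky_prob[i]
  }
  out <- offers
  out$choice_side <- ifelse(choice_right, "right", "left")
  out$chose_safe <- chose_safe
  out$rewarded <- rewarded
  out$reward_volume <- ifelse(chose_safe, offers$safe_volume,
                              ifelse(rewarded, offers$risky_volume, 0))
  out$laser_epoch <- "none"
  out$iti_s <- 3
  out
}

# Standard error of a difference of two independent proportions.
se_diff <- function(p1, n1, p2, n2) {
  sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
}
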