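# The regressor coding is defined once, here, and shared verbatim by the
# generative agent and the fitted choice model (round-trip identity).

# Vectorized coding of the four history/value regressors for trial t given
# trial t-1. Signs: positive regressor values push toward the RIGHT port.
#   dEV   : EV_right - EV_left (uL)
#   x_rs  : repeat the previous safe/risky category => choose right?
#   x_rws : after a rewarded risky choice, risky side right => +1
#   x_lr  : previous choice was right => +1
code_regressors <- function(dEV, prev_choice_right, prev_chose_safe,
                            prev_rewarded, safe_right_now) {
  x_lr <- ifelse(prev_choice_right, 1, -1)
  x_rs <- ifelse(prev_chose_safe, 1, -1) * ifelse(safe_right_now, 1, -1)
  risky_right_now <- !safe_right_now
  x_rws <- as.numeric(prev_rewarded & !prev_chose_safe) *
    ifelse(risky_right_now, 1, -1)
  cbind(dEV = dEV, x_rs = x_rs, x_rws = x_rws, x_lr = x_lr)
}

#' Simulate a biased agent on a sequence of offers
#'
#' Plays out the generative choice rule of [agent_params()] trial by trial:
#' the probability of choosing right is a lapse-mixed logistic of the
#' expected-value difference and the three history regressors (safe/risky
#' hysteresis, risky win-stay, side hysteresis) plus a side bias, using the
#' same regressor coding as [build_design_matrix()]. Safe choices are always
#' rewarded with the safe volume; risky choices pay the risky volume with the
#' cued probability. Laser epochs are assigned at the configured fractions and
#' ITIs are drawn log-normally, with the minimum ITI after choice-report-laser
#' trials enforced.
#'
#' @param offers Offer table from [generate_offers()].
#' @param params An [agent_params()].
#' @param config The [task_config()] (laser fractions, ITI model).
#' @param seed Integer seed for reproducibility.
#' @param post_laser_params Optional [agent_params()] used on trials whose
#'   PREVIOUS trial carried a laser epoch in `post_laser_epochs` — i.e. a
#'   planted next-trial effect of the perturbation.
#' @param post_laser_epochs Epochs that trigger `post_laser_params`.
#' @param history_regressors Which history regressors the first trial lacks
#'   are always zeroed there; no other options.
#' @return The offers data.frame with `choice_side`, `chose_safe`, `rewarded`,
#'   `reward_volume`, `laser_epoch` and `iti_s` filled in, ordered per
#'   session.
#' @examples
#' off <- generate_offers(200, seed = 1)
#' beh <- simulate_agent(off, agent_params(w_ev = 0.2), seed = 2)
#' mean(beh$chose_safe)
#' @export
simulate_agent <- function(offers, params = agent_params(),
                           config = task_config(), seed = NULL,
                           post_laser_params = NULL,
                           post_laser_epochs = c("cue", "choice_report"),
                           history_regressors = NULL) {
  stopifnot(inherits(params, "agent_params"),
            inherits(config, "task_config"))
  stopifnot_trials(offers, need_choices = FALSE)
  n <- nrow(offers)
  ev <- offer_evs(offers)
  dEV <- ev$ev_right - ev$ev_left
  safe_right <- offers$safe_side == "right"

  with_seed(seed, {
    # laser assignment is independent of behavior
    u <- stats::runif(n)
    laser <- rep("none", n)
    laser[u < config$laser_frac_cue] <- "cue"
    laser[u >= config$laser_frac_cue &
            u < config$laser_frac_cue + config$laser_frac_choice] <-
      "choice_report"
    iti <- stats::rlnorm(n, config$iti_meanlog, config$iti_sdlog)
    iti[laser == "choice_report"] <-
      pmax(iti[laser == "choice_report"], config$laser_min_iti)

    choice_right <- logical(n)
    chose_safe <- logical(n)
    rewarded <- logical(n)
    reward_volume <- numeric(n)
    u_choice <- stats::runif(n)
    u_lapse <- stats::runif(n)
    u_lapse_side <- stats::runif(n)
    u_reward <- stats::runif(n)

    for (i in seq_len(n)) {
      p <- if (i == 1L) {
        params
      } else if (!is.null(post_laser_params) &&
                 laser[i - 1L] %in% post_laser_epochs) {
        post_laser_params
      } else {
        params
      }
      if (i == 1L) {
        x <- c(dEV = dEV[1L], x_rs = 0, x_rws = 0, x_lr = 0)
      } else {
        x <- code_regressors(dEV[i], choice_right[i - 1L],
                             chose_safe[i - 1L], rewarded[i - 1L],
                             safe_right[i])[1L, ]
      }
      eta <- p$w_ev * x[["dEV"]] + p$w_rs_hyst * x[["x_rs"]] +
        p$w_risky_winstay * x[["x_rws"]] + p$w_lr_hyst * x[["x_lr"]] +
        p$w_lr_bias
      if (u_lapse[i] < p$lapse) {
        choice_right[i] <- u_lapse_side[i] < 0.5
      } else {
        choice_right[i] <- u_choice[i] < logistic(eta)
      }
      chose_safe[i] <- choice_right[i] == safe_right[i]
      if (chose_safe[i]) {
        rewarded[i] <- TRUE
        reward_volume[i] <- offers$safe_volume[i]
      } else {
        rewarded[i] <- u_reward[i] < offers$risky_prob[i]
        reward_volume[i] <- if (rewarded[i]) offers$risky_volume[i] else 0
      }
    }

    out <- offers
    out$choice_side <- ifelse(choice_right, "right", "left")
    out$chose_safe <- chose_safe
    out$rewarded <- rewarded
    out$reward_volume <- reward_volume
    out$laser_epoch <- laser
    out$iti_s <- iti
    out
  })
}
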