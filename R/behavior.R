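#' Choice efficiency of a session
#'
#' Normalizes the mean expected value (EV) per trial obtained by the subject
#' between two reference agents on the same offers: one choosing randomly
#' between the two ports and one always taking the higher-EV port:
#' \deqn{\mathrm{efficiency} = 0.5\,\frac{ratEV - randEV}{maxEV - randEV} + 0.5}
#' so a random chooser scores 0.5 and an EV maximizer scores 1.
#'
#' @param trials A completed trials table (see [simulate_agent()]).
#' @return An object of class `efficiency_summary`: `rat_ev_per_trial`,
#'   `rand_ev_per_trial`, `max_ev_per_trial`, `efficiency`.
#' @examples
#' beh <- simulate_agent(generate_offers(500, seed = 1),
#'                       agent_params(w_ev = 5), seed = 2)
#' compute_efficiency(beh)$efficiency
#' @export
compute_efficiency <- function(trials) {
  stopifnot_trials(trials)
  ev <- offer_evs(trials)
  chosen_ev <- ifelse(trials$chose_safe, ev$ev_safe, ev$ev_risky)
  rat <- mean(chosen_ev)
  rand <- mean((ev$ev_left + ev$ev_right) / 2)
  mx <- mean(pmax(ev$ev_left, ev$ev_right))
  structure(list(rat_ev_per_trial = rat, rand_ev_per_trial = rand,
                 max_ev_per_trial = mx,
                 efficiency = efficiency_from_ev(rat, rand, mx)),
            class = "efficiency_summary")
}

#' @rdname compute_efficiency
#' @param rat_ev,rand_ev,max_ev Mean EV per trial of the subject, the
#'   random-choice agent, and the EV-maximizing agent.
#' @export
efficiency_from_ev <- function(rat_ev, rand_ev, max_ev) {
  if (max_ev == rand_ev) {
    stop("efficiency undefined: the maximizer and random agent obtain the ",
         "same EV per trial (identical offers on both sides)")
  }
  0.5 * (rat_ev - rand_ev) / (max_ev - rand_ev) + 0.5
}

#' @export
print.efficiency_summary <- function(x, ...) {
  cat(sprintf(
    "Session efficiency: %.3f\n  rat %.2f | random %.2f | maximizer %.2f uL/trial\n",
    x$efficiency, x$rat_ev_per_trial, x$rand_ev_per_trial,
    x$max_ev_per_trial))
  invisible(x)
}

#' Performance criterion threshold over training sessions
#'
#' Threshold = median efficiency of all sessions minus 1.5 times the
#' interquartile range of the second half of sessions (linear-interpolation,
#' type-7 quartiles). Sessions below threshold are flagged for exclusion.
#'
#' @param session_efficiencies Ordered numeric vector of per-session
#'   efficiencies (>= 2 sessions).
#' @return List with `threshold` and logical `excluded` per session.
#' @examples
#' criterion_threshold(c(0.6, 0.7, 0.8, 0.9))$threshold # 0.675
#' @export
criterion_threshold <- function(session_efficiencies) {
  x <- as.numeric(session_efficiencies)
  n <- length(x)
  if (n < 2L) stop("need at least 2 sessions")
  second_half <- x[(floor(n / 2) + 1L):n]
  iqr2 <- stats::IQR(second_half, type = 7)
  thr <- stats::median(x) - 1.5 * iqr2
  list(threshold = thr, excluded = x < thr)
}

#' Normal-approximation 95% CI half-width for a difference of proportions
#'
#' \eqn{z \sqrt{p_1(1-p_1)/n_1 + p_2(1-p_2)/n_2}}; used for all conditional
#' choice-probability differences.
#'
#' @param p1,n1,p2,n2 Conditional proportions and their trial counts.
#' @param z Normal quantile; default the 97.5% quantile to 5 significant
#'   digits (1.96).
#' @return The half-width of the CI on `p1 - p2`.
#' @examples
#' binomial_ci(0.5, 100, 0.5, 100) # 0.1386
#' @export
binomial_ci <- function(p1, n1, p2, n2, z = signif(stats::qnorm(0.975), 5)) {
  if (any(c(n1, n2) < 1)) stop("both counts must be >= 1")
  if (any(c(p1, p2) < 0 | c(p1, p2) > 1)) stop("proportions must be in [0, 1]")
  z * sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
}

# Constructor for a conditional-probability-difference estimate. Undefined
# (zero-count) estimates carry NA value and undefined = TRUE rather than
# erroring, so session-level sweeps can proceed.
bias_estimate <- function(label, p1, n1, p2, n2, baseline = NA_real_,
                          n_baseline = NA_integer_) {
  undefined <- n1 == 0L || n2 == 0L
  value <- if (undefined) NA_real_ else p1 - p2
  ci <- if (undefined) NA_real_ else binomial_ci(p1, n1, p2, n2)
  structure(list(label = label, p1 = p1, n1 = n1, p2 = p2, n2 = n2,
                 value = value, ci95 = ci, baseline = baseline,
                 n_baseline = n_baseline,
                 delta1 = p1 - baseline, delta2 = p2 - baseline,
                 undefined = undefined),
            class = "bias_estimate")
}

#' @export
print.bias_estimate <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("%s: undefined (n1 = %d, n2 = %d)\n", x$label, x$n1, x$n2))
  } else {
    cat(sprintf("%s: %.4f +/- %.4f  [p1 = %.3f (n = %d), p2 = %.3f (n = %d)]\n",
                x$label, x$value, x$ci95, x$p1, x$n1, x$p2, x$n2))
  }
  invisible(x)
}

# Previous-trial context vectors, aligned to current trials (first trial has
# no context and never enters a conditional estimator).
prev_context <- function(trials) {
  n <- nrow(trials)
  list(
    has_prev = c(FALSE, rep(TRUE, n - 1L)),
    prev_chose_safe = c(NA, trials$chose_safe[-n]),
    prev_rewarded = c(NA, trials$rewarded[-n]),
    prev_choice_side = c(NA, trials$choice_side[-n]),
    prev_risky_prob = c(NA, trials$risky_prob[-n]),
    prev_laser = c(NA, trials$laser_epoch[-n]),
    prev_iti = c(NA, trials$iti_s[-n])
  )
}

#' Risky win-stay bias
#'
#' Difference in the probability of choosing the safe option depending on the
#' previous trial's reward source:
#' `P(choose safe | previous trial a rewarded SAFE choice) -
#'  P(choose safe | previous trial a rewarded RISKY choice)`.
#' A positive value means the subject gambles more after risky wins than after
#' guaranteed rewards — the risky win-stay bias. The per-condition deltas
#' relative to the unconditional P(choose safe) are returned as `delta1` /
#' `delta2`.
#'
#' @param trials Completed trials table.
#' @param mask Optional logical vector selecting which (current) trials enter
#'   the estimate, e.g. post-laser trials; default all.
#' @return A `bias_estimate`.
#' @examples
#' beh <- simulate_agent(generate_offers(5000, seed = 1),
#'                       agent_params(w_risky_winstay = 1), seed = 2)
#' risky_winstay_bias(beh)
#' @export
risky_winstay_bias <- function(trials, mask = NULL) {
  stopifnot_trials(trials)
  pc <- prev_context(trials)
  if (is.null(mask)) mask <- rep(TRUE, nrow(trials))
  elig <- mask & pc$has_prev
  post_safe <- elig & pc$prev_chose_safe & pc$prev_rewarded
  post_risky <- elig & !pc$prev_chose_safe & pc$prev_rewarded
  n1 <- sum(post_safe); n2 <- sum(post_risky)
  p1 <- if (n1) mean(trials$chose_safe[post_safe]) else NA_real_
  p2 <- if (n2) mean(trials$chose_safe[post_risky]) else NA_real_
  nb <- sum(elig)
  bias_estimate("risky win-stay", p1, n1, p2, n2,
                baseline = mean(trials$chose_safe[elig]), n_baseline = nb)
}

#' Spatial win-stay and lose-switch biases
#'
#' Change in the probability of repeating the previously chosen port after a
#' rewarded trial (win-stay), and of switching ports after an unrewarded trial
#' (lose-switch), each relative to the corresponding session-wide probability.
#'
#' @inheritParams risky_winstay_bias
#' @return List with `bias_estimate`s `win_stay` and `lose_switch`.
#' @export
spatial_winstay_lose_switch <- function(trials, mask = NULL) {
  stopifnot_trials(trials)
  pc <- prev_context(trials)
  if (is.null(mask)) mask <- rep(TRUE, nrow(trials))
  elig <- mask & pc$has_prev
  repeated <- trials$choice_side == pc$prev_choice_side
  n_all <- sum(elig)
  if (n_all == 0L) stop("no eligible trials")
  p_rep_all <- mean(repeated[elig])
  post_win <- elig & pc$prev_rewarded
  post_loss <- elig & !pc$prev_rewarded
  n_w <- sum(post_win); n_l <- sum(post_loss)
  p_rep_win <- if (n_w) mean(repeated[post_win]) else NA_real_
  p_sw_loss <- if (n_l) mean(!repeated[post_loss]) else NA_real_
  list(
    win_stay = bias_estimate("spatial win-stay", p_rep_win, n_w,
                             p_rep_all, n_all, baseline = p_rep_all,
                             n_baseline = n_all),
    lose_switch = bias_estimate("spatial lose-switch", p_sw_loss, n_l,
                                1 - p_rep_all, n_all,
                                baseline = 1 - p_rep_all, n_baseline = n_all)
  )
}

#' Graded dependence of the risky win-stay bias on gamble probability
#'
#' Bins trials following a rewarded risky choice by the probability of the
#' gamble that won, computes the post-risky-win probability of gambling again
#' relative to the session baseline in each bin, and fits an ordinary
#' least-squares line of that delta against the probability.
#'
#' @param trials Completed trials table.
#' @param min_n Minimum trials per probability bin to include it.
#' @return Object of class `graded_bias`: data.frame `bins` (`prob`,
#'   `p_gamble`, `n`, `delta`), plus `slope`, `intercept`, `baseline`.
#' @export
graded_winstay_by_prob <- function(trials, min_n = 1L) {
  stopifnot_trials(trials)
  pc <- prev_context(trials)
  elig <- pc$has_prev
  gamble <- !trials$chose_safe
  baseline <- mean(gamble[elig])
  post_rw <- elig & !pc$prev_chose_safe & pc$prev_rewarded
  probs <- sort(unique(pc$prev_risky_prob[post_rw]))
  probs <- probs[probs > 0]
  rows <- lapply(probs, function(p) {
    sel <- post_rw & abs(pc$prev_risky_prob - p) < 1e-9
    n <- sum(sel)
    if (n < min_n) return(NULL)
    data.frame(prob = p, p_gamble = mean(gamble[sel]), n = n,
               delta = mean(gamble[sel]) - baseline)
  })
  bins <- do.call(rbind, rows)
  if (is.null(bins) || nrow(bins) < 2L) {
    stop("fewer than 2 populated probability bins; slope undefined")
  }
  fit <- stats::lm(delta ~ prob, data = bins)
  structure(list(bins = bins, slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 baseline = baseline),
            class = "graded_bias")
}

#' @export
print.graded_bias <- function(x, ...) {
  cat(sprintf("Risky win-stay vs gamble probability: slope %.4f (intercept %.4f)\n",
              x$slope, x$intercept))
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' Laser-vs-control comparison of sequential biases
#'
#' Computes a bias estimator on trials whose PREVIOUS trial carried the stated
#' laser epoch, and on control trials (previous trial without laser). With
#' `iti_matched = TRUE`, control trials are restricted to those whose previous
#' trial's ITI was at least `min_iti` seconds, mirroring the minimum ITI that
#' choice-report illumination imposes — the appropriate control when a bias
#' decays with time between trials.
#'
#' @param trials Completed trials table with `laser_epoch` and `iti_s`.
#' @param epoch `"cue"` or `"choice_report"`.
#' @param bias Which estimator: `"risky_winstay"` or `"spatial"`.
#' @param iti_matched Restrict controls to previous-ITI >= `min_iti`?
#' @param min_iti Seconds; default 4.
#' @return List with elements `control` and `laser`, each the estimator's
#'   return value.
#' @export
laser_comparison <- function(trials, epoch = c("choice_report", "cue"),
                             bias = c("risky_winstay", "spatial"),
                             iti_matched = FALSE, min_iti = 4) {
  epoch <- match.arg(epoch)
  bias <- match.arg(bias)
  stopifnot_trials(trials)
  pc <- prev_context(trials)
  laser_mask <- pc$has_prev & pc$prev_laser == epoch
  if (!any(laser_mask, na.rm = TRUE)) {
    stop("no trials follow a '", epoch, "' laser trial")
  }
  control_mask <- pc$has_prev & pc$prev_laser == "none"
  if (iti_matched) control_mask <- control_mask & pc$prev_iti >= min_iti
  laser_mask[is.na(laser_mask)] <- FALSE
  control_mask[is.na(control_mask)] <- FALSE
  est <- switch(bias,
                risky_winstay = risky_winstay_bias,
                spatial = spatial_winstay_lose_switch)
  list(control = est(trials, mask = control_mask),
       laser = est(trials, mask = laser_mask))
}
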