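#' Simulate a population of task-modulated Poisson units
#'
#' Generates spike trains for `config$n_units` units across the trials of a
#' completed session. Each unit's instantaneous rate on trial k is
#' \deqn{g_k [\mathrm{baseline} + \mathrm{transient}(t)(1 +
#'   \mathrm{history\_gain}\,1(\mathrm{prev~unrewarded})) +
#'   \mathrm{selectivity}(t)]}
#' with a Gaussian transient after trial initiation (reward-history units fire
#' more after unrewarded trials), Gaussian selectivity bumps after center-poke
#' exit (side / risky-vs-safe / reward-receipt units), and a shared
#' across-trial gain \eqn{g_k = 1 - \gamma\,1(\mathrm{prev~rewarded}) +
#' \epsilon_k} — an exactly rank-1 trial modulation. Negative instantaneous
#' rates are clipped to 0 and counted.
#'
#' @param behavior Completed trials table from [simulate_agent()].
#' @param config A [neural_config()].
#' @param seed Integer seed.
#' @param t_center_exit Time (s) of center-poke exit after initiation.
#' @param t_trial_end Trial duration (s) after initiation.
#' @param dt Generation time step (s).
#' @return List with `spikes` (data.frame `unit_id`, `trial`, `time_s` —
#'   times absolute within the session), `events` (per trial: `trial`,
#'   `trial_init`, `center_exit`, `trial_end`, absolute seconds), `truth`
#'   (per unit: planted selectivity labels and preferences), `gain`
#'   (per-trial shared gain g_k), `n_clipped` (rate samples clipped at 0).
#' @examples
#' beh <- simulate_agent(generate_offers(50, seed = 1), seed = 2)
#' pop <- simulate_population(beh, neural_config(n_units = 4), seed = 3)
#' table(pop$spikes$unit_id)
#' @export
simulate_population <- function(behavior, config = neural_config(),
                                seed = NULL, t_center_exit = 1.5,
                                t_trial_end = 3, dt = 0.005) {
  stopifnot_trials(behavior)
  stopifnot(inherits(config, "neural_config"))
  K <- nrow(behavior)
  if (K < 1L) stop("behavior table is empty")
  prev_rew <- c(FALSE, behavior$rewarded[-K])
  prev_unrew <- c(FALSE, !behavior$rewarded[-K])
  with_seed(seed, {
    nu <- config$n_units
    truth <- data.frame(
      unit_id = seq_len(nu),
      history = stats::runif(nu) < config$frac_history,
      side = stats::runif(nu) < config$frac_side,
      risk = stats::runif(nu) < config$frac_risk,
      reward = stats::runif(nu) < config$frac_reward
    )
    # preferred condition of each selective unit; history units prefer
    # no-reward (the transient grows after unrewarded trials)
    truth$side_pref <- ifelse(stats::runif(nu) < 0.5, "right", "left")
    truth$risk_pref <- ifelse(stats::runif(nu) < 0.5, "risky", "safe")
    truth$reward_pref <- ifelse(stats::runif(nu) < 0.5, "rewarded",
                                "unrewarded")
    gain <- 1 - config$trial_gain_gamma * as.numeric(prev_rew) +
      stats::rnorm(K, 0, config$trial_gain_sd)
    gain <- pmax(gain, 0)

    tgrid <- seq(dt / 2, t_trial_end - dt / 2, by = dt)
    nb <- length(tgrid)
    transient <- exp(-(tgrid - 0.15)^2 / (2 * 0.12^2))
    bump <- exp(-(tgrid - (t_center_exit + 0.25))^2 / (2 * 0.15^2))
    trial_starts <- (seq_len(K) - 1L) * (t_trial_end + 1)

    n_clipped <- 0L
    sp <- vector("list", nu)
    for (u in seq_len(nu)) {
      hist_mult <- if (truth$history[u]) {
        1 + config$history_gain * as.numeric(prev_unrew)
      } else rep(1, K)
      sel_on <- rep(0, K)
      if (truth$side[u]) {
        sel_on <- sel_on + (behavior$choice_side == truth$side_pref[u])
      }
      if (truth$risk[u]) {
        chose_risky <- !behavior$chose_safe
        sel_on <- sel_on + ((truth$risk_pref[u] == "risky") == chose_risky)
      }
      if (truth$reward[u]) {
        sel_on <- sel_on +
          ((truth$reward_pref[u] == "rewarded") == behavior$rewarded)
      }
      # trials x bins rate matrix
      rate <- gain * (config$baseline_hz +
                        config$transient_amp_hz * outer(hist_mult, transient) +
                        config$select_amp_hz * outer(sel_on, bump))
      neg <- rate < 0
      if (any(neg)) {n_clipped <- n_clipped + sum(neg); rate[neg] <- 0}
      counts <- matrix(stats::rpois(K * nb, rate * dt), nrow = K)
      nz <- which(counts > 0, arr.ind = TRUE)
      if (nrow(nz)) {
        reps <- counts[nz]
        tr <- rep(nz[, 1L], reps)
        tb <- rep(nz[, 2L], reps)
        times <- trial_starts[tr] + tgrid[tb] +
          stats::runif(length(tb), -dt / 2, dt / 2)
        sp[[u]] <- data.frame(unit_id = u, trial = tr, time_s = times)
      }
    }
    spikes <- do.call(rbind, sp)
    spikes <- spikes[order(spikes$unit_id, spikes$time_s), , drop = FALSE]
    rownames(spikes) <- NULL
    events <- data.frame(trial = seq_len(K),
                         trial_init = trial_starts,
                         center_exit = trial_starts + t_center_exit,
                         trial_end = trial_starts + t_trial_end)
    list(spikes = spikes, events = events, truth = truth, gain = gain,
         n_clipped = n_clipped)
  })
}
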