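test_that("efficiency formula hits its anchor points", {
  # direct arithmetic: 0.5 * (18 - 15) / (20 - 15) + 0.5 = 0.8
  expect_equal(efficiency_from_ev(18, 15, 20), 0.8)
  # random-equivalent agent scores exactly 0.5, maximizer exactly 1
  expect_equal(efficiency_from_ev(15, 15, 20), 0.5)
  expect_equal(efficiency_from_ev(20, 15, 20), 1.0)
  expect_error(efficiency_from_ev(10, 10, 10), "undefined")
})

test_that("session efficiency is order-invariant and increasing in ratEV", {
  beh <- simulate_agent(generate_offers(500, seed = 1),
                        agent_params(w_ev = 0.2), seed = 2)
  e1 <- compute_efficiency(beh)
  perm <- beh[sample(nrow(beh)), ]
  perm$trial_index <- seq_len(nrow(perm))
  e2 <- compute_efficiency(perm)
  expect_equal(e1$efficiency, e2$efficiency)
  # flipping one bad choice to the better side can only raise efficiency
  ev_safe <- beh$safe_volume
  ev_risky <- beh$risky_prob * beh$risky_volume
  bad <- which(beh$chose_safe & ev_risky > ev_safe)[1]
  beh2 <- beh
  beh2$chose_safe[bad] <- FALSE
  beh2$choice_side[bad] <- ifelse(beh2$safe_side[bad] == "right", "left",
                                  "right")
  beh2$rewarded[bad] <- TRUE
  beh2$reward_volume[bad] <- beh2$risky_volume[bad]
  expect_gt(compute_efficiency(beh2)$efficiency, e1$efficiency)
})

test_that("criterion threshold follows the median-minus-1.5-IQR rule", {
  expect_equal(criterion_threshold(rep(0.8, 6))$threshold, 0.8)
  # hand computation under type-7 quartiles
  res <- criterion_threshold(c(0.6, 0.7, 0.8, 0.9))
  expect_equal(res$threshold, 0.675)
  expect_identical(res$excluded, c(TRUE, FALSE, FALSE, FALSE))
  # only the second half enters the IQR term
  a <- criterion_threshold(c(0.6, 0.7, 0.8, 0.9))
  b <- criterion_threshold(c(0.7, 0.6, 0.8, 0.9))
  expect_equal(a$threshold, b$threshold)
  expect_error(criterion_threshold(0.8), "at least 2")
})

test_that("binomial CI half-width matches hand arithmetic and shrinks", {
  expect_equal(binomial_ci(0.5, 100, 0.5, 100, z = 1.96), 0.1385929,
               tolerance = 1e-6)
  expect_equal(binomial_ci(0, 50, 1, 80), 0)
  w <- vapply(c(1e2, 1e3, 1e4, 1e5),
              function(n) binomial_ci(0.4, n, 0.6, n), 0)
  expect_true(all(diff(w) < 0))
  expect_error(binomial_ci(0.5, 0, 0.5, 10), "counts")
})

test_that("risky win-stay bias on the hand fixture is exactly 1", {
  rb <- risky_winstay_bias(fixture_trials())
  expect_equal(rb$p1, 1); expect_equal(rb$n1, 2L)
  expect_equal(rb$p2, 0); expect_equal(rb$n2, 2L)
  expect_equal(rb$value, 1.0)
})

test_that("bias estimators agree with the brute-force oracle on simulation", {
  beh <- simulate_agent(generate_offers(30000, seed = 21),
                        agent_params(w_ev = 0.1, w_risky_winstay = 0.8,
                                     w_lr_hyst = 0.3),
                        seed = 22)
  orc <- oracle_cond_freqs(beh)
  rb <- risky_winstay_bias(beh)
  expect_equal(rb$p1, orc$p_safe_post_safe)
  expect_equal(rb$p2, orc$p_safe_post_risky)
  expect_gt(rb$value, 0)  # positive weight => more gambling after risky wins
  sp <- spatial_winstay_lose_switch(beh)
  expect_equal(sp$win_stay$p1, orc$p_repeat_win)
  expect_equal(sp$win_stay$p2, orc$p_repeat_all)
  expect_equal(sp$lose_switch$p1, orc$p_switch_loss)
})

test_that("zero-count conditions give a flagged undefined estimate", {
  tr <- fixture_trials()
  tr$chose_safe <- TRUE
  tr$choice_side <- tr$safe_side
  tr$rewarded <- TRUE
  tr$reward_volume <- tr$safe_volume
  rb <- risky_winstay_bias(tr)  # no post-risky-reward trials exist
  expect_true(rb$undefined)
  expect_true(is.na(rb$value))
})

test_that("pure side hysteresis produces no outcome-dependent spatial bias", {
  beh <- simulate_agent(generate_offers(60000, seed = 31),
                        agent_params(w_ev = 0, w_lr_hyst = 0.8), seed = 32)
  sp <- spatial_winstay_lose_switch(beh)
  expect_lt(abs(sp$win_stay$value), sp$win_stay$ci95)
  expect_lt(abs(sp$lose_switch$value), sp$lose_switch$ci95)
})

test_that("graded bias recovers a planted linear dependence on probability", {
  # plant P(gamble | post-risky-win at prob p) = 0.4 + 0.3 p, baseline 0.4
  set.seed(41)
  n <- 40000L
  off <- generate_offers(n, seed = 42)
  chose_safe <- logical(n); rewarded <- logical(n)
  chose_safe[1] <- TRUE; rewarded[1] <- TRUE
  for (i in 2:n) {
    p_gamble <- if (!chose_safe[i - 1] && rewarded[i - 1]) {
      0.4 + 0.3 * off$risky_prob[i - 1]
    } else 0.4
    chose_safe[i] <- runif(1) >= p_gamble
    rewarded[i] <- if (chose_safe[i]) TRUE else runif(1) < off$risky_prob[i]
  }
  tr <- off
  tr$chose_safe <- chose_safe
  tr$choice_side <- ifelse(chose_safe, tr$safe_side,
                           ifelse(tr$safe_side == "right", "left", "right"))
  tr$rewarded <- rewarded
  tr$reward_volume <- ifelse(chose_safe, tr$safe_volume,
                             ifelse(rewarded, tr$risky_volume, 0))
  gb <- graded_winstay_by_prob(tr)
  expect_equal(nrow(gb$bins), 10)       # p = 0 cannot yield a risky win
  expect_equal(gb$slope, 0.3, tolerance = 0.25)
  expect_gt(gb$slope, 0.15)
})

test_that("flat bias gives zero slope and degenerate bins error", {
  beh <- simulate_agent(generate_offers(40000, seed = 51),
                        agent_params(w_ev = 0), seed = 52)
  gb <- graded_winstay_by_prob(beh)
  se_slope <- summary(stats::lm(delta ~ prob, data = gb$bins))$coef[2, 2]
  expect_lt(abs(gb$slope), 3 * se_slope)
  one_bin <- simulate_agent(generate_offers(2000, task_config(
    prob_grid = c(0.5)), seed = 53), seed = 54)
  expect_error(graded_winstay_by_prob(one_bin[one_bin$risky_prob == 0.5, ]),
               "bins")
})

test_that("laser comparison recovers a planted risky win-stay ablation", {
  cfg <- task_config(laser_frac_choice = 0.15)
  base <- agent_params(w_ev = 0.1, w_risky_winstay = 1)
  ablated <- agent_params(w_ev = 0.1, w_risky_winstay = 0)
  beh <- simulate_agent(generate_offers(60000, cfg, seed = 61), base,
                        config = cfg, seed = 62,
                        post_laser_params = ablated,
                        post_laser_epochs = "choice_report")
  lc <- laser_comparison(beh, epoch = "choice_report", bias = "risky_winstay")
  expect_gt(lc$control$value, lc$control$ci95)  # bias present in controls
  expect_lt(abs(lc$laser$value), lc$laser$ci95) # abolished post-laser
  expect_error(laser_comparison(beh, epoch = "cue"), "cue")
})

test_that("null laser has no effect within joint CI", {
  cfg <- task_config(laser_frac_cue = 0.15)
  beh <- simulate_agent(generate_offers(40000, cfg, seed = 71),
                        agent_params(w_ev = 0.1, w_risky_winstay = 0.8),
                        config = cfg, seed = 72)
  lc <- laser_comparison(beh, epoch = "cue", bias = "risky_winstay")
  expect_lt(abs(lc$control$value - lc$laser$value),
            lc$control$ci95 + lc$laser$ci95)
})

test_that("ITI matching removes an apparent laser effect on decaying biases", {
  # plant a spatial win-stay bias that decays with the previous ITI; the
  # choice-report laser only lengthens the ITI, so naive controls show a
  # spurious reduction that ITI-matched controls remove
  set.seed(81)
  n <- 100000L
  off <- generate_offers(n, seed = 82)
  laser <- ifelse(runif(n) < 0.25, "choice_report", "none")
  iti <- rlnorm(n, log(3), 0.6)
  iti[laser == "choice_report"] <- pmax(iti[laser == "choice_report"], 4)
  choice <- character(n); rewarded <- logical(n)
  choice[1] <- "left"; rewarded[1] <- TRUE
  for (i in 2:n) {
    p_rep <- if (rewarded[i - 1]) 0.5 + 0.45 * exp(-iti[i - 1] / 4) else 0.5
    choice[i] <- if (runif(1) < p_rep) choice[i - 1] else
      setdiff(c("left", "right"), choice[i - 1])
    rewarded[i] <- runif(1) < 0.35
  }
  tr <- off
  tr$choice_side <- choice
  tr$chose_safe <- choice == tr$safe_side
  tr$rewarded <- rewarded
  tr$reward_volume <- ifelse(tr$rewarded, tr$safe_volume, 0)
  tr$laser_epoch <- laser
  tr$iti_s <- iti
  naive <- laser_comparison(tr, epoch = "choice_report", bias = "spatial")
  matched <- laser_comparison(tr, epoch = "choice_report", bias = "spatial",
                              iti_matched = TRUE)
  gap_naive <- naive$control$win_stay$value - naive$laser$win_stay$value
  gap_matched <- matched$control$win_stay$value - matched$laser$win_stay$value
  expect_gt(gap_naive,
            naive$control$win_stay$ci95 + naive$laser$win_stay$ci95)
  expect_lt(abs(gap_matched),
            matched$control$win_stay$ci95 + matched$laser$win_stay$ci95)
})

test_that("CI widths shrink as 1/sqrt(n) on simulated data", {
  w <- vapply(c(2000L, 8000L, 32000L), function(n) {
    beh <- simulate_agent(generate_offers(n, seed = n),
                          agent_params(w_ev = 0.1), seed = n + 1L)
    risky_winstay_bias(beh)$ci95
  }, 0)
  expect_true(all(diff(w) < 0))
  expect_equal(w[1] / w[3], 4, tolerance = 0.35)
})
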