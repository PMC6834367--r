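# Congruence between a recovered and a planted factor, up to sign.
congruence <- function(u, v) abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))

test_that("exact rank-1 tensors are recovered with near-perfect congruence", {
  set.seed(1)
  w <- abs(rnorm(12)); b <- abs(rnorm(15)); a <- abs(rnorm(30))
  X <- cp_reconstruct_factors(w, b, a)
  fit <- fit_cp_rank1(X, n_inits = 3, seed = 2)
  expect_gt(congruence(fit$w, w), 0.999)
  expect_gt(congruence(fit$b, b), 0.999)
  expect_gt(congruence(fit$a, a), 0.999)
  expect_lt(fit$rel_error, 1e-6)
})

test_that("CP fitting is deterministic given the seed", {
  set.seed(3)
  X <- cp_reconstruct_factors(runif(8), runif(9), runif(10)) +
    array(rnorm(8 * 9 * 10, 0, 0.05), c(8, 9, 10))
  f1 <- fit_cp_rank1(X, n_inits = 4, seed = 11)
  f2 <- fit_cp_rank1(X, n_inits = 4, seed = 11)
  expect_identical(f1$w, f2$w)
  expect_identical(f1$a, f2$a)
})

test_that("ALS reconstruction error is monotonically non-increasing", {
  set.seed(4)
  X <- array(abs(rnorm(10 * 12 * 20)), c(10, 12, 20))
  fit <- fit_cp(X, rank = 2, n_inits = 1, seed = 5, max_iter = 60)
  expect_true(all(diff(fit$error_trace) <= 1e-10))
})

test_that("canonical factors are unit-norm, sign-fixed and idempotent", {
  set.seed(6)
  X <- cp_reconstruct_factors(rnorm(10), rnorm(12), rnorm(14)) +
    array(rnorm(10 * 12 * 14, 0, 0.01), c(10, 12, 14))
  fit <- fit_cp_rank1(X, n_inits = 3, seed = 7)
  expect_equal(sqrt(sum(fit$w^2)), 1)
  expect_equal(sqrt(sum(fit$b^2)), 1)
  expect_gte(mean(fit$w), 0)
  expect_gte(mean(fit$b), 0)
  # refitting the model's own reconstruction returns identical canonical
  # factors
  fit2 <- fit_cp_rank1(cp_reconstruct_factors(fit$w, fit$b, fit$a),
                       n_inits = 3, seed = 8)
  expect_equal(fit2$w, fit$w, tolerance = 1e-6)
  expect_equal(fit2$b, fit$b, tolerance = 1e-6)
  expect_equal(fit2$a, fit$a, tolerance = 1e-6)
})

test_that("Poisson noise at moderate SNR barely degrades recovery", {
  set.seed(9)
  w <- runif(20, 0.5, 1.5); b <- runif(25, 0.5, 1.5); a <- runif(60, 0.5, 1.5)
  lam <- cp_reconstruct_factors(w, b, a) * 20
  X <- array(rpois(length(lam), lam), dim(lam))
  fit <- fit_cp_rank1(X, n_inits = 3, seed = 10)
  expect_gt(congruence(fit$w, w), 0.99)
  expect_gt(congruence(fit$b, b), 0.99)
})

test_that("similarity index: identity, orthogonality, sign ambiguity", {
  set.seed(12)
  f <- list(w = rnorm(10), b = abs(rnorm(12)), a = rnorm(15))
  expect_equal(similarity_index(f, f), 1)
  # orthogonal neuron factors kill the product
  g <- f
  g$w <- rep(c(1, -1), 5) * abs(f$w)
  g$w <- g$w - f$w * sum(g$w * f$w) / sum(f$w^2)
  expect_lt(similarity_index(f, g), 1e-10)
  # flipping the sign of (w, a) jointly leaves the factorization unchanged
  h <- list(w = -f$w, b = f$b, a = -f$a)
  expect_equal(similarity_index(f, h), 1)
  expect_error(similarity_index(f, list(w = rep(0, 10), b = f$b, a = f$a)),
               "zero-norm")
})

test_that("rank selection is stable on planted constructions", {
  set.seed(13)
  # exact rank 1: rank 1 stable, the degenerate rank-2 fit unstable
  X1 <- cp_reconstruct_factors(runif(15, 0.5, 1), runif(12, 0.5, 1),
                               runif(40, 0.5, 1))
  sel1 <- select_rank(X1, max_rank = 2, n_inits = 10, seed = 14)
  expect_identical(sel1$rank, 1L)
  expect_gt(sel1$mean_similarity[1], 0.9)
  # well-separated exact rank 2
  w2 <- cbind(c(rep(1, 8), rep(0, 7)), c(rep(0, 8), rep(1, 7)))
  b2 <- cbind(exp(-(1:12)), rev(exp(-(1:12))))
  a2 <- cbind(runif(40, 0.5, 1), runif(40, 1, 2))
  X2 <- cp_reconstruct_factors(w2, b2, a2)
  sel2 <- select_rank(X2, max_rank = 2, n_inits = 10, seed = 15)
  expect_gte(sel2$rank, 2L)
})

test_that("pure noise tensors are unstable at rank 2", {
  set.seed(16)
  Xn <- array(abs(rnorm(12 * 12 * 30)), c(12, 12, 30))
  sel <- select_rank(Xn, max_rank = 2, n_inits = 6, seed = 17)
  expect_lt(sel$mean_similarity[2], 0.9)
})

test_that("triggered averages vanish for reward-independent factors", {
  set.seed(21)
  a <- rnorm(300, 10, 1)
  rew <- runif(300) < 0.6
  ta <- triggered_average(a, rew, n_shuffles = 200, seed = 22)
  expect_true(all(abs(ta$lags$reward_avg) < 0.3))
  expect_true(all(abs(ta$lags$noreward_avg) < 0.3))
  expect_error(triggered_average(a[1:5], rew[1:5]), "trials")
})

test_that("planted post-reward gain reduction shows at lag 1 and matches a
           brute-force evaluation of the construction", {
  set.seed(23)
  K <- 400
  rew <- runif(K) < 0.6
  gamma <- 0.3
  g <- 1 - gamma * c(FALSE, rew[-K]) + rnorm(K, 0, 0.02)
  ta <- triggered_average(g, rew, n_shuffles = 300, seed = 24)
  lag1 <- ta$lags$reward_avg[ta$lags$lag == 1]
  # brute force: raw conditional means minus the exact permutation
  # expectation (shuffled labels hit every trial equally, so the correction
  # converges on mean over trials 2..K of dev, weighted by lag coverage)
  dev <- g - mean(g)
  raw <- mean(dev[which(rew[-K]) + 1])
  sh_expect <- mean(dev[2:K])
  expect_lt(lag1, 0)
  expect_equal(lag1, raw - sh_expect, tolerance = 0.02)
  # no-reward lag-1 average goes the other way
  expect_gt(ta$lags$noreward_avg[2], 0)
})

test_that("more shuffles only tighten the correction", {
  set.seed(25)
  a <- rnorm(200, 5, 1)
  rew <- runif(200) < 0.5
  t100 <- triggered_average(a, rew, n_shuffles = 100, seed = 26)
  t1000 <- triggered_average(a, rew, n_shuffles = 1000, seed = 27)
  expect_equal(t100$lags$reward_avg, t1000$lags$reward_avg, tolerance = 0.2)
})

test_that("trial-factor/reward-history correlation detects planted gain", {
  set.seed(31)
  K <- 300
  rew <- runif(K) < 0.6
  g <- 1 - 0.3 * c(FALSE, rew[-K]) + rnorm(K, 0, 0.05)
  res <- trialfactor_reward_correlation(g, rew)
  expect_lt(res$r, 0)
  expect_lt(res$p_value, 0.05)
  expect_error(trialfactor_reward_correlation(rep(1, 50), runif(50) < 0.5),
               "constant")
  expect_error(trialfactor_reward_correlation(rnorm(5), rep(TRUE, 5)),
               "at least 10")
})

test_that("tensor build normalizes per neuron without changing trial-factor
           conclusions", {
  beh <- simulate_agent(generate_offers(150, seed = 41),
                        agent_params(w_ev = 0.1), seed = 42)
  pop <- simulate_population(beh, neural_config(n_units = 10,
                                                trial_gain_gamma = 0.35,
                                                frac_history = 0),
                             seed = 43)
  ars <- lapply(1:10, function(u) {
    st <- pop$spikes$time_s[pop$spikes$unit_id == u]
    bin_and_smooth(st, pop$events$trial_init, c(0, 1))
  })
  Xn <- build_tensor(ars, normalize = TRUE)
  Xr <- build_tensor(ars, normalize = FALSE)
  expect_equal(dim(Xn), c(10, 20, 150))
  expect_true(all(apply(Xn, 1, max) <= 1 + 1e-9))
  fn <- fit_cp_rank1(Xn, n_inits = 3, seed = 44)
  fr <- fit_cp_rank1(Xr, n_inits = 3, seed = 45)
  cn <- trialfactor_reward_correlation(fn$a, beh$rewarded)
  cr <- trialfactor_reward_correlation(fr$a, beh$rewarded)
  expect_identical(sign(cn$r), sign(cr$r))
  expect_lt(cn$r, 0)
  # mismatched axes refuse to stack
  expect_error(build_tensor(c(ars, list(matrix(0, 3, 3)))), "share")
})

test_that("removing history-modulated neurons abolishes the trial-factor
           reward modulation", {
  beh <- simulate_agent(generate_offers(250, seed = 51),
                        agent_params(w_ev = 0.1), seed = 52)
  nc <- neural_config(n_units = 16, frac_history = 0.5, history_gain = 0.8,
                      trial_gain_gamma = 0, frac_side = 0, frac_risk = 0,
                      frac_reward = 0, trial_gain_sd = 0.02)
  pop <- simulate_population(beh, nc, seed = 53)
  ars <- lapply(1:16, function(u) {
    st <- pop$spikes$time_s[pop$spikes$unit_id == u]
    bin_and_smooth(st, pop$events$trial_init, c(0, 1))
  })
  hist_units <- which(pop$truth$history)
  fit_all <- fit_cp_rank1(build_tensor(ars), n_inits = 3, seed = 54)
  r_all <- trialfactor_reward_correlation(fit_all$a, beh$rewarded)
  fit_wo <- fit_cp_rank1(build_tensor(ars[-hist_units]), n_inits = 3,
                         seed = 55)
  r_wo <- trialfactor_reward_correlation(fit_wo$a, beh$rewarded)
  expect_lt(r_all$r, 0)
  expect_lt(r_all$p_value, 0.05)
  expect_lt(abs(r_wo$r), abs(r_all$r) / 2)
})
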