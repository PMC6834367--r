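#' Four-parameter psychometric sigmoid
#'
#' Evaluates \eqn{p(\mathrm{choose~safe}) = y_0 + \frac{1 - 2a}{1 +
#' e^{-b(x - x_0)}}} where `x` is the safe-minus-risky expected-value
#' difference (uL). `y0` and `a` are lower/upper lapse-like offsets in
#' [0, 0.5], `b` the slope and `x0` the inflection point.
#'
#' @param x EV difference(s), safe minus risky.
#' @param pars Named vector/list with `y0`, `a`, `b`, `x0`.
#' @return Probabilities of choosing safe.
#' @export
psychometric_curve <- function(x, pars) {
  pars <- as.list(pars)
  pars$y0 + (1 - 2 * pars$a) / (1 + exp(-pars$b * (x - pars$x0)))
}

#' Fit the psychometric curve to binned choice proportions
#'
#' Drops trials where both ports offered certain rewards (risky probability
#' 1), bins the remaining trials into `n_bins` equal-width bins of the
#' safe-minus-risky EV difference, and fits the 4-parameter sigmoid by
#' minimizing the mean squared error between the binned safe-choice
#' proportions and the curve, under box constraints (`y0`, `a` in [0, 0.5],
#' `b >= 0`, `x0` within the data range). Optimization is multi-start
#' L-BFGS-B; the best of all starts is returned, so the reported MSE is no
#' larger than that of any initialization.
#'
#' @param trials Completed trials table.
#' @param n_bins Number of EV-difference bins (default 11).
#' @param n_starts Random restarts (default 20).
#' @param seed Seed for the restart draws.
#' @param tol Convergence tolerance on the MSE (factr-scaled).
#' @return Object of class `psychometric_fit`: `coefficients`
#'   (`y0`, `a`, `b`, `x0`), `mse`, `bins` (data.frame `center`, `prop`,
#'   `n`), `n_starts`, `start_mse` (MSE reached from each start).
#' @examples
#' beh <- simulate_agent(generate_offers(4000, seed = 1),
#'                       agent_params(w_ev = 0.2), seed = 2)
#' fit <- fit_psychometric(beh, seed = 3)
#' coef(fit)
#' @export
fit_psychometric <- function(trials, n_bins = 11L, n_starts = 20L,
                             seed = NULL, tol = 1e-9) {
  stopifnot_trials(trials)
  keep <- trials$risky_prob < 1 - 1e-9
  tr <- trials[keep, , drop = FALSE]
  if (nrow(tr) < 4L) stop("too few trials after excluding both-certain offers")
  ev <- offer_evs(tr)
  x <- ev$ev_safe - ev$ev_risky
  if (diff(range(x)) < 1e-12) {
    stop("degenerate EV-difference range: fewer than 4 populated bins")
  }
  br <- seq(min(x), max(x), length.out = n_bins + 1L)
  bin <- cut(x, breaks = br, include.lowest = TRUE)
  centers <- (br[-1L] + br[-length(br)]) / 2
  prop <- tapply(tr$chose_safe, bin, mean)
  nper <- tapply(tr$chose_safe, bin, length)
  ok <- !is.na(prop)
  bins <- data.frame(center = centers[ok], prop = as.numeric(prop[ok]),
                     n = as.integer(nper[ok]))
  if (nrow(bins) < 4L) {
    stop("fewer than 4 populated bins; the 4-parameter fit is underdetermined")
  }
  lower <- c(y0 = 0, a = 0, b = 0, x0 = min(bins$center))
  upper <- c(y0 = 0.5, a = 0.5, b = 10, x0 = max(bins$center))
  obj <- function(p) {
    mean((bins$prop - psychometric_curve(bins$center, stats::setNames(
      p, c("y0", "a", "b", "x0"))))^2)
  }
  starts <- with_seed(seed, {
    s <- matrix(stats::runif(4L * n_starts), ncol = 4L)
    sweep(sweep(s, 2L, upper - lower, "*"), 2L, lower, "+")
  })
  # always include a data-driven start
  starts <- rbind(c(min(bins$prop) / 2, (1 - max(bins$prop)) / 2, 0.3,
                    stats::median(bins$center)), starts)
  best <- NULL
  start_mse <- numeric(nrow(starts))
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(pmin(pmax(starts[i, ], lower), upper), obj,
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(factr = tol / .Machine$double.eps))
    start_mse[i] <- o$value
    if (is.null(best) || o$value < best$value) best <- o
  }
  pars <- stats::setNames(best$par, c("y0", "a", "b", "x0"))
  structure(list(coefficients = pars, mse = best$value, bins = bins,
                 n_starts = nrow(starts), start_mse = start_mse),
            class = "psychometric_fit")
}

#' @export
coef.psychometric_fit <- function(object, ...) object$coefficients

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "Psychometric sigmoid: y0 = %.3f, a = %.3f, b = %.3f, x0 = %.2f (MSE %.2e)\n",
    x$coefficients["y0"], x$coefficients["a"], x$coefficients["b"],
    x$coefficients["x0"], x$mse))
  invisible(x)
}

#' @export
predict.psychometric_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$bins$center
  psychometric_curve(newdata, object$coefficients)
}

#' @export
plot.psychometric_fit <- function(x, ...) {
  graphics::plot(x$bins$center, x$bins$prop, xlab = "EV(safe) - EV(risky) (uL)",
                 ylab = "P(choose safe)", ylim = c(0, 1), pch = 16, ...)
  xs <- seq(min(x$bins$center), max(x$bins$center), length.out = 200)
  graphics::lines(xs, psychometric_curve(xs, x$coefficients))
  invisible(x)
}
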