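#' Design matrix for the five-term logistic choice model
#'
#' Codes, for every trial after the first, the regressors of the choice
#' model: expected-value difference `dEV` (right minus left, uL), safe/risky
#' hysteresis `x_rs`, risky win-stay `x_rws` (nonzero only after a rewarded
#' risky choice), side hysteresis `x_lr`, and an intercept (side bias). The
#' response is the indicator of choosing the right port. The coding is the
#' single shared definition also used by [simulate_agent()], so weights fitted
#' to simulated data estimate the planted [agent_params()] directly.
#'
#' @param trials Completed, ordered trials table.
#' @return List with `X` (matrix, columns `dEV`, `x_rs`, `x_rws`, `x_lr`,
#'   `intercept`), `y` (0/1 chose right) and `trial_index` (the retained
#'   trials; the first trial is dropped).
#' @examples
#' beh <- simulate_agent(generate_offers(100, seed = 1), seed = 2)
#' head(build_design_matrix(beh)$X)
#' @export
build_design_matrix <- function(trials) {
  stopifnot_trials(trials)
  n <- nrow(trials)
  if (n < 2L) stop("need at least 2 trials")
  ev <- offer_evs(trials)
  dEV <- ev$ev_right - ev$ev_left
  idx <- 2:n
  X <- code_regressors(
    dEV = dEV[idx],
    prev_choice_right = trials$choice_side[idx - 1L] == "right",
    prev_chose_safe = trials$chose_safe[idx - 1L],
    prev_rewarded = trials$rewarded[idx - 1L],
    safe_right_now = trials$safe_side[idx] == "right"
  )
  X <- cbind(X, intercept = 1)
  list(X = X, y = as.integer(trials$choice_side[idx] == "right"),
       trial_index = trials$trial_index[idx])
}

#' Fit the logistic choice model
#'
#' Maximum-likelihood logistic regression of choosing right on the regressors
#' of [build_design_matrix()], with standard errors from the observed
#' information. If the fit fails to converge or the data are separable, a
#' small-ridge penalized refit is applied and flagged.
#'
#' @param x Either a completed trials table (the design matrix is built
#'   internally) or a design matrix as returned in `$X`.
#' @param y Response vector (0/1 chose right); ignored when `x` is a trials
#'   table.
#' @param ridge Ridge penalty used only in the separation fallback.
#' @return An object of class `choice_model_fit` with components
#'   `coefficients` (named `w_ev`, `w_rs_hyst`, `w_risky_winstay`,
#'   `w_lr_hyst`, `w_lr_bias`), `se`, `vcov`, `logLik`, `converged`,
#'   `ridge_used`, `n`.
#' @examples
#' beh <- simulate_agent(generate_offers(2000, seed = 1),
#'                       agent_params(w_ev = 0.15, w_risky_winstay = 0.8),
#'                       seed = 2)
#' coef(fit_choice_model(beh))
#' @export
fit_choice_model <- function(x, y = NULL, ridge = 1e-3) {
  if (is.data.frame(x)) {
    dm <- build_design_matrix(x)
    X <- dm$X; y <- dm$y
  } else {
    X <- as.matrix(x)
    if (is.null(y)) stop("`y` is required when `x` is a matrix")
  }
  par_names <- c(dEV = "w_ev", x_rs = "w_rs_hyst", x_rws = "w_risky_winstay",
                 x_lr = "w_lr_hyst", intercept = "w_lr_bias")

  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  ridge_used <- FALSE
  if (sep || !fit$converged) {
    # penalized IRLS: beta <- (X'WX + 2*lambda*I)^-1 X'W z
    ridge_used <- TRUE
    beta <- rep(0, ncol(X))
    for (it in 1:200) {
      eta <- drop(X %*% beta)
      mu <- logistic(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      z <- eta + (y - mu) / w
      H <- crossprod(X, X * w) + diag(2 * ridge, ncol(X))
      new_beta <- solve(H, crossprod(X, w * z))
      if (max(abs(new_beta - beta)) < 1e-10) {beta <- new_beta; break}
      beta <- new_beta
    }
    beta <- drop(beta)
    eta <- drop(X %*% beta)
    mu <- logistic(eta)
    info <- crossprod(X, X * (mu * (1 - mu))) + diag(2 * ridge, ncol(X))
    V <- solve(info)
    ll <- sum(stats::dbinom(y, 1, mu, log = TRUE))
    converged <- TRUE
  } else {
    beta <- fit$coefficients
    mu <- fit$fitted.values
    info <- crossprod(X, X * (mu * (1 - mu)))
    V <- solve(info)
    ll <- sum(stats::dbinom(y, 1, mu, log = TRUE))
    converged <- fit$converged
  }
  nm <- par_names[colnames(X)]
  names(beta) <- nm
  dimnames(V) <- list(nm, nm)
  structure(list(coefficients = beta, se = sqrt(diag(V)), vcov = V,
                 logLik = ll, converged = converged, ridge_used = ridge_used,
                 n = length(y)),
            class = "choice_model_fit")
}

#' @export
coef.choice_model_fit <- function(object, ...) object$coefficients

#' @export
vcov.choice_model_fit <- function(object, ...) object$vcov

#' @export
logLik.choice_model_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
print.choice_model_fit <- function(x, ...) {
  cat("Logistic choice model (", x$n, " trials, logLik ",
      sprintf("%.1f", x$logLik), if (x$ridge_used) ", ridge fallback" else "",
      ")\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.choice_model_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, logLik = object$logLik, n = object$n,
                 ridge_used = object$ridge_used), class = "summary.choice_model_fit")
}

#' @export
print.summary.choice_model_fit <- function(x, ...) {
  cat("Logistic choice model,", x$n, "trials\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
predict.choice_model_fit <- function(object, newdata, type = c("response", "link"),
                                     ...) {
  type <- match.arg(type)
  X <- if (is.data.frame(newdata)) build_design_matrix(newdata)$X else
    as.matrix(newdata)
  eta <- drop(X %*% object$coefficients)
  if (type == "link") eta else logistic(eta)
}
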