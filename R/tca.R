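# Canonical polyadic (CP) decomposition of neuron x time x trial tensors,
# alternating least squares with closed-form mode updates.

khatri_rao <- function(A, B) {
  # columnwise Kronecker; rows ordered with B's index fastest
  R <- ncol(A)
  out <- matrix(0, nrow(A) * nrow(B), R)
  for (r in seq_len(R)) out[, r] <- kronecker(A[, r], B[, r])
  out
}

unfold <- function(X, mode) {
  d <- dim(X)
  switch(mode,
         matrix(X, d[1L], d[2L] * d[3L]),
         matrix(aperm(X, c(2L, 1L, 3L)), d[2L], d[1L] * d[3L]),
         matrix(aperm(X, c(3L, 1L, 2L)), d[3L], d[1L] * d[2L]))
}

cp_reconstruct <- function(w, b, a) {
  d <- c(nrow(w), nrow(b), nrow(a))
  array(tcrossprod(w, khatri_rao(a, b)), dim = d)
}

#' Stack simultaneously recorded units into a session tensor
#'
#' Builds the `neurons x timebins x trials` array analyzed by the CP
#' decomposition from per-unit trial-aligned rate matrices. By default each
#' neuron is normalized by its maximum rate (plus a small epsilon) so that
#' high-rate units do not dominate the fit; the normalization factors are
#' recorded in the `"normalization"` attribute.
#'
#' @param rates_list List of trials x bins matrices (or [bin_and_smooth()]
#'   results), one per unit, sharing trial and bin axes.
#' @param normalize Divide each neuron by its max rate + `eps`?
#' @param eps Stabilizer added to the per-neuron maximum.
#' @return A 3-d array, neurons x timebins x trials.
#' @export
build_tensor <- function(rates_list, normalize = TRUE, eps = 1e-6) {
  mats <- lapply(rates_list, function(r) if (is.list(r)) r$rates else as.matrix(r))
  dims <- unique(t(vapply(mats, dim, integer(2))))
  if (nrow(dims) != 1L) stop("all units must share trial and bin axes")
  K <- dims[1L, 1L]; Tn <- dims[1L, 2L]; N <- length(mats)
  X <- array(0, dim = c(N, Tn, K))
  norms <- numeric(N)
  for (u in seq_len(N)) {
    m <- mats[[u]]
    norms[u] <- if (normalize) max(m) + eps else 1
    X[u, , ] <- t(m) / norms[u]
  }
  attr(X, "normalization") <- norms
  X
}

#' Fit a CP decomposition by alternating least squares
#'
#' Approximates a nonnegative `neurons x timebins x trials` tensor by
#' \eqn{\sum_{r=1}^{R} w_r \otimes b_r \otimes a_r} (neuron, temporal and
#' trial factors). Each mode update is the closed-form least-squares solution
#' given the other two modes, so the reconstruction error is non-increasing
#' across iterations. The best of `n_inits` random initializations is
#' returned. Factors are canonicalized: unit-norm `w` and `b` columns with
#' the scale absorbed into `a`, and signs flipped so `mean(w) >= 0` and
#' `mean(b) >= 0` per component.
#'
#' @param tensor 3-d array (see [build_tensor()]).
#' @param rank Number of components R.
#' @param n_inits Random restarts.
#' @param tol Relative-error change convergence tolerance.
#' @param max_iter Maximum ALS sweeps per start.
#' @param seed Integer seed; identical seeds give identical factors.
#' @return Object of class `cp_fit`: `w` (neurons x R), `b` (timebins x R),
#'   `a` (trials x R), `rank`, `rel_error` (Frobenius, relative),
#'   `error_trace` of the winning start, `converged`, `n_inits`.
#' @examples
#' X <- cp_reconstruct_factors(w = c(1, 2), b = c(1, 1, 1), a = c(2, 1))
#' fit <- fit_cp(X, rank = 1, seed = 1)
#' fit$rel_error
#' @export
fit_cp <- function(tensor, rank = 1L, n_inits = 10L, tol = 1e-8,
                   max_iter = 500L, seed = NULL) {
  d <- dim(tensor)
  if (is.null(d) || length(d) != 3L) stop("`tensor` must be a 3-d array")
  if (any(d < 2L)) stop("each tensor dimension must be >= 2 for fitting")
  X1 <- unfold(tensor, 1L); X2 <- unfold(tensor, 2L); X3 <- unfold(tensor, 3L)
  nrmX <- sqrt(sum(tensor^2))
  if (nrmX == 0) stop("tensor is identically zero")

  solve_mode <- function(Xm, U, V) {
    G <- crossprod(U) * crossprod(V)
    t(solve(G + diag(1e-12, ncol(G)), t(Xm %*% khatri_rao(U, V))))
  }
  rel_err <- function(w, b, a) {
    # ||X - Xhat||_F via the factor Gram matrices (cheap for small R)
    Z <- khatri_rao(a, b)
    cross <- sum(X1 * tcrossprod(w, Z))
    nrmH2 <- sum(crossprod(w) * crossprod(b) * crossprod(a))
    sqrt(max(nrmX^2 - 2 * cross + nrmH2, 0)) / nrmX
  }

  with_seed(seed, {
    best <- NULL
    for (init in seq_len(n_inits)) {
      w <- matrix(stats::runif(d[1L] * rank), d[1L], rank)
      b <- matrix(stats::runif(d[2L] * rank), d[2L], rank)
      a <- matrix(stats::runif(d[3L] * rank), d[3L], rank)
      trace <- numeric(0)
      prev <- Inf
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        w <- solve_mode(X1, a, b)
        b <- solve_mode(X2, a, w)
        a <- solve_mode(X3, b, w)
        e <- rel_err(w, b, a)
        trace <- c(trace, e)
        if (is.finite(prev) && abs(prev - e) < tol) {converged <- TRUE; break}
        prev <- e
      }
      if (is.null(best) || trace[length(trace)] < best$rel_error) {
        best <- list(w = w, b = b, a = a, rel_error = trace[length(trace)],
                     error_trace = trace, converged = converged)
      }
    }
    # canonicalize
    for (r in seq_len(rank)) {
      nw <- sqrt(sum(best$w[, r]^2)); nb <- sqrt(sum(best$b[, r]^2))
      if (nw == 0 || nb == 0) stop("degenerate zero factor recovered")
      best$w[, r] <- best$w[, r] / nw
      best$b[, r] <- best$b[, r] / nb
      best$a[, r] <- best$a[, r] * nw * nb
      if (mean(best$w[, r]) < 0) {
        best$w[, r] <- -best$w[, r]; best$a[, r] <- -best$a[, r]
      }
      if (mean(best$b[, r]) < 0) {
        best$b[, r] <- -best$b[, r]; best$a[, r] <- -best$a[, r]
      }
    }
    structure(c(best, list(rank = as.integer(rank),
                           n_inits = as.integer(n_inits))),
              class = "cp_fit")
  })
}

#' Rank-1 CP fit
#'
#' Convenience wrapper around [fit_cp()] with `rank = 1`; factors are plain
#' vectors.
#'
#' @inheritParams fit_cp
#' @return A `cp_fit` whose `w`, `b`, `a` are vectors.
#' @export
fit_cp_rank1 <- function(tensor, n_inits = 10L, tol = 1e-8, max_iter = 500L,
                         seed = NULL) {
  fit <- fit_cp(tensor, rank = 1L, n_inits = n_inits, tol = tol,
                max_iter = max_iter, seed = seed)
  fit$w <- drop(fit$w); fit$b <- drop(fit$b); fit$a <- drop(fit$a)
  fit
}

#' Build an exact low-rank tensor from factors
#'
#' @param w,b,a Factor vectors (rank 1) or matrices with one column per
#'   component.
#' @return The 3-d array \eqn{\sum_r w_r \otimes b_r \otimes a_r}.
#' @export
cp_reconstruct_factors <- function(w, b, a) {
  cp_reconstruct(as.matrix(w), as.matrix(b), as.matrix(a))
}

#' @export
print.cp_fit <- function(x, ...) {
  cat(sprintf("CP fit: rank %d, relative error %.4g (%d inits)\n",
              x$rank, x$rel_error, x$n_inits))
  invisible(x)
}

#' @export
plot.cp_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3)); on.exit(graphics::par(op))
  w <- as.matrix(x$w); b <- as.matrix(x$b); a <- as.matrix(x$a)
  graphics::matplot(w, type = "h", xlab = "neuron", ylab = "neuron factor")
  graphics::matplot(b, type = "l", xlab = "time bin", ylab = "temporal factor")
  graphics::matplot(a, type = "l", xlab = "trial", ylab = "trial factor")
  invisible(x)
}

#' Similarity index between two CP factorizations
#'
#' For rank 1, the product over the three modes of the absolute cosine
#' similarity of the factors (1 for identical up to scale/sign, 0 for
#' orthogonal). For rank R, components are matched greedily to maximize that
#' per-pair product and the mean over matched pairs is returned.
#'
#' @param fa,fb `cp_fit` objects (or lists with `w`, `b`, `a`) of equal rank
#'   and dimensions.
#' @param scale_penalty Multiply each matched pair's cosine product by
#'   `1 - |s1 - s2| / max(s1, s2)` where `s` is the component scale (the
#'   norm of `w_r (x) b_r (x) a_r`)? Without it, degenerate factorizations
#'   with nearly collinear components and canceling scales look spuriously
#'   reproducible.
#' @return Similarity in [0, 1].
#' @export
similarity_index <- function(fa, fb, scale_penalty = TRUE) {
  A <- lapply(list(fa$w, fa$b, fa$a), as.matrix)
  B <- lapply(list(fb$w, fb$b, fb$a), as.matrix)
  R <- ncol(A[[1L]])
  if (ncol(B[[1L]]) != R) stop("factorizations must have equal rank")
  cosm <- function(u, v) {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) stop("zero-norm factor")
    abs(sum(u * v)) / (nu * nv)
  }
  comp_scale <- function(F, r) {
    sqrt(sum(F[[1L]][, r]^2) * sum(F[[2L]][, r]^2) * sum(F[[3L]][, r]^2))
  }
  S <- matrix(1, R, R)
  for (m in 1:3) {
    for (r in seq_len(R)) for (s in seq_len(R)) {
      S[r, s] <- S[r, s] * cosm(A[[m]][, r], B[[m]][, s])
    }
  }
  if (scale_penalty) {
    for (r in seq_len(R)) for (s in seq_len(R)) {
      sa <- comp_scale(A, r); sb <- comp_scale(B, s)
      S[r, s] <- S[r, s] * (1 - abs(sa - sb) / max(sa, sb))
    }
  }
  # greedy one-to-one matching on the product similarity
  total <- 0
  for (i in seq_len(R)) {
    ij <- which(S == max(S), arr.ind = TRUE)[1L, ]
    total <- total + S[ij[1L], ij[2L]]
    S[ij[1L], ] <- -Inf
    S[, ij[2L]] <- -Inf
  }
  total / R
}

#' Select tensor rank by initialization stability
#'
#' Fits each candidate rank `n_inits` times from random starts and computes
#' the mean [similarity_index()] between factorizations from consecutive
#' initializations. The chosen rank is the largest whose mean similarity
#' exceeds `threshold` (0.9 by default); 0 if none qualifies.
#'
#' @param tensor 3-d array.
#' @param max_rank Largest rank to try.
#' @param n_inits Fits per rank (each itself best-of-1 start).
#' @param threshold Mean-similarity cutoff.
#' @param seed Integer seed.
#' @param ... Passed to [fit_cp()] (`tol`, `max_iter`).
#' @return List with `rank` (chosen), `mean_similarity` per candidate rank.
#' @export
select_rank <- function(tensor, max_rank = 3L, n_inits = 10L,
                        threshold = 0.9, seed = NULL, ...) {
  sims <- numeric(max_rank)
  for (r in seq_len(max_rank)) {
    fits <- lapply(seq_len(n_inits), function(i) {
      s <- if (is.null(seed)) NULL else seed + 1000L * r + i
      fit_cp(tensor, rank = r, n_inits = 1L, seed = s, ...)
    })
    pair_sims <- vapply(seq_len(n_inits - 1L), function(i) {
      similarity_index(fits[[i]], fits[[i + 1L]])
    }, 0)
    sims[r] <- mean(pair_sims)
  }
  ok <- which(sims > threshold)
  list(rank = if (length(ok)) max(ok) else 0L, mean_similarity = sims)
}

#' Shuffle-corrected reward-triggered averages of the trial factor
#'
#' For each lag j = 0..`max_lag`, the mean deviation of the trial factor from
#' its session mean, j trials after every rewarded trial (and after every
#' unrewarded trial). The same quantity computed over `n_shuffles` random
#' permutations of the reward labels is averaged and subtracted, removing the
#' bias that rewarded trials are not a random subset.
#'
#' @param trial_factor Numeric per-trial factor `a`.
#' @param rewards Logical per-trial reward indicator.
#' @param n_shuffles Label permutations (default 100).
#' @param max_lag Largest lag in trials (default 7).
#' @param seed Integer seed.
#' @return Object of class `triggered_average`: data.frame `lags` with
#'   `lag`, `reward_avg`, `noreward_avg` (shuffle-corrected) and the
#'   uncorrected `reward_raw`, `noreward_raw`.
#' @export
triggered_average <- function(trial_factor, rewards, n_shuffles = 100L,
                              max_lag = 7L, seed = NULL) {
  a <- as.numeric(trial_factor)
  rewards <- as.logical(rewards)
  K <- length(a)
  if (K != length(rewards)) stop("lengths differ")
  if (K < max_lag + 1L) stop("need at least ", max_lag + 1L, " trials")
  dev <- a - mean(a)
  lag_means <- function(rw) {
    vapply(0:max_lag, function(j) {
      idx <- which(rw)
      idx <- idx[idx + j <= K]
      if (!length(idx)) return(NA_real_)
      mean(dev[idx + j])
    }, 0)
  }
  raw_r <- lag_means(rewards)
  raw_n <- lag_means(!rewards)
  sh <- with_seed(seed, {
    acc_r <- acc_n <- matrix(0, n_shuffles, max_lag + 1L)
    for (s in seq_len(n_shuffles)) {
      perm <- sample(rewards)
      acc_r[s, ] <- lag_means(perm)
      acc_n[s, ] <- lag_means(!perm)
    }
    list(r = colMeans(acc_r), n = colMeans(acc_n))
  })
  structure(list(lags = data.frame(
    lag = 0:max_lag,
    reward_avg = raw_r - sh$r,
    noreward_avg = raw_n - sh$n,
    reward_raw = raw_r,
    noreward_raw = raw_n
  ), n_shuffles = n_shuffles), class = "triggered_average")
}

#' @export
print.triggered_average <- function(x, ...) {
  cat("Shuffle-corrected triggered averages of the trial factor\n")
  print(round(x$lags, 4), row.names = FALSE)
  invisible(x)
}

#' Correlation between trial factor and previous-trial reward
#'
#' Pearson correlation of the trial factor `a_k` with the indicator of reward
#' on trial `k - 1`, the session-level statistic used to ask whether the
#' population gain tracks reward history (negative r: activity decreases
#' after reward).
#'
#' @param trial_factor Numeric per-trial factor.
#' @param rewards Logical per-trial reward indicator.
#' @return List with `r`, `p_value`, `n`.
#' @export
trialfactor_reward_correlation <- function(trial_factor, rewards) {
  a <- as.numeric(trial_factor)
  rewards <- as.logical(rewards)
  K <- length(a)
  if (K != length(rewards)) stop("lengths differ")
  if (K < 10L) stop("need at least 10 trials")
  y <- a[-1L]
  x <- as.numeric(rewards[-K])
  if (stats::sd(y) == 0 || stats::sd(x) == 0) {
    stop("correlation undefined: constant trial factor or rewards")
  }
  ct <- stats::cor.test(y, x, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = K - 1L)
}
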