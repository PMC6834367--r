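# Cross-session unit identity from tetrode waveform templates.
# Templates are 4 x S matrices (channels x samples, arbitrary units).

#' Random tetrode waveform template
#'
#' Builds a biphasic spike shape (trough followed by a slower positive
#' after-wave) whose trough/peak positions, widths and lobe ratio vary from
#' unit to unit, with per-channel amplitudes drawn log-normally (s.d. 0.35 on
#' the log scale, i.e. roughly a 2-fold amplitude range across the tetrode's
#' channels). Serves as the ground-truth base template for drift simulations;
#' different units get genuinely different shapes, so cross-unit pairs are
#' separable by shape as well as by amplitude pattern.
#'
#' @param n_samples Samples per channel.
#' @param seed Integer seed.
#' @return A 4 x `n_samples` matrix.
#' @export
make_base_waveform <- function(n_samples = 32L, seed = NULL) {
  with_seed(seed, {
    t <- seq(0, 1, length.out = n_samples)
    trough_pos <- stats::runif(1, 0.22, 0.38)
    trough_w <- stats::runif(1, 0.04, 0.09)
    peak_pos <- trough_pos + stats::runif(1, 0.15, 0.35)
    peak_w <- stats::runif(1, 0.08, 0.18)
    peak_amp <- stats::runif(1, 0.25, 0.6)
    shape <- -exp(-(t - trough_pos)^2 / (2 * trough_w^2)) +
      peak_amp * exp(-(t - peak_pos)^2 / (2 * peak_w^2))
    amps <- exp(stats::rnorm(4, 0, 0.35))
    outer(amps, shape)
  })
}

#' Simulate waveform drift across sessions
#'
#' For each session, the base template's channels are rescaled by independent
#' log-normal amplitude factors and perturbed by additive shape noise
#' (relative to the base peak amplitude), emulating slow electrode drift
#' while retaining ground-truth identity.
#'
#' @param base 4 x S base template (see [make_base_waveform()]).
#' @param n_sessions Number of sessions to generate.
#' @param config A [waveform_sim_config()].
#' @param seed Integer seed.
#' @return List of 4 x S per-session templates.
#' @export
simulate_waveform_drift <- function(base, n_sessions,
                                    config = waveform_sim_config(),
                                    seed = NULL) {
  base <- as.matrix(base)
  if (nrow(base) != 4L) stop("base template must have 4 channels")
  stopifnot(inherits(config, "waveform_sim_config"))
  peak <- max(abs(base))
  with_seed(seed, {
    lapply(seq_len(n_sessions), function(s) {
      scales <- exp(stats::rnorm(4L, 0, config$amp_drift_sd))
      base * scales + matrix(
        stats::rnorm(length(base), 0, config$shape_jitter_sd * peak),
        nrow = 4L)
    })
  })
}

#' Optimal scaling of one waveform onto another
#'
#' The scale minimizing \eqn{\|\alpha x - y\|^2}, in closed form
#' \eqn{\alpha = (x \cdot y) / (x \cdot x)} — the exact optimum of the 1-d
#' least-squares problem.
#'
#' @param x,y Equal-length channel waveforms; `x` (session 1) is scaled onto
#'   `y` (session 2).
#' @return The scalar alpha.
#' @examples
#' optimal_scale(1:4, 2 * (1:4)) # 2
#' @export
optimal_scale <- function(x, y) {
  if (length(x) != length(y)) stop("waveforms must have equal length")
  ss <- sum(x * x)
  if (ss == 0) stop("zero-norm x waveform")
  sum(x * y) / ss
}

# per-channel optimal scales for two 4 x S templates
channel_alphas <- function(X, Y) {
  vapply(1:4, function(i) optimal_scale(X[i, ], Y[i, ]), 0)
}

check_templates <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != 4L || nrow(Y) != 4L) stop("templates must have 4 channels")
  if (ncol(X) != ncol(Y)) stop("templates must have equal sample counts")
  list(X = X, Y = Y)
}

#' Waveform shape distance d1
#'
#' Sum over the 4 tetrode channels of the Euclidean distance between the
#' optimally scaled session-1 channel and the session-2 channel, normalized
#' by the session-2 channel norm:
#' \eqn{d_1 = \sum_{i=1}^{4} \|\alpha_i x_i - y_i\| / \|y_i\|}.
#' Per-channel scaling is absorbed, so d1 is invariant to positive rescaling
#' of X's channels; it measures shape change only.
#'
#' @param X,Y 4 x S templates (session 1, session 2).
#' @return Nonnegative distance.
#' @export
waveform_d1 <- function(X, Y) {
  tp <- check_templates(X, Y); X <- tp$X; Y <- tp$Y
  al <- channel_alphas(X, Y)
  sum(vapply(1:4, function(i) {
    ny <- sqrt(sum(Y[i, ]^2))
    if (ny == 0) stop("zero-norm y channel ", i)
    sqrt(sum((al[i] * X[i, ] - Y[i, ])^2)) / ny
  }, 0))
}

#' Waveform amplitude-change distance d2
#'
#' \eqn{d_2 = \max_i |\log \alpha_i| + \max_{i,j} |\log \alpha_i -
#' \log \alpha_j|}: the first term detects overall amplitude change, the
#' second a change in the amplitude pattern across the 4 channels. A
#' non-positive alpha (inverted waveform) cannot be the same neuron and
#' returns `Inf` (non-match sentinel).
#'
#' @param X,Y 4 x S templates (session 1, session 2).
#' @return Nonnegative distance, or `Inf` when any alpha <= 0.
#' @examples
#' w <- make_base_waveform(seed = 1)
#' waveform_d2(w, 2 * w) # log(2)
#' @export
waveform_d2 <- function(X, Y) {
  tp <- check_templates(X, Y); X <- tp$X; Y <- tp$Y
  al <- channel_alphas(X, Y)
  if (any(al <= 0)) return(Inf)
  la <- log(al)
  max(abs(la)) + max(abs(outer(la, la, "-")))
}

#' Match units across two consecutive sessions
#'
#' Scores every same-tetrode pair of units by [waveform_d1()],
#' [waveform_d2()] and the Pearson correlation of their trial-start-aligned
#' mean firing rates (PSTHs). Pairs with `d1 < d1_max`, `d2 < d2_max` and a
#' significantly positive PSTH correlation are candidates; a one-to-one
#' assignment is made greedily in ascending d1. Unmatched units remain
#' distinct.
#'
#' @param waves_a,waves_b Lists of 4 x S templates (session 1, session 2).
#' @param psths_a,psths_b Lists of mean-rate vectors aligned to trial start,
#'   parallel to the template lists.
#' @param d1_max,d2_max Distance thresholds (defaults 0.8 and 1, calibrated
#'   on cross-animal null pairs).
#' @param alpha Significance level for the PSTH correlation.
#' @return data.frame of all pairs: `a`, `b`, `d1`, `d2`, `psth_r`,
#'   `psth_p`, `candidate`, `is_match`.
#' @export
match_units <- function(waves_a, waves_b, psths_a, psths_b,
                        d1_max = 0.8, d2_max = 1, alpha = 0.05) {
  na <- length(waves_a); nb <- length(waves_b)
  if (na != length(psths_a) || nb != length(psths_b)) {
    stop("template and PSTH lists must be parallel")
  }
  pairs <- expand.grid(a = seq_len(na), b = seq_len(nb))
  stats_fn <- function(i, j) {
    d1 <- waveform_d1(waves_a[[i]], waves_b[[j]])
    d2 <- waveform_d2(waves_a[[i]], waves_b[[j]])
    ct <- suppressWarnings(
      stats::cor.test(psths_a[[i]], psths_b[[j]], method = "pearson"))
    c(d1 = d1, d2 = d2, r = unname(ct$estimate), p = ct$p.value)
  }
  sm <- t(mapply(stats_fn, pairs$a, pairs$b))
  pairs$d1 <- sm[, "d1"]; pairs$d2 <- sm[, "d2"]
  pairs$psth_r <- sm[, "r"]; pairs$psth_p <- sm[, "p"]
  pairs$candidate <- pairs$d1 < d1_max & pairs$d2 < d2_max &
    pairs$psth_p < alpha & pairs$psth_r > 0
  pairs$is_match <- FALSE
  cand <- which(pairs$candidate)
  cand <- cand[order(pairs$d1[cand])]
  used_a <- logical(na); used_b <- logical(nb)
  for (k in cand) {
    if (!used_a[pairs$a[k]] && !used_b[pairs$b[k]]) {
      pairs$is_match[k] <- TRUE
      used_a[pairs$a[k]] <- TRUE
      used_b[pairs$b[k]] <- TRUE
    }
  }
  pairs
}

#' Calibrate d1/d2 thresholds on a null distribution
#'
#' Given templates from pairs that cannot be the same neuron (units from
#' different animals), reports the empirical distributions of d1 and d2 and
#' the quantiles at the requested false-positive rate as suggested
#' thresholds. Refuses degenerate nulls in which the distances collapse to
#' zero (identical templates).
#'
#' @param pairs_x,pairs_y Parallel lists of 4 x S templates forming the null
#'   pairs (>= 100 pairs).
#' @param fpr Target false-positive rate (default 0.05).
#' @return List with `d1`, `d2` (null values), `suggested` (named quantile
#'   thresholds).
#' @export
null_threshold_calibration <- function(pairs_x, pairs_y, fpr = 0.05) {
  n <- length(pairs_x)
  if (n != length(pairs_y)) stop("pair lists must be parallel")
  if (n < 100L) stop("need at least 100 null pairs")
  d1 <- mapply(waveform_d1, pairs_x, pairs_y)
  d2 <- mapply(waveform_d2, pairs_x, pairs_y)
  if (stats::median(d1) < 1e-8 && stats::median(d2[is.finite(d2)]) < 1e-8) {
    stop("degenerate null: distances collapse at 0 (identical templates)")
  }
  list(d1 = d1, d2 = d2,
       suggested = c(d1 = unname(stats::quantile(d1, fpr, type = 7)),
                     d2 = unname(stats::quantile(d2[is.finite(d2)], fpr,
                                                 type = 7))))
}
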