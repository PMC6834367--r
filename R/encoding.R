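#' Per-trial spike counts in a window around alignment events
#'
#' @param spike_times Numeric vector of one unit's spike times (s).
#' @param alignment_events Numeric vector, one event time per trial (s).
#' @param window Two-element window (s) relative to each event.
#' @return Integer vector of counts, one per trial.
#' @export
spike_counts <- function(spike_times, alignment_events, window) {
  if (length(window) != 2L || diff(window) <= 0) {
    stop("`window` must be an increasing [start, end] pair")
  }
  vapply(alignment_events, function(ev) {
    sum(spike_times >= ev + window[1L] & spike_times < ev + window[2L])
  }, integer(1))
}

#' Unit inclusion filter
#'
#' Retains units that fired more than two spikes on at least half of trials,
#' counting spikes over the full trial window.
#'
#' @param spikes Long spike table (`unit_id`, `time_s`).
#' @param events Per-trial event table with `trial_init` and `trial_end` (s).
#' @return Integer vector of retained unit ids.
#' @export
inclusion_filter <- function(spikes, events) {
  units <- sort(unique(spikes$unit_id))
  keep <- vapply(units, function(u) {
    st <- spikes$time_s[spikes$unit_id == u]
    n <- vapply(seq_len(nrow(events)), function(i) {
      sum(st >= events$trial_init[i] & st < events$trial_end[i])
    }, integer(1))
    mean(n > 2L) >= 0.5
  }, logical(1))
  units[keep]
}

# Centered moving average with symmetrically shrinking windows at the edges,
# matching the usual span-k moving-mean smoother for odd k.
moving_average <- function(x, span) {
  span <- as.integer(span)
  if (span <= 1L) return(x)
  if (span %% 2L == 0L) span <- span - 1L
  h <- span %/% 2L
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- min(h, i - 1L, n - i)
    out[i] <- mean(x[(i - k):(i + k)])
  }
  out
}

#' Bin and smooth spikes into trial-aligned firing rates
#'
#' Counts spikes in fixed-width bins (50 ms by default) around each alignment
#' event, converts counts to Hz, and smooths each trial's rate vector with a
#' centered moving average (span 5 bins by default, shrinking symmetrically at
#' the edges). The raw counts are returned alongside so total spike counts per
#' trial are conserved before smoothing.
#'
#' @param spike_times One unit's spike times (s).
#' @param alignment_events One event time per trial (s).
#' @param window `[start, end]` (s) relative to the event.
#' @param bin_width Bin width in seconds (default 0.05).
#' @param smooth_span Moving-average span in bins (default 5); 1 disables
#'   smoothing.
#' @return Object of class `aligned_rates`: `rates` (trials x bins, Hz,
#'   smoothed), `counts` (raw per-bin counts), `times` (bin centers, s),
#'   `bin_width`, `window`.
#' @examples
#' ar <- bin_and_smooth(c(0.01, 0.30), alignment_events = 0,
#'                      window = c(0, 0.5), smooth_span = 1)
#' ar$rates
#' @export
bin_and_smooth <- function(spike_times, alignment_events, window,
                           bin_width = 0.05, smooth_span = 5L) {
  if (length(window) != 2L || diff(window) <= 0) stop("empty analysis window")
  edges <- seq(window[1L], window[2L], by = bin_width)
  if (length(edges) < 2L) stop("window shorter than one bin")
  nb <- length(edges) - 1L
  K <- length(alignment_events)
  counts <- matrix(0L, K, nb)
  for (i in seq_len(K)) {
    rel <- spike_times - alignment_events[i]
    rel <- rel[rel >= edges[1L] & rel < edges[nb + 1L]]
    if (length(rel)) {
      counts[i, ] <- tabulate(findInterval(rel, edges), nbins = nb)
    }
  }
  rates <- counts / bin_width
  if (smooth_span > 1L) {
    rates <- t(apply(rates, 1L, moving_average, span = smooth_span))
    if (nb == 1L) rates <- matrix(rates, K, 1L)
  }
  structure(list(rates = rates, counts = counts,
                 times = (edges[-1L] + edges[-(nb + 1L)]) / 2,
                 bin_width = bin_width, window = window),
            class = "aligned_rates")
}

#' Two-condition selectivity test on spike counts
#'
#' Unpaired two-sample t-test of per-trial spike counts between the two
#' condition labels; the preferred condition is the one with the higher mean.
#'
#' @param counts Per-trial spike counts (or any per-trial response).
#' @param labels Per-trial condition labels (exactly 2 levels).
#' @return List with `p_value`, `preferred`, `means` (named per condition).
#' @export
selectivity_test <- function(counts, labels) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("labels must have exactly 2 levels")
  if (min(table(labels)) < 2L) stop("each condition needs >= 2 trials")
  a <- counts[labels == lev[1L]]
  b <- counts[labels == lev[2L]]
  p <- stats::t.test(a, b)$p.value
  means <- c(mean(a), mean(b))
  names(means) <- lev
  list(p_value = p, preferred = lev[which.max(means)], means = means)
}

# |mu1 - mu2| / sqrt((var1 + var2) / 2), columnwise over a trials x bins
# matrix; bins where both conditions have zero variance give 0.
dprime_bins <- function(rates, g1, g2) {
  m1 <- colMeans(rates[g1, , drop = FALSE])
  m2 <- colMeans(rates[g2, , drop = FALSE])
  v1 <- apply(rates[g1, , drop = FALSE], 2L, stats::var)
  v2 <- apply(rates[g2, , drop = FALSE], 2L, stats::var)
  pooled <- (v1 + v2) / 2
  d <- abs(m1 - m2) / sqrt(pooled)
  d[pooled == 0] <- 0
  d
}

#' Shuffle-corrected d-prime timecourse
#'
#' Per time bin, discriminability between two trial conditions is
#' \eqn{|\mu_1 - \mu_2| / \sqrt{(\sigma_1^2 + \sigma_2^2)/2}}. Because the
#' absolute difference is positively biased, the mean of the same statistic
#' over label shuffles (15 by default) is subtracted; corrected values may be
#' negative and are not clipped.
#'
#' @param aligned An [bin_and_smooth()] result (or any trials x bins matrix in
#'   `$rates`).
#' @param labels Per-trial 2-level labels (or logical).
#' @param n_shuffles Number of label permutations (0 = uncorrected).
#' @param seed Seed for the permutations.
#' @return Object of class `dprime_timecourse`: `dprime` (corrected, per
#'   bin), `uncorrected`, `shuffle_mean`, `times`, `n_zero_var` (bins where
#'   both conditions had zero variance, reported as 0).
#' @export
dprime_timecourse <- function(aligned, labels, n_shuffles = 15L, seed = NULL) {
  rates <- if (is.list(aligned)) aligned$rates else as.matrix(aligned)
  times <- if (is.list(aligned)) aligned$times else seq_len(ncol(rates))
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("labels must have exactly 2 levels")
  g1 <- labels == lev[1L]; g2 <- !g1
  if (sum(g1) < 2L || sum(g2) < 2L) stop("each condition needs >= 2 trials")
  v1 <- apply(rates[g1, , drop = FALSE], 2L, stats::var)
  v2 <- apply(rates[g2, , drop = FALSE], 2L, stats::var)
  n_zero <- sum(v1 + v2 == 0)
  raw <- dprime_bins(rates, g1, g2)
  if (n_shuffles < 1L) {
    return(structure(list(dprime = raw, uncorrected = raw,
                          shuffle_mean = rep(0, length(raw)), times = times,
                          n_zero_var = n_zero),
                     class = "dprime_timecourse"))
  }
  sh <- with_seed(seed, {
    acc <- matrix(0, n_shuffles, ncol(rates))
    for (s in seq_len(n_shuffles)) {
      perm <- sample(g1)
      acc[s, ] <- dprime_bins(rates, perm, !perm)
    }
    acc
  })
  shuffle_mean <- colMeans(sh)
  structure(list(dprime = raw - shuffle_mean, uncorrected = raw,
                 shuffle_mean = shuffle_mean, times = times,
                 n_zero_var = n_zero),
            class = "dprime_timecourse")
}

#' @export
print.dprime_timecourse <- function(x, ...) {
  cat(sprintf("Shuffle-corrected d': %d bins, peak %.3f at %.3f s\n",
              length(x$dprime), max(x$dprime), x$times[which.max(x$dprime)]))
  invisible(x)
}

#' @export
plot.dprime_timecourse <- function(x, ...) {
  graphics::plot(x$times, x$dprime, type = "l", xlab = "time (s)",
                 ylab = "shuffle-corrected d'", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Selectivity fractions and preference splits
#'
#' Summarizes per-unit selectivity results into, per variable, the fraction
#' of significant units and the split of significant units by preferred
#' condition; also returns the overlap (Venn) counts of units significant for
#' two chosen variables.
#'
#' @param results data.frame with columns `unit_id`, `variable`, `p_value`,
#'   `preferred` (one row per unit per tested variable).
#' @param alpha Significance level (default 0.05).
#' @param overlap Character pair of variables to cross-tabulate (default
#'   side x reward, when present).
#' @return List with `fractions` (data.frame per variable: `n_total`,
#'   `n_sig`, `fraction`) , `splits` (list of preferred-condition count
#'   tables among significant units), and `overlap` (named counts `both`,
#'   `only_<v1>`, `only_<v2>`, `neither`, or NULL).
#' @export
preference_fractions <- function(results, alpha = 0.05,
                                 overlap = c("side", "reward")) {
  stopifnot(all(c("unit_id", "variable", "p_value", "preferred") %in%
                  names(results)))
  vars <- unique(results$variable)
  fr <- do.call(rbind, lapply(vars, function(v) {
    r <- results[results$variable == v, ]
    data.frame(variable = v, n_total = nrow(r),
               n_sig = sum(r$p_value < alpha),
               fraction = mean(r$p_value < alpha))
  }))
  splits <- lapply(stats::setNames(vars, vars), function(v) {
    r <- results[results$variable == v & results$p_value < alpha, ]
    table(r$preferred)
  })
  ov <- NULL
  if (all(overlap %in% vars)) {
    r1 <- results[results$variable == overlap[1L], ]
    r2 <- results[results$variable == overlap[2L], ]
    ids <- union(r1$unit_id, r2$unit_id)
    s1 <- ids %in% r1$unit_id[r1$p_value < alpha]
    s2 <- ids %in% r2$unit_id[r2$p_value < alpha]
    ov <- c(both = sum(s1 & s2), sum(s1 & !s2), sum(!s1 & s2),
            neither = sum(!s1 & !s2))
    names(ov)[2:3] <- paste0("only_", overlap)
  }
  list(fractions = fr, splits = splits, overlap = ov)
}
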