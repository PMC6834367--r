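---
title: "Models and methods behind riskybias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind riskybias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskybias)
```

This vignette documents the models the package implements, the defaults it
ships, and the numerical and design decisions behind them. Everything here
is exercised by the test suite on synthetic data; no claim below rests on
results the code does not itself compute.

## The task and the synthetic session

A session is a sequence of independent trials. Each trial offers a
guaranteed ("safe") water volume on one side and a probabilistic ("risky")
volume on the other; the safe side is re-drawn every trial. Defaults in
`task_config()`:

* volumes {6, 12, 24, 48} uL, drawn uniformly and independently per side;
* risky probability uniform on {0, 0.1, ..., 1};
* flashes = round(10 p) (0-10 flashes conveys the probability), click rate
  numerically equal to the volume in Hz (both ranges 6-48);
* safe side Bernoulli(0.5);
* inter-trial intervals log-normal with median 3 s (sdlog 0.6). The ITI
  distribution is a modeling choice: only its median and spread matter for
  the ITI-matched control analyses, and a right-skewed positive
  distribution is the natural choice for self-paced trial initiation;
* optional laser epochs ("cue" or "choice_report") assigned independently
  at configurable fractions (0.15 is the fraction used in the perturbation
  configurations); a choice-report laser imposes a minimum 4 s ITI, because
  the illumination itself extends 4 s into the ITI.

The offer joint distribution is uniform by default. The empirical offer
frequencies of the original task are not tabulated anywhere we can consume,
so uniform sampling is the default and the generator accepts any
configuration a user prefers; none of the estimators depends on the offer
distribution for correctness.

## The generative agent and the choice model

The agent chooses right with probability

$$p(\mathrm{right}) = \frac{\mathrm{lapse}}{2} + (1-\mathrm{lapse})\,
\sigma\!\left(w_{ev}\,\Delta EV + w_{rs}\,x_{rs} + w_{rws}\,x_{rws} +
w_{lr}\,x_{lr} + w_{bias}\right)$$

with $\Delta EV$ the right-minus-left expected value in uL, $x_{lr} = \pm 1$
for the previous choice side, $x_{rs}$ the safe/risky category-repetition
regressor (previous category sign times the sign of where that category sits
now), and $x_{rws}$ active only after a rewarded risky choice, pointing
toward the current risky side. Positive weights always mean
"repeat / approach right". Two points matter:

* **One coding, two uses.** `simulate_agent()` and `build_design_matrix()`
  call the same regressor-coding function, so fitting the model to its own
  simulated output is a round-trip identity: the five fitted weights
  estimate the five planted weights directly. The test suite verifies
  recovery within 3 standard errors at $10^5$ trials.
* **Lapse outside the logistic.** The lapse is a uniform mixture *around*
  the logistic rather than a term inside it, so the logistic weights remain
  identifiable; the fitted model itself carries no lapse term.
* **Collinearity caveat.** On trials following a rewarded risky choice,
  $x_{rs}$ and $x_{rws}$ coincide up to sign, so their estimates are
  anti-correlated; both are still identified because $x_{rs}$ is also active
  after safe and after unrewarded risky trials. Standard errors reflect
  this.

Fitting is plain maximum likelihood (`stats::glm.fit`, binomial). Perfect
separation (e.g. a near-deterministic agent) is detected from the fitted
probabilities and triggers a small-ridge penalized IRLS refit
(`ridge = 1e-3` by default), flagged in the returned object. The
EV regressor is left in uL rather than z-scored; the scale of $w_{ev}$
(per uL) is then directly interpretable, and an option to standardize is
unnecessary for any analysis the package performs.

The laser-perturbation hook (`post_laser_params`) swaps in an alternative
weight vector on trials whose *previous* trial carried a chosen laser epoch:
perturbations in this task act on the *next* trial's biases, so that is the
generative locus of the planted effect.

## Behavioral metrics

* **Efficiency** is `0.5 (ratEV − randEV)/(maxEV − randEV) + 0.5`, computed
  from per-trial expected values; it is undefined (and raises an error) when
  every offer pair is equal on both sides. The training criterion is
  `median(all sessions) − 1.5 * IQR(second half of sessions)`; quartiles use
  linear interpolation (R's type 7), stated explicitly because the
  criterion's value depends on the quartile convention.
* **Bias estimators** are conditional probability differences. "Following a
  risky reward" always conditions on the previous trial being a rewarded
  risky *choice*; unrewarded risky trials are a separate null. The first
  trial of a session enters no conditional estimator. The spatial win-stay
  and lose-switch deltas are referenced to the session-wide repeat and
  switch probabilities: the reference for "change in probability" is a
  design choice, and the unconditional session-wide rate is the default
  because it is estimable on every session; both conditional values and the
  baseline are returned so any other reference can be formed.
* **Confidence intervals** use the normal approximation
  $z\sqrt{p_1(1-p_1)/n_1 + p_2(1-p_2)/n_2}$ with $z = 1.96$ (the 97.5%
  normal quantile to five significant digits). This Wald-type interval
  slightly undercovers at small counts; the test suite checks coverage at
  session sizes (5000 trials) where the approximation operates in its
  asymptotic regime.
* **Laser comparisons** condition on the previous trial's laser epoch.
  With `iti_matched = TRUE`, control trials are restricted to those whose
  previous ITI was at least 4 s — the appropriate control when a bias decays
  with time, because choice-report illumination mechanically lengthens the
  ITI. A test plants an ITI-decaying spatial bias and verifies that the
  naive contrast shows a spurious "laser effect" that ITI matching removes.
* **Graded bias versus probability** bins post-risky-win trials by the
  previous gamble's probability (exact levels 0.1-1.0 by default — bins
  cannot include p = 0, which cannot yield a win) and fits an ordinary
  least-squares line to the per-bin delta.

## Psychometric sigmoid

$p(\mathrm{safe}) = y_0 + (1-2a)/(1+e^{-b(V_S-V_R-x_0)})$ is fitted to 11
equal-width bins of the safe-minus-risky EV difference, after excluding
trials where both ports were certain. The objective is the unweighted mean
squared error on the binned proportions, minimized under box constraints
($y_0, a \in [0, 0.5]$, $b \in [0, 10]$, $x_0$ within the data range) by
L-BFGS-B from 20 random starts plus one data-driven start; the best start
wins, so the returned MSE is never worse than any initialization (asserted
in the tests). Fewer than 4 populated bins makes the 4-parameter fit
underdetermined and raises an error. Binned least squares (rather than
per-trial likelihood) is the fitting target because the curve is defined on
binned proportions; the bins also make the fit robust to the heavily
non-uniform density of EV differences.

## Single-unit encoding

Spike counts are binned at 50 ms, converted to Hz, and smoothed with a
centered moving average of span 5 bins that shrinks symmetrically at the
edges; raw counts are kept alongside, so the pre-smoothing spike count per
trial is conserved exactly. Units enter analysis only if they fired more
than two spikes (strictly; a unit with exactly two spikes everywhere is
excluded) on at least half of trials.

Discriminability per time bin is $d' = |\mu_1-\mu_2| /
\sqrt{(\sigma_1^2+\sigma_2^2)/2}$. The absolute value biases $d'$ upward, so
the mean of the same statistic over label shuffles (15 by default; tests use
more where a tighter null is wanted) is subtracted. Corrected values may
legitimately be negative and are not clipped; bins where both conditions
have zero variance are reported as 0 and counted. Analysis windows are not
dictated by the data format: reward-history tests default to [0, 1] s after
trial initiation and choice-report tests to [0, 1] s after center-poke exit,
both configurable. Risky-versus-safe choice selectivity should be computed
on rewarded trials only (reward receipt otherwise confounds the contrast);
the per-unit population average of $|d'|$ is used when summarizing, since
preferred conditions differ across units.

## Tensor decomposition

The session tensor is neurons × 50-ms bins × trials, each neuron divided by
its maximum rate plus a small epsilon so high-rate units do not dominate;
the factors' scale is arbitrary anyway, and the normalization constants are
recorded. Rank-R canonical polyadic factors are fitted by alternating least
squares: each mode update is the exact least-squares solution given the
other two modes, so the reconstruction error is non-increasing (asserted per
iteration in the tests). Convergence is declared when the relative error
changes by less than `tol = 1e-8`; the best of `n_inits` uniform random
initializations is returned. Factors are canonicalized — unit-norm neuron
and temporal factors, scale absorbed into the trial factor, signs flipped so
the neuron and temporal factors have nonnegative means — which makes
re-fitting a canonicalized model reproduce identical factors.

Rank is selected by refitting each candidate rank from independent random
starts and averaging a similarity index over consecutive pairs; the chosen
rank is the largest with mean similarity above 0.9. The similarity of two
factorizations multiplies, per matched component, the absolute cosine
similarities of the three modes *and* a scale-agreement factor
$1 - |s_1-s_2|/\max(s_1,s_2)$; components are matched greedily. The scale
factor matters: a rank-2 fit of rank-1 data produces two nearly collinear
components whose canceling scales vary across initializations — without the
scale penalty such degenerate fits can look reproducible and the procedure
over-selects. Greedy matching is an approximation to the full permutation
search; for the rank 1-3 regime analyzed here the two coincide except in
contrived ties.

Trial-factor analyses: the shuffle-corrected reward-triggered average takes,
for each lag 0-7, the mean deviation of the trial factor from its session
mean j trials after rewarded (and after unrewarded) trials, minus the same
quantity averaged over label permutations (100 by default — the shuffle
count is unstated for this analysis in the source procedure, and 100 makes
the correction's Monte-Carlo error negligible relative to the effects
tested). "Reward history" for the session-level correlation is the
previous-trial reward indicator; an exponential-kernel history is a natural
extension but is not what the correlation analysis specifies, so it is not
the default.

## Population simulator: what it emulates, and what it does not

`simulate_population()` generates inhomogeneous-Poisson spike trains whose
rate on trial k is
$g_k[\,\mathrm{baseline} + \mathrm{transient}(t)(1 + h\,\mathbb{1}(\text{prev
unrewarded})) + \mathrm{selectivity}(t)\,]$: a Gaussian transient 0.15 s
after trial initiation (s.d. 0.12 s) carrying reward history, Gaussian
selectivity bumps 0.25 s after the center-poke exit (fixed at 1.5 s after
initiation) for side / risk / reward-receipt preferences, and a shared
across-trial gain $g_k = 1 - \gamma\,\mathbb{1}(\text{prev rewarded}) +
\epsilon_k$ — exactly the rank-1 trial-factor structure the decomposition
is meant to recover. History-modulated units fire more after unrewarded
trials (the dominant empirical class). Negative rates are clipped at zero
and counted.

This emulates the *structure* the analyses target, not cortical data:
spiking is Poisson (no refractoriness, bursting or autocorrelation), trial
durations and event times are fixed, selectivity is additive and Gaussian in
time, and the across-trial gain is exactly rank 1. Passing tests therefore
demonstrate that the estimators recover what was planted under their own
assumptions — they do not certify behavior on real recordings, where
rank-1-ness, Poisson noise and stationarity all fail to various degrees.

## Unit tracking

For two same-tetrode templates on consecutive sessions, each channel of
session 1 is scaled by the closed-form least-squares optimum
$\alpha = (x \cdot y)/(x \cdot x)$ — identical to the numerical minimization
it replaces, exact and faster. Distances: $d_1$ sums the
$\|\alpha_i x_i - y_i\|/\|y_i\|$ residuals over the 4 channels (shape
change; invariant to per-channel rescaling of X), and $d_2 = \max_i|\log
\alpha_i| + \max_{i,j}|\log\alpha_i - \log\alpha_j|$ (amplitude change and
amplitude-pattern change). A non-positive $\alpha$ means an inverted
waveform and is an automatic non-match ($d_2 = \infty$) rather than a
complex logarithm. Both distances are directional (session 1 onto session
2), and the decision uses that direction throughout. Candidates must pass
$d_1 < 0.8$, $d_2 < 1$ and a significantly positive Pearson correlation of
trial-start-aligned PSTHs; one-to-one assignment is greedy in ascending
$d_1$. The manual-review stage of the original procedure is replaced by the
PSTH criterion plus the returned per-pair table, which preserves everything
a reviewer would inspect.

The drift generator draws per-session, per-channel log-normal amplitude
scales (s.d. 0.08) and additive shape noise (2% of the base peak); base
templates vary in trough/peak position, width and lobe ratio across units
and spread channel amplitudes log-normally (s.d. 0.35, about a two-fold
range across a tetrode). These values were fixed once as a realistic
"matchable drift" regime: under them, true pairs pass the 0.8/1 thresholds
and cross-unit nulls fail them in ≥95% of simulated pairs (verified in the
tests, 100-120 pairs per run, and in a 300-pair calibration during
development). Shape diversity across units is essential — were all units to
share one template shape, the null would be separable only by amplitude
pattern, which is not how real units differ.

## Problem sizes and runtime choices

The test suite runs at desk scale: $10^5$ trials for weight-recovery and
estimator-consistency checks, 5000-trial sessions for CI coverage (100
seeded repetitions), 2000 trials per condition for the $d'$ closed-form
check, 500 repetitions for shuffle-correction unbiasedness, a
60 × 60 × 300 Poisson tensor for CP recovery, 15 × 12 × 40 tensors for rank
selection, and 100-120 waveform pairs for matching calibration. These sizes
were chosen so every stochastic assertion sits several standard errors from
its threshold while the whole suite completes in about a minute.

## Known limitations

* The offer joint distribution is uniform unless configured otherwise.
* The Wald CI undercovers slightly for counts below a few hundred; a
  score-type interval would be more accurate there but would no longer be
  the interval the downstream comparisons are defined with.
* Rank selection near the 0.9 stability threshold is inherently noisy for
  tensors that are "almost" higher-rank; the similarity trace for every
  candidate rank is returned so borderline cases can be inspected.
* The ALS fitter is dense and unconstrained; it is not intended for tensors
  beyond a few hundred units/trials, which is far above any simultaneous
  recording session it targets.
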