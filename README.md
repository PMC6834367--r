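# riskybias

Sequential-bias and neural-population analyses for a rodent risky-choice
task, with a synthetic-data generator that plants every effect the analyses
are meant to detect.

## The problem

In the task, a rat chooses between two side ports: one offers a guaranteed
("safe") water reward and the other a probabilistic ("risky") reward. Click
rates convey the water volume at each port (6–48 uL) and light flashes
convey the risky probability (0–1 in steps of 0.1); the safe side moves
randomly every trial. Although trial outcomes are independent by design,
animals show *sequential biases*: they gamble more after a risky win (a
risky "win-stay" bias, expressed in abstract safe/risky coordinates) and
repeat or switch ports depending on the previous outcome (spatial
win-stay/lose-switch biases). The package implements the full quantitative
pipeline used to measure these biases behaviorally, to find their neural
correlates in orbitofrontal single-unit recordings, and to test them with
trial-triggered perturbations — all runnable end-to-end on simulated data
with known ground truth.

## What is inside

**Behavior.** Choice *efficiency* normalizes the subject's mean expected
value (EV) per trial between a random chooser and an EV maximizer:

    efficiency = 0.5 * (ratEV − randEV) / (maxEV − randEV) + 0.5

so 0.5 is chance and 1.0 is ideal; a training criterion flags sessions below
`median − 1.5·IQR(second half)`. Sequential biases are conditional choice
probability differences, e.g. risky win-stay =
P(choose safe | previous trial a rewarded safe choice) − P(choose safe |
previous trial a rewarded risky choice), with normal-approximation 95% CIs
`z·sqrt(p1(1−p1)/n1 + p2(1−p2)/n2)`. Laser-vs-control comparisons condition
on the previous trial's laser epoch, with optional minimum-ITI-matched
controls.

**Choice models.** A five-term logistic model of choosing right,
`P(right) = σ(w_ev·ΔEV + w_rs·x_rs + w_rws·x_rws + w_lr·x_lr + w_bias)`,
with safe/risky hysteresis, risky win-stay, side hysteresis and side-bias
regressors — the identical coding drives the generative agent, so planted
weights are recoverable. A 4-parameter psychometric sigmoid
`y0 + (1−2a)/(1+exp(−b(VS−VR−x0)))` is fitted to 11 binned safe-choice
proportions by constrained multi-start least squares.

**Neural encoding.** 50-ms binning with moving-average smoothing, a
more-than-two-spikes-on-half-of-trials inclusion filter, unpaired t-test
selectivity with preference splits, and shuffle-corrected discriminability
`d' = |μ1 − μ2| / sqrt((σ1² + σ2²)/2)` (the mean of 15 label-shuffled d'
values is subtracted to remove the absolute-value bias).

**Tensor decomposition.** Neuron × time × trial tensors are approximated by
rank-1 (or rank-R) canonical polyadic factors `Σ w_r ⊗ b_r ⊗ a_r` via
alternating least squares; rank is selected by the similarity of factors
across random initializations (threshold 0.9); trial factors are related to
reward history via shuffle-corrected reward-triggered averages (lags 0–7)
and a Pearson correlation with the previous trial's reward.

**Unit tracking.** Cross-session identity of tetrode units from per-channel
optimally scaled waveform distances d1 (shape) and d2 (amplitude pattern,
`max|log α| + max|log α_i − log α_j|`), thresholds 0.8 and 1, plus a PSTH
correlation check and greedy one-to-one assignment; null calibration from
cross-animal template pairs.

## Worked example

```r
library(riskybias)
off <- generate_offers(5000, task_config(), seed = 1)
beh <- simulate_agent(off, agent_params(w_ev = 0.15, w_risky_winstay = 0.8,
                                        w_lr_hyst = 0.4), seed = 2)
compute_efficiency(beh)
#> Session efficiency: 0.935
#>   rat 24.60 | random 16.92 | maximizer 25.75 uL/trial
risky_winstay_bias(beh)
#> risky win-stay: 0.1227 +/- 0.0345  [p1 = 0.689 (n = 3326), p2 = 0.566 (n = 998)]
summary(fit_choice_model(beh))
#> Logistic choice model, 4999 trials
#>                  Estimate Std. Error z value Pr(>|z|)
#> w_ev             0.147770   0.004680  31.573   <2e-16 ***
#> w_rs_hyst       -0.044092   0.047932  -0.920    0.358
#> w_risky_winstay  0.911049   0.107528   8.473   <2e-16 ***
#> w_lr_hyst        0.417667   0.042016   9.941   <2e-16 ***
#> w_lr_bias       -0.001322   0.041304  -0.032    0.974
```

The agent earns 93.5% of the achievable EV range; its positive risky
win-stay bias (0.123 ± 0.035: safe choices are 12 points likelier after a
guaranteed reward than after a risky win) and the planted logistic weights
(0.15, 0, 0.8, 0.4, 0) are recovered within sampling error. Note the small
negative `w_rs_hyst`: on post-risky-win trials the hysteresis and win-stay
regressors coincide, so these two estimates are anti-correlated at finite n.

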