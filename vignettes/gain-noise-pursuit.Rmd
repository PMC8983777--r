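---
title: "Gain noise in pursuit initiation: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gain noise in pursuit initiation: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pursuitgain)
```

This vignette is the package's account of the science it implements: the
generative model of pursuit variability, the variance-model fits and their
comparison, the trace-preprocessing pipeline, the biomimetic
population-decoder simulator, and the places where the design was genuinely
open and a choice had to be made.

## 1. The simple gain-noise model

Eye speed at pursuit initiation is modelled, trial by trial, as

$$E = (G + \eta_G)(\hat{s} + \eta_s) + \eta_m,$$

with the sensory estimate taken as unbiased ($\hat s = s$, the target
speed), and three independent zero-mean Gaussian noise sources:

| source  | distribution            | meaning                                   |
|---------|-------------------------|-------------------------------------------|
| $\eta_s$ | $N(0,\, w_s^2 s^2)$     | signal-dependent sensory (Weber) noise     |
| $\eta_m$ | $N(0,\, w_m^2 \mu^2)$   | signal-dependent motor noise, $\mu = Gs$   |
| $\eta_G$ | $N(0,\, \sigma^2)$      | gain noise: fluctuation of visuomotor gain |

Independence gives mean $\mu = Gs$ and variance
$\mathrm{Var}(E) = (w_s^2 + w_m^2)\mu^2 + \mu^2(\sigma^2 + \sigma^2
w_s^2)/G^2$, i.e. signal-dependent noise with squared *effective* Weber
fraction

$$w_\mathrm{eff}^2 = (w_s^2 + w_m^2) + \frac{\sigma^2 + \sigma^2
w_s^2}{G^2}.$$

Dimensionally the right-hand side is the *squared* Weber fraction
(variance $= w_\mathrm{eff}^2\mu^2$); the package therefore exposes
`effective_weber_sq()` and its square root `effective_weber()`, keeping
internal consistency with $\sigma^2 = w^2\mu^2$ throughout. The key
property — tested exhaustively — is that $\partial w_\mathrm{eff}^2 /
\partial G < 0$ exactly when $\sigma > 0$ and $w_\mathrm{eff}$ is
gain-independent when $\sigma = 0$. Because target size sets $G$, only
gain noise lets the Weber fraction of behavior vary with target size at
matched mean output.

`gain_noise_params()` bundles $(w_s, w_m, \sigma)$ with a size-to-gain map.
The default gains are the regression slopes reported for monkey R (0.31,
0.52, 0.62 for 2, 6, 20 deg patches; `monkey_gains("X")` gives 0.46, 0.77,
0.80). The noise defaults $w_s = 0.1$, $w_m = 0.05$, $\sigma = 0.05$ are
**placeholders**: the corresponding fitted values for the monkeys live in
supplementary material not reproduced here, so these are plausible
magnitudes for primate pursuit, not published estimates. Every analysis in
the package either recovers them from synthetic data or treats them as free
configuration.

## 2. The synthetic behavior generator

`simulate_pursuit_trials()` draws scalar single-trial eye speeds exactly
from the generative equation above, over the task's condition grid: five
target speeds evenly spaced 4–20 deg/s, patch diameters {2, 6, 20} deg, and
left/right directions generated symmetrically (all analyses condition on
direction). `simulate_pursuit_traces()` wraps each scalar in a
time-resolved trace: zero before pursuit onset, a half-cosine ramp of 30 ms
beginning at 75 ms plus a per-trial latency offset drawn uniformly from
$\pm h$ ($h = 20$ ms by default), then a plateau at the scalar value, at
1 ms resolution for 300 ms.

What the trace model is and is not: real eye-speed traces have richer
dynamics (acceleration transients, ringing, feedback after ~100 ms); the
half-cosine template is the simplest smooth monotone onset with a
*well-defined ground-truth latency*, which is all the alignment algorithm
needs to be exercised against. Motor noise is applied to the scalar
plateau, not per sample, because the downstream statistics operate on the
time-averaged scalar; an optional additive white measurement noise per
sample (`sample_noise_sd`) exists and defaults to off. The unjittered
plateau begins at 105 ms, just before the 110–190 ms averaging window, so
that with zero jitter the window average recovers the scalar exactly and
scalar-only and trace-based analyses coincide — a property the test suite
asserts. Passing tests on this generator therefore show that the *analysis
chain* is correct under the model's assumptions; they cannot show that real
pursuit data satisfy those assumptions (Gaussianity, independence of the
three sources, per-trial constancy of the gain).

The only deliberately unrealistic ingredient is the saccade injector
(`inject_saccades()`), which adds one-sample 200 deg/s velocity spikes so
the exclusion step can be tested against ground truth.

## 3. The preprocessing pipeline

`exclude_trials()` screens 0–250 ms after motion onset and discards trials
whose absolute sample-to-sample acceleration exceeds a threshold (default
5000 deg/s²). The criterion used on the real data ("any trial with a
saccade") is not specified quantitatively, so the threshold is a
configurable stand-in: far above the ≤500 deg/s² reached by the synthetic
ramps, far below an injected spike's ~2×10⁵ deg/s².

`align_latency()` removes trial-by-trial latency variation by exhaustive
grid search: for each trial it finds the time lag, matching gain and speed
offset that minimise the summed squared error between
$g\cdot x(t+\mathrm{lag}) + o$ and the conditional mean trace over
0–250 ms. Grids default to lag −40..50 ms in 1 ms steps, gain 0.2..1.9 in
0.05 steps, offset ±2 deg/s in 0.25 steps (~6.5×10⁴ grid points per trial;
the quadratic objective is evaluated from five running sums per lag, so the
search is effectively instantaneous). Three choices here deserve flagging:

* **Only the lag is applied to the data.** The procedure "shifts and
  scales" each trial to match the mean, but the scaled trial is used only
  for *matching*: applying the fitted gain and offset to the data would
  erase exactly the trial-to-trial amplitude variance the entire analysis
  is about. Gain and offset are nuisance parameters of the match.
* **Only relative latency is identified.** The conditional mean is itself
  smeared by the jitter, so the recovered lags carry an arbitrary
  common-mode shift (typically 1–3 ms with the default template). Tests
  assert relative-lag recovery and post-alignment variance reduction, not
  absolute lags, and the common-mode component is harmless because the
  averaging window sits on the plateau.
* The conditional mean is computed once from raw traces; an optional
  `refine_iterations` re-estimates it from realigned traces. Uniform
  weighting over the window is assumed; shifted-out samples are dropped
  from the objective rather than zero-padded, so edge samples never
  fabricate error.

`time_average()` takes the closed-window 110–190 ms mean;
`condition_stats()` computes per-(direction, size, speed) means and
unbiased variances; `fit_gain_regression()` estimates per-size gains as OLS
slopes of single-trial eye speed on target speed.

## 4. Variance models, fitting and model comparison

`fit_variance_model()` fits one of four models of the condition variances
$\sigma^2_{\mathrm{obs},ij}$ by minimising
$\mathrm{SSE} = \sum_{ij} (\sigma^2_{\mathrm{obs},ij} -
\sigma^2_{\mathrm{pre},ij})^2$ over training speeds {4, 12, 20} deg/s:

* `fixed_w`: $\sigma^2_{\mathrm{pre}} = w^2\mu_{ij}^2$ (one shared $w$);
* `flexible_w`: $w_i$ free per size;
* `gain_noise`: $\sigma^2_{\mathrm{pre}} = w_s^2\mu_{ij}^2 + (\sigma^2 +
  \sigma^2 w_s^2) s_j^2$ — the gain cancels algebraically, so $w_s$ and
  $\sigma$ are the only free parameters;
* `no_gain_noise`: the same with $\sigma$ pinned to 0.

**Numerical choice.** All four objectives are linear least squares in
transformed parameters ($a = w^2$, or $(a, b) = (w_s^2, \sigma^2(1 +
w_s^2))$ under non-negativity), so the global minimum is available in
closed form; the package solves the tiny non-negative least-squares
problem exactly instead of running an iterative bounded optimiser with
multiple starts. There are no tolerances, no local minima, and ties and
negative fitted variances cannot occur (parameters are constrained
non-negative, and Weber fractions are capped at 2 by clipping). A separate
motor-noise parameter is *not* offered in the gain-noise fit: its
contribution $w_m^2\mu^2$ is exactly collinear with $w_s^2\mu^2$ in the
prediction, so it cannot change predicted variances — only the
interpretation of the recovered coefficient, which should be read as
$\sqrt{w_s^2 + w_m^2}$ when motor noise is present.

`score_rmse()` evaluates $\mathrm{RMSE} = \sqrt{\tfrac{1}{MN}\sum_{ij}
(\sigma^2_{\mathrm{obs},ij} - \sigma^2_{\mathrm{pre},ij})^2}$ on the
held-out speeds {8, 16} deg/s. Train and test sets are configurable; the
defaults implement the train/test protocol of the original analysis.

`bootstrap_compare()` repeats, `n_boot` times: sample half the trials in
every condition (stratified), fit both candidate models on that half's
condition statistics, score both on the held-out half's statistics over
*all* speeds, record the RMSE difference. The t statistic is the mean of
the difference distribution divided by its SD, with `n_boot - 1` degrees of
freedom. Two open points were decided as follows: the test is **one-sided**
by default (is model A better?), with `alternative = "two.sided"`
available, since the scientific questions are directional; and the
reference analysis reports t(499) while describing 1000 replicates, so the
package simply sets dof = `n_boot` − 1 and leaves `n_boot` to the caller.
Replicates whose halves yield undefined variances are skipped and counted.
Comparing a model with itself yields a degenerate all-zero difference
distribution, reported as t = 0, p = 0.5.

## 5. The biomimetic MT population

`mt_population()` samples 1280 model neurons: 180 foveal (eccentricity
uniform on 0.25–1 deg) and the rest with eccentricities drawn by inverse
CDF from a density $\propto$ eccentricity$^{-0.9}$ on 1–30 deg, polar angle
uniform. Tuning: preferred direction uniform on (−180, 180], direction
width uniform on 20–90 deg, preferred speed uniform in log₂ units over
0.5–256 deg/s, speed width uniform on 0.64–2.8 octaves, amplitude uniform
on 20–200 spikes/s. Receptive-field diameter is $(0.69\,\mathrm{ecc} +
1)/\sqrt{\pi}$ and the suppressive surround radius is three times the CRF
radius.

The response chain per neuron: wrapped-Gaussian direction tuning,
log₂-Gaussian speed tuning, and a size factor built from the *exact*
circle–circle overlap of the stimulus disc (centred at the fovea — trials
begin at fixation and only the open-loop epoch is modelled) with the CRF
and surround, passed through the threshold nonlinearity
$([\sqrt{z} - \omega]^+/(1-\omega))^n$ and divisive surround
normalisation $r_\mathrm{crf}/((1-\beta) + \beta(\epsilon +
(r_\mathrm{crf} + r_\mathrm{sur})/2))$. Defaults $\omega = 0$, $n = 1$,
$\beta = 1$ follow the reference parameterisation; all are exposed in
`mt_config()` so robustness sweeps can be scripted. Three decisions were
open:

* $\epsilon = 0.5$ is forced by requiring the normalised response to lie in
  [0, 1] at $\beta = 1$ (the extreme $r_\mathrm{crf} = 1, r_\mathrm{sur} =
  0$ gives $1/(\epsilon + 1/2) = 1$).
* The **surround region is the annulus** between the CRF radius and three
  times that radius, normalised by annulus area: "extra-classical"
  suppression should grow only as the stimulus extends *beyond* the CRF.
  Normalising by the full surround disc is available via
  `surround_full_disc`.
* Preferred-speed differences enter the correlation kernel in **log₂
  units**, consistent with the model's logarithmic speed axis.

Noise correlations decay with tuning distance:
$r_{ij} = r_\max e^{-\Delta PD^2/(\Delta PD_\max^2 \lambda_\theta^2)}
e^{-\Delta PS^2/(\Delta PS_\max^2 \lambda_s^2)}
e^{-\Delta C^2/(\Delta C_\max^2 \lambda_C^2)}$ with $\lambda_\theta = 0.40$,
$\lambda_s = 0.30$, $\lambda_C = 0.30$, $r_\max = 0.55$. The maxima are
fixed nominal values (180 deg, 9 octaves, 60 deg) rather than per-sample
empirical maxima, so the correlation structure does not depend on the
particular population draw; the diagonal is set to 1 (the kernel formula
itself would give $r_\max$ at $i = j$). If the matrix fails a
positive-definiteness probe it is projected to the nearest valid
correlation matrix (eigenvalue clipping plus diagonal rescale) and the
Frobenius norm of the adjustment is recorded; with the default
configuration no repair is needed.

Single-trial rates are $f_i + \eta_i$ with $\eta$ multivariate Gaussian,
$\mathrm{Cov}(\eta_i,\eta_j) = r_{ij}\sqrt{f_i f_j}$ — Poisson-like
variance equal to the mean rate, in rate units, with negative rates
rectified to zero and silent neurons receiving no noise. An explicit
correlated point-process sampler would fix higher moments too; the Gaussian
construction matches the first and second moments that every analysis in
the package consumes, and `sample_responses()` is the single place to swap
in a copula-based alternative.

## 6. The two-pathway decoder

`vector_average_speed()` computes $\hat s_h = \sum_i \cos\theta'_i\,
MT_i \log_2 s'_i / (\nu + \sum_i MT_i)$ (and $\hat s_v$ with sines), with
$\nu = 0.05$; the speed estimate $\hat s = \sqrt{\hat s_h^2 + \hat s_v^2}$
is kept in log₂ units and multiplied *directly* by the gain — no
exponentiation — because the logarithmic compression is compensated by the
gain's growth with speed. `gain_pathway()` is the direction-blind linear
sum $G_{MT} = \tfrac{1}{c}\sum_i MT_i \log_2 s'_i$ (as specified;
null-direction neurons consequently contribute positively to the gain).
`calibrate_decoder()` sets $c$ so that mean simulated pursuit for the
20-deg patch, averaged across the five speeds with gain noise disabled, is
10 deg/s; since the pathway is linear in $1/c$ this is a closed-form
rescale, independent of any initial guess, and calibrating with $\eta_G =
0$ matches the noisy-mean target because gain noise is zero-mean.
Simulated behavior is $m = (G_{MT} + \eta_G)\hat s$ per trial, and
`analyze_simulated_weber()` routes $m$ through the same condition-statistics
and variance-model machinery as behavior.

**The gain-noise SD for the biomimetic model** has no published value. The
default $\sigma = 0.30$ was selected once by the shipped grid procedure
(`scripts/choose-gain-noise-sd.R`): scan $\sigma$ over 0.05–0.50 in steps
of 0.05 and take the smallest value for which simulated behavior (300
trials per condition) shows per-size Weber fractions ordered $w(2) > w(6) >
w(20)$ with non-overlapping trial-resampling bootstrap intervals, for every
one of three independently sampled populations. Smaller values (0.10–0.20)
achieve the ordering for some population draws but not all.

Two properties of the simulator are worth stating because the tests rely on
them. First, *without* gain noise the per-size Weber fractions of simulated
behavior are not exactly equal: the decoder's output noise is
rate-dependent, and smaller patches recruit fewer, noisier neurons, leaving
a small residual size dependence (about 0.01 in $w$ at these problem
sizes). The contrast the simulator is asked to reproduce is therefore the
*ordered separation* appearing only with gain noise, not exact equality
without it. Second, gain noise is "noise added downstream" of MT: at
matched population responses it inflates behavioral variance at every
condition and strictly reduces the magnitude of trial-by-trial MT–pursuit
correlations, which `mt_pursuit_correlations()` measures within a single
condition for neurons whose preferred direction lies within ±45 deg of the
target direction or its opposite (the preferred- and null-direction classes
studied experimentally).

## 7. Statistical conventions in the test suite

Monte-Carlo agreement checks compare a sample moment against its analytic
value within three empirical standard errors. Where a check runs over a
parameter grid (81 cells for the variance identity), the three-SE rule is
applied *family-wise*: each cell is held to the Šidák-adjusted bound that
keeps the probability of any false alarm across the grid at the three-sigma
level, together with a bias guard on the mean z-score. This is the
simultaneous version of the same error rate, chosen because a per-cell
three-SE gate applied 81 times would fail somewhere by chance in roughly
one run in six even for an exact generator.

Problem sizes used by the checked analyses: 10⁶ trials per cell for the
variance identity; 2000 trials per speed for gain recovery; 10⁴ trials for
the correlation ceiling; 500 fresh trials per speed for decoder
calibration; 300 trials per condition with 200 bootstrap resamples for the
Weber-separation contrast; 500 split-half replicates for model comparison.
These are the sizes at which the corresponding quantities are statistically
decidable at the stated tolerances.

## 8. Known limitations

* The trace generator's onset template is stylised; the alignment algorithm
  is validated against its ground truth, not against real oculomotor
  dynamics, and real saccade detection needs more than an acceleration
  threshold.
* The Gaussian rate model matches first and second moments only; spike-count
  discreteness and higher-order correlations are absent.
* The decoder is open-loop by construction: no visual feedback, no temporal
  dynamics within the trial, no explicit model of the gain-control
  pathway's own circuitry beyond the additive $\eta_G$.
* Absolute pursuit latency is not identified by the alignment procedure
  (only relative latency is), and none of the analyses depend on it.
* Supplementary-level robustness sweeps (over $\omega$, $n$, $\beta$,
  population size) are scriptable through `mt_config()` but are not part of
  the shipped analyses.
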