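---
title: "Serial dependence with adaptation-aware readout: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial dependence with adaptation-aware readout: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(serialdep)
library(dplyr)
library(ggplot2)
```

`serialdep` implements an analysis pipeline for serial dependence in
orientation perception: the attraction of perceptual reports toward recently
seen stimuli, and its apparent conflict with the *repulsive* biases that
neuronal adaptation induces in sensory cortex. The package covers four
stages — behavioral psychometrics, an encoder–decoder population model,
inverted-encoding-model (IEM) decoding of voxel patterns, and hemodynamic
deconvolution — plus a synthetic-data generator that emulates the
discrimination task and orientation-tuned voxel data, so that every stage is
testable without access to human data.

## Conventions

Orientation is 180°-periodic. All circular arithmetic (tuning curves, the
adaptation gain dip, the IEM channel basis, circular summary statistics) is
carried out in a doubled-angle representation: an orientation difference of
`x` degrees enters trigonometric functions as `2x` in radians, and results
are halved back. `wrap_ori()` reduces signed differences to the principal
interval (−90°, 90°]. The orientation difference driving every
history-dependent quantity is `delta` = θ~n−1~ − θ~n~ (previous minus
current), wrapped.

Circular summaries use the mean resultant vector in doubled-angle space:
`circ_mean_deg()` (direction, reported in orientation degrees),
`circ_sd_deg()` (`sqrt(-2 log |R|)`, unitless), and `circ_corr_deg()`. The
correlation uses the *pairwise* Fisher–Lee T-linear form rather than the
mean-centered one: decoded and presented orientations are close to uniform
on the circle, where the resultant is near zero and the circular mean — and
with it the mean-centered estimator — becomes arbitrary.

## The binary response model and the DoG

Observers judge whether a probe was rotated clockwise (CW) or
counterclockwise of a remembered grating. The response model treats encoding
as Gaussian with bias μ and SD σ and mixes in a fixed guess rate g:

$$P(\mathrm{CW} \mid \delta\theta) = \tfrac{g}{2} +
  (1-g)\,\Phi\!\left(\frac{\delta\theta - \mu}{\sigma}\right),
  \qquad g = 0.25 .$$

The guess rate is never estimated: it bounds every trial's likelihood away
from zero (so the NLL is always finite) and keeps σ comparable across
observers. `fit_psychometric()` maximizes this likelihood with bounded
L-BFGS-B from several σ starts (2°, 5°, 10°; ties broken by lower NLL, then
smaller σ), dropping and counting unanswered trials.

Serial dependence is parameterized with the derivative-of-Gaussian

$$\mathrm{bias}(x) = x\,A\,w\,c\,e^{-(wx)^2}, \qquad c = \sqrt{2e},$$

where the normalization is chosen so the curve's peak (at $x = 1/(w\sqrt 2)$)
equals `A` exactly — the amplitude is then the peak bias in degrees.
`fit_dog()` fits (A, w, σ) by maximum likelihood with the per-trial bias
`dog(delta)` inside the response model; `fit_dog_ls()` fits raw continuous
errors (e.g. decoder errors) by least squares. The width is bounded to
[0.01, 0.3] /deg (FWHM roughly 4°–118°): below that bound the DoG
degenerates into a tilted line over (−90°, 90°] and the fit on flat data
becomes a meaningless boundary solution. FWHM is always computed numerically
by root-finding at half peak. Sliding-window summaries (`sliding_bias()`)
use a half-open 32°-wide window on `delta` (a window centered at 16°
contains exactly [0°, 32°)) stepping by 1°; empty windows are reported `NA`,
never zero. Close/far precision (`precision_close_far()`) splits at
|Δθ| = 30°, folds trials with negative `delta` so bias does not inflate the
variance estimate, and equates bin sizes by subsampling the larger bin 31
times without replacement, reporting the median.

## The encoder–decoder model

The encoding stage is a population of 100 von Mises units evenly tiling
orientation space. The expected unadapted response of unit $i$ to stimulus
$\theta_n$ is

$$\mathrm{Resp}_N(\theta_n)_i = R\,\gamma_N\,
  e^{\kappa(\cos(\phi_i - \theta_n) - 1)},$$

with κ = 1, baseline gain γ~N~ = 1 and rate scale R (so the peak unadapted
rate is exactly R; the exponent is read with the −1 inside so that R has
this role). Adaptation dips the gain around the previous stimulus:

$$\gamma_A(\theta_{n-1})_i = \gamma_N - \mathrm{rect}\!\left(
  \gamma_m \cos^3(\gamma_s(\phi_i - \theta_{n-1}))\right),$$

where γ~m~ ∈ [0, 1] is the dip depth, γ~s~ > 0 scales its width, and the
half-wave rectification keeps gains in [1−γ~m~, 1]. The cosine argument is
the *wrapped* principal difference scaled by γ~s~, in doubled-angle space:
for γ~s~ ≠ 1 the cubed cosine is not itself 180°-periodic, so scaling the
unwrapped difference would make the profile depend on an arbitrary branch
choice. With wrapping, rectification zeroes the lobe before the antipode
for every γ~s~ in the fitted range, so the profile stays continuous.

```{r gain, echo = FALSE}
m <- pop_model()
tibble(phi = m$phi,
       `gamma_s = 1` = gain_profile(m, 90, 0.3, 1),
       `gamma_s = 2` = gain_profile(m, 90, 0.3, 2)) |>
  tidyr::pivot_longer(-phi) |>
  ggplot(aes(phi, value, colour = name)) +
  geom_line() +
  labs(x = "tuning center (deg)", y = "gain",
       title = "Adaptation gain dip around a previous stimulus at 90 deg") +
  theme_minimal()
```

Decoding assumes Poisson spiking and evaluates, on a 1° orientation grid,
the log-likelihood that each orientation produced the observed activity.
The decoders differ only in their *assumed* expected rates:

* **unaware** — assumes the unadapted profile; when the input was actually
  adapted, likelihoods are repelled from the previous stimulus (this is the
  model of the fMRI decoder, which knows nothing of history);
* **aware** — assumes the true adapted profile; on noiseless input the
  maximum coincides with the presented orientation exactly (verified over
  the full 1° grid of stimulus/adapter pairs);
* **overaware** — assumes an adaptation (γ~m2~, γ~s2~) different from the
  true one; exaggerating the dip produces net *attraction*;
* **bayes-unaware / bayes-aware** — the corresponding likelihood multiplied
  by a temporal-contiguity prior: a mixture of a circular Gaussian centered
  on the previous stimulus (width ψ, free) and a uniform floor, with mixture
  weight P~SAME~ = 0.64 fixed. No Bayes-overaware variant is provided, so
  all readouts have two free parameters.

Noiseless observations use expected rates directly as the Poisson "counts"
via the continuous extension
$\log p = k \log\lambda - \lambda - \log\Gamma(k+1)$, and a rate floor of
10^−12^ inside the log guards the (unreachable in the fitted ranges) case of
an exactly zero expected rate. The grid MAP is refined by parabolic
interpolation around the peak (offsets clamped to half a grid step); ties
resolve deterministically to the first grid maximum.

```{r curves, echo = FALSE}
delta <- seq(-90, 90, 2)
bind_rows(
  model_bias_curve(m, "unaware", delta, gamma_m = 0.3) |> mutate(readout = "unaware"),
  model_bias_curve(m, "aware", delta, gamma_m = 0.3) |> mutate(readout = "aware"),
  model_bias_curve(m, "overaware", delta, gamma_m = 0.3, gamma_m2 = 0.45) |>
    mutate(readout = "overaware"),
  model_bias_curve(m, "bayes_aware", delta, gamma_m = 0.3, psi = 20) |>
    mutate(readout = "bayes-aware")) |>
  ggplot(aes(delta, bias, colour = readout)) +
  geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
  geom_line() +
  labs(x = expression(Delta * theta ~ "(deg)"), y = "decoded bias (deg)") +
  theme_minimal()
```

Every noiseless bias curve is odd-symmetric with zeros at 0° and ±90°;
`sim_decoder_errors()` adds Poisson sampling for variance analyses. The rate
scale R has no effect on the *bias* of non-Bayesian readouts (it cancels in
the argmax) and is conventionally fixed at 5 for them; for Bayesian readouts
it sets the sharpness of the likelihood relative to the prior and is a free
parameter. At R ≈ 1.7 the simulated decoder's error SD is about 5°, i.e.
the behavioral precision scale.

## Two-stage model fitting

`fit_encoding()` fits (γ~m~, γ~s~) by minimizing the residual sum of squares
between observed decoding errors and the *noiseless* unaware bias curve —
noise-free model activity makes the objective deterministic without changing
the expected bias. `fit_readout()` then fits the readout's two parameters —
(R, ψ) for the Bayesian readouts, (γ~m2~, γ~s2~) for the overaware one — by
maximizing the binary-response likelihood with the trial bias interpolated
from the readout's noiseless curve, σ held at a per-observer estimate
(a constant-bias psychometric fit) and the 25% guess rate. Both stages run a
dense 30 × 30 grid first (γ~m~, γ~m2~ ∈ [0, 0.8]; γ~s~, γ~s2~ ∈ [0.25, 4];
ψ ∈ [2°, 60°]; R ∈ [0.5, 50], log-spaced — ranges chosen to bracket the
no/strong-adaptation, narrow/broad-dip and weak/dominant-prior regimes) and
refine the best grid point with Nelder–Mead, never accepting a refined value
worse than the grid optimum. Fits are per cross-validation fold (consecutive
blocks of trials, `cv_folds()`, defaulting to 68 = 4 × 17), the same folds
in both stages; `compare_readouts()` pools held-out log-likelihood, and
`readout_variance()` simulates 1000 Poisson trials per fold, pools them, and
summarizes close/far circular SD and Jensen–Shannon divergence against a
reference error distribution (4°-binned, with additive smoothing).

**Identifiability.** The encoding parameters trade off along a
near-degenerate ridge: for instance (γ~m~, γ~s~) = (0.30, 1.00) and
(0.37, 1.31) generate unaware bias curves that differ by less than 0.3° at
every Δθ. With realistic error noise the *curve* is therefore recovered far
more reliably than the individual parameters, and parameter-space
disagreement between fits should be judged by the curves they imply. The
same applies to (γ~m2~, γ~s2~) in the overaware readout. The package's
recovery tests assert curve-space agreement for this reason.

## The synthetic-data generator

`sim_trials()` reproduces the task structure: blocks of trials whose
orientations are either a permuted linear grid spanning 180° with a random
per-block phase (uniform mode; a 17-trial block has exact 180/17° spacing)
or jittered 22.5°-spaced bins offset by 11.25° with near-oblique stimuli
always followed by near-cardinal ones (binned mode; jitter is uniform ±5°,
a magnitude the task description leaves open). Timing uses a 1 s stimulus,
delays of {5, 7, 9} s, ITIs uniform on [5, 9] s and a 2.5 s probe/response
period, which puts the median onset-to-onset interval at 17.5 s, matching
the paradigm; probe offsets default to ±4.6°, the average titrated
difficulty. `sim_responses()` inverts the response model for any bias
function (a DoG or a model bias curve), and `sim_spikes()` draws Poisson
counts from the adapted population.

`sim_voxels()` builds BOLD-like time series for 32 voxels with von Mises
tuning (κ~vox~ = 2, FWHM ≈ 49°, a mid-range value for voxel-level
orientation selectivity). Stimulus and probe events get amplitudes from the
same tuning curves, are convolved with a double-gamma kernel sampled at the
0.8 s TR over 30 taps, summed, and overlaid with white Gaussian noise.
Three generator defaults are deliberately anchored to the paradigm rather
than left free: the kernel's undershoot is placed 8–18 s poststimulus
(visual-cortex kernels in this paradigm show it there; the canonical SPM
shape puts it several seconds later, which would leak the previous trial's
undershoot into the current decoding window and manufacture a spurious
repulsion), the probe's amplitude equals the tuning-curve value (no extra
scaling), and the noise SD of 2 (in units of the kernel peak) is calibrated
so that windowed-average IEM decoding of the simulated data attains a
circular correlation near 0.3, the performance level reported for mid-level
visual cortex. Adaptation is emulated by subtracting `adapt_frac` (default
0.40) times the previous trial's *realized* response from the current one.
Ground-truth per-trial amplitudes are returned alongside the series so that
every downstream stage has an oracle.

What the generator does *not* emulate: spatially correlated noise,
physiological (cardiac/respiratory) fluctuations, scanner drift, voxel-wise
HRF variability, attention or arousal dynamics, and eye movements. Passing
tests therefore show that the pipeline is correct and sensitive under the
stated statistical structure, not that real fMRI data will behave this
cleanly.

## IEM decoding and HRF handling

`iem_train()`/`iem_decode()` implement the standard inverted encoding model:
8 channels with rectified cos⁵ tuning (doubled-angle) evenly tiling the
space, weights estimated as `pinv(C) B` (SVD pseudo-inverse, deterministic),
channel responses reconstructed as `B pinv(W)`, and orientation read out as
the angle of the channel vector mean, with the vector length kept as a
certainty proxy; zero-resultant profiles are flagged undefined and excluded
from circular summaries. Trial patterns average 4 TRs spanning 4.8–8.0 s
after onset — late enough to carry the stimulus response, early enough that
the probe (≥ 6 s after onset) contributes almost nothing through the
hemodynamic lag. `select_voxels()` applies the two-stage localizer filter
(spatial-condition t statistic, then a one-way F across 10° orientation
bins, each keeping the top half). `pca_dim()` compares the dimensionality
of activity after close (<30°) versus far (>60°) previous stimuli on
trial-count-equated subsets.

`fir_design()`/`deconvolve_hrf()` estimate per-voxel stimulus and probe
kernels over 30 TR lags by ordinary least squares (the design carries only
onsets, so kernels are orientation-independent); `fit_hrf_gamma()`
parameterizes a kernel as a difference of two gamma densities (six
parameters: two delay/dispersion pairs, undershoot ratio, amplitude) from
three starting points, flagging voxels whose fit fails to converge or
explains less than half the kernel variance rather than keeping them
silently. `trial_betas()` solves all trials' stimulus and probe amplitudes
simultaneously with the voxel's kernel, which removes the linear
contribution of earlier events to the current estimate — on noiseless
simulated data this returns the generating amplitudes to machine precision
even with adaptation on.

## Numerical choices and degenerate inputs

* Likelihood grid 1°, parabolic peak refinement, first-maximum tie-break.
* Rate floor 10^−12^ inside Poisson logs; gain floor 10^−12^ inside assumed-
  rate logs.
* Pseudo-inverses via SVD (`MASS::ginv`); rank-deficient GLM designs fall
  back to minimum-norm least squares with a warning, rank-deficient IEM
  training designs are an error naming the cause.
* One-class response sets are fitted but flagged (`boundary = TRUE`);
  degenerate `delta` support and empty close/far bins are errors.
* All stochastic functions take integer seeds; identical seeds give
  identical output.

## Problem sizes used in the shipped checks

The package's own validation uses desk-scale versions of the study design:
272-trial sessions (16 blocks of 17) for the voxel-simulation checks,
800-trial observers for parameter recovery, 10⁴ trials for psychometric
recovery, and 10 × 1000 pooled Poisson simulations for variance summaries.
These sizes sit at or near the per-participant scale of the paradigm (a
scanned observer contributes ~750–880 trials) while keeping the full suite
fast.

## Known limitations

* Group-level inference (random-effects tests across observers) is out of
  scope; fits are per observer and group summaries are plain aggregations.
* The encoding/readout parameter ridge means reported (γ~m~, γ~s~) pairs
  from different datasets should be compared via their bias curves.
* The voxel generator's noise is white; temporally autocorrelated noise
  would mildly inflate the effective precision of trial-beta estimates
  relative to what real data allow.
* The behavioral generator draws each trial's response independently;
  sequential effects beyond the one-trial-back bias (choice history,
  fatigue) are not modeled.
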