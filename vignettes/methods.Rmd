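---
title: "pulseDDM: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pulseDDM: models, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulseDDM)
```

## The model

pulseDDM fits a one-dimensional bounded drift-diffusion model of evidence
accumulation jointly to spike trains and binary choices from pulse-based
(auditory click) decision tasks.  A scalar latent accumulator $a(t)$, in
units of (adapted) clicks, evolves as

$$ da = \lambda\, a\, dt + \Delta(t)\, dt + \sigma_a\, dW
      + \sigma_s \Sigma(t)\, \eta\, dt $$

where $\Delta(t)$ and $\Sigma(t)$ are the difference and sum of the
sensory-adapted click magnitudes, $\lambda$ is the leak ($\lambda<0$) or
instability ($\lambda>0$) rate, $\sigma_a^2$ the diffusion variance rate,
and $\sigma_s^2$ the per-unit-click noise variance.  A symmetric absorbing
bound at $\pm B$ freezes the path (decision commitment); the initial state
is $N(0, \sigma_i^2)$.

Each click's effective magnitude is depressed by recent stimulus history:
an adaptation state $C$ relaxes to 1 with timescale $\tau_\phi$ and is
multiplied by $\phi$ at every click; a click's magnitude is the pre-jump
state, so an isolated click always counts 1.  Both sides share one
adaptation state by default (`shared = FALSE` gives per-side states — the
pooled form is the package's reading of the dynamics; the literature
contains both).

Neuron $n$ fires as a Poisson (or negative-binomial) process with
conditional intensity $\mathrm{softplus}(\theta_n a(t) + \theta^0_{n}(t))$:
a per-neuron slope on the accumulator plus a stimulus-independent
time-varying baseline, parameterized by six Gaussian radial basis functions
whose means tile the longest trial and whose common variance equals the
inter-mean spacing.  Baselines are pre-fit per neuron by Poisson maximum
likelihood and held fixed — the `a = 0` firing rate of the joint model then
equals the fitted trial-average rate, which is why the pre-fit uses the
softplus link (the clamped-linear variant is available via
`link = "linear"`).  The choice is a lapse-contaminated threshold rule:
with probability $\gamma$ a coin flip, otherwise right iff $a(T) > c$.

Three likelihood variants share this machinery: the **joint** model (one
accumulator drives all simultaneously recorded neurons and the choice), the
**choice-only** model (no spike factors), and the **independent-noise**
model (one accumulator per neuron with private noise, identical parameters;
the choice probability is the average of the per-accumulator choice
probabilities).  Only neurons recorded on a trial contribute to that
trial's likelihood (ragged session layout).

## Numerics

**Fokker-Planck discretization.**  The distribution of $a(t)$ lives on an
odd number of spatial bins (default $n = 53$): the outer two sit exactly at
$\pm B$ and absorb, the $n-2$ interior bins tile $(-B, B)$ with width
$2B/(n-2)$ and a center bin at 0.  One time step (default $\Delta t = 10$
ms) applies, per source bin, the exact linear-ODE drift update, then a
Gaussian spread discretized on a sub-grid (refinement factor 10, truncated
at 4 SD and tapered to zero at the edge so the operator is continuous in
the parameters, with the point spacing rescaled so the discrete kernel's
variance is exact) and settled onto the two nearest bins by linear
distance weighting.  The spread variance is
$(\sigma_a^2 \Delta t + \sigma_s^2 \Sigma_t)\,(e^{2\lambda\Delta t} - 1)/(2\lambda\Delta t)$
— the exact one-step variance of noise injected during an
Ornstein-Uhlenbeck step, consistent with the exact-exponential mean update
(the factor is 1 at $\lambda = 0$ and a $\sim\!2\%$ effect at
$|\lambda| = 2$, but it is what makes the propagated variance agree with
fine-step simulation to Monte-Carlo precision).  The operator is
column-stochastic by construction and its bound columns are identity.

**Settling variance correction.**  Two-bin linear settling of a smooth
density is a cloud-in-cell projection: it preserves the mean exactly but
inflates the variance by $\approx w^2/6$ per step ($w$ the bin width).
Uncorrected, this acts as artificial diffusion (at $n = 53$, $B = 40$ it
nearly triples the spread of a pure-diffusion process over half a second)
and biases $\hat\sigma_a^2$ downward.  The package therefore subtracts
$w^2/6$ from the spread kernel's variance before settling; the settled
one-step kernel then has the intended variance.  The correction requires
$w^2/6$ below the per-step variance — at the default $n = 53$ and plausible
parameters this holds; on very coarse grids (e.g. $n = 27$ with
$B \approx 15$) no two-bin scheme can represent a 10-ms diffusion step, and
fits on such grids are not recommended.  `correct = FALSE` reproduces the
literal construction.  `initial_distribution()` defaults to the literal
(uncorrected) one-time projection.

**Half-offset binning.**  Click bins are $[t\Delta t, (t+1)\Delta t)$;
spike bins are shifted by $\Delta t/2$ so spike bin $t$ straddles the
forward edge of click bin $t$ (aligning the two grids produces systematic
parameter bias).  Spike times are shifted by the per-neuron response
latency (a registry column, e.g. 60 ms frontal, 120 ms parietal) before
binning; negative times are dropped and counted.

**Choice factor on the grid.**  Evaluating the Heaviside pointwise at bin
centers makes the likelihood a step function of $c$, which defeats
quasi-Newton optimization.  Each bin is instead treated as a uniform
interval one grid width wide and the factor is the fraction of the interval
above $c$: continuous, piecewise linear, and equal to $1/2$ when $c$ sits
exactly at a bin center (the Heaviside tie convention).

**Likelihood and posteriors.**  A scaled forward pass per trial gives the
log-likelihood (spike factors per bin, choice factor at $T$); the posterior
over $a(t)$ conditioned on any subset of {spikes, choice} is
forward-backward smoothing with the stored per-bin operators
($O(Tn^2)$ per trial).  Posterior moments can exclude the bound-bin mass
(the display convention for commitment mass); change-of-mind detection uses
the spikes-only posterior mean with 50 ms dwell before and after a
criterion crossing and a minimum excursion of 2 clicks within that window,
all expressed in seconds so detection is invariant to the time grid.

**Optimization.**  Maximum likelihood under the printed box domain
($\sigma_i^2 \in [10^{-3}, 100]$, $B \in [8, 40]$, $\lambda \in [-5, 5]$,
$\sigma_a^2 \in [10^{-3}, 400]$, $\sigma_s^2 \in [10^{-3}, 10]$,
$\phi \in [10^{-3}, 1.2]$, $\tau_\phi \in [5\times10^{-3}, 1]$,
$c \in [-10, 10]$, $\gamma \in [0, 1]$, $\theta_n \in [-10, 10]$; the
printed domain lists two upper bounds for one variance — the package
assigns 100 to $\sigma_i^2$ and 400 to $\sigma_a^2$ on ordering grounds) is
performed by L-BFGS-B in a transformed space (log for positive-domain
parameters, logit for $\gamma$) with forward finite-difference gradients
(no automatic differentiation exists for this likelihood in R; the
objective was made continuous precisely so finite differences are
trustworthy).  The default start is a physiologically neutral point
($B = 20$, $\lambda = 0$, $\sigma_a^2 = 10$, mild adaptation $\phi = 0.8$)
with data-driven slope signs; the transformed-domain midpoint is a poor
start because the geometric midpoint of the $\phi$ domain (~0.035) is a
degenerate strong-adaptation regime that traps the optimizer.  Multi-start
(jittered by 10% of the domain width) is available via `n_starts`.

**Confidence intervals.**  Laplace: $\pm 2\sqrt{\mathrm{diag}(H^{-1})}$
from the finite-difference Hessian at the optimum, truncated at the domain.
Non-positive-definite Hessians are repaired by (a) re-evaluating in the
transformed space and mapping the intervals back, then (b) replacing
negative eigenvalues with twice the quadratic coefficient of a line search
along the offending eigenvector; directions that remain convex are reported
as `NA` rather than guessed.

## The synthetic world

`make_dataset()` generates complete sessions with the statistical structure
the model assumes: Poisson click trains at 40 Hz total with the per-trial
right-rate fraction uniform on $[0.025, 0.975]$ (spanning 39:1 easy to
near-symmetric hard trials), durations uniform on 0.2–1.0 s rounded up to
the time grid, Euler-Maruyama latent paths at a $10^{-4}$ s step with
clicks applied at their exact times (the simulator is deliberately an
independent oracle for the binned Fokker-Planck code — it never touches the
transition operators), spikes from the softplus model on bin-averaged
paths, and lapse-threshold choices.  Default parameters are the plausible
regime used throughout the tests: $\sigma_i^2 = 1$, $B = 15$,
$\lambda = -1$, $\sigma_a^2 = 20$, $\sigma_s^2 = 1$, $\phi = 0.3$,
$\tau_\phi = 0.05$, $c = 0$, $\gamma = 0.05$, slopes $\pm 3$, RBF baselines
around 10–20 Hz.  Durations are rounded to the grid and paths extended to
the last half-offset spike window, so the generator is exactly the
continuous-time analogue of the discretized likelihood; real recordings
additionally contain non-Poisson history effects, non-stationary baselines
across sessions, and latency jitter that the generator does not emulate — a
green recovery test establishes correctness of the inference machinery, not
adequacy of the model for any particular brain region.

What the generator's noise switch does: `noise = "shared"` drives all
neurons and the choice from one path per trial; `noise = "independent"`
gives each neuron a private path and the choice follows one selected at
random, matching the independent-noise likelihood's averaging rule.

## Known limitations

- Coarse grids ($w^2/6$ above the per-step variance) cannot represent the
  diffusion; the likelihood then under-weights accumulator noise.  Use
  $n \ge 53$ for bounds around 15–40.
- Finite-difference gradients make fitting $O(d)$ likelihood evaluations
  per iteration; joint fits with many neurons are minutes, not seconds.
- The discrete-time bound under-absorbs relative to the continuous SDE by
  an effective barrier shift $\propto \sigma\sqrt{\Delta t}$; comparisons
  against fine-step simulation at strongly binding bounds should use a
  smaller $\Delta t$.
- Bits-per-trial uses $K \ln 2$ in the denominator (the standard unit); no
  alternative reading is implemented.
- Session storage is JSON only (exact 17-digit round trip); there is no
  HDF5 backend in this build.
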