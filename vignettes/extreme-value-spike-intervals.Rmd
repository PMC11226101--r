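---
title: "Extreme value statistics of inter-spike intervals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extreme value statistics of inter-spike intervals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifevt)
```

## The scientific question

A leaky integrate-and-fire (LIF) neuron is deterministic: with constant
parameters it fires with a fixed period. Real inter-spike intervals
fluctuate, and recorded synaptic-delay distributions are typically
exponential (consistent with spike arrivals forming a Poisson process) or,
occasionally, heavier-tailed. `lifevt` studies the **maximum** inter-spike
interval per recording window. Extreme value theory (EVT) says the
distribution of such block maxima, suitably normalized, can only converge
to one of three laws — Gumbel, Fréchet, or reversed Weibull — and which one
is determined solely by the tail of the interval law. The package
simulates the stochastic neuron, extracts per-trial maxima, and verifies
the two relevant limits: exponential intervals → Gumbel, Pareto intervals
→ Fréchet.

## The stochastic neuron

Between spikes the membrane potential follows

$$\xi\,\frac{dV}{dt} = -(V - V_\mathrm{rest}) + R I_\mathrm{ext},$$

integrated by explicit forward Euler on a fixed grid (`dt`, default 1 ms;
no adaptive stepping — the model's value lies in spike timing, not
waveform accuracy). A spike is recorded when $V > \theta$ strictly
(equality does not fire; on a floating-point grid ties effectively never
occur anyway), upon which $V \leftarrow V_\mathrm{reset}$ and — the single
stochastic ingredient — the time constant $\xi$ is redrawn from a law
$\xi(\mu, \sigma)$:

* **fixed**: $\xi = \mu$ deterministically (recovers the classical model);
* **exponential**: $\xi = \mu - (1/\sigma)\log U$ with $U \sim
  \mathrm{Uniform}(0,1]$, a shifted exponential with lower endpoint $\mu$;
* **Pareto**: $\xi = \mu\,U^{-1/\sigma}$, with survival function
  $(\mu/x)^\sigma$ for $x \ge \mu$.

Uniform draws exclude zero by construction (`1 - runif()`), so the
logarithm and the negative power are always finite; no clamping is needed.

Defaults are standard textbook constants: $V_\mathrm{rest} =
V_\mathrm{reset} = V_\mathrm{init} = -65$ mV, $\theta = -55$ mV, $R = 1$
M$\Omega$, $I_\mathrm{ext} = 12$ nA, so the drive $R I_\mathrm{ext} = 12$
mV exceeds the 10 mV gap to threshold and the neuron fires; and $\mu = 20$
ms. With $V_\mathrm{init} = V_\mathrm{reset}$ every inter-spike cycle is
statistically identical, which is why the first interval is measured from
$t = 0$ (a documented, toggleable convention in `extract_intervals()`).

### The sigma convention

For the exponential family, $\sigma$ is a rate (the exponential scale is
$1/\sigma$), yet it carries the unit ms in the reference configuration
($\sigma = 5$ ms). Both readings give a shifted exponential, so every EVT
conclusion holds either way; only the width of the interval law changes
(0.2 ms versus 5 ms). `time_constant_model()` implements the rate reading
literally as the default and exposes `convention = "scale"` as a toggle.
The reference experiments use the literal convention.

### The synapse gate

A spike is transmitted only when the synaptic current from the previous
spike, $I_s(t) = I_s(0) e^{-t/\tau_s}$, has decayed below $\omega =
I_s(0)e^{-1}$ — i.e. at least $\tau_s$ ms have elapsed. $\tau_s$ is not
pinned by the reference configuration; the package defaults to 2 ms on the
stated ground that synaptic decay is fast relative to membrane relaxation
(the deterministic period at $\xi = 20$ ms is $\approx 36$ ms). Under the
defaults the gate therefore never changes a spike time, and the test suite
verifies this exactly at $\tau_s \le dt$. Only the ratio $I_s(0)/\omega$
matters, so $I_s(0)$ defaults to 1 in arbitrary units.

### Two generation modes

`simulate_trial()` supports two readings of "the interval law is
$\xi(\mu,\sigma)$":

* **direct** (default for experiments): intervals $d_i$ are drawn from
  $\xi(\mu,\sigma)$ itself and accumulated until the 1000 ms window is
  exceeded. The interval law is realized exactly; spike times are
  continuous.
* **ode**: full threshold-and-reset integration. Each interval is then the
  deterministic crossing time for its drawn $\xi$ — approximately $\xi
  \ln 6$ under the default constants — so the interval law is the $\xi$
  law rescaled by $\ln 6$ and quantized to the `dt` grid. The limit family
  is unchanged (the Gumbel/Fréchet domains are closed under affine
  rescaling), which the test suite exercises at reduced trial counts.

The ode mode is validated against an independent scalar recurrence
(spike-for-spike identity) and against the closed-form first-passage time
$\xi \ln 6 \approx 1.7918\,\xi$, with the discretization error shrinking
as `dt` decreases through 1, 0.1, 0.01 ms. Silent configurations
($V_\mathrm{rest} + R I_\mathrm{ext} \le \theta$) yield empty trains with
a warning rather than an error, so parameter sweeps survive; an experiment
aborts only if more than half its trials are silent.

## The EVT pipeline

For each trial the block maximum $Z_n = \max_i d_i$ is taken; block sizes
are random (the spike count varies), the per-trial maximum is used
regardless, and the mean block size is recorded. Maxima are histogrammed
in right-open bins of width `bin_width` (default `dt` = 1 ms, mirroring
the plotted figures) with masses normalized to sum exactly to one.

`fit_extreme()` offers:

* **histogram_ls** (default): nonlinear least squares matching each bin
  mass to `pdf(center) × bin_width`. This mirrors fitting a curve through
  the plotted histogram and is the route behind the headline R² values.
* **mle**: maximum likelihood on the raw maxima. Statistically preferable,
  and the route used when parameter values (rather than curve agreement)
  are compared to closed forms. Its R² is computed post hoc against the
  histogram.

The midpoint approximation inside `histogram_ls` matters when the bin
width is large relative to the distribution's scale: with 1 ms bins over a
0.2 ms-scale Gumbel the least-squares fit achieves high R² by inflating
the scale, while the MLE recovers the true scale but scores a poor
post-hoc histogram R². Neither is a bug; they answer different questions
(curve description versus parameter estimation), and both are exposed.

Numerical choices: Nelder–Mead on log-transformed positive parameters;
Gumbel starts by moment matching ($s_0 = \mathrm{sd}\sqrt{6}/\pi$,
$loc_0 = \bar{x} - 0.5772\,s_0$), Fréchet starts by log-moment matching
with the location initialized at 0 (the natural centering for maxima of
Pareto-type intervals, whose norming location constant is 0); in the
Fréchet MLE the location is parameterized as $\min(x) - e^\eta$ so it
stays below the sample. On non-convergence the optimizer restarts with the
scale start halved and doubled; if all restarts fail, the error carries
the optimizer diagnostics. The Fréchet is fitted with all three parameters
free; near its Gumbel limit (large shape, e.g. tail index 20) the shape
and location trade off and individual parameters are weakly identified
even when the fitted curve is excellent — shape recovery is therefore
asserted in the heavy-tailed regime (tail index 7.5) and, for large m, via
the MLE. A zero-variance sample (fixed $\xi$) is refused with a
degenerate-sample error rather than fitted.

The reversed Weibull is implemented for completeness of the three-family
theorem but not exercised by the experiments (interval laws here are
unbounded above).

## Reproducibility

All randomness flows through L'Ecuyer-CMRG streams (`make_stream()`);
trial $i$ of an experiment runs on substream $i$ of the master seed
(substreams are $2^{127}$ steps apart), so an experiment is a
deterministic function of its configuration and seed, prefixes of longer
runs are bit-identical, and any single trial can be replayed in isolation.
Drawing from a stream saves and restores the global `.Random.seed`, so
package code never perturbs user RNG state.

## Verification strategy and problem sizes

The test suite favors independent oracles over re-derivation: a scalar
recurrence for the discretized neuron; brute-force Monte-Carlo maxima
against the exact law $F^n$; quadrature and finite differences for the
densities; hand-computed values for R²; closed-form norming constants for
parameter recovery.

The reference experiments are run at reduced trial counts chosen to keep
a laptop-scale run while leaving the R² ≥ 0.99 criterion comfortably
attainable: 10,000 trials for the exponential/Gumbel experiment (reference
configuration: 100,000) and 100,000 for the Pareto/Fréchet experiments
(reference: 1,000,000); `reproduce_reference()` exposes this as
`scale_factor`.

Convergence of normed maxima to the limit laws is checked with a
replicated estimator: per replicate, $10^5$ maxima of $n$ draws are
sampled exactly from $F^n$ by inverse transform ($F^{-1}(U^{1/n})$, with
common uniforms across $n$ so block sizes are compared on the same
randomness), and the Kolmogorov–Smirnov distance at each $n \in \{10, 100,
1000\}$ is the median over seven replicates. The replication is essential:
at $n \ge 100$ the distributional bias falls below the sampling
fluctuation of a single KS estimate, and the median isolates the
decreasing bias the check is about.

## What the generator does and does not emulate

The simulator realizes the modeling assumptions exactly: i.i.d. intervals,
a stationary rate within and across trials, a single neuron, one-way
transmission, and a perfectly exponential or Pareto time-constant law.
Passing tests therefore demonstrate internal consistency of the theory and
its implementation — that the claimed limit laws emerge from the claimed
dynamics — not that biological spike trains satisfy those assumptions.
Real recordings feature rate drift, refractory structure beyond the simple
synapse gate, burstiness, and network feedback, all outside this model.
Fitting the generalized extreme value family to experimental recordings is
deliberately out of scope.

## Known limitations

* `histogram_ls` parameter estimates are binning-dependent (see above);
  compare with `mle` before interpreting parameters.
* Three-parameter Fréchet fits near the Gumbel limit are weakly
  identified; prefer the shape from heavy-tailed regimes or large samples.
* In ode mode intervals are quantized to the `dt` grid, so
  continuous-distribution diagnostics (e.g. KS against a fitted continuous
  law) are pessimistic at coarse `dt`.
* The direct mode discards the final, truncated interval of each window;
  for $\mu = 20$ ms and 1000 ms windows this censoring is negligible for
  maxima but would matter for windows of only a few $\mu$.
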