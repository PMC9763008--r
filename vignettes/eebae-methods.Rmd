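---
title: "Adaptive psychometric estimation with an entropy-bounded exploration-exploitation policy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive psychometric estimation with an entropy-bounded exploration-exploitation policy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eebae)
```

## The estimation problem

A psychometric function maps a controllable stimulus $d$ to the probability
$\Phi(\theta, d)$ of a binary behavioral response $y \in \{0, 1\}$
(accept/reject, correct/wrong), parameterized by the subject's unknown
$\theta$. Adaptive estimation chooses each trial's stimulus based on
everything observed so far, so that $\theta$ is pinned down in as few trials
as possible — trials with a human subject are the scarce resource.

`eebae` implements the grid-based Bayesian approach. The parameter space is
discretized into a finite grid $\Xi$ (Cartesian product of per-parameter
axes) carrying a probability mass function $p_t(\theta)$, initialized
uniform over the nodes. After observing response $y_t$ to stimulus $d_t$,
Bayes' rule gives

$$p_{t+1}(\theta) \propto p_t(\theta)\, p(y_t \mid \theta, d_t),
\qquad p(y \mid \theta, d) = \Phi(\theta, d)^{y}\,
\bigl(1 - \Phi(\theta, d)\bigr)^{1-y}.$$

The point estimate is the posterior mean (the MEAN estimator), and accuracy
is tracked as the per-parameter squared error against the simulated
subject's true $\theta$, averaged over replications.

## Stimulus selection and the entropy bound

The classical adaptive rule selects the stimulus maximizing the mutual
information between the parameter random variable $\Theta$ and the upcoming
binary response $Y$:

$$d_t = \arg\max_{d \in \mathcal{D}} I(\Theta; Y \mid d, p_t), \qquad
I(\Theta; Y \mid d, p_t) = h\!\Bigl(\sum_\theta p_t(\theta)\,\Phi(\theta, d)\Bigr)
- \sum_\theta p_t(\theta)\, h\bigl(\Phi(\theta, d)\bigr),$$

with $h(p) = -p \log_2 p - (1-p)\log_2(1-p)$ the binary entropy. Both a
brute-force joint-sum evaluation (`mutual_information_joint()`) and this
decomposition (`mutual_information()`) are implemented; the test suite
checks their agreement to $10^{-10}$ on randomized instances, so the fast
decomposition used everywhere is continuously cross-validated against the
definition.

Two facts shape the design:

* **Entropy bound.** For any stimulus,
  $I(\Theta; Y \mid d, p) \le H(\Theta) = -\sum_\theta p(\theta)\log_2 p(\theta)$.
  No trial can be expected to deliver more information than the current
  parameter uncertainty. `information_sweep()` asserts this bound (with
  $10^{-9}$ bits of slack for floating point) on every explore trial of
  every simulated experiment.
* **Information cannot hurt.** The expected posterior entropy after one
  observation, $\sum_y p(y \mid d)\, H(p(\cdot \mid y))$, never exceeds the
  prior entropy. `expected_posterior_entropy()` computes it directly from
  the two candidate posteriors, and the chain-rule identity (expected
  posterior entropy $= H - I$) is a test invariant rather than the
  implementation, so the two routes stay independent.

As the posterior concentrates, $H(\Theta)$ falls, and with it the ceiling on
what any cleverly chosen stimulus can add. That is the rationale for the
exploration-exploitation policy: run the argmax-MI sweep only while
$H(\Theta) > \varepsilon$; once $H(\Theta) \le \varepsilon$, select stimuli
uniformly at random. Random selection still updates the posterior and still
reduces uncertainty on average; what it saves is the full sweep over the
node-by-stimulus table, which is the per-trial cost that dominates for large
grids. The threshold condition is re-evaluated on the prior of every trial
(it is not latched), so the number of exploitation trials in a run is a
random variable; the boundary case $H = \varepsilon$ resolves to exploit.
Three policies are exposed: `ee`, `classical` (always explore), and
`random` (always exploit), all sharing the same Bayes core.

## The two bundled models

**Contrast sensitivity (CSF).** Log10 sensitivity follows a truncated
log-parabola in log10 spatial frequency $f$:

$$S'(f) = \log_{10}\gamma_{\max} - \log_{10}2 \cdot
\Bigl(\tfrac{\log_{10} f - \log_{10} f_{\max}}{\beta'/2}\Bigr)^2,
\qquad \beta' = \log_{10}(2\beta_1),$$

plateauing at $\log_{10}\gamma_{\max} - \delta_1$ for $f < f_{\max}$
whenever the parabola falls below that level. The truncation condition is
evaluated in log10 sensitivity units — the same units as the plateau value
it switches to; the parabola branch applies at and above the peak, and also
below the peak while still above the plateau. The response link is

$$\Phi = \min\bigl(1 - \mu,\; 0.5 + 0.5 \cdot 10^{\,2 (S(f) + \log_{10} c)}\bigr),$$

rising from the 0.5 guess rate at low contrast to the lapse-bounded ceiling
$1 - \mu$ (default $\mu = 0.04$). Among the algebraically plausible
arrangements of this link's printed forms in the literature, this is the one
that is monotone non-decreasing in contrast, bounded in $[0.5, 1-\mu]$, and
needs no extra clipping; it is deliberately isolated in
`csf_response_prob()` so an alternative link (for instance a Weibull-type
$1 - 0.5\,e^{-10^{2(S + \log_{10} c)}}$) can be swapped in without touching
any other module. Stimuli are represented in log10 units (log frequency,
log contrast) throughout.

**Gap acceptance (GAF).** A driver facing a traffic gap of $d$ seconds
accepts it with probability $\Phi_N\bigl((d - \bar T_{cr}) / \sigma\bigr)$,
where $\Phi_N$ is the standard normal CDF, $\bar T_{cr}$ the critical gap
mean and $\sigma$ its spread, both in seconds.

Any new model plugs in by providing `response_prob(theta, stimulus)`; all
downstream modules depend only on that contract.

## Reference experiment settings

The bundled JSON configurations encode the two reference experiments the
package reproduces end to end:

| | CSF | GAF |
|---|---|---|
| parameter ranges | $\gamma_{\max} \in [2, 2000]$, $f_{\max} \in [0.2, 100]$, $\beta_1 \in [2, 128]$, $\delta_1 \in [0.2, 3]$ | $\bar T_{cr} \in [5, 10]$ s, $\sigma \in [1, 4]$ s |
| parameter grid | 20 nodes per axis ($20^4 = 160{,}000$) | 20 per axis (400) |
| stimulus grid | $20 \times 20$ over $\log_{10} f \in [\log_{10} 0.2, \log_{10} 36]$, $\log_{10} c \in [-3, 0]$ | 25 gaps in $[4, 12]$ s |
| trials | 250 | 300 |
| threshold $\varepsilon$ | 1.5 bits | 6.4 bits |
| truth $\theta$ | $(100, 2.5, 2.5, 0.25)$ | $(7.3, 2.2804)$ |

Both use the non-informative uniform prior over grid nodes and a
5000-replication protocol in the configuration files; the test suite and the
acceptance script scale this down (200 replications for GAF, 50 for CSF) to
keep a desk-scale runtime, which leaves the Monte Carlo standard error of
the reported means far below the tolerances being checked.

## Design choices

* **Axis spacing.** The four CSF parameter ranges span one to three orders
  of magnitude, so their axes are log10-equispaced; GAF parameters and all
  stimulus axes are linear in their natural units (the CSF stimulus axes are
  linear in their stated log10 units). "Uniform prior" means equal mass per
  node — uniform on the chosen node set, which on a log axis is not a
  uniform density in raw units.
* **Posterior mean on the spacing scale.** `estimate_mean()` averages node
  coordinates on each axis's own scale (log10 coordinates for log axes,
  mapped back to natural units). On an all-linear grid such as GAF this is
  exactly the arithmetic posterior mean; on log axes it makes the
  uniform-prior estimate the midpoint of each range on its own scale rather
  than an average dominated by the top decade. Squared errors are recorded
  in raw units by default, with `error_scale = "log10"` as a config switch.
* **Logarithm base.** Bits (base 2) everywhere, for both entropies and
  thresholds. The GAF threshold of 6.4 must lie below the initial uniform
  entropy of a 400-node grid for the policy to explore at all; that is true
  in bits ($\log_2 400 \approx 8.64$) and false in nats ($\ln 400 \approx
  5.99$), which pins the unit.
* **Continuous truth.** The virtual subject draws responses from the model
  evaluated at the exact true parameters, which need not be grid nodes
  (the reference $\sigma = 2.2804$ is off-grid). The estimator only ever
  sees the grid.
* **Independent random streams.** Each replication owns two generator
  states — one for exploitation stimulus draws, one for subject responses —
  so policy randomness never perturbs response randomness under seed reuse,
  and the EE and classical arms of a comparison can share streams (common
  random numbers: identical trials before the switch). Per-replication
  seeds are drawn without replacement from a generator seeded by the base
  seed, making partial re-runs reproducible and seeds pairwise distinct.

## Numerical choices

* $0 \log 0 := 0$ throughout, implemented by clamping probabilities to
  $[10^{-300}, 1]$ inside logarithms only — stored state is never clamped.
* The argmax over the per-stimulus MI vector is taken after rounding to
  $10^{-10}$ bits, with ties broken by lowest index. This makes stimulus
  selection deterministic and reproducible across BLAS code paths: exact
  symmetries (e.g. the uniform prior on a symmetric grid) reach the same
  floating-point MI values through different summation orders in
  matrix-vector and matrix-matrix kernels, and without quantization the
  selected stimulus could differ between runs that are mathematically
  identical.
* `run_replications()` defaults to a lockstep "batch" engine: all
  replications advance one trial at a time, so the explore-trial information
  sweep for every still-exploring replication is a single `crossprod`
  against the shared likelihood table (a matrix-matrix product instead of
  many matrix-vector products over a table with $1.6 \times 10^5 \times 400$
  entries for CSF). A per-replication "loop" engine through
  `run_experiment()` is the reference implementation; the test suite checks
  the two produce identical trial logs for identical seeds.
* The likelihood table caches both $\Phi$ and $h(\Phi)$ per
  (node, stimulus), so a sweep is two matrix products plus one binary
  entropy over the predictive vector.
* A posterior update whose normalizing constant is zero (a response that is
  impossible everywhere on the support) raises an error rather than
  returning NaNs; it cannot occur for the bundled models, whose response
  probabilities are strictly inside $(0, 1)$.

## What the simulator does and does not emulate

The virtual subject is a stationary Bernoulli responder: the true
parameters are fixed for the whole run, responses are conditionally
independent given the stimulus, and the response model is exactly the model
being fitted. Real observers violate all three — lapses of attention,
learning and fatigue drifts, and model misspecification are not emulated
(the CSF lapse bound $\mu$ caps the ceiling but the generating model is
still the fitted model). Passing tests therefore demonstrate the
correctness and internal consistency of the estimation machinery and the
policy's accuracy equivalence *under the model*, not robustness to
misspecified observers.

With the truth placed on a grid node and a long run, the posterior mean
should land within one grid spacing of the truth in nearly all
replications; this identifiability check is part of the test suite. Off-grid
truth leaves a discretization floor in the MSE that no number of trials
removes — visible in the reference GAF setting, where the spread parameter's
squared error plateaus near its discretization limit. Because the reference
GAF truth $(7.3, 2.2804)$ sits close to the uniform-prior mean $(7.5, 2.5)$,
its trial-one squared error is already small; convergence tests in the suite
therefore also use an off-center truth, where the decline is unambiguous.

## Known limitations

* The per-trial sweep cost is linear in (nodes $\times$ stimuli); grids much
  beyond $10^5$ nodes call for the batch engine and patience. No adaptive
  grid refinement, particle, or MCMC posterior is provided, and no MAP
  estimator — the posterior mean is the package's point estimate.
* The exploitation-trial count of an EE run is an emergent quantity: it is
  the number of trials after the entropy trajectory first crosses
  $\varepsilon$ (plus any later re-crossings), and thus depends on
  everything that shapes that trajectory — the response link, the grids,
  and the truth. It is reported, never targeted.
* Wall-clock savings of `ee` over `classical` are measured and written to
  comparison summaries as information only; they depend on hardware and
  BLAS and are never asserted.
* $\varepsilon$ is a fixed input; the package provides no rule for choosing
  it beyond the requirement $0 < \varepsilon < \log_2(\text{node count})$
  for the switch to be reachable.
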