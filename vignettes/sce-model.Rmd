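---
title: "The statistical creator-evaluator model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The statistical creator-evaluator model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musevol)
```

## The model and its assumptions

`musevol` models the evolution of a cultural feature frequency
$\theta \in (0,1)$ — for instance the per-piece frequency of tritones in a
musical corpus — through generations of creators who learn from data that
has passed social selection. Three assumptions define the model:

1. **Beta creator models.** Each generation's data-generation model is a
   beta distribution $\varphi_t(\theta) = \mathrm{Beta}(\theta; a_t, b_t)$,
   equivalently the moment pair $(\mu_t, \sigma_t)$ on the representable
   region $\sigma^2 < \mu(1-\mu)$. The beta family is the natural minimal
   choice for a bounded frequency, and corpus-era frequency distributions
   are empirically beta-like.
2. **Selection by typicality and novelty.** Generated data chunks are kept
   with weight $\varphi_t^{\beta_T} e^{-\beta_N \varphi_t}$: the typicality
   term rewards chunks probable under the evaluator's model (here identical
   to the creator's), the novelty term penalizes chunks similar to abundant
   existing data. In the infinite-data limit the selected data are
   distributed as $\tilde\varphi_t = \varphi_t^{1+\beta_T}
   e^{-\beta_N\varphi_t}$ (unnormalized). $\beta_T \le -1$ is rejected:
   it puts infinite weight on zero-probability chunks.
3. **Moment-matched learning.** The next model's $(\mu, \sigma)$ equal the
   exact mean and SD of the normalized $\tilde\varphi_t$. The state space
   is thus the two-dimensional map $(\mu_t,\sigma_t) \mapsto
   (\mu_{t+1},\sigma_{t+1})$ implemented by `sce_update()`.

The model deliberately abstracts away from data sampling: $\theta$ is
treated as directly observable, and the map is the infinite-data limit.
Finite-corpus effects enter only through the synthetic-data generator and
the corpus statistics, never through the map itself.

Analytically known consequences, all covered by tests: with $\beta_N = 0$
the map is closed-form on the shapes ($a'-1 = (1+\beta_T)(a-1)$, likewise
$b$), the beta mode is invariant, $\sigma_t \to 0$ and $\mu_t \to$ mode;
with $\beta_N > 0$ the reweighted density is bimodal once
$\max\varphi > 1/\beta_N$, the two peaks have equal height
$1/(e\beta_N)$ at the roots of $\varphi = 1/\beta_N$, the orbit climbs a
slow manifold with $\sigma/\mu$ nearly constant below one and converges to
a fixed state at $\mu = 1/2$; with both terms active the SD settles where
the two effects balance.

The comparison **log-potential model** (`logpotential_iterate()`) applies
selection weight $\theta^\beta$ to a log-normal creator model; the update
is exact in log space ($\tilde\sigma$ fixed, $\tilde\mu \mapsto \tilde\mu
+ \beta\tilde\sigma^2$), so the mean grows geometrically at rate
$e^{\beta\tilde\sigma^2}$ with $\sigma/\mu$ conserved at machine
precision. Because the log-normal is untruncated, its mean may exceed 1;
no truncation is applied, matching the closed form. The two models differ
observably: the log-potential ratio is pinned by the initial condition and
its growth is sharply $\beta$-sensitive, while the SCE ratio is driven to
an attractor and its growth rate is insensitive to $\beta_N$ — this
contrast is what lets data discriminate them.

## Tunable parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `beta_T` | typicality coefficient (dimensionless) | 0 | no selection |
| `beta_N` | novelty coefficient (dimensionless) | 0 | no selection |
| `rel_tol` | quadrature relative tolerance | 1e-10 | well below every asserted agreement |
| `ratio_tol` | plateau detection, per-generation ratio change | 1e-3 | "almost constant" needs a number; 1e-3/gen resolves the manifold while ignoring drift |
| `width`, `step` | corpus window width/shift (years) | 100, 25 | the corpus-analysis windowing convention |
| `beta_max`, `grid_points` | fitting box and grid density | 20, 21 | generous box; log-spaced grid above 0.1 |
| `generations_per_step` | model generations per data time step | 1 | minimal assumption, declared not hidden |
| `min_notes` | piece-length inclusion filter | 100 | short pieces give unreliable frequencies |

One model generation per data window step is a declared convention, not an
estimate: nothing in a window series identifies the generation time, so
the fitted coefficients are interpretable only relative to this choice.

## Numerical choices

**Quadrature.** Moments of $\tilde\varphi_t$ are computed as ratios of
integrals so the normalization constant never needs separate treatment.
The integration variable is substituted as $\theta = F^{-1}(u)$ where $F$
is the CDF of the *effective* beta with shapes $1+(1+\beta_T)(a-1)$,
$1+(1+\beta_T)(b-1)$ — the typicality factor is then exactly flat in $u$,
and only the bounded novelty weight $e^{-\beta_N\varphi}$ (shifted so its
maximum is one) remains. The $u$-interval is split where $\varphi$ crosses
$2^j/\beta_N$ ($j = 0,\dots,5$), bracketing the weight's sharp transition
layers, and refined dyadically toward $u = 0, 1$ where $\theta(u)$ has
algebraic derivative singularities. A composite 20-node Gauss-Legendre
rule over this graded grid computes all three moments from one vectorized
sweep; an adaptive rule with staged tolerance relaxation is the fallback
for irregular cases (e.g. negative $\beta_N$). The variance is computed as
a central moment in a second pass: $m_2 - m_1^2$ loses all precision once
$\sigma^2$ falls below $10^{-16}$, which typicality-only orbits reach.
Against closed forms and dense Riemann oracles the scheme agrees to
$10^{-14}$ (typicality) and $\sim10^{-7}$ (novelty states in the studied
regime). Beyond shapes of $10^{12}$, where `qbeta` degrades, the effective
beta is replaced by its normal limit (skewness $< 10^{-6}$ there).

**Degenerate states.** An update whose moments leave the representable
region terminates the orbit with an explicit flag — never silent clipping,
which would fabricate dynamics outside the analyzed regime. Representability
is tested with a $10^{-12}$ margin. For contracted states with
$\sigma \lesssim 10^{-8}$ the computed SD has an absolute noise floor near
$10^{-16}$ (the precision of the quantile map), so monotonicity assertions
stop there; the SD limit of typicality-only orbits is verified through the
exact closed form.

**Strong novelty is oscillatory.** For $\beta_N = 2$ from
$(\mu,\sigma) = (0.02, 0.01)$ the orbit converges to a small period-2
cycle around the uniform fixed state (ratio alternating
$\approx 0.570/0.584$) rather than a fixed point. The plateau diagnostic
therefore reads the asymptote with `ratio_tol` set to the cycle amplitude
(0.02) when comparing plateau levels across $\beta_N$.

**Fitting.** The objective is the summed squared residual of window means
and SDs, the model initialized per series at the earliest window's
moments. The optimizer is a deterministic coarse grid (log-spaced above
0.1) followed by Nelder-Mead refinement with an out-of-box penalty and one
restart: the objective is non-smooth where orbits hit the
representable-region boundary (scored as $10^{12}$), so derivative-free
and reproducible beats fast. Noiseless self-generated series are recovered
to better than $10^{-3}$ in both coefficients; per-series RMSE is reported
over the concatenated mean and SD residuals (divisor $2T$ — a convention,
stated so the numbers are interpretable).

**Exact rationals for rhythm.** Note-value ratios are reduced integer
pairs; membership in the 11 common ratios is decided exactly, never by
floating-point comparison. MIDI files carry no notated durations, so on
that path note values are approximated by inter-onset intervals quantized
to a configurable grid (default twelfths of a quarter note); exact values
are guaranteed only for note-list and MusicXML input.

## What the synthetic generator does and does not emulate

`simulate_corpus()` implements the model's own generative assumptions: per
piece a latent $\theta \sim \mathrm{Beta}(a_t, b_t)$, a piece length
uniform on $[100, 1000]$ notes (the typical order of magnitude for a
musical piece), and a binomial event count. This validates the entire
pipeline — extraction-free statistics, windowing, zero-exclusion, fitting —
under known truth, including the reproduction of the four empirical laws
(beta-like era distributions; growing mean and SD; near-constant ratio
below one; near-exponential growth).

It does **not** emulate real corpora in several respects: musical events
are not independent Bernoulli trials (bigram features are serially
dependent); real pieces cluster by composer and school rather than
arriving i.i.d. within a generation; dating is uncertain; corpus coverage
varies by era; and one model generation is identified with one window
step. Passing synthetic tests therefore demonstrates correctness of the
implementation and internal consistency of the model, not that real
corpora satisfy the model's assumptions.

Two finite-sample effects are worth knowing about. Zero-count pieces are
excluded by the descriptive corpus statistics (the corpus-analysis
convention), which biases window means upward when $\mu N \lesssim 3$; and
binomial observation noise inflates window SDs above the latent
$\sigma_t$ by $\mathrm{E}[\theta(1-\theta)/N]$. Fitting the raw window
moments therefore pulls the optimum along a shallow $(\beta_T, \beta_N)$
ridge toward inflated novelty. `recovery_experiment()` instead estimates
the latent moments consistently: it keeps zero-frequency pieces and
subtracts the unbiased within-piece binomial term
$\overline{f(1-f)/(N-1)}$ from the window variance before fitting. With
this estimator $\beta_N$ is recovered well within the asserted 25% at 500
pieces per generation; a small spurious $\beta_T$ can remain where the
ridge is flattest — worth remembering when interpreting small fitted
typicality coefficients on real data, whose window moments cannot be
debiased without per-piece note counts.

## Open design decisions, resolved

* **"Best fit" beta distributions** are maximum likelihood (moment-matched
  start, digamma-free direct optimization of the log-likelihood), with
  moment matching as the warned fallback. The per-era fitting criterion is
  not fixed by the corpus-analysis convention; MLE is the standard reading.
* **Note ordering** for polyphonic MIDI merges all tracks, sorts by onset,
  and breaks ties by track then ascending pitch: simultaneous notes
  contribute harmonic intervals in a deterministic order. Determinism was
  preferred over fidelity to an unrecoverable original ordering.
  Percussion-channel events are excluded (no pitch-class meaning).
* **Rare-rhythm normalization** divides by the number of bigrams
  $|v| - 1$ by default; the interval-bigram convention (divide by $|v|$)
  is available via `denominator = "values"`.
* **Window statistics** use the sample (n−1) SD, exclude exact zeros
  before averaging, and never interpolate: smoothing is presentation, not
  data.
* **Negative coefficients** ($\beta_N < 0$, $\beta_T \in (-1, 0)$) are
  accepted — the selection weights remain well-defined — but carry no
  tested guarantees; the analyzed regime is $\beta_T, \beta_N \ge 0$.

## Problem sizes

The shipped tests and the acceptance script run at deliberately modest
scale: orbits of 60-200 generations, corpora of 200-500 pieces per
generation over 16 generations, window series of 10-17 points, and
fitting grids of 8-21 points per dimension. These sizes are where the
asserted tolerances are comfortably met by the numerics; all scale
linearly if enlarged.

## Known limitations

* The map is the infinite-data limit: finite-population sampling noise in
  the *learning* step (as opposed to the observation step) is out of scope.
* Single creator and evaluator with identical models; decoupled or
  multi-agent variants are not implemented.
* The MusicXML reader extracts monophonic pitch/duration streams only
  (no voices, no tie merging beyond sequential reading).
* The uniform distribution is a fixed point of the SCE map for *every*
  coefficient pair ($\varphi \equiv 1$ makes the selection weight constant),
  so a series that has saturated at $\mu = 1/2$ carries no parameter
  information: coefficients are identifiable only from the transient, and
  noisy saturated series exhibit a flat least-squares ridge no estimator
  can resolve. Fit to series that are still evolving.
* Fitted coefficients come with no uncertainty quantification; the
  objective surface near the representable-region boundary makes naive
  curvature-based intervals untrustworthy, and bootstrap machinery is out
  of scope.
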