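# musevol

Statistical models of cultural evolution in music styles.

`musevol` is for researchers studying how transmitted cultural traits —
here, frequencies of musical events such as dissonant intervals — evolve
across generations of creators and audiences. It implements the
**statistical creator–evaluator (SCE) model**, an iterated-learning
dynamical system, together with the symbolic-music feature extractors and
corpus statistics needed to confront the model with data, and a
least-squares fitter that estimates the model's selection coefficients
from observed time series.

## The model

A creator generation is represented by a beta distribution over a feature
frequency θ ∈ (0, 1),

  φ_t(θ) = Beta(θ; a_t, b_t),

equivalently parameterized by its mean and standard deviation (μ_t, σ_t).
Each generation, data are reweighted by social selection,

  φ̃_t(θ) = φ_t(θ)^(1 + β_T) · exp(−β_N φ_t(θ)),

where β_T is the **typicality** coefficient (rewarding conformity with the
current style) and β_N the **novelty** coefficient (penalizing similarity
to abundant existing data). The next generation learns φ_{t+1} by moment
matching: its (μ, σ) equal those of the normalized φ̃_t. The map has three
characteristic regimes:

* **typicality only** (β_T > 0, β_N = 0): closed form
  a′ − 1 = (1 + β_T)(a − 1), b′ − 1 = (1 + β_T)(b − 1); the SD shrinks to
  zero and the mean converges to the invariant mode;
* **novelty only** (β_N > 0): mean and SD both grow along a slow manifold
  with σ/μ nearly constant and slightly below one, approximately
  exponentially, toward a fixed state at μ = 1/2;
* **mixed**: the SD settles where typicality and novelty balance.

A closed-form comparison model (the **log-potential model**, a log-normal
creator model under R(θ) = ln θ selection with coefficient β) grows
exactly geometrically with σ/μ conserved, and serves as the discriminating
alternative when fitting.

The feature extractors implement pitch-class-interval sequences from
symbolic scores (MIDI, MusicXML, or a plain note-list format): tritone
frequency #{n : x_n = 6}/|x|, non-diatonic-motion frequency over the
20-element bigram set C, the 121 interval-bigram frequencies, and
rare-rhythm frequency from note-value ratios decided in exact rational
arithmetic.

## Worked example

Simulate a novelty-driven trajectory from a rare feature, sample a
synthetic corpus from it, aggregate into sliding windows, and recover the
selection coefficient:

```r
library(musevol)

tr <- sce_iterate(moment_pair(0.02, 0.01), selection_params(beta_T = 0, beta_N = 1),
                  generations = 16,
                  time_map = list(start_year = 1500, years_per_generation = 25))
head(tr, 4)
#>   generation        a         b         mu      sigma     ratio year
#> 1          0 3.900000 191.10000 0.02000000 0.01000000 0.5000000 1500
#> 2          1 9.000551 165.30375 0.05163700 0.01671366 0.3236760 1525
#> 3          2 4.299993  47.92458 0.08233659 0.03767750 0.4576033 1550
#> 4          3 4.163087  23.33541 0.15139326 0.06714220 0.4434953 1575

rec <- recovery_experiment(selection_params(beta_T = 0, beta_N = 1),
                           moment_pair(0.02, 0.01), generations = 16,
                           pieces_per_generation = 500, seed = 1)
rec
#> <recovery_report: sce model>
#>        true recovered relative_error
#> beta_T    0 0.1388114             NA
#> beta_N    1 1.1568563      0.1568563
```

The novelty coefficient is recovered to ~16% from a corpus of 8,500
sampled pieces (the small spurious β_T sits along the flat ridge of the
least-squares surface; see the methods vignette for how the window
moments are debiased for binomial observation noise before fitting).
`window_series()` gives the descriptive 100-year/25-year sliding-window
statistics, `fit_model()` the underlying least-squares fit, and
`forecast_model(fit, horizon)` continues a fitted map beyond the data.

The same pipeline is scriptable from a shell via `inst/scripts/musevol`
(`simulate`, `synth`, `extract`, `stats`, `fit`, `forecast`), with flat
key-value config files; examples live in `inst/configs/`.

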