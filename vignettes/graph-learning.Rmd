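---
title: "Modeling graph learning from mental errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling graph learning from mental errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphlearn)
```

## The problem and the model

In a serial-response experiment, a subject watches a sequence of stimuli
drawn as a random walk on a hidden transition graph and responds to each
one; reaction time indexes how strongly the observed transition was
anticipated. If learning were exact, the natural estimator of the
transition structure would be the maximum likelihood tally
$\hat A_{ij} = n_{ij} / \sum_k n_{ik}$, which is unbiased and therefore
blind to higher-order structure such as communities. Human reactions,
however, do depend on higher-order structure, which points at systematic
errors in the learning process itself.

`graphlearn` implements a learner whose only departure from exact counting
is an error-prone memory of *when* things happened. When crediting a
transition, the learner recalls the stimulus $\Delta t$ steps before the
intended one with probability

$$P(\Delta t) = \tfrac{1}{Z} e^{-\beta\,\Delta t}, \qquad \Delta t \ge 0,$$

the distribution that minimizes the free energy
$F(Q) = \beta E(Q) - S(Q)$, where $E(Q) = \sum_{\Delta t} Q(\Delta t)\,\Delta t$
is the mean recall error and $-S(Q)$ the (negative-entropy) complexity of
the memory. The single parameter $\beta$, the inverse temperature, sets
memory precision: $\beta \to \infty$ recovers exact counting, $\beta \to 0$
recalls all past stimuli uniformly. At each trial the lag distribution,
renormalized over the available history, induces a belief over which node
occurred last; one unit of count mass is split over rows according to that
belief (`sequential_learn()`). Internally the belief is maintained by the
recursion $u_t = e^{-\beta} u_{t-1} + e_{x_t}$, so a full pass over a walk
costs $O(Tn)$ rather than $O(T^2)$.

In the long-run limit the estimate has the closed form

$$\hat A = (1 - e^{-\beta})\, A\, (I - e^{-\beta} A)^{-1},$$

a discounted average $\sum_{\Delta t} P(\Delta t) A^{\Delta t + 1}$ over
walks of all lengths (`asymptotic_estimate()`, computed with a linear
solve; the system is safely non-singular because the spectral radius of
$e^{-\beta}A$ is $e^{-\beta} < 1$). At intermediate $\beta$ this blurring
makes within-community transition estimates exceed between-community ones
on the modular graph, and makes modular-graph edges look more probable
than lattice edges (`effect_curves()`); on the ring graph it predicts
anticipations of never-seen "violation" transitions that decay with
topological distance (`distance_profile()`).

## Experiment graphs and walk protocols

The three built-in 15-node graphs are 4-regular with a uniform 0.25
transition probability per edge, so that any behavioral difference between
graph regions must reflect higher-order structure:

* **modular** — three communities of five densely connected nodes. The
  figure-level description pins the wiring only up to the construction
  used here: within a community all pairs are connected except the two
  boundary nodes, and each boundary node carries one edge to the adjacent
  community's nearest boundary node. This is the unique wiring satisfying
  4-regularity, three 5-node communities and dense clusters.
* **lattice** — the 3 × 5 grid with periodic boundaries.
* **ring** — each node tied to its nearest and next-nearest neighbors.

Three walk protocols mirror the experimental designs: plain random walks
(`random_walk()`); the recency-controlled session of 700 random trials
followed by eight repeats of 85 random plus 15 Hamiltonian trials
(`hamiltonian_session()` — segments are found by randomized depth-first
backtracking, which the session RNG seeds, since the original search
method is unspecified; we require the segment to start adjacent to the
preceding trial and the following random segment to resume adjacent to its
last node, keeping the whole session a valid walk); and the ring session
with 50 violations — 20 of distance two, 20 of distance three, 10 of
distance four — placed uniformly at random within trials 501–1500 under a
no-two-adjacent constraint that avoids compounding two non-edge steps
(`violation_walk()`).

## From anticipations to reaction times

The reaction-time model is the linear map
$\hat r(t) = r_0 + r_1\, a(t)$, where $a(t)$ is the learner's estimated
probability of the transition observed at trial $t$, computed from counts
through trial $t-1$. Fitting is per subject (`fit_maxent_subject()`):
given $\beta$, the linear parameters are closed-form least squares, so the
fit is a one-dimensional search over $\beta$ — RMSE is scanned on a
100-point log-spaced grid over $[10^{-4}, 10]$, the grid argmin (ties
broken toward smaller $\beta$, the more parsimonious memory) is refined by
gradient descent with backtracking until the absolute gradient falls below
$10^{-6}$, and the two limits $\beta \to 0$ and $\beta \to \infty$ are
checked explicitly; both limits are represented symbolically, never as
extreme floats. The gradient is a central finite difference with step
$10^{-6}\max(\beta, 1)$; an analytic gradient would be an optimization,
not a change of estimator. Anticipations are always computed over the
*entire* walk, because the subject experienced every trial even when the
analyst later discards some.

The competing hierarchy (`fit_order_model()`) gives the explicit
$k$-step-learning alternative
$\hat r^{(\ell)}(t) = c_0 + \sum_{k=1}^{\ell} c_k a^{(k)}(t)$, fitted by
OLS (with a tiny ridge fallback, penalty $10^{-8}$, should the
anticipation columns be collinear). Models are compared with the
Gaussian-residual BIC, $T\ln(\mathrm{SSE}/T) + k\ln T$, with $k = 3$ for
the maximum-entropy model and $\ell + 1$ for the order-$\ell$ model; the
original analysis does not state its BIC convention, so this form is
declared here and used consistently.

Before fitting, reaction times are filtered and residualized
(`filter_trials()`, `nuisance_residualize()`): drop trials 1–500 (or keep
only Hamiltonian trials), drop incorrect responses, then drop times more
than 3 SD from the subject's mean or under 100 ms — the mean and SD are
computed after the first two rules, an ordering that published accounts
of this pipeline leave ambiguous — and finally cap at 2000 ms (model fitting) or 3500 ms
(network effects). Nuisance structure (button combination, log-trial
practice trend, stage terms when a subject ran two sessions, and recency)
is removed by per-subject OLS; residuals are re-centered at the subject's
mean so they stay in milliseconds. One design subtlety: when a subject
saw a *different* graph in each stage, stage and graph are perfectly
confounded within that subject, and removing per-stage means would null
the modular-lattice contrast outright. In that case the residualization
drops the stage terms (keeping the shared log-trial trend) and the
counterbalanced stage order across the cohort cancels stage effects in
the across-subject t-test instead — the same identification the original
mixed model obtains by estimating stage and graph jointly across
subjects. The original group analyses
used mixed-effects models; this package deliberately replaces them with
per-subject fixed-effects residualization plus across-subject one-sample
t-tests on contrast differences (`group_effects()`). The fitting unit is
the subject, no mixed-model engine is pulled in, and the published
mixed-effects coefficient magnitudes (35, 23, 28 ms, …) are therefore
direction-only references for synthetic cohorts, not numeric targets.

## Measuring the memory distribution directly

In the n-back task the lag-error distribution is observable: each positive
("match") response is a sample of $P(\Delta t)$, obtained by finding the
most recent prior occurrence of the current letter and measuring its
distance to the target position (`measure_delta_t()`). Lags are
case-insensitive in the letter comparison. Positives whose letter last
occurred *after* the target would give $\Delta t < 0$; since the model's
memory distribution has support $\Delta t \ge 0$, these are excluded and
tallied rather than kept — a declared convention, as published accounts
of the measurement leave the sign rule implicit. $\beta$ is the negative slope of a least-squares line
through $\log(\text{count})$ versus $\Delta t$ (`fit_beta_from_samples()`),
with one count added to every bin so the logarithm is defined; per-subject
fits use lags 0–4 where individual data are dense, pooled fits 0–10.
Uncertainty comes from 1000 bootstrap resamples (`bootstrap_beta()`), and
n-back versus serial-response estimates are compared by Spearman
correlation with a two-sided permutation test (`correlate_betas()`),
excluding subjects whose serial fit landed on a limit.

One property of this measurement deserves emphasis. The simulator
(`simulate_nback_session()`) draws a lag from the Boltzmann distribution,
truncated to the available history, and answers "match" when the recalled
letter equals the current one. With a 5-letter alphabet the current letter
can re-occur *between* the recalled position and the target, so the
measured lag is $\min(\Delta, G)$ with $G$ geometric of rate $1/5$; the
measured histogram is then exactly geometric with ratio
$\tfrac{4}{5}e^{-\beta}$, and the fitted slope exceeds the generating
$\beta$ by $\ln(5/4) \approx 0.223$. The test suite asserts this derived
value on end-to-end simulated sessions. Lags sampled directly from the
Boltzmann distribution (`sample_memory_lags()`) carry no such
contamination and recover $\beta$ cleanly; consequently, a measured n-back
$\beta$ should be read as an upper bound on the memory-precision parameter
of this generative model whenever chance re-occurrences are plausible.

## The synthetic cohort generator

`simulate_subject_rt()` inverts the analysis model: it draws a walk, runs
the learner at a known $\beta^*$, and emits
$r_0 + r_1 a(t) + \text{combo offset} + \text{trial trend} +
\text{recency trend} + \varepsilon$, with error trials, implausible
outliers (uniform on 2500–6000 ms) and a per-subject random assignment of
the 15 button combinations to nodes. Defaults — $\beta^* = 0.3$,
$r_0 = 900$ ms, $r_1 = -700$ ms, noise SD 150 ms — are of the same order
as typical human fits and are configuration constants, not measurements;
the nuisance defaults (combo offsets spanning ±35 ms, −25 ms per log
trial, +0.5 ms per trial of recency, 6% error rate, 1% outliers) were
chosen once as plausible magnitudes for this kind of task. The
deterministic part of every reaction time must be positive (otherwise the
generator errors); the Gaussian noise is then clamped at 1 ms, which at
the default signal-to-noise is essentially never active. A
`generate_from = "order1"` toggle produces cohorts whose reaction times
follow the first-order competing model instead, for model-recovery
exercises.

What the generator does *not* emulate: motor learning beyond the log-trial
trend, sequential dependencies in errors, subject-level distributions of
$\beta$ beyond what the caller scripts, or non-Gaussian reaction-time
skew. Passing recovery tests on these cohorts therefore demonstrates that
the estimation machinery is correct and well calibrated under the model's
own assumptions — not that the model is true of people.

## Numerical choices and problem sizes

* Closed-form estimates use `solve()` on the well-conditioned system
  above; agreement with a 500-term truncated series is required to
  $10^{-8}$ in tests, with the geometric tail bound
  $e^{-\beta K}/(1-e^{-\beta})$ checked explicitly.
* Zero-mass rows of any estimate (nodes never yet credited) default to
  the uniform $1/n$: the analysis never queries them on filtered real
  data, but a defined fallback keeps anticipation series total.
* Counts start at exactly zero — no pseudocounts, since the source states
  no prior.
* Ties in the grid argmin go to smaller $\beta$; exact RMSE ties between
  a finite fit and a limit go to the limit (uniform first).
* The test suite exercises ergodic convergence on a $5\times 10^4$-step
  walk (entrywise agreement with the closed form within 0.02), parameter
  recovery on 20 subjects of 1500 trials, and group-effect direction on a
  30-subject ring cohort; these sizes were chosen as the smallest at
  which the corresponding statistical claims are stable.

## Known limitations

* Quantities estimated from the original human subjects — the
  mixed-effects contrast magnitudes, the population averages
  $\bar\beta \approx 0.30$ (random walks) and $0.61$ (Hamiltonian walks),
  $\bar r_1 \approx -735$ ms, and the n-back/serial correlation
  $r_s = 0.28$ — require the original trial-level data, which is not
  publicly deposited. The package reproduces the *directions* of these
  effects on synthetic cohorts and the full analysis machinery, not the
  published numbers.
* With the default noise level (150 ms) and ~900 retained trials, the
  RMSE profile over $\beta$ is shallow; single-subject $\hat\beta$ has
  heavy right-tailed scatter, and when the full nuisance structure is
  simulated and residualized the median absolute error of
  $\hat\beta$ across a 20-subject cohort is typically in the 0.1–0.2
  range. The slope sign of $r_1$ is recovered essentially always.
* The n-back measurement is contaminated by chance letter re-occurrence
  as derived above; with 5 letters the bias is $+\ln(5/4)$ on the fitted
  slope under this generative model.
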