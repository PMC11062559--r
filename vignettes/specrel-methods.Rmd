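---
title: "Testing the computational relevance of trial-averaged population responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing the computational relevance of trial-averaged population responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specrel)
```

## The question

Trial-averaged population responses — "templates" — are everywhere in systems
neuroscience: tuning curves, average response vectors, PSTH-derived
summaries. Treating them as meaningful implicitly assumes two things. First,
*reliability*: single-trial responses repeat consistently enough that a
downstream reader could recognize the template in them. Second,
*behavioural relevance*: trials whose response matches the template better
should more often end in correct behaviour. `specrel` implements a two-part
statistical test of exactly these assumptions, together with the null models,
neuron-level dissections, and a generative simulator for interpreting the
results.

## The two indices

**Specificity.** For trial $i$ with population vector $r_i$, and
trial-averaged templates $\lambda_{correct}$ (the trial's own condition) and
$\lambda_{wrong}$ (the alternative condition),

$$\rho_i \;=\; \mathrm{cor}(\lambda_{correct}, r_i) \;-\;
               \mathrm{cor}(\lambda_{wrong}, r_i),$$

with $\mathrm{cor}$ the Pearson coefficient. Because each correlation lies in
$[-1, 1]$, $\rho_i \in [-2, 2]$; the bound $2$ is attained when a trial is
perfectly correlated with its own template and perfectly anti-correlated
with the other. No normalization is applied: the sign and global tendency
are what the test interprets. A linear correlation is the right match
measure here *because* averaging is linear — if one accepts the assumptions
behind the template, one accepts a linear, one-dimensional notion of
similarity.

**Behavioural relevance.** Given the $\rho$ values of behaviourally correct
trials ($X$, e.g. hits) and incorrect trials ($Y$, e.g. misses), the package
pools and ranks them (mid-ranks for ties), forms the rank sums $R_X, R_Y$,
and computes

$$U_X = R_X - \tfrac{n_X(n_X+1)}{2}, \qquad
  A = \frac{U_X}{n_X n_Y}, \qquad
  \Omega = \max(A, 1 - A).$$

$A$ is the Vargha–Delaney effect size: the probability that a random draw
from $X$ exceeds a random draw from $Y$, exact ties counted half.
$\Omega \in [0.5, 1]$, with $0.5$ meaning complete distributional overlap
and $1$ complete stochastic dominance; the $\max$ makes it symmetric in the
two groups. Internally $\Omega$ is evaluated as
$\max(U_X, U_Y)/(n_X n_Y)$ — algebraically the same quantity, but exactly
symmetric at floating point. The package ships a deliberately naive
pairwise-enumeration oracle (`brute_force_A()`); the rank implementation is
required by the test suite to agree with it exactly on every input, which
pins down tie handling unambiguously.

Hit and correct-rejection trials count as behaviourally correct, miss and
false-positive trials as incorrect; detection tasks are normally analysed as
hit vs miss within stimulus-present conditions and CR vs FP within
stimulus-absent conditions, which `behavioural_relevance()` supports by
taking the two samples explicitly.

## Edge cases the implementation commits to

* **Undefined correlations.** A zero-variance trial vector (or template)
  has no Pearson correlation. Such trials are listed in
  `specificity_result$excluded` with a reason — imputing $0$ would bias
  $\rho$, silently dropping them would hide data problems.
* **Minimum group size for $\Omega$.** One observation per group makes the
  rank test degenerate, so groups of fewer than 2 produce a
  flagged-undefined result carrying the group sizes, never a number.
* **Self-inclusion.** By default the scored trial contributes to its own
  template, the simplest reading of the procedure. This inflates
  correlations at small trial counts — and, in a session with *no* signal
  at all, produces a small positive $\rho$ bias that does not vanish with
  trial count (the template's across-neuron variation is then pure noise,
  part of which is the scored trial's own noise). `specificity_index(...,
  leave_one_out = TRUE)` recomputes the correct template without the scored
  trial; the package's own null-calibration checks use it for exactly this
  reason. $\Omega$ is unaffected either way, since the bias is common to
  both outcome groups.
* **Quantiles and percentiles.** All quantile computations (the
  Yule–Kendall skewness $\gamma$, surrogate percentile bands, covariate
  splits) use linear interpolation between order statistics
  (`stats::quantile` type 7), fixed package-wide so results reproduce bit
  for bit.
* **Ties in neuron rankings** (jackknife-based selection) break by neuron
  order, making selections stable across runs.

## Null models

Two surrogate generators ask whether single-trial variability is consistent
with "noisy copies of the template":

* `gaussian_surrogate()` (continuous data): per condition and neuron, draws
  from a normal with that neuron's across-trial mean and variance; draws are
  independent across neurons and not clipped (negative $\Delta F/F$ is
  legitimate). Default 200 draws per condition.
* `poisson_reallocation_surrogate()` (count data): per trial, keeps the
  total spike count fixed and reassigns each spike independently to neuron
  $m$ with probability $\lambda_m / \sum_m \lambda_m$ — one multinomial draw
  per surrogate. This is the only law satisfying the three defining
  constraints (fixed vector length, per-neuron allocation probabilities
  proportional to the template, exactly conserved total) under neuron
  independence. Default 100 draws per trial.

`surrogate_specificity_band()` scores every surrogate against the same
correct/wrong templates as the real trials and returns the median and a
percentile band (default 5–95%). Surrogate $\rho$ values are pooled across
ensembles by default, with per-ensemble medians also returned, since
reasonable analyses may summarize per trial first.

## Neuron- and group-level dissections

* `jackknife_contributions()` removes one neuron at a time and applies
  $SpecIdx_{JK}[i,j] = n\,\rho_i - (n-1)\,\rho_i^{(\neg j)}$. The
  Yule–Kendall $\gamma$ of the contribution distribution — pooled over all
  cells as the headline, and per neuron across trials — quantifies whether a
  right tail of "super-coder" neurons exists ($\gamma \approx 0$ means
  contributions are symmetric, i.e. no such subgroup).
* `select_extreme_neurons()` ranks neurons by the *median* of their
  jackknifed contributions (robust; no aggregator is canonically fixed) and
  slices the top or bottom `ceil(fraction * n)`.
* `subsample_metrics()` recomputes templates, $\rho$ and $\Omega$ on random
  neuron subsets across a fraction grid. No extrapolation curve is fitted —
  no functional form is canonical — so the raw per-fraction distributions
  are returned.
* `cluster_trials()` standardizes each neuron across trials (so high-rate
  neurons do not dominate Euclidean distance), runs k-means with 10
  restarts per candidate $k$, and picks $k$ by mean silhouette width. The
  choice of a centroid-based algorithm with multiple seeded restarts is an
  explicit design decision of this package.
* `metrics_by_group()` recomputes everything inside trial groups — cluster
  labels, covariate quantile splits (e.g. pupil size), easy/difficult trial
  splits — through one contract, reporting skipped under-sized groups and
  the pooled baseline.

## The generative simulator

`run_simulation()` implements a deliberately bare-bones model for building
intuition about what drives the two indices:

1. Two binary stimuli per trial, $S_1 \sim \mathrm{Bern}(p_1)$,
   $S_2 \sim \mathrm{Bern}(p_2)$ (defaults $0.5$); the stimulus difference
   $\Delta S = S_1 - S_2$. Trials with $\Delta S = 0$ have no correct
   response and are excluded from all analysis stages.
2. A population of $n = 200$ neurons (default) with selectivities
   $\xi_j = 2\,\mathrm{Beta}(\beta, \beta) - 1 \in [-1, 1]$: $\beta < 1$
   gives segregated, bimodal preferences, $\beta = 1$ uniform, $\beta > 1$
   homogeneous near-zero selectivity. Baselines and gains are
   $\mathcal{N}(5, 1)$.
3. Rates $r_{i,j} = \mathrm{ReLU}(r_j^0 + g_j^s \xi_j \Delta S_i) +
   |\mathcal{N}(0, \sigma^2)|$ and Poisson spike counts.
4. Empirical templates for $\Delta S = \pm 1$ are computed from the
   simulated spikes (what an analyst could actually do — not from the
   ground-truth rate profiles), yielding per-trial $\rho$.
5. A noisy sigmoid decision: $\psi' = \rho + \mathcal{N}(0, q^2)$,
   $p = 1/(1+e^{-\psi'})$, outcome $= 1$ iff $p \ge 0.5$ (the tie counts as
   a hit). $\Omega$ then compares $\rho$ between outcome groups.

**Parameter conventions chosen here.** The background-noise scale is tied
to a signal-to-noise control as `noise_sd = gain_mean / snr`, so the
default `snr = 5` reproduces the unit-variance base setting; the mapping
itself is this package's convention, since only the noise term's base form
is canonical. The stimulus-difference sign is $\Delta S = S_1 - S_2$.
Trial count defaults to 200 (roughly 50 analysable trials of each sign
after discarding $\Delta S = 0$), a size at which template estimates are
stable while a full landscape sweep stays interactive. One master seed
spawns independent per-stage streams, so adding a stage never perturbs
earlier draws.

`sweep_landscape()` maps median $\rho$ over a $\beta \times$ SNR grid, or
$\Omega$ over a $\beta \times q$ grid, with an optional compatibility mask
$|\text{measured} - \text{modelled}| < 0.05$ (default threshold) for
locating a measured data set in the parameter landscape. One structural
point matters when choosing the sweep's fixed SNR for the decision-noise
axis: $\Omega$ responds to $q$ only where the $\rho$ distribution lies
within noise reach of the decision threshold. At high SNR, $\rho$ sits far
above zero, virtually no misses occur at small $q$, and $\Omega$ is
honestly undefined rather than high; the package's calibration checks
therefore run that sweep at an intermediate SNR (0.2 on this scale) with
$\beta = 0.5$.

## The fixture generators

`make_continuous_fixture()` and `make_count_fixture()` emulate the two
recording styles the test targets — a continuous-response detection session
with hit/miss/CR/FP outcomes, and an integer-count two-alternative session
with hit/miss outcomes and covariates. Both expose the ground truth
(condition profiles, per-trial match quality) as an attribute and drive
outcomes through a sigmoid link on *condition-centred* match quality, so a
link slope of 0 decouples behaviour from neural response exactly, and a
steep slope with well-separated profiles approaches deterministic,
response-driven behaviour. The count generator optionally embeds two latent
response modes per condition, the structure that trial clustering and
grouped recomputation are designed to reveal.

What the fixtures deliberately do *not* emulate: temporal structure within
trials, correlated noise across neurons, slow drift, or behavioural state
dynamics. Passing calibration on them therefore shows that the estimators
are unbiased and responsive under independent-noise conditions — not that
real recordings satisfy the two assumptions.

## Calibration sizes used by the test suite

The package's calibration suite runs, among analytic anchors checked
exactly:

* landscape structure at 50 replicates per cell over
  $\beta \in \{0.25, 1, 4\} \times \mathrm{SNR} \in \{0.2, 1, 5\}$ (median
  $\rho$ strictly decreasing in $\beta$) and $q \in \{0.25, 1, 4\}$ at
  $\beta = 0.5$, SNR $= 0.2$ ($\Omega$ decreasing in $q$);
* null-fixture recovery over 100 seeds at 400 trials per condition: mean
  $\Omega$ within $0.02$ of $0.5$ when the outcome link slope is 0, and
  mean median-$\rho$ (leave-one-out scoring) within $0.02$ of $0$ when
  condition profiles are identical. The 400-trial size follows from the
  sampling standard deviation of $A$: near the null,
  $E[\Omega] - 0.5 \approx \sigma_A \sqrt{2/\pi} \approx 0.016$ at roughly
  400 trials per outcome group, inside the target band.

## A worked example

```{r example, eval = FALSE}
library(specrel)

# a two-alternative count session with clear condition structure
s <- make_count_fixture(n_neurons = 40, n_trials = 100, separation = 3,
                        link_slope = 10, seed = 42)
pair <- condition_pair("left", "right")

spec <- specificity_index(s, pair)
rel  <- relevance_of(spec)
median(spec$trials$rho)   # reliability: how template-specific are trials?
rel$omega                 # relevance: does a better match predict success?

# null benchmark: spike-conserving reallocation surrogates
tpl <- compute_templates(s)
ens <- lapply(s$trials$trial_id[s$trials$condition == "left"], function(id)
  poisson_reallocation_surrogate(s, id, tpl$left, seed = 7))
surrogate_specificity_band(ens, tpl$left, tpl$right)[c("median", "lower", "upper")]

# who carries the specificity?
jk <- jackknife_contributions(s, pair)
jk$gamma_pooled
select_extreme_neurons(jk, 0.10, "top")
```

## Known limitations

* Only two-condition (two-template) designs are supported; $\rho_i$ has no
  multi-condition generalization here.
* No significance machinery beyond the $U$ statistic is provided: $\Omega$
  is an effect size, and its sampling distribution under realistic neural
  dependence is not modelled.
* The simulator is intentionally minimal — independent Poisson neurons, a
  single scalar decision variable — and supports qualitative reasoning
  about parameter regimes, not fitting to data beyond the compatibility
  mask.
* Analysis-window averaging happens upstream: sessions arrive as
  pre-averaged trials × neurons matrices, and the window is carried as an
  annotation only.
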