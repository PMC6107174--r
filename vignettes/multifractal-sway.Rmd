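---
title: "Multifractal analysis of postural sway: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifractal analysis of postural sway: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mfsway quantifies heterogeneity in nonnegative displacement series --
typically frame-to-frame Euclidean displacements of a tracked body point
-- and asks whether that heterogeneity exceeds or falls short of what the
best-fitting *linear* model of the same series would produce. This
vignette explains the estimators, the surrogate test, the mixed models,
and the design decisions behind each, in the package's own terms.

## The direct multifractal spectrum

A displacement series `u(t)` is treated as a mass distribution over time.
At bin size `L`, the proportion of total displacement in bin `i` is

\[ P_i(L) = \frac{\sum_{k=(i-1)L+1}^{iL} u(k)}{\sum_t u(t)}, \]

with only complete bins counted (the trailing partial bin is discarded
and the normalisation runs over complete bins, so proportions always sum
to one). A distortion exponent `q` turns the proportions into the q-mass

\[ \mu_i(q, L) = \frac{P_i(L)^q}{\sum_j P_j(L)^q}, \]

which emphasises large proportions for `q > 0` and small ones for
`q < 0`. Two quantities are then regressed on `ln L` across a set of bin
sizes:

* `sum(mu * ln mu)` -- the negative Shannon entropy of the q-mass; its
  slope is the dimension `f(q)`;
* `sum(mu * ln P)` -- the q-weighted log-proportion; its slope is the
  singularity strength `alpha(q)`.

A `q` enters the spectrum only when **both** regressions are convincingly
linear: the Pearson `|r|` of each must exceed the fidelity floor
(`r_threshold`, default .995). The absolute value matters because the
slopes of interest can be negative. The spectrum is the downward-opening
curve `(alpha(q), f(q))` over retained q, and its width
`W = max(alpha) - min(alpha)` is the heterogeneity measure carried
through the rest of the pipeline. This direct estimator is used, rather
than variance-based scaling methods (MFDFA, WTMM), because quasiperiodic
signals -- and postural sway is quasiperiodic -- are a known failure mode
of finite-variance scaling estimators.

### Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `q_values` | integers −200..200 | — | wide sweeps do not inflate W: poorly scaling q are dropped by the fidelity filter, and for weakly multifractal series more q only consolidate a narrow spectrum. The integer step is configurable. |
| `l_min` | 4 | samples | smallest bin with meaningful proportions |
| `l_max` | length/4 | samples | whole-series analyses use one quarter of the series (1503 for a 6012-sample series); block analyses use 250 within each 1000-sample block |
| `n_scales` | 16 | — | log-spaced integer bin sizes between `l_min` and `l_max`, deduplicated; log-spacing weights all decades equally in the log-log regression |
| `r_threshold` | .995 | — | retention floor applied to both regressions |

### Numerical choices

* **Extreme q.** `P^q` at `q = ±200` overflows any direct power, so all
  masses are formed in the log domain with max-subtraction
  (`exp(q log P - max - log sum)`), in compiled code. The unit tests
  check `sum(mu) = 1` to 1e-9 at `q = ±200`.
* **Zero-proportion bins.** For `q > 0` an empty bin carries zero mass
  and is simply excluded. For `q <= 0` an empty bin would make the mass
  infinite; rather than flooring the proportion (which invents mass and
  biases negative-q moments), the whole scale is dropped for those q. A
  q left with fewer than three usable scales cannot be retained. Dropped
  scales are recorded on the spectrum object.
* **Degenerate inputs.** All-zero series, oversized bins and scale sets
  with fewer than three sizes are hard errors; an empty retained set
  yields `W = NA` with a warning rather than a fabricated width.

### Validation against a closed-form oracle

The binomial multiplicative cascade with weight `p` has the closed-form
spectrum `alpha(q) = -(p^q ln p + (1-p)^q ln(1-p)) / ((p^q + (1-p)^q) ln 2)`
and limiting width `W = log2((1-p)/p)`. The generator (`binomial_cascade`)
redistributes unit mass over `2^k` cells, the side receiving `p` chosen
by an independent fair coin per node -- statistically symmetric, same
spectrum as the deterministic cascade. On *dyadic* bin sizes
(`dyadic_scales`), bins align exactly with cascade cells and the
estimator reproduces the closed form essentially exactly (all 401 q
retained, width error at floating precision for `k = 12`); this is the
validation route used in the tests. On the default log-spaced scale set,
non-dyadic bins straddle cascade cells, the fidelity filter reacts by
dropping most q, and W is underestimated -- which is the correct
behaviour of the filter, not an estimator defect, and is why cascade
validation pins the scale set to the construction's own dyadic geometry.
A second, scale-agnostic check compares the full pipeline against an
independent brute-force implementation (explicit loops, direct powers,
`lm()` slopes) to 1e-9 on short series.

## The IAAFT surrogate null and the t statistic

The null hypothesis is that a series is a (possibly monotonically
transformed) linear stochastic process. Iterated amplitude-adjusted
Fourier transform surrogates operationalise it: starting from a
phase-randomised copy (uniform phases, conjugate symmetry), each
iteration re-imposes the original amplitude spectrum with the current
phases, then rank-replaces the values with the original's sorted values.
The returned series always ends on the rank step, so its sorted values
equal the original's bit-exactly, and its periodogram matches the
original's closely (correlation > 0.95 on the test signals, typically
> 0.999).

Iteration runs to the default 1000 unless the rank ordering reaches a
fixed point first, after which further iterations would reproduce the
identical series -- the early exit changes nothing but time. A
convergence log (relative amplitude-spectrum mismatch per iteration) is
available via `return_log`.

For each original unit, `n_surrogates` (default 50) surrogates are
generated (seeded `seed + i`) and analysed under the *identical* scaling
configuration. The nonlinearity statistic is

\[ t = \frac{W - \bar W_{surr}}{SE(W_{surr})} . \]

Positive t: the original spectrum is wider than its linear null
(nonlinear interactions amplify heterogeneity). Negative t: narrower
(nonlinearity constricts variability). `|t| > 1.96` is the conventional
two-sided cut used when counting significant series.

**The SE convention.** "Standard error of `W_surr`" admits two readings:
`sd/sqrt(n)` (the default here) and the plain ensemble `sd` (a z-score).
Both are implemented (`se_method`); output objects record which was
used. The readings differ by a factor of `sqrt(50) ~ 7`, which matters
for calibration: under the default reading a *linear* series still shows
|t| > 1.96 frequently, because the original's W is one draw from the
same distribution as the surrogates' while the SE shrinks with ensemble
size. The package's false-positive-rate property test therefore uses the
z-score reading, where t is approximately standard normal under the
null; under the default reading the meaningful null check is that the
*mean* t across many linear series is near zero, which is what the
acceptance checks assert.

## Cohort pipeline

`analyze_series` computes, per series, the whole-series pair
(`W_ALL`, `t_ALL`; scaling region 4..length/4) and per 1000-sample block
the pair (`W_BLOCK`, `t_BLOCK`; scaling region 4..250). Block
partitioning starts at the series' stimulation-onset index (a manifest
column, default 0 -- onset alignment is dataset documentation, not
algorithm); whole-series measures always use the entire stored series.
Four blocks are analysed; a fifth block is deliberately out of scope
(too few subjects supply one, and an unbalanced fifth block would
distort the repeated-measures models).

The surrogate null for a block t is built from surrogates *of that
block*, so each unit is compared against the linear model of that same
unit. The alternative -- cutting blocks out of whole-series surrogates --
is available (`block_surrogates = "series"`) but not default: a
whole-series surrogate redistributes nonstationarity across blocks and
so tests a different hypothesis.

`build_cohort_table` assembles one ALL row plus four block rows per
subject x condition, joining each unit's `W_ALL`/`t_ALL` onto its block
rows, skipping unreadable files with a warning and refusing duplicated
subject x condition keys. `cohort_summary` reports the per-condition
means, SDs and ±1.96 counts used in whole-cohort comparisons.

## The two mixed models

Both models have the full `Condition x Block-terms x covariate` fixed
structure (16 terms including the intercept) and a random intercept per
subject; both are fitted by REML with Satterthwaite degrees of freedom
(lmerTest), the method recorded in the output since p-values differ
slightly across df approximations.

* `fit_w_block`: `W_BLOCK` on orthogonal linear/quadratic/cubic block
  polynomials (orthonormal over the observed design), covariate `W_ALL`
  -- smooth directional change of width over blocks.
* `fit_t_block`: `t_BLOCK` on Block as a class variable with Block 1 the
  reference, covariate `t_ALL` -- discontinuous block-wise shifts.

Covariates enter uncentered, so intercepts and condition terms are on
the raw covariate scale. With balanced data the two codings span the
same block space: the tests verify that their fitted values agree to
1e-8 when given the same response and covariate. Rank-deficient designs
(for example a single condition) raise an error naming the aliased term
rather than silently dropping it.

## The synthetic cohort: what it emulates, what it does not

`synth_cohort` produces the study-shaped dataset the chain is validated
on: 21 subjects x 2 conditions, 6012-sample nonnegative series at 50
samples/s (1000 samples = one 20-s block). Each series is a
quasiperiodic carrier (peaked-spectrum linear process, default period
2 s -- a slow postural oscillation) plus white measurement noise
(sd 0.2 of the carrier amplitude), riding on a constant baseline of 4
carrier amplitudes, with absolute value taken last. The baseline keeps
the displacement measure positive the way real frame-to-frame
displacement magnitudes are, and at 4 signal-sd the absolute value
almost never binds, so the "none" condition stays a genuine linear null.

Condition-dependent nonlinearity:

* **widening** (default for no-wind): the whole displacement magnitude
  is multiplied by a binomial-cascade envelope (weight 0.35, resampled
  to series length, normalised to mean 1). The cascade's multiplicative,
  phase-coherent heterogeneity is exactly what phase randomisation
  destroys, so originals come out wider than their surrogates (t > 0).
* **narrowing** (default for wind): amplitude-stabilised frequency
  modulation -- `sin()` (a bounded, saturating function) applied to the
  carrier phase plus a slow linear drift (steep power-law series, ~3 rad
  excursions). The oscillation's envelope is flat while linear
  surrogates with the same broadened spectrum beat, so originals come
  out narrower (t < 0). A *static* saturating transform (e.g. tanh of a
  linear series) was rejected during design: it lies inside the IAAFT
  null -- a monotone transform of a Gaussian linear process -- and
  measured t ~ 0, as theory predicts.

The truth table records each series' mechanism, cascade weight and seed.
All randomness flows through per-series seeds derived from the cohort
seed, so cohorts are bit-reproducible and never disturb the caller's RNG
state.

What the generator does **not** emulate: insect biomechanics, wind
aerodynamics, tracking error structure, or any particular empirical
marginal distribution of displacement. Passing tests show that the chain
detects the *direction* and *presence* of nonlinearity it was designed
to detect under controlled conditions; they do not show that any
particular organism's sway is multifractal.

## Problem sizes used in tests and the acceptance script

Structural and calibration checks run at sizes chosen to keep a full
validation run to a few minutes on one core while leaving every
scientific conclusion intact: null-calibration cohorts use 4096-sample
series (the shortest length supporting four full blocks, and a power of
two, which the FFT-heavy surrogate step likes), ensembles of 15-20
surrogates, and cohorts of 6-10 subjects; directional checks run at the
full 6012-sample study length where the narrowing mechanism is
strongest; model-recovery checks average 30 replicate fits of the
21-subject design. The analysis scripts under `analysis/` default to the
full study configuration (integer q in -200..200, 50 surrogates per
unit) and provide a `MFSWAY_QUICK` switch for iteration.

## Known limitations

* The t statistic's magnitude depends strongly on the SE convention;
  between-study comparisons should state the convention (output objects
  do).
* W estimates on the default log-spaced scale set are conservative for
  measures with sharp dyadic structure; the fidelity filter trades bias
  for honesty.
* The retention rule makes W a function of the retained-q set, so two
  spectra with different retained sets are comparable only through their
  common configuration.
* The t statistic depends on the q sweep: truncating it (for example to
  −50..50 while iterating) discards the extreme-q tails that carry much
  of the contrast between an amplitude-stabilised series and its linear
  null, and can change t's sign. Compare t values only across runs with
  the identical sweep.
* `iaaft` requires series long enough for a meaningful spectrum
  (>= 16 samples; in practice blocks of 1000 or more).
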