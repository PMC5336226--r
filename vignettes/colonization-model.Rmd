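---
title: "Stochastic colonization of a host gut: model, statistics, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic colonization of a host gut: model, statistics, and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutdrift)
```

## The model and its assumptions

`gutdrift` implements a minimal stochastic description of how bacteria
colonize a host intestine. Each host is one realization of a
continuous-time Markov jump process over per-strain abundances
`N_1, ..., N_s` with a shared carrying capacity `K`:

* strain *i* gains one cell with propensity
  `(b_i N_i + c_i) * max(0, 1 - (N_1 + ... + N_s)/K)`
* strain *i* loses one cell with propensity `d_i N_i`

`b` is the within-host birth rate, `d` lumps death and excretion, and
`c` is the colonization rate — the rate at which ingested cells survive
passage and adhere to the gut, *not* the feeding rate (in the worm
system fewer than one ingested cell in a thousand establishes; the two
are connected by `estimate_feeding_rate()`'s establishment fraction).
All rates are per hour. Immigration is multiplied by the same logistic
factor as birth; that is a deliberate fidelity choice (it matches the
reaction scheme the model is defined by) rather than a mechanistic claim
about how arriving cells sense gut occupancy.

Assumptions worth keeping in mind: rates are constant in time and
identical across hosts; there is no spatial structure inside the gut
(real colonized worms show monochromatic "clumps", which this model
cannot produce); excretion is continuous rather than pulsed; and in the
"neutral" configuration every strain carries identical parameters, so
all between-host variation is demographic noise.

## Regime theory

For a supercritical strain (`b > d`) three quantities organize the
dynamics (`regime_summary()`):

* `p_ext = d/b` — probability that a single founding cell's lineage dies
  out. At the canonical parameters (`b = 0.6`, `d = 0.54`) this is 0.9.
* `T_est = b/(c(b-d))` — mean waiting time between *successful*
  establishments, i.e. `1/(c(1-p_ext))`.
* `T_grow = 1/(b-d)` — e-folding time of an established colony.

The dimensionless ratio `T_grow/T_est` reduces to `c/b` exactly. When it
is small, whichever strain establishes first has grown to dominance
before the next success arrives, and the between-host composition
distribution piles up near 0 and 1. When it is large, many lineages of
both strains establish within one growth time and every host converges
to the inoculum mixture. Note that `K` appears nowhere in the ratio: the
transition is insensitive to carrying capacity, which is why hosts with
order-of-magnitude different gut population sizes show the transition at
similar feeding densities.

The regime label attached by `regime_summary()` (transitional band
defaulting to `c/b` in [0.5, 2]) is cosmetic and feeds no computation;
the band is configurable because the theory supplies a criterion
(`c/b` vs 1), not a boundary.

`linear_bdi_mean()` gives the exact mean of the non-saturating process
started empty, `c(e^{(b-d)t} - 1)/(b-d)`, continuously extended to `ct`
at `b = d`. It is used throughout the tests as the `K -> Inf` oracle for
the simulator and is deliberately limited to the mean — the package does
not implement the full time-dependent distribution.

## Simulation backends and numerical choices

The compiled core offers exact Gillespie SSA and tau-leaping.
Tau selection follows the classic leap condition: the step is chosen so
the expected relative change of each species (and hence of the
propensities) stays below `eps = 0.03`, taking the tighter of the
mean-based and variance-based bounds per species. Three guard rails:

* when total propensity falls below `exact_threshold` (10 events/h) or a
  leap would span fewer than ~10 events, the step is taken exactly —
  small populations are where leaping is both pointless and dangerous;
* a leap whose Poisson draws would push any count negative is rejected
  and retried at halved tau (falling through to an exact step if tau
  collapses), so counts are never negative;
* the logistic factor is clamped at zero, so an overshoot of `K` (at
  most one leap's worth) produces zero gain propensity, not a negative
  one.

Tau-leaping is an Euler-style scheme: in pure exponential growth it
underestimates the realized rate by about `r*eps/2` per unit time. That
bias is invisible to composition statistics (both strains share it) and
to saturated endpoints, but it matters when the object of interest is
the growth rate itself; the net-growth consistency check therefore runs
on the exact backend, which we verified is unbiased (ensemble mean of a
seeded pure birth–death process matches `N0 e^{rt}` within Monte Carlo
error at 4,000 runs).

Reproducibility: every simulation takes an explicit seed;
`simulate_ensemble()` derives per-host seeds from the base seed with a
documented congruential mix (`derive_seed()`), so any single host of any
ensemble can be re-run in isolation. Trajectory recording snapshots the
state on a user grid; within a tau-leap interval the pre-leap state is
reported (the process is piecewise constant between events, and a leap
is treated as a single event at its end).

## Bimodality statistics

The bimodality coefficient is
`BC = (m3^2 + 1)/(m4 + 3(n-1)^2/((n-2)(n-3)))` with `m3` the
bias-corrected sample skewness and `m4` the bias-corrected (SAS
convention) sample excess kurtosis — the conventions the finite-sample
correction term is built for. Implementations using population moments
will disagree at small `n`; the test suite pins the convention against
an independent moment implementation to 1e-12. Reference points: a
normal sample tends to 1/3, a uniform one to 5/9 ≈ 0.556 (which is why
0.55 is the conventional critical value), and a balanced two-point
mixture to 1.

Composition fractions are undefined for uncolonized hosts, so all
cohort statistics drop `total = 0` rows first (`cohort_fractions()`);
cohort sizes are reported as colonized/total.

`bootstrap_bc()` uses the percentile method on n-out-of-n resamples.
Degenerate resamples (constant, or too small for the correction term)
are redrawn and counted in `n_redrawn`; with fractions piled on two
points this is rare for `n` above ~10. The percentile interval is not
guaranteed to contain the point estimate, only to be ordered.

`find_transition()` interpolates BC linearly against `log10(c)` — the
natural scale on which colonization rate is tuned experimentally — and
returns the first downward crossing of the threshold, with all crossings
counted so noisy curves are flagged rather than silently truncated.

`mann_whitney()` wraps the rank-sum test (exact enumeration when both
samples have at most 8 observations and no ties, tie-corrected normal
approximation otherwise). One caveat discovered in testing: for
*neutral* cohorts the low- and high-colonization composition
distributions share the same median (1/2) and differ in spread, to which
a location-type rank test is insensitive; comparing `|f - 1/2|` between
cohorts is the sensitive version of that contrast. `compare_cohorts()`
reports the plain comparison, which is the appropriate test when the
strains are not symmetric.

## Parameter estimation

**Logistic growth (`fit_logistic`).** Nonlinear least squares of the
logistic closed form on the `log10(count + 1)` scale (counts span
decades; +1 keeps zeros finite if retained), Levenberg–Marquardt over
`(log10 N0, log r, log10 K)` from a grid of data-driven starts; the
worm-level percentile bootstrap (resampling worms within timepoints —
the worm is the independent unit) restarts each refit from the original
solution.

Zero-count worms are excluded by default. This was a deliberate reversal
made during development: zeros in outgrowth assays are founder-lineage
extinctions, governed by `d/b`, not small values of the growth curve.
Feeding them to a least-squares logistic — which has no zero-inflation
component — measurably biased the recovered `r` upward by 25–35% and
broke both the median-error and CI-coverage targets of the recovery
study below. Growth assays likewise tabulate uncolonized worms separately
from the average-CFU curve. `include_zeros = TRUE` restores the other
behavior for users who want it.

**Death rate (`estimate_death_rate`).** Under division arrest the
population decays exponentially, so `d` is minus the slope of log CFU
against time (two-point closed form or log-linear regression; the
regression CI is reported when there are more than two observations).

**Colonization rate and calibration (`estimate_colonization_rate`).**
At assay times short enough that `bN` is negligible against `c`, mean
CFU/worm accumulates linearly; `c` is the through-origin slope per
feeding density, and the calibration slope `kappa` is the through-origin
regression of `c` on density. The default `kappa = 1e-7` (CFU/worm/h per
CFU/mL) reproduces the observed correspondence 1e6 CFU/mL -> 0.1/h and
1e9 -> 100/h. Single-timepoint densities fall back to `c = CFU/t` and
are flagged, since that leans harder on linearity.

**Feeding rate (`estimate_feeding_rate`).** Pure bookkeeping on the
depletion of external CFU; an increase in external counts aborts the
calculation because it means bacteria were growing outside the host.
The ratio `c/feeding_rate` is the establishment fraction.

**Birth rate.** `b` itself is not estimable from these assays in
isolation (only `b - d` and `d` are); the package treats it as a
configuration choice bounded below by the net growth rate and above by
the maximal external growth rate, rather than pretending to estimate it.

## Synthetic data

The generators produce every input the estimators and the pipeline
consume, with a shared observation layer: dilution plating at factor `D`
(default 20, matching a 200 uL resuspension read in 10 uL spots) with
Poisson colony counts — unbiased, with detection limit `D` and values
quantized to multiples of `D`.

`generate_growth_series()` emulates destructive cross-sectional
sampling of an outgrowth assay: per-worm load = logistic mean x
lognormal worm-to-worm scatter (default sigma = 1.0 decades, matching
the ~±1 log10 spread observed across colonized worms), zeroed with
probability `0.2 * 2^(-t/24h)` (uncolonized worms are common on day one
and disappear over the following days as ambient recolonization refills
them — a smooth decay; a sharp cutoff window was tried first and
rejected because the kink it leaves in the mean curve biases logistic
fits). Of note, the real system shows *more* worm-to-worm variation than
the birth–death–immigration model itself generates; the generators
emulate the data, not the model, which is why scatter is injected at
the observation layer rather than inherited from the simulator.

`generate_arrest_series()` (exponential decay + plating on bulk
digests) and `generate_short_assay()` (linear accumulation with Poisson
sampling over a disrupted batch) complete the calibration inputs.
`generate_cohort()` maps feeding densities through `kappa` to `c`,
simulates each worm, and plates each strain independently; `blind =
TRUE` strips the truth columns without touching the observables.

What passing recovery tests on these generators shows — and what it does
not: they demonstrate that the estimators are consistent and their
bootstrap CIs approximately calibrated *under the stated noise model*
(lognormal scatter, Poisson plating, smooth extinction decay). Real
worm data have additional structure the generators omit — overdispersed
totals, day effects, possible non-neutrality between labels — so CI
coverage on real data should be expected to be somewhat worse.

## Validation design and problem sizes

The recovery and coverage studies fix one design, chosen from the
information budget before the tests were frozen: truth `r = 0.0625/h`
(= 1.5/day), `K = 2e5`, `N0 = 1000`, sampling every 24 h for 10 days,
**24 worms per timepoint**. With 1-decade scatter the plateau location
is pinned to `sigma/sqrt(n_plateau)` ≈ 0.083 decades by roughly six
plateau timepoints of 24 worms, which is what it takes to resolve `K`
to ~15% in median; 12 worms per timepoint — a common bench design —
resolves it only to ~20%. Measured at this design: median relative
error ~11% for both `r` and `K`, CI coverage 95% (`r`) and 98% (`K`)
at 95% nominal.

Ensemble sizes elsewhere follow the experiments being emulated: 56-host
cohorts over 192 h for the composition studies; sweeps over a log grid
of 9 colonization rates from 0.05 to 20/h with 3 replicate sweeps;
2,000–5,000 runs for mean-trajectory and extinction-frequency checks;
the parameter-uncertainty band draws 48 `(b, d, K)` sets by default
(uniform in `b` and `d` with rejection to enforce `b > d`, log-uniform
in `K`).

## Known limitations

* No spatial structure, time-varying rates, or pulsed excretion; the
  model underestimates the variance of per-host totals seen in real
  cohorts.
* Tau-leaping carries the usual first-order rate bias (~`r*eps/2`);
  use `method = "exact"` when the growth rate itself is the target.
* The linear-BDI layer provides only the mean, not the distribution.
* `mann_whitney()` on neutral cohorts is insensitive to pure spread
  changes (see above).
* The transition estimate `c_star` interpolates a noisy curve; its
  replicate-to-replicate spread at the default sweep size is of order
  30%, which is why the headline quantity is a geometric mean over
  replicate sweeps and is only claimed to a factor of 2.
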