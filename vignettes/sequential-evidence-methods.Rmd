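---
title: "Sequential Bayes factors for below-chance binary outcomes: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential Bayes factors for below-chance binary outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The experimental design seqbf models

seqbf analyses experiments in which every participant completes a fixed
number of binary trials — by default 60 — whose outcome on each trial is
decided by two random bits: a bit pre-stored before the session and a bit
drawn live at response time. The XOR of the two bits decides whether the
trial outcome is "negative" (bit 1) or "neutral" (bit 0). With two
independent fair bits the XOR is itself a fair bit, so under the null
hypothesis each participant's negative-outcome count is
Binomial(60, 0.5): mean 30, variance 15. The scientific hypothesis of
interest — *avoidance* — is that counts fall *below* chance.

The package's unit of evidence is the one-sample Bayes factor of the
per-participant counts against the chance level $\mu_0 = 30$,
recomputed after every participant in the order of data collection. The
resulting *sequential Bayes factor curve* is both the decision object
(via an optional-stopping rule) and the raw material for three
temporal-anomaly statistics that ask whether the curve's excursions are
larger than fair-bit randomness produces.

## The Bayes factor

For counts $y_1,\dots,y_n$ with mean $\bar y$ and standard deviation $s$
(the $n-1$ denominator), the test statistic is
$t = (\bar y - \mu_0)/(s/\sqrt n)$. Under the null, $t$ follows a
central $t$ distribution with $\nu = n - 1$ degrees of freedom. Under
the alternative, the standardized effect
$\delta = (\mu - \mu_0)/\sigma$ carries a Cauchy$(0, r)$ prior, and the
sampling density of $t$ given $\delta$ is noncentral $t$ with
noncentrality $\delta\sqrt n$. The Bayes factor is the marginal
likelihood ratio

$$
\mathrm{BF}_{10}
  = \frac{\int f_{\nu,\,\delta\sqrt n}(t)\,\pi(\delta)\,d\delta}
         {f_{\nu,\,0}(t)} .
$$

Directional hypotheses are encoded in the prior: for the avoidance
direction (`direction = "less"`) the Cauchy density is truncated to
$\delta < 0$ and doubled, the convention of the standard Bayesian
$t$-test implementations; `"greater"` mirrors it, and `"two_sided"` uses
the untruncated prior. Three identities follow and are enforced by the
test suite: $\mathrm{BF}_{10}\cdot\mathrm{BF}_{01} = 1$; the two
one-sided Bayes factors sum to twice the two-sided one; and all three
coincide at $t = 0$.

The default prior scale is $r = 0.1$, a deliberately narrow prior
appropriate when the anticipated effect is very small (the design
expects standardized effects near 0.1). The robustness sweep
(`robustness_sweep()`) re-evaluates the final Bayes factor under the
conventional medium/wide/ultrawide scales $\{0.707, 1, 1.414\}$; with a
null-ish sample of two thousand participants these wide priors produce
$\mathrm{BF}_{01}$ well above 30, the usual demonstration that a
non-decisive narrow-prior result is a prior-width artifact rather than
lack of power.

### Numerics

The marginal under $H_1$ is a one-dimensional integral of a noncentral-$t$
density against a (half-)Cauchy. The production quadrature substitutes
$\delta = -r\tan\theta$, which maps the truncated prior to the uniform
density on $(0, \pi/2)$: the Cauchy tail is compactified exactly, and
the integrand becomes a bounded smooth function evaluated by
Gauss–Legendre quadrature (48 nodes by default) in log space, so extreme
$t$ values cannot overflow. Configurations where a fixed prior-mapped
rule under-resolves the likelihood — $|t| > 4$, tiny samples with
moderate $|t|$, wide priors at large $n$, or a likelihood peak far
outside the prior scale ($|t| > 3r\sqrt n$) — are refined by composite
Gauss–Legendre panels placed around the likelihood peak on the
effect-size scale, with panel widths tracking the likelihood scale
$\sqrt{(\nu + t^2)/\nu}/\sqrt n$. Both paths are validated against a
deliberately naive dense-trapezoid oracle to $10^{-5}$ relative
(to $10^{-3}$ in far wrong-direction tails, where the noncentral-$t$
density implementation itself carries $\sim 10^{-4}$ relative error).

Degenerate prefixes require a convention. The curve is defined for
cumulative $n$ from 1 to $N$; below `min_n = 2` the sample standard
deviation does not exist, and occasionally the first few counts are
exactly equal so that $s = 0$ at small $n$. Both cases are assigned
$\mathrm{BF} = 1$ (equipoise): a sample that cannot be standardized
carries no evidence either way. The alternative of capping the Bayes
factor at some large value toward the favored direction was rejected
because degenerate prefixes occur in a few percent of null cohorts, and
any large cap would visibly distort the simulated energy distribution
that the temporal-anomaly calibration depends on. Setting the full
curve length to $N$ (with the $n = 1$ value fixed at 1) also makes the
FFT below yield exactly $N/2$ tested frequencies.

### Optional stopping

The stopping rule is symmetric: data collection stops at the first $n$
where $\mathrm{BF}_{10} \ge 10$ (stop for $H_1$) or
$\mathrm{BF}_{10} \le 1/10$ (stop for $H_0$), whichever boundary is
crossed first. `stopping_check()` reports the decision with the
first-crossing index; `sequential_stop()` is an equivalent
early-terminating evaluation for simulation studies.

Operating characteristics under the study conditions (fixed seeds,
measured once by a 1,000-simulation calibration run and then asserted
in the test suite): cohorts generated with a standardized avoidance
effect $d = 0.3$ (per-trial negative probability $\approx 0.4806$) stop
for $H_1$ before 500 participants in well over 90% of runs. Null
cohorts followed to the full 2,328-participant horizon touch the $H_1$
boundary at some point in about 6.5% of runs — sequential evidence
sampled at every participant gets many chances at a threshold, so this
false-stop rate is a property of the design, not a defect; the suite
asserts it stays below 10% (the calibrated rate plus four Monte Carlo
standard errors at the test's 200 runs).

## Per-lab analysis and meta-analysis

`lab_bayes_factors()` recomputes the one-sided Bayes factor from each
lab's $(n, \bar y, s)$ summary row. `meta_random_effects()` pools the
standardized avoidance effects $d_i = (\mu_0 - \bar y_i)/s_i$ (signed so
that avoidance is positive) with sampling variances
$v_i = 1/n_i + d_i^2/(2 n_i)$ under a random-effects model fit with
`metafor::rma()`, reporting the pooled effect, its standard error,
$\tau^2$, $I^2$, and Cochran's $Q$ with its $\chi^2$ p-value.

The $\tau^2$ estimator default is REML — metafor's own default — rather
than DerSimonian–Laird. On the five-lab summary table the two
estimators differ materially in the heterogeneity they report
(REML: $\tau \approx 0.002$, $I^2 \approx 0.1\%$;
DL: $\tau \approx 0.017$, $I^2 \approx 6.5\%$), and only the REML
figures are consistent with the published analysis this package is
designed to reproduce, which reported essentially zero heterogeneity
from an R workflow. DL remains available via `method = "DL"`.

## Temporal-anomaly statistics

Three scalar statistics summarise a sequential curve
(`anomaly_stats()`):

* **Maximum BF** — the curve's largest value, with the index of its
  first attainment (ties break to the earliest $n$).
* **Curve energy** — $\sum_n (\mathrm{BF}_n - 1)$, the signed discrete
  area between the curve and the equipoise line $\mathrm{BF} = 1$.
  Positive energy means the trajectory spent its excursions on the
  $H_1$ side.
* **FFT amplitude sum** — the sum of the one-sided discrete-Fourier
  amplitude spectrum of the raw BF series.

The spectrum retains frequencies $1 \dots N/2$ (sampling rate $1/N$;
2,328 participants give 1,164 tested frequencies), excludes the DC term,
and pads odd-length series by repeating the last value. Because the
analysis tradition this reproduces did not document its normalization,
two conventions are exposed: `"half"` divides coefficient moduli by
$N$, and `"amplitude"` uses the textbook $2/N$ (Nyquist $1/N$) scaling
under which a pure cosine of amplitude $A$ reads exactly $A$ in its
bin. The default is `"half"`: in a 1,000-simulation null calibration
the published exceedance rate of the human amplitude sum (1.47%) is
reproduced under `"half"` (1.4%) but not under `"amplitude"` (2.5%).
The energy and FFT statistics are computed on the raw BF scale, not log
BF, consistent with the energy definition.

### Monte Carlo calibration

None of the three statistics has a usable closed-form null
distribution, so `build_null()` calibrates them empirically: `n_sims`
cohorts of `n_participants` × `n_trials` fair bits are simulated, each
is run through the identical sequential analysis, and the statistics
are collected. Observed statistics are then referred to this null
distribution by `empirical_p()` — the *inclusive* proportion of
simulations at least as extreme, with no add-one correction, matching
the convention of reporting exact simulation counts. The joint
max-BF/energy score (`combined_exceedance()`) is the proportion of
simulations dominating the observed pair in both coordinates; because
dominance is coordinatewise, the monotone display transforms
($\log$ max BF, $\operatorname{asinh}$ energy) do not affect it.

Under the null, the empirical p-value of a fresh null draw is uniform
up to the discreteness of the simulation count; the suite checks this
with a Kolmogorov–Smirnov test on 300 repetitions.

Reproducibility: the master seed draws one sub-seed per simulation, so
individual simulations can be reproduced in isolation and the whole
null distribution is a pure function of
(`n_sims`, `n_participants`, `n_trials`, config, seed).

### Simulation problem sizes

The calibration studies in the test suite and the acceptance script use
1,000 simulations of the full 2,328-participant series — enough to pin
the published exceedance rates (1.24%, 4.2%, 1.47%) to within four
Monte Carlo standard errors, which is the precision those anchors
support. Auxiliary property checks (p-value uniformity, engine
agreement) run at reduced cohort sizes (100–300 participants) because
the properties they exercise do not depend on the horizon length.

To make thousand-curve studies cheap, `build_null()` evaluates
simulated curves from a per-sample-size cubic-spline table of
$\log \mathrm{BF}_{10}$ as a function of $t$ (grid $|t| \le 5$, step
0.25), falling back to exact quadrature off-grid. The table agrees with
the exact path to about $10^{-6}$ relative — far below Monte Carlo
resolution — and is validated against it in the tests; `engine =
"exact"` disables it.

## The synthetic-cohort generator

`simulate_cohort()` emulates the study's statistical structure: the
two-bit XOR trial scheme with a seeded pseudo-random generator standing
in for the hardware randomness (statistically indistinguishable for
calibration purposes), the five-lab cohort layout
(1413/235/154/103/99, $N = 2004$) as consecutive blocks in a single
collection order, and an optional avoidance effect injected by biasing
the live bit so that the XOR identity and the fair pre-stored bit are
preserved while the outcome is Bernoulli($p$);
`p_negative_for_effect()` converts a target standardized effect to the
per-trial probability. What it deliberately does **not** model: which
picture is shown within a valence class (the analysis consumes counts
only), response times, masking timing, or timestamps (the analysis
needs only a total order); the true interleaving of labs over calendar
time is not recoverable from published information, so lab blocks are
laid out in the order given. Passing tests on these cohorts therefore
demonstrate correctness of the statistical machinery under the design's
idealised randomness — they cannot speak to hardware-generator physics
or operational irregularities in real data collection.

## Known limitations

* Per-lab analyses accept summary rows, so results computed from
  printed 2-decimal summaries inherit rounding at about ±0.04 on a
  per-lab Bayes factor.
* The simulated energy distribution is extremely heavy-tailed; its
  sample SD stabilises slowly in `n_sims` (tail excursions dominate),
  so mean-energy comparisons are made at Monte Carlo tolerances
  computed from the published dispersion.
* The package implements the one-sample design only; no Bayes factors
  for other designs, no meta-regression, and no inferential claims
  about mechanism — the anomaly module reports calibrated proportions,
  nothing more.
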