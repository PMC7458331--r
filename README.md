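# seqbf

Sequential Bayes factors for below-chance binary outcomes, with Monte
Carlo calibration of temporal-anomaly statistics.

## What problem this solves

In some experimental designs — notably high-powered multi-lab
replications of "retroactive avoidance" effects — every participant
completes a fixed number of binary trials (60 by default) whose outcome
is decided by the XOR of two random bits, and the hypothesis under test
is that participants' counts of aversive ("negative") outcomes fall
*below* chance. Under the null each count is Binomial(60, 0.5); the
alternative puts a Cauchy(0, *r*) prior on the standardized effect
δ = (μ − μ₀)/σ, truncated to the avoidance direction.

seqbf provides, for analysts of such designs:

* the one-sided **Bayes factor** for the one-sample *t* statistic
  against chance,
  BF₁₀ = ∫ f₍ν,δ√n₎(t) π(δ) dδ / f₍ν,0₎(t),
  with π a truncated-and-doubled Cauchy(0, *r*) (default *r* = 0.1),
  evaluated by validated Gauss–Legendre quadrature;
* the **sequential BF curve** (recomputed after every participant in
  collection order), with a symmetric optional-stopping rule at
  BF = 10 and prior-robustness sweeps over *r* ∈ {0.1, 0.707, 1, 1.414};
* **per-lab Bayes factors** from summary rows and a **random-effects
  meta-analysis** (pooled effect, τ², I², Cochran's Q);
* three **temporal-anomaly statistics** of a curve — maximum BF, curve
  energy Σ(BFₙ − 1), and the sum of one-sided FFT amplitudes — with
  **empirical p-values** calibrated against seeded Monte Carlo null
  simulations (inclusive ≥ convention), plus the joint max-BF/energy
  exceedance;
* a **synthetic-cohort generator** reproducing the two-bit XOR trial
  scheme, the five-lab 2,004-participant cohort structure, and optional
  avoidance effects of a chosen standardized size.

## Worked example

Per-lab Bayes factors and the meta-analysis from the published five-lab
summary table:

```r
library(seqbf)

lab_bayes_factors(replication_lab_table())
#>     label    n mean   sd bf10_reported      t  bf10  bf01
#> 1 Germany 1413 30.0 3.88          0.20  0.000 0.200 5.009
#> 2   Italy  235 30.1 4.10          0.31  0.449 0.311 3.212
#> 3  Russia  154 29.5 3.83          1.93 -1.652 1.965 0.509
#> 4  France  103 29.5 4.27          1.19 -1.141 1.179 0.848
#> 5  Sweden   99 30.2 3.80          0.40  0.524 0.401 2.491

meta_random_effects(replication_lab_table())
#> <seqbf_meta> 5 labs, REML estimator
#>   pooled d = 0.0099 (SE 0.0224), p = 0.658
#>   tau^2 = 4.9e-06, I^2 = 0.117%, Q(4) = 4.280, p_Q = 0.369
```

The recomputed per-lab Bayes factors match the published 2-decimal
values up to the rounding of the printed means and SDs, and the pooled
analysis shows essentially no between-lab heterogeneity. The overall
sample (n = 2004, M = 29.97, SD = 3.92) gives

```r
bf_from_summary(2004, 29.97, 3.92)
#> [1] 0.2261        # BF01 = 4.42: moderate evidence for the null

robustness_sweep(tibble::tibble(n = 2004, mean = 29.97, sd = 3.92))
#>   prior_scale   bf10  bf01
#> 1       0.1   0.226   4.42
#> 2       0.707 0.0339 29.5
#> 3       1     0.0240 41.7
#> 4       1.41  0.0169 59.0   # wide priors: strong evidence for H0
```

A full sequential analysis on a synthetic cohort with an injected
avoidance effect (standardized d = 0.2):

```r
cohort <- simulate_cohort(labs = c(Munich = 300, Padua = 150),
                          p_negative = p_negative_for_effect(0.2),
                          seed = 11)
curve <- sequential_bf(cohort)
curve
#> <seqbf_curve> 450 participants, Cauchy(0, 0.1), direction = less
#>   final BF10 = 725.5 (BF01 = 0.001378), max BF10 = 725.5 at n = 450

stopping_check(curve)
#>   decision    n_stop bf_at_stop
#> 1 stop_for_H1    186       10.2
```

With the injected effect, the evidence trajectory crosses the BF ≥ 10
stopping boundary after 186 participants. `autoplot(curve)` draws the
trajectory; `build_null()` + `anomaly_test(curve, null)` calibrate its
maximum, energy, and FFT amplitude sum against fair-bit simulations.

A thin command-line front end over the same functions lives at
`inst/cli/seqbf.R` (subcommands `simulate`, `seqbf`, `anomaly`, `meta`,
`run-all`).

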