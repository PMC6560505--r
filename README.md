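# mixvpc

Visual predictive checks (VPCs) that account for multimodal parameter
distributions in finite-mixture nonlinear mixed-effects pharmacokinetic
models — for pharmacometricians who use mixture models when a
clearance-splitting covariate (typically a genotype) is unobserved, and
who need diagnostics that do not average subpopulation-specific misfit
away.

## What it does

A two-component mixture NLME model gives each individual a latent
subpopulation with its own typical value of the bimodal parameter (e.g.
clearance), mixed with probability `P_mix`. From the per-component
individual objective function values (`IOFV`, the −2 log marginal
likelihood of an individual under component *k*, Laplace-approximated),
the individual posterior membership probability is

    IP_mix,k = P_mix,k · exp(−IOFV_k / 2) / Σ_j P_mix,j · exp(−IOFV_j / 2)

and `MIXEST = argmax_k IP_mix,k` is the most likely subpopulation.
`mixvpc` implements the full chain as a self-contained replacement for the
NONMEM/PsN workflow:

* **Simulation** of mixture-population PK data (one-compartment oral;
  two-compartment with parallel linear + Michaelis–Menten elimination,
  weight-scaled), with preset scenarios (`linear-70-30`, `linear-85-15`,
  `parallel-40-60`) and arbitrary designs.
* **Estimation** of mixture, non-mixture and binary-covariate model
  variants by Laplace-approximated maximum likelihood (adaptive
  Gauss–Hermite as a verification mode), with phm-like per-individual
  output tables (ID, SUBPOP, IOFV, IL, IPmix, MIXEST).
* **Allocation** of observed and simulated individuals to subpopulations
  by the deterministic `MIXEST` rule or by a randomized draw from
  `IP_mix` (unbiased; `MIXEST` shrinks toward the dominant group), with
  PMIX/ORIGID/SIMID summaries and the allocation bias in percentage
  points.
* **VPCs**: traditional single-panel checks and mixture-specific
  per-subpopulation panels (binning, observed percentiles,
  simulation-based confidence bands across R replicates, outside-band
  flags), plus an `IP_mix` separation histogram.

Everything is tibble-in/tibble-out with `tidy()`/`glance()` accessors and
`autoplot()` methods; a thin command-line front-end lives in
`inst/cli/mixvpc`.

## Worked example

Simulate a reduced 70/30 mixture population (fourfold clearance
difference, 100 subjects), fit the two-component mixture, and build
MIXEST-stratified VPCs:

```r
library(mixvpc)

spec <- scenario_preset("linear-70-30", n_subjects = 100)
sim  <- simulate_dataset(spec, seed = 42)
fit  <- fit_mixture(sim$dataset, model_spec("onecmt_oral", "mixture"),
                    likelihood_settings(n_starts = 2), seed = 1)
tidy(fit)
#> # A tibble: 10 × 3
#>    term       component estimate
#>  1 CL                 1  19.6
#>  2 CL                 2  86.3
#>  3 ka                NA   1.06
#>  4 V                 NA 103.
#>  5 pmix               1   0.642
#>  6 pmix               2   0.358
#>  7 omega.ka          NA   0.0182
#>  8 omega.CL          NA   0.0762
#>  9 omega.V           NA   0.113
#> 10 sigma.prop        NA   0.0398
```

The true clearances 20/80 L/h are recovered (19.6/86.3) and the dominant
mixing proportion is estimated at 64.2% (truth 70%; at n = 100 the
binomial standard error alone is ~4.6%).

```r
vpc <- mixture_vpc(sim$dataset, fit,
                   vpc_config(n_replicates = 100, strategy = "mixest", seed = 7))
vpc$allocation
#> <allocation_summary> strategy: mixest  bias: +1.78 pp (dominant component 1)
#>   component pmix_pct origid_pct simid_pct
#> 1         1     64.2         66      64.1
#> 2         2     35.8         34      35.9
autoplot(vpc)   # one panel per subpopulation with PMIX/ORIGID/SIMID labels
```

`ORIGID` (66%) exceeds `PMIX` (64.2%) by +1.8 percentage points: the
deterministic MIXEST rule over-allocates the dominant subpopulation, the
shrinkage phenomenon the randomized `IP_mix` strategy avoids. `glance(vpc)`
counts the (bin × percentile) cells whose observed percentile falls
outside its 95% simulation band — here 0/18 in the dominant panel and 4/18
in the minority panel, whose ~34 subjects make for noisy small-sample
percentiles.

`separation_histogram(fit$records)` summarizes how decisively individuals
are classified (separation index 1.0 here: every subject has a posterior
membership probability ≥ 0.8 for one component — a clearly separated
mixture).

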