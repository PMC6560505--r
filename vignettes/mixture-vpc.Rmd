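---
title: "Mixture-model visual predictive checks: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture-model visual predictive checks: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Population pharmacokinetic (PK) analyses usually assume that
interindividual variability (IIV) around a typical parameter value is
unimodal. When the population is heterogeneous — a genetic polymorphism in
a clearance pathway is the classic case — a parameter such as clearance is
bimodally distributed, and if the covariate that explains the split is
unavailable, a finite-mixture nonlinear mixed-effects (NLME) model is the
standard remedy: each individual belongs to one of K latent subpopulations,
each with its own typical value, mixed with estimated proportions.

The visual predictive check (VPC) — comparing percentiles of the observed
data against simulation-based confidence bands of the same percentiles —
is the workhorse simulation diagnostic for NLME models, but a conventional
VPC pools all individuals and can therefore hide subpopulation-specific
misfit: over-prediction in one subpopulation can cancel under-prediction
in the other. `mixvpc` implements VPCs that account for multimodal
parameter distributions by allocating individuals (observed and simulated)
to subpopulations and drawing one VPC panel per subpopulation, annotated
with allocation statistics.

## Models

Two structural models are built in.

**One-compartment, first-order absorption and elimination** (closed form):
\[
C(t) = \sum_{d} \frac{D_d\, k_a}{V\,(k_a - k_e)}
\left( e^{-k_e (t - t_d)} - e^{-k_a (t - t_d)} \right),
\qquad k_e = CL/V ,
\]
with the limit form \(D k_a (t-t_d) e^{-k_a(t-t_d)}/V\) used when
\(|k_a-k_e| < 10^{-8} k_a\) to avoid catastrophic cancellation.

**Two-compartment disposition with parallel linear and Michaelis–Menten
elimination** (IV bolus dosing):
\[
\frac{dA_1}{dt} = -\frac{CL_{lin}}{V_1} A_1 - \frac{V_{max} C}{K_m + C}
- \frac{Q}{V_1} A_1 + \frac{Q}{V_2} A_2, \qquad
\frac{dA_2}{dt} = \frac{Q}{V_1} A_1 - \frac{Q}{V_2} A_2,
\qquad C = A_1 / V_1 .
\]
The disposition parameters \(CL_{lin}, V_{max}, V_1, V_2\) are scaled
linearly with body weight relative to 70 kg. Linear (rather than
allometric) scaling of exactly these four parameters keeps the scenario
minimal in the absence of established exponents for this example; the
route is an IV bolus into the central compartment, consistent with a
parameterization that includes no absorption constant.

Interindividual variability is lognormal, \(\theta_i = \theta\, e^{\eta_i}\)
with \(\eta_i \sim N(0, \omega^2)\), independent across parameters
(diagonal \(\Omega\)). Residual error is proportional
(\(y = f (1 + \sqrt{\sigma^2_p}\epsilon)\)), additive, or combined.

In a K = 2 mixture, one designated parameter (CL or \(CL_{lin}\)) has
typical values \(\theta_1, \theta_2\) by subpopulation, with mixing
probability \(P_{mix1} = \theta_3\), \(P_{mix2} = 1 - \theta_3\). The
covariate model variant instead multiplies the parameter by an estimated
fold-change raised to a binary covariate; the non-mixture variant collapses
to a single component.

## Individual likelihoods, IP_mix and MIXEST

For subject \(i\) and component \(k\), the individual objective function
value is the per-component marginal likelihood on the \(-2\log\) scale,

\[
IOFV_{ik} = -2 \log \int p(y_i \mid \eta, \theta_k)\, p(\eta; \Omega)\, d\eta ,
\]

approximated by the Laplace method at the conditional mode of \(\eta\)
(adaptive Gauss–Hermite quadrature is available for one random effect as a
verification mode). Following the usual NLME reporting convention the
additive \(N_{obs}\log 2\pi\) constant is excluded, so only OFV
*differences* are meaningful; any constant shared across components cancels
exactly in the posterior.

The individual posterior probability of membership combines the relative
individual likelihood with the population mixing proportions:

\[
IP_{mix,k} = \frac{P_{mix,k}\; e^{-IOFV_k/2}}
{\sum_j P_{mix,j}\; e^{-IOFV_j/2}},
\]

evaluated by log-sum-exp. Note the sign: \(IOFV\) is \(-2\log L\), so the
relative likelihood is \(e^{-IOFV/2}\) — a smaller IOFV (better fit) must
give a larger probability. The formula is sometimes printed with a positive
exponent; that convention would rank worse-fitting components higher and is
deliberately not followed here. `MIXEST` is the posterior argmax (ties go
to the lowest component index), equivalently the argmin of
\(IOFV_k - 2\log P_{mix,k}\).

Because individual data are finite, `MIXEST` is a shrinkage-prone
classifier: uninformative individuals are pulled toward the dominant
subpopulation. The *randomized* allocation instead draws each individual's
subpopulation from its \(IP_{mix}\) vector, which is unbiased for the mean
posterior by construction.

## Estimation

`fit_mixture()` maximizes \(\sum_i \log \sum_k P_{mix,k} e^{-IOFV_{ik}/2}\)
over transformed parameters — log for typical values and variances, logit
for the mixing proportion — with `nlminb`, using an explicit
central-difference gradient (relative step \(10^{-5}\)). The inner
per-subject mode search is a damped Newton iteration with
finite-difference derivatives, preceded by a coarse coordinate scan over
\(\eta \in [-3, 3]\) so that badly mispredicting components (enormous
residuals, far-off modes) still converge to the right basin; per-subject
modes are warm-started across outer iterations, and the inner tolerances
are tight enough (\(\Delta h < 10^{-12}(|h|+1)\)) that the outer objective
is smooth to \(\sim 10^{-6}\), which finite-difference gradients require.
The Laplace correction is \(\log\det(\nabla^2 h/2)\) at the mode; if
finite-difference noise breaks positive definiteness the prior curvature
\(\Omega^{-1}\) is substituted.

Multiple optimizer starts stagger the two component typical values around
the pooled one-component estimate (0.5×/2×, then 1/3×/3×, 2/3×/1.5×, ...),
all with mixing proportion started at 0.5; for the one-compartment model
the pooled estimate itself is seeded by a moment heuristic (clearance from
dose/AUC of the median profile, terminal-slope elimination rate, ka fixed
at 1/h). After fitting, components are relabelled so that component 1
carries the smaller typical value; a mixing proportion within \(10^{-6}\)
of the boundary raises a degenerate-fit warning. The number of components
is 2 throughout — the data structures are K-ary, but fitting more than two
components is untested.

The inner Laplace step for both structural models is implemented in C (the
one-compartment prediction in closed form; the two-compartment system with
an adaptive Dormand–Prince RK45 integrator with bolus events, rtol
\(10^{-8}\), atol \(10^{-10}\)); the plain-R path (deSolve/lsoda, `nlminb`)
remains as the reference implementation and the two are required to agree
in the test suite. Simulation of datasets uses the R path throughout.

`evaluate_mixture()` recomputes IOFV, \(IP_{mix}\) and MIXEST for every
subject at *fixed* parameters — the analog of an estimation run with zero
updating iterations — which is how every simulated replicate is processed
during a mixture VPC.

## Mixture VPCs

`mixture_vpc()` runs the pipeline: (1) simulate R replicate datasets from
the fitted parameters over the original design, redrawing subpopulation
membership per subject per replicate; (2) evaluate the model at the fitted
parameters on the original data and on every replicate; (3) allocate
observed individuals once per run and every replicate independently, by
MIXEST or by randomized \(IP_{mix}\) draw; (4) per subpopulation, bin the
allocated observations by time and compare observed percentiles against
the empirical confidence band of the same percentile across replicates;
(5) annotate each panel with PMIX (estimated mixing percentage), ORIGID
(percent of original individuals allocated) and SIMID (mean percent of
simulated individuals allocated across replicates). The allocation bias
reported alongside is ORIGID − PMIX for the dominant component; it is
measured against the *estimated* PMIX because that is the quantity
displayed on the same plot and the only baseline available for real data
(the bias against the true proportions is attached as well when the truth
is known). A discrepancy between ORIGID/SIMID and PMIX, or an excess of
observed percentiles outside their bands within a subpopulation panel,
flags misspecification that a pooled VPC can average away.

Defaults: percentiles 5/50/95, 95% confidence bands, R = 200 replicates,
binning on the nominal design times (all built-in designs are fixed-time;
equal-count quantile binning is available for irregular data). These are
conventional VPC settings — the method itself does not prescribe them —
and all are exposed in `vpc_config()`. The randomized strategy uses one
dedicated seed stream per VPC run, split into observed-data and
per-replicate substreams, so increasing R never perturbs the observed-data
allocation. `separation_histogram()` summarizes the \(IP_{mix,1}\)
distribution in 20 bins with a separation index (share of individuals with
maximal posterior probability at least 0.8): mass near 0.5 identifies the
uninformative individuals that make MIXEST allocation biased.

## The synthetic-data generator

`scenario_preset()` defines three study conditions:

| scenario | model | n | mixture | proportions |
|---|---|---|---|---|
| `linear-70-30` | 1-cmt oral, 100 mg, 6 samples in 12 h | 1000 | CL 20/80 L/h | 70/30 |
| `linear-85-15` | as above | 1000 | CL 20/60 L/h | 85/15 |
| `parallel-40-60` | 2-cmt parallel elimination, 4×50 mg, 22 samples in 672 h | 36 | CL_lin 0.03/0.12 L/h | 40/60 |

Shared one-compartment values: ka = 1 h⁻¹, V = 100 L, IIV variance 0.09,
proportional residual variance 0.04. The single IIV variance (0.09) is
placed on all three structural parameters (ka, CL, V); which parameters
carry random effects is configurable. For the parallel scenario
(Vmax = 1.2 mg/h, Km = 10 mg/L, V1 = 3 L, V2 = 2 L, Q = 0.075 L/h) the
IIV magnitudes, body-weight distribution and exact sampling schedule are
package choices: variance 0.09 on CL_lin, Vmax and V1, lognormal body
weights with median 70 kg and 20% CV (a realistic adult range), and 22
sampling times placed densely after the first and last dose with troughs
between. Each component shares the same \(\Omega\)
and \(\sigma\); membership is per-subject and constant within a subject.
Subjects carry a binary covariate `COV` equal to their true subpopulation,
which is what the covariate model variant uses.

The generator emulates lognormal IIV, Bernoulli membership, and
proportional/additive residual error on fixed designs. It does not emulate
dropout or missingness, time-varying covariates, dose adaptation,
irregular sampling, or model misspecification beyond what a scenario
encodes — so passing recovery and calibration tests demonstrates internal
consistency under the stated conditions, not robustness to the messiness
of real clinical data.

## Numerical and testing choices

* Parameter-recovery and allocation checks in the test suite run the
  linear scenarios at n = 250 subjects and the acceptance script at the
  full n = 1000; the parallel scenario is always n = 36. The reduced size
  widens the admissible interval for the estimated mixing proportion
  accordingly (binomial SE alone is ~2.9% at n = 250).
* In the parallel-scenario fit the shared structural parameters (Vmax, Km,
  V1, V2, Q) and the IIV variances of Vmax and V1 are held at their known
  values, estimating the two clearances, the mixing proportion, the
  clearance IIV and the residual variance. With 36 subjects this mirrors
  the usual practice of fixing literature disposition values and keeps the
  mixture parameters identifiable.
* Laplace accuracy: on single-observation toy problems the Laplace IOFV is
  within ~0.02 of brute-force integration; with several observations per
  subject the error per subject can reach ~0.05 when an observation sits
  far in the residual tail. Exact-integration comparisons in the tests
  therefore either use the adaptive-quadrature mode or toys within the
  approximation's validity range.
* VPC coverage: with R = 200 replicates and 95% bands, roughly 5% of
  (bin × percentile) cells are expected outside by chance; the calibration
  tests allow 10% to absorb binomial noise over ~18 cells.
* All randomness is seed-driven; substream seeds are derived with a
  Lehmer-style mix kept below 2³¹.

## Limitations

* Only EVID 0/1 NONMEM-style records are supported (no reset events,
  infusions, or time-varying covariates); times are absolute hours.
* Exact numerical equivalence with NONMEM's FOCE-I is not a goal; OFV
  differences, posteriors and allocation statistics are the comparison
  currency.
* Standard errors are not reported; uncertainty assessment would require
  an observed-information or resampling step that is out of scope.
* Prediction-corrected and covariate-stratified VPCs are not implemented.
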