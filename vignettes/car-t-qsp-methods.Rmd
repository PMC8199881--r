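---
title: "Population QSP modeling of CD19 CAR-T cell kinetics: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population QSP modeling of CD19 CAR-T cell kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartqsp)
```

## The model

`cartqsp` implements a population quantitative systems pharmacology (QSP)
model of CD19-specific CAR-T cell therapy in non-Hodgkin lymphoma. Five
species evolve jointly after infusion at day 0: four CAR-T cell phenotypes
— naive (T~N~), central memory (T~CM~), effector memory (T~EM~), and
terminally differentiated effector (T~Eff~) cells, in cells·µL⁻¹ — and the
CD19⁺ metabolic tumor volume (MTV, in mL), which both drives T-cell
expansion and is depleted by it.

The structural equations are:

* T~N~, T~CM~ and T~EM~ expand upon tumor contact through a shared
  Michaelis–Menten term $V_{max1}\cdot CD19^+ \cdot T/(K_{M1}+T)$ — note
  the *T-cell concentration* in the denominator, so at high cell counts
  expansion is proportional to tumor burden. Each phenotype also
  proliferates homeostatically ($k_{p1..3}$), differentiates progressively
  (T~N~ → T~CM~ → T~EM~ → T~Eff~ via $k_{12}, k_{23}, k_{34}$), and dies
  ($k_{e1..4}$).
* T~Eff~ cells neither expand nor proliferate: they receive inflow
  $k_{34} T_{EM}$ and die at the fast rate $k_{e4}$.
* Tumor volume grows logistically ($k_5$, capacity $K_0$) and is killed by
  all four phenotypes through saturable terms
  $V_{max5,x}\cdot T_x \cdot CD19^+/(K_{M5}+CD19^+)$.

Units are deliberately left mixed (µL for the cell distribution space, mL
for tumor volume): resolving them would obscure the physical origin of
each parameter, so `Vmax1` carries (cells·µL⁻¹)·day⁻¹·mL⁻¹ and `Vmax5,x`
carries mL·day⁻¹·(cells·µL⁻¹)⁻¹.

The alternative expansion form with tumor volume in the denominator, which
other immunotherapy models use, is available via
`qsp_params(expansion_denominator = "tumor")`. It is exposed as a switch
only; the T-cell-denominator form is the default because it produces the
characteristic rapid expansion followed by a sharp collapse.

## Population layers

Three layers sit on top of the structural model:

* **Interindividual variability (IIV)** is exponential,
  $\theta_i = \theta\, e^{\eta_i}$ with $\eta_i \sim N(0, \omega^2)$, and is
  supported on exactly two parameters: the baseline expansion rate
  `Vmax1_base_ref` (150% CV) and the central-memory killing rate `Vmax5_2`
  (307% CV). Variances are reported as coefficients of variation through
  the log-normal relation $CV\% = \sqrt{e^{\omega^2}-1}\cdot 100$. (A
  commonly typeset variant of this formula omits the square root; the
  square-root form is the standard convention and is the one that makes a
  variance of $\ln 3.25$ correspond to 150% CV.)
* **A two-subpopulation mixture**: a fraction `MIXP` = 0.803 of patients
  belong to a reference-expansion population, the rest to a low-expansion
  subpopulation whose typical `Vmax1_base` is ~92% lower (0.000700 vs
  0.00846). IIV on the low subpopulation's expansion rate is negligible
  and not modeled.
* **Covariates**: a previous autologous stem cell transplantation (ASCT)
  multiplies `Vmax1_base` by $(1 + 2.53) = 3.53$ in both subpopulations
  (fractional-change model); the day-7 CD4⁺/CD8⁺ CAR-T ratio enters the
  reference subpopulation only, as a power function with exponent −0.385.
  A missing ratio is imputed to the covariate-neutral value 1.

Residual error is log-transform-both-sides: $\ln Y^{obs} = \ln f + \varepsilon$
with species-specific variances (59.1–120% CV). Tumor scans recorded as
0 mL (complete response) cannot enter a log-scale residual; they are
treated as **left-censored** at a configurable limit of quantification
(default 0.1 mL), contributing a normal log-CDF term. Excluding them
instead is possible by filtering the observation table, but censoring is
the default because discarding complete responses would bias the killing
parameters downward.

## Initial conditions and dose

No infusion-product concentrations are observable post hoc, and the
distribution phase immediately after infusion carries little information
about expansion. The model therefore starts each phenotype at an imputed
0.1 cells·µL⁻¹ at day 0 and the tumor at the baseline MTV. A ten-fold
change in the imputed dose moves the time of maximum concentration
earlier but changes the maximum itself by well under 20% (this is asserted
in the test suite), so the imputation is not load-bearing for the
endpoints built on C~max~.

## Numerical choices

* **Solver**: `lsoda` on a compiled right-hand side, rtol 1e−8,
  atol 1e−10. The expansion/collapse phase is stiff (expansion rates of
  order $V_{max1}\cdot MTV \approx 30$ day⁻¹ at large tumor burdens).
  Rate terms clamp their state arguments at zero so transient solver
  undershoot cannot feed back; reported trajectories clip excursions above
  −1e−9 to zero and treat anything larger as an integration failure.
* **Laplace instead of FOCE-I**: the original analysis used first-order
  conditional estimation with interaction. This package marginalizes each
  patient's one- or two-dimensional η by a Laplace approximation at the
  empirical Bayes mode — functionally comparable at this data richness,
  far simpler to implement and verify (the test suite checks it against
  direct numerical quadrature to within 1% on a toy patient). Numeric OFV
  equality with any specific NONMEM configuration is not claimed.
* **Outer optimization**: positives are estimated on the log scale and the
  mixture proportion on the logit scale, so `nlminb` runs unconstrained.
  The objective carries ~1e−8 noise from the inner η optimization, which
  breaks the solver's default tiny finite-difference steps; an explicit
  central-difference gradient with step 1e−4 dominates that noise. A
  "false convergence" return at a numerically flat gradient is accepted as
  converged. Multi-start (`n_starts`) from jittered, seeded initial values
  is available; the default is a single start because the mixture OFV
  surface over the small free-parameter sets used here has shown no
  multimodality, and each extra start multiplies the cost.
* **Warm starts**: per-patient η modes are cached between outer
  iterations, which is what keeps an n = 100 fit in the minutes range on
  one CPU.
* **Likelihood-ratio testing** uses chi-square quantiles (ΔOFV > 3.84 at
  one degree of freedom, α = 0.05), with degrees of freedom counted as
  the number of freed parameters.
* **SIR uncertainty**: proposal covariance from the numerical Hessian at
  the optimum; the default schedule is five iterations of
  1000/1000/1000/2000/2000 samples and 200/400/500/1000/1000 resamples,
  scalable down proportionally when speed matters more than tail accuracy.

## The synthetic cohort

No patient-level data from the original study are public, so the package
generates virtual cohorts with the study's statistical structure:

* sampling design: cells at days 7, 14 and 26 (the day 25–28 window
  collapsed to its midpoint; ±1.5-day jitter optional), tumor scans at
  days 0, 30 and 90 (months converted at 30 days/month);
* covariates: baseline MTV log-normal with median 100 mL and log-sd 1.5,
  truncated to 2.5–3600 mL — chosen to span the observed clinical range
  (2.54–3555 mL) with a median between the reference (64 mL) and
  low-expansion (712 mL) group medians; ASCT prevalence 0.37 (7 of 19
  patients); day-7 CD4/CD8 ratio log-normal around 1. Covariates are
  drawn independently of each other and of the subpopulation label, since
  their joint distribution is unreported;
* the full generative chain (mixture draw → IIV → covariates → ODE →
  log-normal residual → LOQ censoring) retains its hidden truth for
  recovery testing;
* survival is *not* part of the original model; `simulate_survival()` is a
  test harness linking an exponential hazard to the subpopulation label
  (default hazard ratio 4 for the low expanders, administrative censoring
  at 24 months) so the endpoint chain can be exercised end to end.

The default cohort size is 19, mirroring the clinical dataset; recovery
and power tests use n = 100–200 because 19 patients cannot identify the
mixture and variance structure. What passing tests show is therefore
*self-consistency*: the pipeline recovers the parameters of data generated
by its own model. They do not show that real CAR-T data follow these
dynamics, that covariates are independent in reality, or that the residual
model is correctly specified — those claims need clinical data.

## Endpoints

`kinetic_metrics()` computes C~max~, T~max~ (earliest argmax) and the
trapezoid AUC over days 0–28 of the summed CAR-T concentration. Observed
sparse series lack a day-0 sample; the curve is anchored at the summed
imputed dose (0.4 cells·µL⁻¹) because no interpolation scheme for the
observed AUC is stated anywhere — this choice affects AUC only modestly
since the anchor is tiny relative to typical maxima.

The clinical composite score is `CCS = Cmax / baseline MTV`, computed per
phenotype; the naive-cell score CCS~TN~ is the proposed survival
predictor (published cut-off 0.00136 (cells·µL⁻¹)·mL⁻¹; that specific
value is *not* recalibrated here since it requires the clinical data).
`roc_cutoff()` selects an optimal cut-off by the Youden index — the
standard default; the original criterion is unstated — breaking ties
toward higher specificity. Survival stratification uses the product-limit
estimator, log-rank tests and univariate Cox models (Breslow ties, Wald
intervals, Schoenfeld diagnostic) from the survival package; a median
never reached is reported as the explicit sentinel `"not reached"`.

Whether an observed C~max~ should be the maximum over the three sampled
days only is implied but unstated; this package assumes yes (the maximum
over whatever rows the observation table contains).

## A worked chain

```{r, eval = FALSE}
library(cartqsp)
coh <- generate_cohort(200, seed = 314159)
met <- cohort_metrics(coh)
score <- ccs(met$cmax_TN, met$baseline_mtv)$score
is_low <- coh$truth$subpop[match(met$patient_id,
                                 coh$truth$patient_id)] == "low"
roc <- roc_cutoff(score, is_low)
surv <- simulate_survival(coh, seed = 271828)
cox_hr(data.frame(time = surv$time_months, event = surv$event),
       score > roc$cutoff)
```

The package's test suite runs this chain and asserts AUC > 0.8 and a
hazard ratio below 1 for patients above the cut-off — the qualitative
chain from expansion capacity to composite score to survival, without
claiming the clinical study's numeric values.

## Known limitations

* Pre-infusion kinetics (apheresis, manufacturing, lymphodepletion
  effects on tumor) are out of scope, as is any cytokine or qPCR assay
  model; qPCR-scale composite scores are supported only as an
  alternative-unit input.
* The killing-rate ratios of phenotypes 1/3/4 to phenotype 2
  (2.57 : 4.04 : 3.78 : 4.24) are fixed; individual variability on
  killing scales all four jointly.
* No correlated random effects, no automatic covariate search, no
  multivariable Cox models.
* Recovery tolerances (±30% on expansion rates, ±0.12 on the mixture
  proportion at n = 100) reflect what a single synthetic cohort of that
  size supports; they are not statements about estimator bias.
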