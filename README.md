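# cartqsp

Population quantitative systems pharmacology (QSP) modeling of CD19-specific
CAR-T cell therapy in non-Hodgkin lymphoma: simulation, nonlinear
mixed-effects estimation, and survival-endpoint analysis, with a
virtual-patient cohort generator in place of the (non-public) clinical data.

## The problem and who this is for

After CAR-T infusion, a patient's naive (T_N), central memory (T_CM),
effector memory (T_EM) and terminally differentiated effector (T_Eff)
CAR-T cells expand on contact with CD19+ tumor, differentiate
progressively, and kill the tumor; a substantial minority of patients show
almost no expansion and have poor prognosis. This package is for
pharmacometricians and quantitative clinical researchers who want to
simulate that system, fit its population model to long-format concentration
data, and evaluate early survival predictors built on it.

The structural model couples five ODEs (concentrations in cells·µL⁻¹,
tumor volume in mL, time in days):

    dT_N/dt   = Vmax1·CD19·T_N/(KM1+T_N)   + kp1·T_N  − k12·T_N  − ke1·T_N
    dT_CM/dt  = Vmax1·CD19·T_CM/(KM1+T_CM) + kp2·T_CM + k12·T_N  − k23·T_CM − ke2·T_CM
    dT_EM/dt  = Vmax1·CD19·T_EM/(KM1+T_EM) + kp3·T_EM + k23·T_CM − k34·T_EM − ke3·T_EM
    dT_Eff/dt = k34·T_EM − ke4·T_Eff
    dCD19/dt  = k5·(1 − CD19/K0)·CD19 − Σx Vmax5,x·T_x·CD19/(KM5+CD19)

On top sit exponential inter-individual variability
(θ_i = θ·e^η, η ~ N(0, ω²)), a two-subpopulation mixture (a
low-expansion subpopulation with a ~92% lower typical expansion rate,
mixture proportion MIXP = 0.803), covariate effects (previous ASCT:
×3.53; day-7 CD4/CD8 CAR-T ratio: power −0.385), and log-normal residual
error per species with left-censoring for complete-response tumor scans.
Estimation maximizes the mixture-weighted marginal likelihood with a
per-patient Laplace approximation; uncertainty comes from sampling
importance resampling. Endpoints include Cmax/Tmax/AUC(0–28d), the
clinical composite score CCS = Cmax / baseline metabolic tumor volume,
ROC-based cut-off selection (Youden index), Kaplan–Meier/log-rank, and
univariate Cox hazard ratios.

See `vignettes/car-t-qsp-methods.Rmd` for the full account of the model,
its assumptions, and the design decisions.

## Worked example

Simulate a typical reference patient with a 100 mL baseline tumor, then a
virtual cohort, and run the composite-score chain:

```r
library(cartqsp)

p <- qsp_params()                      # published typical values
traj <- simulate_patient(make_individual(baseline_mtv = 100), p,
                         t_end = 90, grid_step = 0.1)
total <- data.frame(time_days = traj$time_days,
                    conc = rowSums(traj[, c("TN", "TCM", "TEM", "TEFF")]))
kinetic_metrics(total, basis = "model", baseline_mtv = 100)
#> # A tibble: 1 × 5
#>    cmax  tmax auc_0_28 cmax_over_mtv basis
#>   <dbl> <dbl>    <dbl>         <dbl> <chr>
#> 1  8.57  15.1     165.        0.0857 model
```

The typical patient reaches a maximum of ~8.6 CAR-T cells·µL⁻¹ about two
weeks after infusion, with an exposure of ~165 cells·µL⁻¹·day over the
first 28 days.

```r
coh <- generate_cohort(200, seed = 314159)     # virtual cohort, truth retained
met <- cohort_metrics(coh)                     # observed-basis kinetic metrics
score <- ccs(met$cmax_TN, met$baseline_mtv)$score
is_low <- coh$truth$subpop[match(met$patient_id,
                                 coh$truth$patient_id)] == "low"
roc_cutoff(score, is_low)
#> ROC: AUC 0.916; youden cut-off 0.0038514 (direction <): sens 0.816, spec 0.883
```

The naive-cell composite score separates the low-expansion subpopulation
(ROC AUC ~0.92 on this seed); patients above the Youden cut-off have a
hazard ratio well below 1 (0.44, 95% CI 0.32–0.63 on this seed) when
survival is linked to the subpopulation:

```r
surv <- simulate_survival(coh, seed = 271828)
cox_hr(data.frame(time = surv$time_months, event = surv$event),
       score > roc_cutoff(score, is_low)$cutoff)
```

Fitting the population model to a cohort recovers the mixture structure
(`fit_population()` frees the two expansion rates and the mixture
proportion by default) and `tidy()`/`glance()` summarize the result.

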