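#' Michaelis-Menten expansion term
#'
#' Rate at which a CAR-T cell phenotype expands upon tumor contact:
#' `Vmax1 * CD19 * T / (KM1 + T)`. Expansion is proportional to tumor
#' volume and saturates in the phenotype's own concentration, with
#' half-maximum at `T = KM1` and upper bound `Vmax1 * CD19`.
#'
#' @param Vmax1 maximum expansion rate per mL tumor volume
#'   ((cells/uL)/day/mL).
#' @param CD19 metabolic tumor volume (mL).
#' @param T_cells phenotype concentration (cells/uL).
#' @param KM1 concentration at half-maximum expansion (cells/uL).
#' @return expansion rate (cells/uL/day); vectorized.
#' @export
#' @examples
#' expansion_term(0.00846, CD19 = 100, T_cells = 1, KM1 = 1.13)
expansion_term <- function(Vmax1, CD19, T_cells, KM1) {
  stopifnot(all(Vmax1 >= 0), all(CD19 >= 0), all(T_cells >= 0), all(KM1 > 0))
  Vmax1 * CD19 * T_cells / (KM1 + T_cells)
}

#' Saturable tumor-killing term
#'
#' Tumor volume killed per day by one CAR-T phenotype:
#' `Vmax5x * T * CD19 / (KM5 + CD19)`, half-maximal at `CD19 = KM5`.
#'
#' @param Vmax5x maximum killing rate (mL/day/(cells/uL)).
#' @param T_cells phenotype concentration (cells/uL).
#' @param CD19 metabolic tumor volume (mL).
#' @param KM5 tumor volume at half-maximum killing (mL).
#' @return killing rate (mL/day); vectorized.
#' @export
killing_term <- function(Vmax5x, T_cells, CD19, KM5) {
  stopifnot(all(Vmax5x >= 0), all(T_cells >= 0), all(CD19 >= 0), all(KM5 > 0))
  Vmax5x * T_cells * CD19 / (KM5 + CD19)
}

#' Time-derivatives of the five-species system
#'
#' Pure-R right-hand side of the model: naive (T_N), central memory (T_CM)
#' and effector memory (T_EM) CAR-T cells each expand upon tumor contact
#' (shared `Vmax1`, `KM1`), proliferate homeostatically (`kp1..kp3`),
#' differentiate progressively (T_N -> T_CM -> T_EM -> T_Eff via
#' `k12, k23, k34`) and die (`ke1..ke4`); terminally differentiated
#' effectors (T_Eff) only receive inflow and die; CD19+ tumor volume grows
#' logistically (`k5`, `K0`) and is killed by all four phenotypes.
#'
#' Fitting and simulation use an equivalent compiled implementation; this
#' function is the reference form and is cross-checked against it.
#'
#' @param state numeric length-5: `TN, TCM, TEM, TEFF` (cells/uL),
#'   `CD19` (mL); all finite and non-negative.
#' @param params a [qsp_params()] object.
#' @param Vmax1_i,Vmax5_2_i optional individual values overriding the
#'   typical `Vmax1_base_ref` and `Vmax5_2` (killing rates of the other
#'   phenotypes are rescaled to preserve their fixed ratios to `Vmax5_2`).
#' @return numeric length-5 of time-derivatives.
#' @export
#' @examples
#' ode_rhs(c(1, 0, 0, 0, 100), qsp_params())
ode_rhs <- function(state, params, Vmax1_i = NULL, Vmax5_2_i = NULL) {
  if (length(state) != 5 || any(!is.finite(state)))
    abort("state must be 5 finite values")
  if (any(state < 0)) abort("state entries must be >= 0")
  p <- params
  vmax1 <- Vmax1_i %||% p$Vmax1_base_ref
  v52 <- Vmax5_2_i %||% p$Vmax5_2
  v5 <- c(p$Vmax5_1, p$Vmax5_2, p$Vmax5_3, p$Vmax5_4) / p$Vmax5_2 * v52
  tc <- state[1:4]; cd <- state[5]
  expand <- if (identical(p$expansion_denominator, "tumor")) {
    vmax1 * cd * tc[1:3] / (p$KM1 + cd)
  } else {
    expansion_term(vmax1, cd, tc[1:3], p$KM1)
  }
  kill <- sum(killing_term(v5, tc, cd, p$KM5))
  c(expand[1] + p$kp1 * tc[1] - p$k12 * tc[1] - p$ke1 * tc[1],
    expand[2] + p$kp2 * tc[2] + p$k12 * tc[1] - p$k23 * tc[2] - p$ke2 * tc[2],
    expand[3] + p$kp3 * tc[3] + p$k23 * tc[2] - p$k34 * tc[3] - p$ke3 * tc[3],
    p$k34 * tc[3] - p$ke4 * tc[4],
    p$k5 * (1 - cd / p$K0) * cd - kill)
}

# parms vector for the compiled rhs; order must match src/qsp_ode.c
.qsp_c_parms <- function(params, Vmax1_i = NULL, Vmax5_2_i = NULL) {
  p <- params
  v52 <- Vmax5_2_i %||% p$Vmax5_2
  v5 <- c(p$Vmax5_1, p$Vmax5_2, p$Vmax5_3, p$Vmax5_4) / p$Vmax5_2 * v52
  c(Vmax1_i %||% p$Vmax1_base_ref, p$KM1, p$kp1, p$kp2, p$kp3,
    p$k12, p$k23, p$k34, p$ke1, p$ke2, p$ke3, p$ke4,
    v5, p$KM5, p$k5, p$K0,
    as.numeric(identical(p$expansion_denominator, "tumor")))
}

#' Construct an individual parameter record
#'
#' One patient's realized parameters: the individual expansion rate
#' `Vmax1_i` (after mixture, covariates and interindividual variability),
#' the individual central-memory killing rate `Vmax5_2_i` (other
#' phenotypes' killing rates keep their fixed ratios to it), baseline
#' metabolic tumor volume, and the imputed post-distribution dose of
#' 0.1 cells/uL per phenotype.
#'
#' @param patient_id identifier.
#' @param Vmax1_i individual expansion rate ((cells/uL)/day/mL).
#' @param baseline_mtv baseline metabolic tumor volume (mL), > 0.
#' @param Vmax5_2_i individual killing rate anchor (default typical value).
#' @param subpop `"reference"` or `"low"`.
#' @param dose_per_phenotype initial concentration per phenotype at day 0
#'   (cells/uL).
#' @param eta_Vmax1,eta_Vmax5_2 latent log-scale deviations (bookkeeping).
#' @param params a [qsp_params()] supplying defaults.
#' @return one-row tibble of class `qsp_individual`.
#' @export
make_individual <- function(patient_id = "pt1", Vmax1_i = NULL,
                            baseline_mtv = 100, Vmax5_2_i = NULL,
                            subpop = "reference", dose_per_phenotype = 0.1,
                            eta_Vmax1 = 0, eta_Vmax5_2 = 0,
                            params = qsp_params()) {
  Vmax1_i <- Vmax1_i %||% params$Vmax1_base_ref
  Vmax5_2_i <- Vmax5_2_i %||% params$Vmax5_2
  stopifnot(Vmax1_i >= 0, baseline_mtv > 0, dose_per_phenotype >= 0,
            subpop %in% c("reference", "low"))
  out <- tibble(patient_id = patient_id, subpop = subpop,
                Vmax1_i = Vmax1_i, Vmax5_2_i = Vmax5_2_i,
                eta_Vmax1 = eta_Vmax1, eta_Vmax5_2 = eta_Vmax5_2,
                baseline_mtv = baseline_mtv,
                dose_per_phenotype = dose_per_phenotype)
  class(out) <- c("qsp_individual", class(out))
  out
}

#' Simulate one patient's trajectory
#'
#' Integrates the five-species system from infusion (day 0) with initial
#' conditions `T_N = T_CM = T_EM = T_Eff = dose_per_phenotype` and
#' `CD19 = baseline_mtv`, using a stiff-capable solver (lsoda, relative
#' tolerance 1e-8, absolute 1e-10) on a compiled right-hand side: the rapid
#' expansion/collapse phase is stiff. Tiny negative solver excursions
#' (> -1e-9) are clipped to 0 in the reported states; anything more
#' negative is an error.
#'
#' @param individual a [make_individual()] row (or a one-row tibble with
#'   the same columns).
#' @param params a [qsp_params()] object.
#' @param t_end end of integration (days), > 0.
#' @param grid_step reporting grid step (days).
#' @param times optional explicit report times (days, must include or start
#'   after 0; 0 is always prepended), overriding the regular grid.
#' @return tibble of class `qsp_trajectory` with columns `patient_id`,
#'   `time_days`, `TN`, `TCM`, `TEM`, `TEFF`, `CD19`.
#' @export
#' @examples
#' traj <- simulate_patient(make_individual(baseline_mtv = 100), qsp_params(),
#'                          t_end = 28, grid_step = 1)
#' head(traj)
simulate_patient <- function(individual, params = qsp_params(),
                             t_end = 90, grid_step = 0.1, times = NULL) {
  if (is.null(times) && t_end <= 0) abort("t_end must be > 0")
  ind <- as.list(individual[1, ])
  tt <- if (is.null(times)) seq(0, t_end, by = grid_step) else sort(unique(c(0, times)))
  if (any(tt < 0)) abort("report times must be >= 0")
  y0 <- c(TN = ind$dose_per_phenotype, TCM = ind$dose_per_phenotype,
          TEM = ind$dose_per_phenotype, TEFF = ind$dose_per_phenotype,
          CD19 = ind$baseline_mtv)
  parms <- .qsp_c_parms(params, Vmax1_i = ind$Vmax1_i,
                        Vmax5_2_i = ind$Vmax5_2_i %||% NULL)
  sol <- try(deSolve::lsoda(y0, tt, func = "qsp_derivs", parms = parms,
                            dllname = "cartqsp", initfunc = "qsp_initmod",
                            rtol = 1e-8, atol = 1e-10, maxsteps = 50000),
             silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(tt)) {
    abort(paste0("ODE integration failed for patient ", ind$patient_id,
                 " (Vmax1_i = ", signif(ind$Vmax1_i, 4),
                 ", baseline_mtv = ", signif(ind$baseline_mtv, 4), "): ",
                 if (inherits(sol, "try-error")) attr(sol, "condition")$message
                 else "solver returned a truncated grid"))
  }
  states <- unclass(sol)[, -1, drop = FALSE]
  if (any(states < -1e-9))
    abort(paste0("solver produced substantially negative states (min ",
                 signif(min(states), 3), ") for patient ", ind$patient_id))
  states[states < 0] <- 0
  out <- as_tibble(states)
  out <- dplyr::bind_cols(tibble(patient_id = ind$patient_id,
                                 time_days = sol[, 1]), out)
  class(out) <- c("qsp_trajectory", class(out))
  out
}

#' Pivot a trajectory to tidy long format
#'
#' @param traj a `qsp_trajectory` (or any wide tibble with the species
#'   columns).
#' @return tibble with columns `patient_id`, `time_days`, `species`,
#'   `value` — the tidy export format.
#' @export
trajectory_long <- function(traj) {
  tidyr::pivot_longer(as_tibble(traj), cols = dplyr::all_of(.qsp_species),
                      names_to = "species", values_to = "value")
}

#' @export
autoplot.qsp_trajectory <- function(object, ...) {
  long <- trajectory_long(object)
  ggplot2::ggplot(long, ggplot2::aes(.data$time_days, .data$value,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~ .data$species, scales = "free_y") +
    ggplot2::labs(x = "time after infusion (days)",
                  y = "concentration (cells/uL) or tumor volume (mL)") +
    ggplot2::theme_minimal()
}
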