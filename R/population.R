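#' Exponential interindividual variability transform
#'
#' Maps a typical ("population") parameter value to an individual value via
#' the exponential model `theta_i = theta * exp(eta)`, so individual values
#' are log-normal with median `theta` when `eta ~ N(0, omega2)`.
#'
#' @param theta_k typical value, >= 0.
#' @param eta individual log-scale deviation.
#' @return individual parameter value; vectorized.
#' @export
iiv_transform <- function(theta_k, eta) {
  stopifnot(all(theta_k >= 0))
  theta_k * exp(eta)
}

#' Convert a log-scale variance to a coefficient of variation (and back)
#'
#' Uses the log-normal relation `CV% = sqrt(exp(omega2) - 1) * 100` with
#' exact inverse `omega2 = ln((CV/100)^2 + 1)`. This is the conventional
#' reading of the CV formula in population modeling and makes the reported
#' "% CV" variability rows internally consistent (e.g. omega2 = ln(3.25)
#' corresponds to 150% CV).
#'
#' @param omega2 variance on the log scale, >= 0.
#' @return `omega2_to_cv()`: CV in percent.
#' @export
#' @examples
#' omega2_to_cv(log(3.25)) # 150
#' cv_to_omega2(omega2_to_cv(0.7)) # 0.7
omega2_to_cv <- function(omega2) {
  if (any(omega2 < 0)) abort("omega2 must be >= 0")
  sqrt(exp(omega2) - 1) * 100
}

#' @rdname omega2_to_cv
#' @param cv coefficient of variation in percent, >= 0.
#' @export
cv_to_omega2 <- function(cv) {
  if (any(cv < 0)) abort("cv must be >= 0")
  log((cv / 100)^2 + 1)
}

#' Covariate model for the expansion rate
#'
#' Computes the typical individual maximum expansion rate given a patient's
#' covariates and subpopulation. For the reference population,
#' `Vmax1 = Vmax1_base_ref * (1 + ASCT_Vmax1 * ASCT) * ratio^CD4CD8_exp`
#' (fractional-change model for previous autologous stem cell
#' transplantation, power model for the day-7 CD4/CD8 CAR-T ratio). For the
#' low-expansion subpopulation only the ASCT effect applies:
#' `Vmax1 = Vmax1_base_low * (1 + ASCT_Vmax1 * ASCT)`.
#'
#' @param params a [qsp_params()] object.
#' @param ASCT 0/1 previous autologous stem cell transplantation.
#' @param cd4cd8_day7 day-7 CD4+/CD8+ CAR-T cell ratio, > 0; `NA` is
#'   imputed to the covariate-neutral reference value 1.
#' @param subpop `"reference"` or `"low"`.
#' @return typical `Vmax1` for the patient; vectorized over covariates.
#' @export
#' @examples
#' apply_covariates(qsp_params(), ASCT = 1, cd4cd8_day7 = 1) # 0.00846 * 3.53
apply_covariates <- function(params, ASCT, cd4cd8_day7 = 1,
                             subpop = "reference") {
  stopifnot(all(ASCT %in% c(0, 1)), all(subpop %in% c("reference", "low")))
  cd4cd8_day7[is.na(cd4cd8_day7)] <- 1
  if (any(cd4cd8_day7 <= 0 & subpop == "reference"))
    abort("cd4cd8_day7 must be > 0 for the reference subpopulation")
  base <- ifelse(subpop == "low", params$Vmax1_base_low, params$Vmax1_base_ref)
  ratio_effect <- ifelse(subpop == "low", 1, cd4cd8_day7^params$CD4CD8_exp)
  base * (1 + params$ASCT_Vmax1 * ASCT) * ratio_effect
}

#' Residual log-density of one observation
#'
#' Log-transform-both-sides residual model: the log observation is normal
#' around the log prediction with species-specific variance `sigma2`.
#' Tumor scans recorded as 0 mL (complete response) are treated as
#' left-censored at a limit of quantification `loq`: their contribution is
#' the normal log-CDF of `ln(loq) - ln(predicted)`.
#'
#' @param observed observed value, > 0 unless censored.
#' @param predicted model prediction, > 0.
#' @param sigma2 residual variance on the log scale.
#' @param censored logical flag (left-censored at `loq`).
#' @param loq limit of quantification for censored tumor scans (mL).
#' @param patient_id,time_days optional labels used in error diagnostics.
#' @return log-density (or log-probability, if censored) contribution;
#'   vectorized.
#' @export
residual_log_density <- function(observed, predicted, sigma2,
                                 censored = FALSE, loq = 0.1,
                                 patient_id = NULL, time_days = NULL) {
  n <- max(length(observed), length(predicted))
  censored <- rep_len(censored, n)
  sigma2 <- rep_len(sigma2, n)
  if (any(predicted <= 0) || any(!is.finite(predicted))) {
    i <- which(predicted <= 0 | !is.finite(predicted))[1]
    abort(paste0("non-positive model prediction",
                 if (!is.null(patient_id)) paste0(" for patient ", rep_len(patient_id, n)[i]),
                 if (!is.null(time_days)) paste0(" at day ", rep_len(time_days, n)[i])))
  }
  if (any(!censored & observed <= 0))
    abort("uncensored observations must be > 0 under the log residual model")
  sdv <- sqrt(sigma2)
  out <- numeric(n)
  unc <- !censored
  if (any(unc))
    out[unc] <- dnorm(log(observed[unc]) - log(rep_len(predicted, n)[unc]),
                      sd = sdv[unc], log = TRUE)
  if (any(censored))
    out[censored] <- pnorm(log(loq) - log(rep_len(predicted, n)[censored]),
                           sd = sdv[censored], log.p = TRUE)
  out
}

#' Draw one virtual patient's individual parameters
#'
#' Samples the subpopulation label (`reference` with probability `MIXP`),
#' the interindividual deviations (`eta_Vmax1 ~ N(0, omega2_Vmax1)` in the
#' reference subpopulation only — variability on the low subpopulation's
#' expansion rate was negligible and is not modeled; `eta_Vmax5_2` in
#' both), applies the covariate model, and assembles a
#' [make_individual()] record.
#'
#' @param params a [qsp_params()] object.
#' @param variability a [qsp_variability()] object.
#' @param covariates one-row data frame with `ASCT`, `cd4cd8_day7`,
#'   `baseline_mtv` (and optionally `patient_id`).
#' @param seed optional integer seed (draws are reproducible given it);
#'   `NULL` uses the current RNG stream.
#' @param dose_per_phenotype initial concentration per phenotype (cells/uL).
#' @return one-row `qsp_individual` tibble (with latent `eta` values and
#'   the drawn subpopulation label).
#' @export
sample_individual <- function(params = qsp_params(),
                              variability = qsp_variability(),
                              covariates, seed = NULL,
                              dose_per_phenotype = 0.1) {
  .qsp_with_seed(seed, {
    cv <- as.list(covariates[1, ])
    subpop <- if (runif(1) < params$MIXP) "reference" else "low"
    eta1 <- if (subpop == "reference" && variability$omega2_Vmax1 > 0)
      rnorm(1, 0, sqrt(variability$omega2_Vmax1)) else 0
    eta5 <- if (variability$omega2_Vmax5_2 > 0)
      rnorm(1, 0, sqrt(variability$omega2_Vmax5_2)) else 0
    typ <- apply_covariates(params, ASCT = cv$ASCT,
                            cd4cd8_day7 = cv$cd4cd8_day7 %||% 1,
                            subpop = subpop)
    make_individual(patient_id = cv$patient_id %||% "pt1",
                    Vmax1_i = iiv_transform(typ, eta1),
                    baseline_mtv = cv$baseline_mtv,
                    Vmax5_2_i = iiv_transform(params$Vmax5_2, eta5),
                    subpop = subpop, dose_per_phenotype = dose_per_phenotype,
                    eta_Vmax1 = eta1, eta_Vmax5_2 = eta5, params = params)
  })
}
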