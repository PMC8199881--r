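#' Study sampling design
#'
#' Cell concentrations were sampled at days 7, 14 and 25-28 after infusion
#' (the 25-28 window collapses to day 26 by default, with optional uniform
#' jitter); tumor volume was assessed at baseline and around one and three
#' months (30 days/month).
#'
#' @param cell_days days at which the four CAR-T phenotypes are observed.
#' @param scan_days days at which tumor volume is observed.
#' @param cell_day_jitter half-width (days) of uniform jitter applied to
#'   the last cell-sampling day, emulating the day 25-28 window; 0 disables.
#' @param loq left-censoring limit for tumor scans (mL): values whose noisy
#'   realization falls below it are recorded as 0 mL, censored.
#' @return list of class `qsp_design`.
#' @export
cohort_design <- function(cell_days = c(7, 14, 26), scan_days = c(0, 30, 90),
                          cell_day_jitter = 0, loq = 0.1) {
  stopifnot(all(cell_days > 0), all(scan_days >= 0), cell_day_jitter >= 0,
            loq > 0)
  structure(list(cell_days = sort(cell_days), scan_days = sort(scan_days),
                 cell_day_jitter = cell_day_jitter, loq = loq),
            class = "qsp_design")
}

#' Sample virtual-patient covariates
#'
#' Baseline metabolic tumor volume is log-normal (default median 100 mL,
#' log-sd 1.5, truncated to the clinically observed span ~2.5-3600 mL);
#' previous autologous stem cell transplantation is Bernoulli (default
#' prevalence 0.37, i.e. 7 of 19 patients); the day-7 CD4/CD8 CAR-T ratio
#' is log-normal with median 1 (log-sd 0.5). Covariates are generated
#' independently across patients and across variables.
#'
#' @param n number of patients, >= 1.
#' @param mtv_median,mtv_sdlog,mtv_range baseline tumor volume distribution
#'   (mL): log-normal median, log-sd, truncation range.
#' @param asct_prob ASCT prevalence.
#' @param ratio_sdlog log-sd of the day-7 CD4/CD8 ratio.
#' @param seed optional integer seed.
#' @return tibble with `patient_id`, `ASCT`, `cd4cd8_day7`, `baseline_mtv`.
#' @export
#' @examples
#' sample_covariates(5, seed = 1)
sample_covariates <- function(n, mtv_median = 100, mtv_sdlog = 1.5,
                              mtv_range = c(2.5, 3600), asct_prob = 0.37,
                              ratio_sdlog = 0.5, seed = NULL) {
  stopifnot(n >= 1)
  .qsp_with_seed(seed, {
    mtv <- rlnorm(n, log(mtv_median), mtv_sdlog)
    mtv <- pmin(pmax(mtv, mtv_range[1]), mtv_range[2])
    tibble(patient_id = sprintf("pt%03d", seq_len(n)),
           ASCT = rbinom(n, 1, asct_prob),
           cd4cd8_day7 = rlnorm(n, 0, ratio_sdlog),
           baseline_mtv = mtv)
  })
}

#' Generate a virtual cohort
#'
#' Assembles the full data-generating chain: sample covariates (unless
#' supplied), draw each patient's subpopulation / interindividual
#' deviations / individual parameters, integrate the five-species system,
#' evaluate it at the design times, multiply by log-normal residual error
#' per species, and left-censor tumor scans whose realization falls below
#' the limit of quantification (recorded as 0 mL). The hidden truth
#' (individual parameters, latent deviations, subpopulation labels) is
#' retained for recovery testing.
#'
#' @param n number of patients (the clinical cohort had 19).
#' @param params,variability model parameters ([qsp_params()],
#'   [qsp_variability()]); set variances to 0 for noise-free data.
#' @param design a [cohort_design()].
#' @param covariates optional pre-sampled covariate tibble (overrides `n`).
#' @param residual if `FALSE`, observations equal model predictions exactly.
#' @param dose_per_phenotype imputed day-0 concentration per phenotype.
#' @param seed optional integer seed governing every draw.
#' @return list of class `qsp_cohort` with elements `observations`
#'   (patient_id, time_days, species, value, censored), `covariates`,
#'   `truth` (one `qsp_individual` row per patient), `design`, `params`,
#'   `variability`. Patients whose simulation fails are skipped with a
#'   warning and listed in `failed`.
#' @export
#' @examples
#' coh <- generate_cohort(5, seed = 42)
#' head(coh$observations)
generate_cohort <- function(n = 19, params = qsp_params(),
                            variability = qsp_variability(),
                            design = cohort_design(), covariates = NULL,
                            residual = TRUE, dose_per_phenotype = 0.1,
                            seed = NULL) {
  .qsp_with_seed(seed, {
    covariates <- covariates %||% sample_covariates(n)
    n <- nrow(covariates)
    failed <- character()
    obs_list <- vector("list", n)
    truth_list <- vector("list", n)
    for (i in seq_len(n)) {
      cell_days <- design$cell_days
      if (design$cell_day_jitter > 0) {
        k <- length(cell_days)
        cell_days[k] <- cell_days[k] +
          runif(1, -design$cell_day_jitter, design$cell_day_jitter)
      }
      ind <- sample_individual(params, variability, covariates[i, ],
                               dose_per_phenotype = dose_per_phenotype)
      all_times <- sort(unique(c(cell_days, design$scan_days)))
      traj <- try(simulate_patient(ind, params, times = all_times),
                  silent = TRUE)
      if (inherits(traj, "try-error")) {
        warn(paste0("simulation failed for ", ind$patient_id, "; skipped"))
        failed <- c(failed, ind$patient_id)
        next
      }
      long <- trajectory_long(traj)
      cells <- dplyr::filter(long, .data$species != "CD19",
                             .data$time_days %in% cell_days)
      tumor <- dplyr::filter(long, .data$species == "CD19",
                             .data$time_days %in% design$scan_days)
      obs <- dplyr::bind_rows(cells, tumor)
      obs <- dplyr::rename(obs, predicted = "value")
      if (residual) {
        sig <- variability$sigma2[obs$species]
        obs$value <- obs$predicted * exp(rnorm(nrow(obs), 0, sqrt(sig)))
      } else {
        obs$value <- obs$predicted
      }
      obs$censored <- obs$species == "CD19" & obs$value < design$loq
      obs$value[obs$censored] <- 0
      obs_list[[i]] <- dplyr::select(obs, "patient_id", "time_days",
                                     "species", "value", "censored")
      truth_list[[i]] <- ind
    }
    structure(list(observations = dplyr::bind_rows(obs_list),
                   covariates = covariates,
                   truth = dplyr::bind_rows(truth_list),
                   design = design, params = params,
                   variability = variability, failed = failed),
              class = "qsp_cohort")
  })
}

#' @export
print.qsp_cohort <- function(x, ...) {
  cat("Virtual CAR-T cohort:", nrow(x$covariates), "patients,",
      nrow(x$observations), "observations\n")
  if (nrow(x$truth)) {
    cat("  subpopulations:",
        sum(x$truth$subpop == "reference"), "reference /",
        sum(x$truth$subpop == "low"), "low expansion\n")
  }
  if (length(x$failed)) cat("  failed simulations:", toString(x$failed), "\n")
  invisible(x)
}

#' @export
autoplot.qsp_cohort <- function(object, ...) {
  obs <- dplyr::filter(object$observations, !.data$censored)
  ggplot2::ggplot(obs, ggplot2::aes(.data$time_days, .data$value,
                                    group = .data$patient_id)) +
    ggplot2::geom_line(alpha = 0.4) + ggplot2::geom_point(size = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~ .data$species, scales = "free_y") +
    ggplot2::labs(x = "time after infusion (days)",
                  y = "observed concentration (cells/uL) / volume (mL)") +
    ggplot2::theme_minimal()
}

#' Simulate survival outcomes linked to the expansion subpopulation
#'
#' Test harness for the endpoint analyses: exponential progression/death
#' times whose hazard differs between the low-expansion and reference
#' subpopulations by a configurable hazard ratio, with administrative
#' censoring at a maximum follow-up (default 24 months).
#'
#' @param cohort a [generate_cohort()] result with truth labels.
#' @param hazard_ratio_low hazard ratio of the low-expansion subpopulation
#'   relative to reference (default 4).
#' @param median_ref_months median survival in the reference group.
#' @param censor_months administrative censoring time (months).
#' @param seed optional integer seed.
#' @return tibble with `patient_id`, `time_months`, `event` (1 = event,
#'   0 = censored).
#' @export
simulate_survival <- function(cohort, hazard_ratio_low = 4,
                              median_ref_months = 12, censor_months = 24,
                              seed = NULL) {
  if (!nrow(cohort$truth)) abort("cohort must carry truth labels")
  .qsp_with_seed(seed, {
    lam_ref <- log(2) / median_ref_months
    lam <- ifelse(cohort$truth$subpop == "low",
                  lam_ref * hazard_ratio_low, lam_ref)
    t_event <- if (all(lam > 0)) rexp(length(lam), lam) else {
      tt <- rep(Inf, length(lam)); pos <- lam > 0
      tt[pos] <- rexp(sum(pos), lam[pos]); tt
    }
    tibble(patient_id = cohort$truth$patient_id,
           time_months = pmin(t_event, censor_months),
           event = as.integer(t_event <= censor_months))
  })
}

#' Write a cohort to plain-text files
#'
#' @param cohort a `qsp_cohort`.
#' @param dir output directory (created if missing); writes
#'   `observations.csv`, `covariates.csv`, `truth.csv`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$observations, file.path(dir, "observations.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
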