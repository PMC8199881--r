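# ---- fast internal simulation/likelihood paths ------------------------------
# These avoid tibble overhead inside the inner (eta) and outer (population)
# optimization loops; the exported wrappers below are the documented surface.

.sim_states <- function(params, Vmax1_i, Vmax5_2_i, baseline_mtv, dose, times) {
  tt <- sort(unique(c(0, times)))
  y0 <- c(dose, dose, dose, dose, baseline_mtv)
  sol <- deSolve::lsoda(y0, tt, func = "qsp_derivs",
                        parms = .qsp_c_parms(params, Vmax1_i, Vmax5_2_i),
                        dllname = "cartqsp", initfunc = "qsp_initmod",
                        rtol = 1e-8, atol = 1e-10, maxsteps = 50000)
  if (nrow(sol) < length(tt)) stop("ODE integration failed")
  states <- unclass(sol)[, -1, drop = FALSE]
  states[states < 0] <- 0
  list(times = sol[, 1], states = states)
}

# patient observations pre-indexed for speed
.prep_obs <- function(obs) {
  times <- sort(unique(obs$time_days))
  list(times = times,
       row = match(obs$time_days, times),
       col = match(obs$species, .qsp_species),
       species = obs$species,
       value = obs$value,
       censored = as.logical(obs$censored))
}

.obs_loglik <- function(po, params, Vmax1_i, Vmax5_2_i, baseline_mtv, dose,
                        sigma2, loq) {
  sim <- tryCatch(.sim_states(params, Vmax1_i, Vmax5_2_i, baseline_mtv,
                              dose, po$times),
                  error = function(e) NULL)
  if (is.null(sim)) return(-Inf)
  keep <- match(po$times, sim$times)
  pred <- sim$states[cbind(keep[po$row], po$col)]
  if (any(pred <= 0 & !po$censored)) return(-Inf)
  pred[pred <= 0] <- .Machine$double.xmin
  sdv <- sqrt(sigma2[po$col])
  ll <- numeric(length(pred))
  unc <- !po$censored
  ll[unc] <- dnorm(log(po$value[unc]) - log(pred[unc]), sd = sdv[unc],
                   log = TRUE)
  if (any(po$censored))
    ll[po$censored] <- pnorm(log(loq) - log(pred[po$censored]),
                             sd = sdv[po$censored], log.p = TRUE)
  sum(ll)
}

# ---- exported likelihood operations -----------------------------------------

#' Individual-level log-likelihood
#'
#' Sum of per-observation residual log-densities for one patient, given a
#' fully specified individual parameter set: the patient's trajectory is
#' integrated and evaluated at the observation times, and each observation
#' contributes under the log-transform-both-sides residual model (censored
#' tumor scans contribute a log-CDF term; see [residual_log_density()]).
#'
#' @param obs the patient's observations: tibble with `time_days`,
#'   `species`, `value`, `censored`.
#' @param individual a [make_individual()] row.
#' @param params a [qsp_params()] object.
#' @param variability a [qsp_variability()] (only `sigma2` is used).
#' @param loq left-censoring limit for tumor scans (mL).
#' @return scalar log-likelihood; `-Inf` (with a warning) if the
#'   simulation fails.
#' @export
individual_loglik <- function(obs, individual, params = qsp_params(),
                              variability = qsp_variability(), loq = 0.1) {
  if (nrow(obs) < 1) abort("patient must have at least one observation")
  ind <- as.list(individual[1, ])
  po <- .prep_obs(obs)
  ll <- .obs_loglik(po, params, ind$Vmax1_i, ind$Vmax5_2_i,
                    ind$baseline_mtv, ind$dose_per_phenotype,
                    variability$sigma2, loq)
  if (!is.finite(ll)) warn(paste0("simulation failed or produced zero ",
                                  "predictions for ", ind$patient_id))
  ll
}

# eta layout for a subpopulation: which deviations are free
.eta_layout <- function(variability, subpop) {
  use1 <- subpop == "reference" && variability$omega2_Vmax1 > 0
  use5 <- variability$omega2_Vmax5_2 > 0
  list(use1 = use1, use5 = use5, d = use1 + use5,
       omega2 = c(if (use1) variability$omega2_Vmax1,
                  if (use5) variability$omega2_Vmax5_2))
}

#' Laplace-approximate marginal log-likelihood for one patient
#'
#' Integrates the individual likelihood over the interindividual
#' deviations (eta) by Laplace approximation: an inner optimization finds
#' the posterior mode of eta (the empirical Bayes estimate), and the
#' curvature of the joint log-density at the mode supplies the Gaussian
#' correction. In the reference subpopulation eta acts on both the
#' expansion rate and the central-memory killing rate; in the low-expansion
#' subpopulation only on the killing rate. With all variances zero this
#' reduces exactly to [individual_loglik()] at eta = 0.
#'
#' @inheritParams individual_loglik
#' @param covariates one-row data frame with the patient's `ASCT`,
#'   `cd4cd8_day7`, `baseline_mtv`.
#' @param subpop `"reference"` or `"low"`.
#' @param dose_per_phenotype imputed day-0 dose (cells/uL).
#' @param eta_start warm start for the inner optimization.
#' @param details if `TRUE`, return a list with the mode, Hessian and
#'   convergence flag instead of the bare value.
#' @param obs_prepped internal: pre-indexed observations (from repeated
#'   calls inside [fit_population()]); supersedes `obs`.
#' @return scalar log marginal likelihood (or a detail list).
#' @export
marginal_loglik <- function(obs, params = qsp_params(),
                            variability = qsp_variability(), covariates,
                            subpop = "reference", loq = 0.1,
                            dose_per_phenotype = 0.1, eta_start = NULL,
                            details = FALSE, obs_prepped = NULL) {
  cv <- as.list(covariates[1, ])
  typ1 <- apply_covariates(params, ASCT = cv$ASCT,
                           cd4cd8_day7 = cv$cd4cd8_day7 %||% 1,
                           subpop = subpop)
  po <- obs_prepped %||% .prep_obs(obs)
  lay <- .eta_layout(variability, subpop)
  ll_eta <- function(eta) {
    e1 <- if (lay$use1) eta[1] else 0
    e5 <- if (lay$use5) eta[lay$use1 + 1] else 0
    .obs_loglik(po, params, typ1 * exp(e1), params$Vmax5_2 * exp(e5),
                cv$baseline_mtv, dose_per_phenotype, variability$sigma2, loq)
  }
  if (lay$d == 0) {
    val <- ll_eta(numeric(0))
    if (!details) return(val)
    return(list(logL = val, eta_mode = numeric(0), converged = TRUE,
                subpop = subpop))
  }
  neg_h <- function(eta) {
    ll <- ll_eta(eta)
    if (!is.finite(ll)) return(1e10)
    -(ll + sum(dnorm(eta, 0, sqrt(lay$omega2), log = TRUE)))
  }
  start <- eta_start %||% rep(0, lay$d)
  fit <- nlminb(start, neg_h, control = list(rel.tol = 1e-8, iter.max = 200))
  conv <- fit$convergence == 0
  H <- tryCatch(optimHess(fit$par, neg_h), error = function(e) NULL)
  ok <- FALSE
  if (!is.null(H)) {
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    if (all(ev > 0)) ok <- TRUE
  }
  if (!ok) H <- (if (is.null(H)) diag(lay$d) else H) + diag(1e-6, lay$d)
  logdet <- determinant(H, logarithm = TRUE)$modulus
  logL <- -fit$objective + lay$d / 2 * log(2 * pi) - 0.5 * as.numeric(logdet)
  if (!details) return(logL)
  list(logL = logL, eta_mode = fit$par, hessian = H, converged = conv,
       subpop = subpop)
}

# ---- free-parameter transforms ----------------------------------------------

.free_space <- function(name) {
  if (name %in% c("MIXP")) "logit"
  else if (name %in% c("CD4CD8_exp", "ASCT_Vmax1")) "identity"
  else "log"
}

.get_free <- function(name, params, variability) {
  if (startsWith(name, "sigma2_")) variability$sigma2[[sub("sigma2_", "", name)]]
  else if (startsWith(name, "omega2_")) variability[[name]]
  else params[[name]]
}

.set_free <- function(name, value, params, variability) {
  if (startsWith(name, "sigma2_")) {
    variability$sigma2[[sub("sigma2_", "", name)]] <- value
  } else if (startsWith(name, "omega2_")) {
    variability[[name]] <- value
  } else params[[name]] <- value
  list(params = params, variability = variability)
}

.to_trans <- function(x, space) switch(space, log = log(x),
                                       logit = stats::qlogis(x), x)
.from_trans <- function(x, space) switch(space, log = exp(x),
                                         logit = stats::plogis(x), x)

# ---- population fit ----------------------------------------------------------

#' Fit the population model to a cohort
#'
#' Maximizes the mixture-weighted approximate marginal likelihood over the
#' free parameters: each patient contributes
#' `log(MIXP * L_i(reference) + (1 - MIXP) * L_i(low))`, with per-subpopulation
#' marginal likelihoods from [marginal_loglik()]. Positive parameters are
#' estimated on the log scale and the mixture proportion on the logit
#' scale, so the outer quasi-Newton search is unconstrained. Per-patient
#' empirical Bayes eta modes are warm-started across outer iterations,
#' which keeps cohort-scale fits within minutes. The objective function
#' value OFV = -2 ln(likelihood) is reported; lower is better.
#'
#' The minimal sensible fixed set (homeostatic proliferation rates, tumor
#' growth and carrying capacity, the long-lived death rates, and the
#' killing-rate ratios) is whatever is *not* listed in `free`; by default
#' only the two subpopulation expansion rates and the mixture proportion
#' are estimated.
#'
#' @param cohort a [generate_cohort()] result, or a list with elements
#'   `observations` and `covariates` in the same format.
#' @param params,variability initial / fixed parameter values.
#' @param free character vector naming the estimated parameters: any
#'   [qsp_params()] field, `omega2_Vmax1`, `omega2_Vmax5_2`, or
#'   `sigma2_TN` .. `sigma2_CD19`.
#' @param loq left-censoring limit (mL).
#' @param dose_per_phenotype imputed day-0 dose (cells/uL).
#' @param n_starts number of outer starts; starts beyond the first jitter
#'   the initial transformed parameters (`jitter_sd`), seeded.
#' @param jitter_sd standard deviation of the transformed-scale jitter.
#' @param seed seed for the multi-start jitter.
#' @param control passed to [nlminb()] for the outer optimization.
#' @return object of class `qsp_fit`: `estimates` (params + variability at
#'   the optimum), `ofv`, `individuals` (per-patient empirical Bayes etas,
#'   individual expansion rate, responsibility of the reference
#'   subpopulation, most likely label), `converged`, `free`, plus the
#'   internal objective needed by [sir_uncertainty()].
#' @export
fit_population <- function(cohort, params = qsp_params(),
                           variability = qsp_variability(),
                           free = c("Vmax1_base_ref", "Vmax1_base_low",
                                    "MIXP"),
                           loq = 0.1, dose_per_phenotype = 0.1,
                           n_starts = 1, jitter_sd = 0.3, seed = 1,
                           control = list(rel.tol = 1e-7, iter.max = 150)) {
  obs <- cohort$observations
  covs <- cohort$covariates
  if (is.null(obs) || nrow(obs) == 0) abort("cohort has no observations")
  ids <- covs$patient_id
  by_pt <- lapply(split(obs, obs$patient_id)[as.character(ids)], .prep_obs)
  spaces <- vapply(free, .free_space, character(1))
  theta0 <- vapply(seq_along(free), function(j)
    .to_trans(.get_free(free[j], params, variability), spaces[j]), numeric(1))
  warm <- new.env(parent = emptyenv())

  build <- function(theta) {
    pv <- list(params = params, variability = variability)
    for (j in seq_along(free))
      pv <- .set_free(free[j], .from_trans(theta[j], spaces[j]),
                      pv$params, pv$variability)
    pv
  }

  patient_terms <- function(theta) {
    pv <- build(theta)
    p <- pv$params; v <- pv$variability
    lref <- numeric(length(ids)); llow <- numeric(length(ids))
    for (i in seq_along(ids)) {
      cvi <- covs[i, ]
      for (sp in c("reference", "low")) {
        key <- paste0(ids[i], ".", sp)
        lay <- .eta_layout(v, sp)
        st <- if (lay$d > 0) {
          w <- warm[[key]]
          if (is.null(w) || length(w) != lay$d) rep(0, lay$d) else w
        } else NULL
        det <- marginal_loglik(cohort$observations[0, ], params = p,
                               variability = v, covariates = cvi,
                               subpop = sp, loq = loq,
                               dose_per_phenotype = dose_per_phenotype,
                               eta_start = st, details = TRUE,
                               obs_prepped = by_pt[[i]])
        if (lay$d > 0) warm[[key]] <- det$eta_mode
        if (sp == "reference") lref[i] <- det$logL else llow[i] <- det$logL
      }
    }
    list(lref = lref, llow = llow, mixp = p$MIXP, pv = pv)
  }

  negll <- function(theta) {
    tm <- patient_terms(theta)
    a <- log(tm$mixp) + tm$lref
    b <- log1p(-tm$mixp) + tm$llow
    m <- pmax(a, b)
    val <- -sum(m + log(exp(a - m) + exp(b - m)))
    if (!is.finite(val)) 1e10 else val
  }

  # central-difference gradient with a step large enough to dominate the
  # inner-optimization noise (~1e-8) in the objective
  grad_step <- 1e-4
  negll_grad <- function(theta) {
    vapply(seq_along(theta), function(j) {
      e <- replace(numeric(length(theta)), j, grad_step)
      (negll(theta + e) - negll(theta - e)) / (2 * grad_step)
    }, numeric(1))
  }

  if (length(free) == 0) {
    # fully fixed model: evaluate the mixture likelihood once
    best <- list(par = numeric(0), objective = negll(numeric(0)),
                 convergence = 0L, message = "no free parameters")
  } else {
    best <- NULL
    for (s in seq_len(n_starts)) {
      th <- if (s == 1) theta0 else
        .qsp_with_seed(seed + s, theta0 + rnorm(length(theta0), 0, jitter_sd))
      res <- nlminb(th, negll, gradient = negll_grad, control = control)
      if (is.null(best) || res$objective < best$objective) best <- res
    }
  }

  # nlminb can report "false convergence" when finite-difference noise
  # dominates near the optimum; accept if the gradient is flat relative to
  # the objective scale (a unit step along any coordinate would move the
  # OFV by well under 0.1%)
  converged <- best$convergence == 0 ||
    (length(free) > 0 &&
       max(abs(negll_grad(best$par))) < max(1, 5e-4 * abs(best$objective)))

  tm <- patient_terms(best$par)
  a <- log(tm$mixp) + tm$lref
  b <- log1p(-tm$mixp) + tm$llow
  m <- pmax(a, b)
  logmix <- m + log(exp(a - m) + exp(b - m))
  resp <- exp(a - logmix)
  label <- ifelse(resp >= 0.5, "reference", "low")
  if (tm$mixp < 0.001 || tm$mixp > 0.999)
    warn(paste0("degenerate mixture: estimated MIXP = ", signif(tm$mixp, 3)))

  # empirical Bayes summaries under the most likely subpopulation
  etas <- purrr::map_dfr(seq_along(ids), function(i) {
    sp <- label[i]
    lay <- .eta_layout(tm$pv$variability, sp)
    w <- warm[[paste0(ids[i], ".", sp)]] %||% rep(0, lay$d)
    e1 <- if (lay$use1) w[1] else 0
    e5 <- if (lay$use5) w[lay$use1 + 1] else 0
    ratio_i <- if (is.null(covs$cd4cd8_day7)) 1 else covs$cd4cd8_day7[i]
    typ <- apply_covariates(tm$pv$params, ASCT = covs$ASCT[i],
                            cd4cd8_day7 = ratio_i, subpop = sp)
    tibble(patient_id = ids[i], subpop = sp, responsibility = resp[i],
           eta_Vmax1 = e1, eta_Vmax5_2 = e5, Vmax1_i = typ * exp(e1))
  })

  structure(list(estimates = tm$pv, ofv = 2 * best$objective,
                 individuals = etas,
                 converged = converged,
                 message = best$message, free = free, spaces = spaces,
                 theta_hat = best$par, negll = negll,
                 n_patients = length(ids), n_obs = nrow(obs)),
            class = "qsp_fit")
}

#' Per-patient subpopulation classification
#'
#' Posterior responsibility of the reference subpopulation,
#' `r_i = MIXP * L_i(ref) / (MIXP * L_i(ref) + (1 - MIXP) * L_i(low))`,
#' and the most likely label.
#'
#' @param fit a [fit_population()] result.
#' @return tibble with `patient_id`, `responsibility` (of reference),
#'   `label`.
#' @export
classify_subpop <- function(fit) {
  dplyr::select(fit$individuals, "patient_id", "responsibility",
                label = "subpop")
}

#' Likelihood-ratio test for nested model comparison
#'
#' `delta_OFV = OFV_reduced - OFV_full` compared against the chi-square
#' quantile for the number of freed parameters; at one degree of freedom
#' and alpha = 0.05 the threshold is 3.84 OFV points.
#'
#' @param fit_full,fit_reduced nested [fit_population()] results (the
#'   reduced model fixes `df` of the full model's free parameters).
#' @param df degrees of freedom (number of parameters freed in the full
#'   model).
#' @param alpha significance level.
#' @return one-row tibble: `delta_ofv`, `df`, `threshold`, `p_value`,
#'   `significant`.
#' @export
lrt_covariate <- function(fit_full, fit_reduced, df = 1, alpha = 0.05) {
  delta <- fit_reduced$ofv - fit_full$ofv
  if (delta < -1e-6)
    warn("reduced model has lower OFV than the full model: optimizer failure likely")
  thr <- qchisq(1 - alpha, df)
  tibble(delta_ofv = delta, df = df, threshold = thr,
         p_value = pchisq(max(delta, 0), df, lower.tail = FALSE),
         significant = delta > thr)
}

# ---- SIR uncertainty ---------------------------------------------------------

#' Sampling importance resampling on a likelihood surface
#'
#' Workhorse for [sir_uncertainty()]: iteratively draws parameter vectors
#' from a multivariate-normal proposal centered at the point estimate,
#' weights them by the likelihood-to-proposal ratio, resamples with
#' replacement, and re-estimates the proposal covariance from the
#' resamples for the next iteration.
#'
#' @param neg_loglik function of the parameter vector returning the
#'   negative log-likelihood.
#' @param center point estimate (proposal mean, kept fixed).
#' @param proposal_cov initial proposal covariance.
#' @param samples,resamples integer vectors, one entry per iteration
#'   (default: the 5-iteration schedule 1000/1000/1000/2000/2000 samples
#'   with 200/400/500/1000/1000 resamples).
#' @param seed optional integer seed.
#' @return list with `resamples` (matrix, final iteration), `cov` (final
#'   proposal covariance).
#' @export
sir_resample <- function(neg_loglik, center, proposal_cov,
                         samples = c(1000, 1000, 1000, 2000, 2000),
                         resamples = c(200, 400, 500, 1000, 1000),
                         seed = NULL) {
  stopifnot(length(samples) == length(resamples))
  d <- length(center)
  .qsp_with_seed(seed, {
    covm <- proposal_cov
    ll0 <- -neg_loglik(center)
    out <- NULL
    for (it in seq_along(samples)) {
      if (all(abs(covm) < 1e-14)) {
        out <- matrix(rep(center, resamples[it]), ncol = d, byrow = TRUE)
        next
      }
      ch <- tryCatch(chol(covm), error = function(e) NULL)
      if (is.null(ch)) {
        warn("singular proposal covariance: regularizing")
        covm <- covm + diag(1e-8 + 1e-6 * mean(diag(covm)), d)
        ch <- chol(covm)
      }
      z <- matrix(rnorm(samples[it] * d), samples[it], d)
      draws <- sweep(z %*% ch, 2, center, `+`)
      # log proposal density up to a constant: draws - center = z %*% chol,
      # so the quadratic form reduces to rowSums(z^2)
      logq <- -0.5 * rowSums(z^2)
      logl <- apply(draws, 1, function(th) -neg_loglik(th))
      logw <- (logl - ll0) - logq
      logw[!is.finite(logw)] <- -Inf
      w <- exp(logw - max(logw[is.finite(logw)], na.rm = TRUE))
      if (!any(w > 0)) abort("all SIR importance weights are zero")
      idx <- sample.int(samples[it], resamples[it], replace = TRUE,
                        prob = w)
      out <- draws[idx, , drop = FALSE]
      covm <- cov(out)
    }
    list(resamples = out, cov = covm)
  })
}

#' Parameter uncertainty by sampling importance resampling
#'
#' Builds a multivariate-normal proposal from the numerical Hessian of the
#' negative log-likelihood at the optimum (on the transformed estimation
#' scale), runs the iterative SIR schedule via [sir_resample()], maps the
#' final resamples back to the natural scale, and reports per-parameter
#' relative standard errors, `RSE% = sd(resamples) / estimate * 100`.
#'
#' @param fit a converged [fit_population()] result.
#' @param samples,resamples SIR schedule (see [sir_resample()]); scale both
#'   down proportionally for quick approximate uncertainty.
#' @param seed optional integer seed.
#' @return list of class `qsp_sir`: `rse` tibble (`parameter`, `estimate`,
#'   `sd`, `rse_pct`), `resamples` (natural scale, final iteration).
#' @export
sir_uncertainty <- function(fit, samples = c(1000, 1000, 1000, 2000, 2000),
                            resamples = c(200, 400, 500, 1000, 1000),
                            seed = NULL) {
  if (!isTRUE(fit$converged)) warn("fit did not converge; SIR proposal may be poor")
  H <- optimHess(fit$theta_hat, fit$negll)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    warn("non-positive-definite Hessian at the optimum: regularizing")
    H <- H + diag(abs(min(ev)) + 1e-6, nrow(H))
  }
  covm <- solve(H)
  sir <- sir_resample(fit$negll, fit$theta_hat, covm, samples = samples,
                      resamples = resamples, seed = seed)
  nat <- sir$resamples
  for (j in seq_along(fit$free))
    nat[, j] <- .from_trans(sir$resamples[, j], fit$spaces[j])
  colnames(nat) <- fit$free
  est <- vapply(seq_along(fit$free), function(j)
    .from_trans(fit$theta_hat[j], fit$spaces[j]), numeric(1))
  rse <- tibble(parameter = fit$free, estimate = est,
                sd = apply(nat, 2, sd),
                rse_pct = apply(nat, 2, sd) / abs(est) * 100)
  structure(list(rse = rse, resamples = as_tibble(nat)), class = "qsp_sir")
}

# ---- broom-style methods -----------------------------------------------------

#' @export
tidy.qsp_fit <- function(x, ...) {
  est <- vapply(seq_along(x$free), function(j)
    .from_trans(x$theta_hat[j], x$spaces[j]), numeric(1))
  tibble(term = x$free, estimate = est, transform = x$spaces)
}

#' @export
glance.qsp_fit <- function(x, ...) {
  tibble(ofv = x$ofv, converged = x$converged,
         n_patients = x$n_patients, n_obs = x$n_obs,
         n_free = length(x$free), mixp = x$estimates$params$MIXP)
}

#' @export
print.qsp_fit <- function(x, ...) {
  cat("Population QSP fit:", x$n_patients, "patients,", x$n_obs,
      "observations\n")
  cat("  OFV:", format(x$ofv, digits = 8),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(tidy(x))
  invisible(x)
}
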