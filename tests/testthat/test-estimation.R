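# a small noise-free cohort evaluated at its own generating parameters
noise_free_cohort <- function(n = 3, seed = 61) {
  generate_cohort(n, params = qsp_params(MIXP = 1), variability = novar(),
                  covariates = neutral_covariates(n, baseline_mtv = 120),
                  residual = FALSE, seed = seed)
}

test_that("individual log-likelihood at truth reduces to the sigma constant", {
  coh <- noise_free_cohort()
  v <- qsp_variability()
  obs <- dplyr::filter(coh$observations, patient_id == "pt001", !censored)
  ll <- individual_loglik(obs, coh$truth[1, ], coh$params, v)
  expected <- sum(-0.5 * log(2 * pi * v$sigma2[obs$species]))
  expect_equal(ll, expected, tolerance = 1e-8)
})

test_that("perturbing the expansion rate away from truth lowers the likelihood", {
  coh <- noise_free_cohort()
  v <- qsp_variability()
  obs <- dplyr::filter(coh$observations, patient_id == "pt001", !censored)
  ll_true <- individual_loglik(obs, coh$truth[1, ], coh$params, v)
  for (f in c(0.3, 0.6, 2, 4)) {
    ind <- coh$truth[1, ]
    ind$Vmax1_i <- ind$Vmax1_i * f
    expect_lt(individual_loglik(obs, ind, coh$params, v), ll_true)
  }
})

test_that("a patient with only satisfied censored scans contributes ~0", {
  # strong killing drives the tumor far below the LOQ by day 90
  ind <- make_individual(Vmax1_i = 0.05, Vmax5_2_i = 500, baseline_mtv = 5)
  obs <- tibble::tibble(patient_id = "pt1", time_days = 90, species = "CD19",
                        value = 0, censored = TRUE)
  ll <- individual_loglik(obs, ind, qsp_params(), qsp_variability())
  expect_gt(ll, -0.01)
  expect_lte(ll, 0)
})

test_that("Laplace marginal reduces to the plug-in likelihood when variances vanish", {
  coh <- noise_free_cohort()
  obs <- dplyr::filter(coh$observations, patient_id == "pt001")
  v0 <- novar()
  v0$sigma2[] <- qsp_variability()$sigma2
  ml <- marginal_loglik(obs, coh$params, v0, coh$covariates[1, ],
                        subpop = "reference")
  il <- individual_loglik(obs, coh$truth[1, ], coh$params, v0)
  expect_equal(ml, il, tolerance = 1e-10)
})

test_that("Laplace marginal matches numerical quadrature on a one-eta toy patient", {
  p <- qsp_params()
  v <- qsp_variability(omega2_Vmax1 = 0, omega2_Vmax5_2 = 0.49)
  cov1 <- neutral_covariates(1, baseline_mtv = 200)
  obs <- tibble::tibble(patient_id = "pt001", time_days = 30,
                        species = "CD19", value = 60, censored = FALSE)
  lap <- marginal_loglik(obs, p, v, cov1, subpop = "reference")
  integrand <- Vectorize(function(eta) {
    ind <- make_individual(Vmax1_i = p$Vmax1_base_ref,
                           Vmax5_2_i = p$Vmax5_2 * exp(eta),
                           baseline_mtv = 200)
    exp(individual_loglik(obs, ind, p, v)) * dnorm(eta, 0, sqrt(0.49))
  })
  quad <- integrate(integrand, -5, 5, rel.tol = 1e-8)$value
  expect_equal(exp(lap), quad, tolerance = 0.01)
})

test_that("marginal likelihood stays finite on data far from the model", {
  p <- qsp_params()
  v <- qsp_variability()
  obs <- tibble::tibble(patient_id = "pt001",
                        time_days = rep(c(7, 14, 26), each = 1),
                        species = "TN", value = c(1e6, 1e6, 1e6),
                        censored = FALSE)
  ml <- marginal_loglik(obs, p, v, neutral_covariates(1), subpop = "low")
  expect_true(is.finite(ml))
})

test_that("refitting data generated at the initial values does not raise the OFV", {
  coh <- generate_cohort(8, covariates = neutral_covariates(8, 100),
                         seed = 71)
  at_init <- fit_population(coh, free = character(0))
  fit <- fit_population(coh, free = "Vmax1_base_ref",
                        control = list(rel.tol = 1e-6, iter.max = 40))
  expect_lte(fit$ofv, at_init$ofv + 1e-6)
  expect_true(all(fit$individuals$responsibility >= 0 &
                    fit$individuals$responsibility <= 1))
})

test_that("identical subpopulation parameters give responsibilities equal to MIXP", {
  # identical typical values AND identical variability structure (no IIV on
  # the expansion rate, so reference and low submodels coincide)
  p <- qsp_params(Vmax1_base_low = 0.00846 * (1 - 1e-9))
  v <- qsp_variability(omega2_Vmax1 = 0)
  coh <- generate_cohort(4, params = p, variability = v,
                         covariates = neutral_covariates(4, 80), seed = 81)
  fit <- fit_population(coh, params = p, variability = v,
                        free = character(0))
  expect_equal(fit$individuals$responsibility, rep(p$MIXP, 4),
               tolerance = 1e-4)
})

test_that("classify_subpop exposes labels and responsibilities", {
  coh <- generate_cohort(6, seed = 91)
  fit <- fit_population(coh, free = character(0))
  cls <- classify_subpop(fit)
  expect_named(cls, c("patient_id", "responsibility", "label"))
  expect_true(all(cls$label %in% c("reference", "low")))
  expect_true(all(cls$responsibility >= 0 & cls$responsibility <= 1))
})

test_that("likelihood-ratio bookkeeping follows the chi-square threshold", {
  f1 <- structure(list(ofv = 100), class = "qsp_fit")
  expect_false(lrt_covariate(f1, f1)$significant)
  f2 <- structure(list(ofv = 103.85), class = "qsp_fit")
  res <- lrt_covariate(f1, f2, df = 1)
  expect_true(res$significant)
  expect_equal(res$delta_ofv, 3.85)
  expect_equal(res$threshold, qchisq(0.95, 1), tolerance = 1e-4)
  # threshold scales with df
  expect_false(lrt_covariate(f1, f2, df = 2)$significant)
  expect_warning(lrt_covariate(f2, f1), "optimizer failure")
})

test_that("SIR resampling collapses for a zero-variance proposal", {
  nll <- function(th) 0.5 * sum((th - c(1, 2))^2)
  out <- sir_resample(nll, c(1, 2), matrix(0, 2, 2),
                      samples = c(50, 50), resamples = c(20, 20), seed = 1)
  expect_true(all(out$resamples[, 1] == 1))
  expect_true(all(out$resamples[, 2] == 2))
})

test_that("SIR standard errors match analytic values on a normal likelihood", {
  # exactly quadratic negative log-likelihood: posterior sd = c(0.5, 2)
  sds <- c(0.5, 2)
  nll <- function(th) 0.5 * sum((th - c(3, -1))^2 / sds^2)
  H <- diag(1 / sds^2)
  out <- sir_resample(nll, c(3, -1), solve(H),
                      samples = c(1000, 1000, 2000),
                      resamples = c(300, 500, 1000), seed = 7)
  got <- apply(out$resamples, 2, sd)
  expect_equal(got[1], 0.5, tolerance = 0.1)
  expect_equal(got[2], 2, tolerance = 0.1)
})

test_that("tidy and glance summarize a fit", {
  coh <- generate_cohort(5, seed = 95)
  fit <- fit_population(coh, free = character(0))
  td <- tidy(fit)
  expect_equal(nrow(td), 0)
  gl <- glance(fit)
  expect_equal(gl$n_patients, 5)
  expect_true(is.finite(gl$ofv))
})
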