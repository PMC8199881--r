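#' Structural model parameters
#'
#' Constructs the full set of typical-value ("fixed-effect") parameters of
#' the five-species CAR-T / tumor model. Defaults are the final population
#' estimates of the model: expansion and killing Michaelis-Menten constants,
#' first-order differentiation / death / homeostatic-proliferation rate
#' constants, logistic tumor growth, covariate coefficients, and the mixture
#' proportion of the reference-expansion population.
#'
#' Units are kept in their original mixed form: T-cell concentrations in
#' cells/uL, tumor volume in mL, time in days. `Vmax1_base_ref` /
#' `Vmax1_base_low` are the typical maximum expansion rates per mL tumor
#' volume for the reference and low-expansion subpopulations; killing rates
#' `Vmax5_1`..`Vmax5_4` act per phenotype, with phenotypes 1, 3 and 4 fixed
#' multiples of the estimated `Vmax5_2` (their in-vitro killing-capacity
#' ratios are preserved when individual variability scales `Vmax5_2`).
#'
#' @param ... named overrides of any default value.
#' @param expansion_denominator "tcell" (selected model: the respective
#'   T-cell concentration saturates expansion) or "tumor" (explored
#'   alternative with tumor volume in the denominator; exposed as a switch
#'   without endorsement).
#' @return A named list of class `qsp_params`.
#' @export
#' @examples
#' p <- qsp_params()
#' p$Vmax1_base_ref
#' qsp_params(KM5 = 300)$KM5
qsp_params <- function(..., expansion_denominator = c("tcell", "tumor")) {
  p <- list(
    Vmax1_base_ref = 0.00846,  # (cells/uL)/day/mL, reference population
    Vmax1_base_low = 0.000700, # (cells/uL)/day/mL, low-expansion subpop
    ASCT_Vmax1     = 2.53,     # fractional change for previous ASCT
    CD4CD8_exp     = -0.385,   # power exponent, day-7 CD4/CD8 CAR-T ratio
    KM1            = 1.13,     # cells/uL at half-maximum expansion
    kp1            = 0.0005,   # /day homeostatic proliferation T_N
    kp2            = 0.007,    # /day T_CM
    kp3            = 0.007,    # /day T_EM
    k12            = 0.140,    # /day T_N -> T_CM
    k23            = 0.191,    # /day T_CM -> T_EM
    k34            = 0.355,    # /day T_EM -> T_Eff
    ke1            = 0.0104,   # /day death T_N (= 2% of ke4)
    ke2            = 0.0104,   # /day death T_CM
    ke3            = 0.0104,   # /day death T_EM
    ke4            = 0.518,    # /day death T_Eff
    Vmax5_1        = 2.57,     # mL/day/(cells/uL), killing by T_N
    Vmax5_2        = 4.04,     # killing by T_CM (estimated anchor)
    Vmax5_3        = 3.78,     # killing by T_EM
    Vmax5_4        = 4.24,     # killing by T_Eff
    KM5            = 276,      # mL at half-maximum killing
    K0             = 5000,     # mL tumor carrying capacity
    k5             = 0.0023,   # /day tumor proliferation
    MIXP           = 0.803     # proportion in the reference population
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) abort(paste0("unknown parameter(s): ", toString(bad)))
    p[names(dots)] <- dots
  }
  p$expansion_denominator <- match.arg(expansion_denominator)
  validate_qsp_params(structure(p, class = "qsp_params"))
}

validate_qsp_params <- function(p) {
  num <- setdiff(names(p), "expansion_denominator")
  vals <- unlist(p[num])
  if (any(!is.finite(vals)) || any(vals[setdiff(num, "CD4CD8_exp")] < 0))
    abort("all rates, capacities and the mixture proportion must be finite and >= 0")
  if (p$MIXP > 1) abort("MIXP must lie in [0, 1]")
  if (p$Vmax1_base_low >= p$Vmax1_base_ref)
    abort("Vmax1_base_low must be below Vmax1_base_ref")
  if (p$KM1 <= 0 || p$KM5 <= 0 || p$K0 <= 0)
    abort("KM1, KM5 and K0 must be strictly positive")
  p
}

#' Variability ("random-effect") parameters
#'
#' Log-scale variances for interindividual variability (IIV) and residual
#' unexplained variability (RUV). IIV is supported on exactly the two
#' parameters retained in the final model: `Vmax1_base_ref` (reference
#' subpopulation only) and `Vmax5_2` (both subpopulations). Residual
#' variances are per species under the log-transform-both-sides model.
#' Defaults reproduce the reported coefficients of variation
#' (IIV 150% and 307%; RUV 59.1/85.9/120/70.6/115% for
#' TN/TCM/TEM/TEFF/CD19) via [cv_to_omega2()].
#'
#' @param omega2_Vmax1,omega2_Vmax5_2 IIV variances (log scale).
#' @param sigma2 named numeric of residual variances for species
#'   `TN, TCM, TEM, TEFF, CD19`.
#' @return A list of class `qsp_variability`.
#' @export
qsp_variability <- function(omega2_Vmax1 = cv_to_omega2(150),
                            omega2_Vmax5_2 = cv_to_omega2(307),
                            sigma2 = c(TN = cv_to_omega2(59.1),
                                       TCM = cv_to_omega2(85.9),
                                       TEM = cv_to_omega2(120),
                                       TEFF = cv_to_omega2(70.6),
                                       CD19 = cv_to_omega2(115))) {
  stopifnot(omega2_Vmax1 >= 0, omega2_Vmax5_2 >= 0, all(sigma2 >= 0))
  if (!all(.qsp_species %in% names(sigma2)))
    abort("sigma2 must be named for all species TN, TCM, TEM, TEFF, CD19")
  structure(list(omega2_Vmax1 = omega2_Vmax1,
                 omega2_Vmax5_2 = omega2_Vmax5_2,
                 sigma2 = sigma2[.qsp_species]),
            class = "qsp_variability")
}

#' Read / write a flat key-value parameter configuration
#'
#' Parameter files are flat YAML maps whose keys are exactly the
#' [qsp_params()] fields, optionally together with variability keys
#' (`omega2_Vmax1`, `omega2_Vmax5_2`, `sigma2_TN` .. `sigma2_CD19`).
#' The packaged default (`system.file("extdata", "default_params.yaml",
#' package = "cartqsp")`) reproduces the final published estimates.
#'
#' @param path file path.
#' @return `read_qsp_config()`: a list with elements `params`
#'   ([qsp_params()]) and `variability` ([qsp_variability()]).
#' @export
read_qsp_config <- function(path) {
  kv <- yaml::read_yaml(path)
  pn <- setdiff(names(qsp_params()), "expansion_denominator")
  pargs <- kv[intersect(names(kv), pn)]
  if ("expansion_denominator" %in% names(kv))
    pargs$expansion_denominator <- kv$expansion_denominator
  params <- do.call(qsp_params, pargs)
  sig <- qsp_variability()$sigma2
  for (s in .qsp_species) {
    key <- paste0("sigma2_", s)
    if (key %in% names(kv)) sig[[s]] <- kv[[key]]
  }
  variability <- qsp_variability(
    omega2_Vmax1 = kv$omega2_Vmax1 %||% qsp_variability()$omega2_Vmax1,
    omega2_Vmax5_2 = kv$omega2_Vmax5_2 %||% qsp_variability()$omega2_Vmax5_2,
    sigma2 = sig)
  list(params = params, variability = variability)
}

#' @rdname read_qsp_config
#' @param params a [qsp_params()] object.
#' @param variability a [qsp_variability()] object.
#' @export
write_qsp_config <- function(params, variability = qsp_variability(), path) {
  kv <- unclass(params)
  kv$omega2_Vmax1 <- variability$omega2_Vmax1
  kv$omega2_Vmax5_2 <- variability$omega2_Vmax5_2
  for (s in .qsp_species) kv[[paste0("sigma2_", s)]] <- unname(variability$sigma2[[s]])
  yaml::write_yaml(kv, path, precision = 12)
  invisible(path)
}
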