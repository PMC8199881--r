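#' Cell-kinetic metrics of a CAR-T concentration-time series
#'
#' Computes the maximum total CAR-T concentration (Cmax), its earliest
#' time (Tmax), the linear-trapezoid area under the curve from day 0 to 28
#' (AUC 0-28d), and Cmax normalized to baseline metabolic tumor volume.
#' For sparse observed series with no day-0 sample, the curve is anchored
#' at t = 0 with the summed imputed dose (0.4 cells/uL: 0.1 per phenotype);
#' the trapezoid is linearly interpolated/truncated at day 28. Model-basis
#' series are expected on a dense grid and are handled identically.
#'
#' @param series data frame with columns `time_days` and `conc` (total
#'   CAR-T cells, cells/uL), >= 2 points; values must be non-negative.
#' @param basis `"observed"` or `"model"` (recorded in the output).
#' @param baseline_mtv baseline metabolic tumor volume (mL), used for the
#'   `cmax_over_mtv` ratio (NA if missing).
#' @param dose_anchor concentration imputed at t = 0 when the series lacks
#'   a day-0 point (cells/uL); set `NULL` to disable anchoring.
#' @param horizon upper limit of the AUC window (days).
#' @return one-row tibble: `cmax`, `tmax`, `auc_0_28`, `cmax_over_mtv`,
#'   `basis`.
#' @export
#' @examples
#' kinetic_metrics(data.frame(time_days = c(7, 14, 28), conc = c(5, 10, 2)))
kinetic_metrics <- function(series, basis = c("observed", "model"),
                            baseline_mtv = NA_real_, dose_anchor = 0.4,
                            horizon = 28) {
  basis <- match.arg(basis)
  if (nrow(series) < 1) abort("empty concentration-time series")
  t <- series$time_days; y <- series$conc
  if (any(y < 0) || any(t < 0)) abort("times and concentrations must be >= 0")
  o <- order(t); t <- t[o]; y <- y[o]
  if (t[1] > 0 && !is.null(dose_anchor)) {
    t <- c(0, t); y <- c(dose_anchor, y)
  }
  if (length(t) < 2) abort("need at least 2 points")
  cmax <- max(y)
  tmax <- t[which.max(y)]
  tw <- pmin(t, horizon)
  keep <- t <= horizon
  if (!all(keep) && any(keep)) {
    k <- max(which(keep))
    y28 <- y[k] + (y[k + 1] - y[k]) * (horizon - t[k]) / (t[k + 1] - t[k])
    tt <- c(t[keep], horizon); yy <- c(y[keep], y28)
  } else {
    tt <- t[keep]; yy <- y[keep]
  }
  auc <- sum(diff(tt) * (head2(yy) + tail2(yy)) / 2)
  tibble(cmax = cmax, tmax = tmax, auc_0_28 = auc,
         cmax_over_mtv = cmax / baseline_mtv, basis = basis)
}

head2 <- function(x) x[-length(x)]
tail2 <- function(x) x[-1]

#' Total-CAR-T and per-phenotype kinetic metrics for every cohort patient
#'
#' Convenience wrapper: sums the four phenotype concentrations per sampling
#' day (observed basis), computes [kinetic_metrics()] per patient, and the
#' per-phenotype observed Cmax needed for the clinical composite score.
#'
#' @param cohort a [generate_cohort()] result (or a list with
#'   `observations` and `covariates`).
#' @param dose_anchor day-0 anchor for the summed curve (cells/uL).
#' @return tibble with one row per patient: kinetic metrics of the summed
#'   CAR-T curve plus `cmax_TN`, `cmax_TCM`, `cmax_TEM`, `cmax_TEFF` and
#'   the covariates.
#' @export
cohort_metrics <- function(cohort, dose_anchor = 0.4) {
  cells <- dplyr::filter(cohort$observations, .data$species != "CD19")
  tot <- cells |>
    dplyr::summarise(conc = sum(.data$value),
                     .by = c("patient_id", "time_days"))
  met <- tot |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(~ kinetic_metrics(.x, basis = "observed",
                                          dose_anchor = dose_anchor)) |>
    dplyr::ungroup()
  phen <- cells |>
    dplyr::summarise(cmax = max(.data$value),
                     .by = c("patient_id", "species")) |>
    tidyr::pivot_wider(names_from = "species", values_from = "cmax",
                       names_prefix = "cmax_")
  met |>
    dplyr::left_join(phen, by = "patient_id") |>
    dplyr::left_join(cohort$covariates, by = "patient_id") |>
    dplyr::mutate(cmax_over_mtv = .data$cmax / .data$baseline_mtv)
}

#' Clinical composite score
#'
#' `CCS = Cmax / baseline metabolic tumor volume`: the maximum observed
#' concentration of a CAR-T phenotype (cells/uL, or qPCR copies/ug DNA —
#' the score is unit-preserving) divided by baseline tumor volume (mL).
#' The score for the naive phenotype (CCS_TN) is the proposed early
#' survival predictor, with a published cut-off of 0.00136
#' (cells/uL)/mL.
#'
#' @param cmax maximum phenotype concentration.
#' @param baseline_mtv baseline metabolic tumor volume (mL), > 0.
#' @param cutoff optional cut-off; when given, the output gains an
#'   `exceeds_cutoff` flag.
#' @return tibble with `score` (and `exceeds_cutoff`); vectorized.
#' @export
#' @examples
#' ccs(10, 100)
#' ccs(0.002 * 100, 100, cutoff = 0.00136)
ccs <- function(cmax, baseline_mtv, cutoff = NULL) {
  if (any(baseline_mtv <= 0)) abort("baseline_mtv must be > 0")
  if (any(cmax < 0)) abort("cmax must be >= 0")
  out <- tibble(score = cmax / baseline_mtv)
  if (!is.null(cutoff)) out$exceeds_cutoff <- out$score > cutoff
  out
}

#' Empirical ROC curve and optimal cut-off
#'
#' Sweeps every candidate threshold between consecutive distinct scores,
#' computes sensitivity and specificity for detecting the positive class
#' (scores *below* the threshold are called positive when the positive
#' class has lower scores, controlled by `direction`), selects the optimal
#' cut-off by the Youden index (sensitivity + specificity - 1; ties broken
#' toward higher specificity), and integrates the ROC curve by trapezoid
#' for the AUC.
#'
#' @param scores numeric predictor values.
#' @param labels binary (logical or 0/1) indicator of the positive class
#'   (e.g. membership of the low-expansion subpopulation); both classes
#'   must be present.
#' @param criterion cut-off criterion; only `"youden"` is implemented.
#' @param direction `"auto"` chooses the orientation giving AUC >= 0.5;
#'   `"<"` calls scores below the cut-off positive, `">"` above.
#' @return list of class `qsp_roc`: `cutoff`, `sensitivity`,
#'   `specificity`, `auc`, `criterion`, `direction`, and the full `curve`
#'   tibble.
#' @export
roc_cutoff <- function(scores, labels, criterion = "youden",
                       direction = c("auto", "<", ">")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) abort("both classes must be present")
  if (length(scores) != length(labels)) abort("length mismatch")
  if (!identical(criterion, "youden")) abort("only the Youden criterion is implemented")

  sweep_dir <- function(dir) {
    s <- sort(unique(scores))
    thr <- c(min(s) - 1, (head2(s) + tail2(s)) / 2, max(s) + 1)
    pos <- labels; neg <- !labels
    sens <- spec <- numeric(length(thr))
    for (i in seq_along(thr)) {
      call_pos <- if (dir == "<") scores < thr[i] else scores > thr[i]
      sens[i] <- sum(call_pos & pos) / sum(pos)
      spec[i] <- sum(!call_pos & neg) / sum(neg)
    }
    curve <- tibble(threshold = thr, sensitivity = sens, specificity = spec)
    oc <- curve[order(1 - curve$specificity, curve$sensitivity), ]
    auc <- sum(diff(c(0, 1 - oc$specificity, 1)) *
                 (c(0, oc$sensitivity) + c(oc$sensitivity, 1)) / 2)
    list(curve = curve, auc = auc)
  }

  if (direction == "auto") {
    lo <- sweep_dir("<"); hi <- sweep_dir(">")
    if (lo$auc >= hi$auc) { direction <- "<"; sw <- lo } else { direction <- ">"; sw <- hi }
  } else sw <- sweep_dir(direction)

  youden <- sw$curve$sensitivity + sw$curve$specificity - 1
  best <- which(youden == max(youden))
  if (length(best) > 1) best <- best[which.max(sw$curve$specificity[best])]
  structure(list(cutoff = sw$curve$threshold[best],
                 sensitivity = sw$curve$sensitivity[best],
                 specificity = sw$curve$specificity[best],
                 auc = sw$auc, criterion = criterion, direction = direction,
                 curve = sw$curve),
            class = "qsp_roc")
}

#' @export
print.qsp_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f; %s cut-off %.5g (direction %s): sens %.3f, spec %.3f\n",
              x$auc, x$criterion, x$cutoff, x$direction, x$sensitivity,
              x$specificity))
  invisible(x)
}

#' @export
autoplot.qsp_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 3) +
    ggplot2::annotate("point", x = 1 - object$specificity,
                      y = object$sensitivity, colour = "red") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  subtitle = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves and log-rank comparison
#'
#' Product-limit survival estimates per group, median survival (the
#' earliest time at which estimated survival drops to 0.5 or below; when
#' never reached, reported as the explicit sentinel `"not reached"` with a
#' numeric `NA`), and the log-rank test; pairwise log-rank comparisons are
#' added when more than two groups are present.
#'
#' @param data data frame with columns `time` (>= 0) and `event` (0/1).
#' @param group vector (or column name in `data`) of group labels.
#' @return list of class `qsp_km`: `curves` tibble (group, time,
#'   survival, n_risk, n_event), `medians` tibble (group, median,
#'   median_label), `chisq`, `df`, `p_value`, and `pairwise` (tibble or
#'   NULL).
#' @export
km_logrank <- function(data, group) {
  if (is.character(group) && length(group) == 1) group <- data[[group]]
  group <- factor(group)
  if (any(table(group) == 0) || nlevels(group) < 1) abort("empty group")
  stopifnot(all(data$time >= 0), all(data$event %in% c(0, 1)))
  df <- data.frame(time = data$time, event = data$event, group = group)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  ss <- summary(sf)
  surv <- ss$surv %||% numeric(0) # summary() drops columns with no events
  strata <- if (is.null(ss$strata)) rep(levels(group)[1], length(surv))
            else sub("^group=", "", as.character(ss$strata))
  curves <- tibble(group = strata,
                   time = if (length(surv)) ss$time else numeric(0),
                   survival = surv,
                   n_risk = if (length(surv)) ss$n.risk else numeric(0),
                   n_event = if (length(surv)) ss$n.event else numeric(0))
  med <- purrr::map_dfr(levels(group), function(g) {
    cg <- curves[curves$group == g, ]
    m <- if (nrow(cg) && any(cg$survival <= 0.5))
      min(cg$time[cg$survival <= 0.5]) else NA_real_
    tibble(group = g, median = m,
           median_label = if (is.na(m)) "not reached" else format(m))
  })
  chisq <- df_lr <- p <- NA_real_
  pairwise <- NULL
  if (nlevels(group) >= 2) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    chisq <- sd$chisq; df_lr <- length(sd$n) - 1
    p <- pchisq(chisq, df_lr, lower.tail = FALSE)
    if (nlevels(group) > 2) {
      combs <- utils::combn(levels(group), 2, simplify = FALSE)
      pairwise <- purrr::map_dfr(combs, function(pr) {
        sub <- df[df$group %in% pr, ]
        sub$group <- droplevels(sub$group)
        sdi <- survival::survdiff(survival::Surv(time, event) ~ group,
                                  data = sub)
        tibble(group1 = pr[1], group2 = pr[2], chisq = sdi$chisq,
               p_value = pchisq(sdi$chisq, 1, lower.tail = FALSE))
      })
    }
  }
  structure(list(curves = curves, medians = med, chisq = chisq, df = df_lr,
                 p_value = p, pairwise = pairwise),
            class = "qsp_km")
}

#' @export
print.qsp_km <- function(x, ...) {
  print(x$medians)
  if (!is.na(x$chisq))
    cat(sprintf("log-rank chi-square %.3f (df %d), p = %.4g\n",
                x$chisq, x$df, x$p_value))
  invisible(x)
}

#' @export
autoplot.qsp_km <- function(object, ...) {
  step0 <- object$curves |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble(time = 0, survival = 1, n_risk = NA, n_event = NA), .x)) |>
    dplyr::ungroup()
  ggplot2::ggplot(step0, ggplot2::aes(.data$time, .data$survival,
                                      colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Univariate Cox proportional-hazards analysis
#'
#' Partial-likelihood hazard-ratio estimate (Breslow tie handling) for a
#' binary covariate, with Wald confidence interval and p-value, plus a
#' Schoenfeld-residual proportional-hazards check exposed as a diagnostic.
#' Monotone-likelihood separation (no events in one level, infinite
#' estimate) is flagged rather than silently reported.
#'
#' @param data data frame with `time` and `event`.
#' @param covariate binary vector (or column name) defining the two groups;
#'   the hazard ratio is for `TRUE`/1/second level relative to the other.
#' @param conf_level Wald confidence level.
#' @return one-row tibble: `hr`, `conf_low`, `conf_high`, `p_value`,
#'   `ph_test_p` (Schoenfeld), `separation` flag.
#' @export
cox_hr <- function(data, covariate, conf_level = 0.95) {
  if (is.character(covariate) && length(covariate) == 1)
    covariate <- data[[covariate]]
  x <- as.numeric(as.logical(covariate))
  if (length(unique(x)) < 2) abort("both covariate levels must be present")
  df <- data.frame(time = data$time, event = data$event, x = x)
  if (sum(df$event) < 1) abort("at least one event is required")
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = df,
                         ties = "breslow")
  beta <- unname(coef(fit)); se <- sqrt(unname(fit$var[1, 1]))
  separation <- !is.finite(beta) || abs(beta) > 15 || !is.finite(se)
  if (separation) warn("monotone likelihood / separation: hazard ratio unreliable")
  z <- qnorm(1 - (1 - conf_level) / 2)
  ph_p <- tryCatch(survival::cox.zph(fit)$table["x", "p"],
                   error = function(e) NA_real_)
  tibble(hr = exp(beta), conf_low = exp(beta - z * se),
         conf_high = exp(beta + z * se),
         p_value = 2 * pnorm(-abs(beta / se)),
         ph_test_p = ph_p, separation = separation)
}

#' Hazard ratio to percent risk reduction
#'
#' `(1 - HR) * 100`, rounded to the nearest integer percent (report
#' convention); e.g. HR 0.17 is an 83% reduced risk.
#'
#' @param hr hazard ratio, > 0.
#' @return percent risk reduction (negative for HR > 1); vectorized.
#' @export
#' @examples
#' hr_to_risk_reduction(c(0.17, 0.12))
hr_to_risk_reduction <- function(hr) {
  if (any(hr <= 0)) abort("hazard ratio must be > 0")
  round((1 - hr) * 100)
}

#' Two-group rank-sum comparison
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of a continuous metric
#' between two patient groups.
#'
#' @param values_a,values_b numeric vectors, >= 2 values each.
#' @return one-row tibble: `statistic` (W), `p_value`.
#' @export
group_compare <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  wt <- suppressWarnings(wilcox.test(values_a, values_b,
                                     alternative = "two.sided", exact = NULL))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Pearson correlation, optionally on the log10 scale
#'
#' Used for the expansion-rate vs composite-score correlations (raw scale
#' for flow-cytometry scores; both variables log10-transformed for the
#' qPCR-vs-flow comparison).
#'
#' @param x,y numeric vectors, >= 3 pairs, non-constant.
#' @param log10_scale transform both variables by log10 first (requires
#'   positive values).
#' @return one-row tibble: `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y, log10_scale = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (log10_scale) {
    stopifnot(all(x > 0), all(y > 0))
    x <- log10(x); y <- log10(y)
  }
  if (sd(x) == 0 || sd(y) == 0) abort("constant input: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
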