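test_that("kinetic metrics match hand trapezoid arithmetic", {
  ser <- data.frame(time_days = c(0, 7, 14, 28), conc = c(0.4, 5, 10, 2))
  m <- kinetic_metrics(ser)
  expect_equal(m$cmax, 10)
  expect_equal(m$tmax, 14)
  expect_equal(m$auc_0_28, 155.4)
  # anchoring at the summed imputed dose when day 0 is absent
  m2 <- kinetic_metrics(data.frame(time_days = c(7, 14, 28),
                                   conc = c(5, 10, 2)))
  expect_equal(m2$auc_0_28, 155.4)
  # constant series: AUC = 28 * c
  mc <- kinetic_metrics(data.frame(time_days = c(0, 10, 28), conc = 3),
                        dose_anchor = NULL)
  expect_equal(mc$auc_0_28, 84)
  # truncation at day 28 via interpolation
  mt <- kinetic_metrics(data.frame(time_days = c(0, 14, 42), conc = c(0, 7, 7)),
                        dose_anchor = NULL)
  expect_equal(mt$auc_0_28, 49 + 7 * 14)
  # earliest argmax wins
  me <- kinetic_metrics(data.frame(time_days = c(0, 5, 10), conc = c(0, 4, 4)),
                        dose_anchor = NULL)
  expect_equal(me$tmax, 5)
  expect_error(kinetic_metrics(data.frame(time_days = numeric(),
                                          conc = numeric())), "empty")
  expect_error(kinetic_metrics(data.frame(time_days = 1, conc = -2)), ">= 0")
})

test_that("model-basis metrics on a dense grid match observed-basis on that grid", {
  tr <- simulate_patient(make_individual(baseline_mtv = 100), qsp_params(),
                         t_end = 28, grid_step = 0.1)
  ser <- data.frame(time_days = tr$time_days,
                    conc = rowSums(tr[, c("TN", "TCM", "TEM", "TEFF")]))
  m_model <- kinetic_metrics(ser, basis = "model", baseline_mtv = 100)
  m_obs <- kinetic_metrics(ser, basis = "observed", baseline_mtv = 100)
  expect_equal(m_model$cmax, m_obs$cmax, tolerance = 1e-3)
  expect_equal(m_model$auc_0_28, m_obs$auc_0_28, tolerance = 1e-3)
  expect_equal(m_model$cmax_over_mtv, m_model$cmax / 100)
})

test_that("clinical composite score is a unit-preserving ratio", {
  expect_equal(ccs(10, 100)$score, 0.1)
  expect_equal(ccs(0, 50)$score, 0)
  expect_error(ccs(1, 0), "baseline_mtv")
  # homogeneity: degree 1 in cmax, degree -1 in baseline volume
  s <- ccs(3.2, 410)$score
  expect_equal(ccs(2 * 3.2, 410)$score, 2 * s)
  expect_equal(ccs(3.2, 2 * 410)$score, s / 2)
  # published cut-off flag
  flag <- ccs(0.002 * 100, 100, cutoff = 0.00136)
  expect_true(flag$exceeds_cutoff)
  expect_false(ccs(0.001 * 100, 100, cutoff = 0.00136)$exceeds_cutoff)
})

# Mann-Whitney pair-counting AUC: independent oracle
pair_count_auc <- function(scores, labels, direction = "<") {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  tot <- 0
  for (a in pos) for (b in neg) {
    cmp <- if (direction == "<") (a < b) + 0.5 * (a == b)
           else (a > b) + 0.5 * (a == b)
    tot <- tot + cmp
  }
  tot / (length(pos) * length(neg))
}

test_that("ROC analysis agrees with pair-counting and pROC oracles", {
  # perfect separation
  r <- roc_cutoff(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 0, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  # 6-point toy equals exhaustive pair counting
  sc <- c(0.1, 0.4, 0.35, 0.8, 0.7, 0.2); lb <- c(1, 1, 0, 0, 0, 1)
  r2 <- roc_cutoff(sc, lb, direction = "<")
  expect_equal(r2$auc, pair_count_auc(sc, lb, "<"))
  # random tie-free data: trapezoid AUC == pair-count AUC exactly; also pROC
  set.seed(90)
  for (i in 1:10) {
    s <- rnorm(30); l <- rbinom(30, 1, 0.4)
    if (length(unique(l)) < 2) next
    r3 <- roc_cutoff(s, l, direction = ">")
    expect_equal(r3$auc, pair_count_auc(s, l, ">"), tolerance = 1e-12)
    pr <- pROC::roc(l, s, direction = "<", quiet = TRUE)
    expect_equal(r3$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  }
  # independent labels: AUC near 0.5
  set.seed(91)
  s <- rnorm(2000); l <- rbinom(2000, 1, 0.5)
  expect_equal(roc_cutoff(s, l)$auc, 0.5, tolerance = 0.1)
  expect_error(roc_cutoff(1:5, rep(1, 5)), "both classes")
})

test_that("ROC Youden cut-off breaks ties toward higher specificity", {
  # two thresholds reach the same Youden index; the one with higher
  # specificity must win
  sc <- c(1, 2, 3, 4); lb <- c(1, 0, 1, 0)
  r <- roc_cutoff(sc, lb, direction = "<")
  expect_equal(r$sensitivity, 0.5)
  expect_equal(r$specificity, 1)
  expect_true(r$cutoff > 1 && r$cutoff < 2)
})

# hand-computed log-rank statistic via the hypergeometric sum
logrank_by_hand <- function(time, event, group) {
  g1 <- levels(factor(group))[1]
  o_sum <- e_sum <- v_sum <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o_sum <- o_sum + d1
    e_sum <- e_sum + d * n1 / n
    if (n > 1) v_sum <- v_sum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_sum - e_sum)^2 / v_sum
}

test_that("Kaplan-Meier and log-rank match the hand-computed oracle", {
  # no events: survival stays 1, median not reached
  km0 <- km_logrank(data.frame(time = 1:6, event = 0), rep("A", 6))
  expect_true(all(km0$medians$median_label == "not reached"))
  # 6-subject worked set
  d <- data.frame(time = 1:6, event = 1)
  g <- rep(c("A", "B"), 3)
  km <- km_logrank(d, g)
  expect_equal(km$chisq, logrank_by_hand(d$time, d$event, g),
               tolerance = 1e-10)
  # KM without censoring equals the empirical survival function
  km1 <- km_logrank(data.frame(time = c(1, 2, 3, 4), event = 1),
                    rep("A", 4))
  expect_equal(km1$curves$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(km1$medians$median, 2)  # earliest time with S <= 0.5
  expect_error(km_logrank(data.frame(time = 1, event = 1), character(0)))
})

test_that("log-rank p-values are roughly uniform under the null", {
  set.seed(140)
  ps <- replicate(120, {
    tm <- rexp(40, 0.1); ev <- as.integer(tm < 15); tm <- pmin(tm, 15)
    km_logrank(data.frame(time = tm, event = ev),
               sample(rep(c("A", "B"), 20)))$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("Cox hazard ratios recover known truth and respect symmetry", {
  set.seed(150)
  # null: HR near 1
  tm <- rexp(600, 0.1); grp <- rep(c(0, 1), 300)
  h0 <- cox_hr(data.frame(time = tm, event = 1), grp)
  expect_equal(h0$hr, 1, tolerance = 0.25)
  # true rate ratio 4
  tm4 <- c(rexp(250, 0.05), rexp(250, 0.2)); grp4 <- rep(c(0, 1), each = 250)
  h4 <- cox_hr(data.frame(time = tm4, event = 1), grp4)
  expect_gt(h4$hr, 3); expect_lt(h4$hr, 5.3)
  # relabeling inverts the hazard ratio
  hflip <- cox_hr(data.frame(time = tm4, event = 1), 1 - grp4)
  expect_equal(hflip$hr, 1 / h4$hr, tolerance = 1e-8)
  expect_error(cox_hr(data.frame(time = tm4, event = 1), rep(1, 500)),
               "both covariate levels")
})

test_that("hazard ratios translate to the reported risk reductions", {
  expect_equal(hr_to_risk_reduction(1), 0)
  expect_equal(hr_to_risk_reduction(0.17), 83)
  expect_equal(hr_to_risk_reduction(0.12), 88)
  expect_equal(hr_to_risk_reduction(2), -100)
  expect_error(hr_to_risk_reduction(0), "> 0")
})

test_that("rank-sum comparison agrees with exhaustive permutation", {
  a <- c(1.2, 3.4, 2.2, 5.1); b <- c(0.8, 4.0, 6.3, 7.7)
  p_pkg <- group_compare(a, b)$p_value
  # enumerate all 8-choose-4 group assignments of the pooled data
  pool <- c(a, b)
  w_obs <- sum(rank(pool)[1:4])
  combos <- utils::combn(8, 4)
  ws <- apply(combos, 2, function(idx) sum(rank(pool)[idx]))
  mu <- mean(ws)
  p_exact <- mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
  expect_equal(p_pkg, p_exact, tolerance = 1e-10)
  # identical groups: no evidence of a difference
  expect_gt(group_compare(c(1, 2, 3), c(1, 2, 3))$p_value, 0.9)
})

test_that("Pearson correlation handles raw and log10 scales", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x)$r, 1)
  # log10 on both axes linearizes a power law
  y <- 10^(0.5 * log10(x) + 0.2)
  expect_equal(pearson_r(x, y, log10_scale = TRUE)$r, 1, tolerance = 1e-12)
  expect_error(pearson_r(x, rep(2, 5)), "constant")
})
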