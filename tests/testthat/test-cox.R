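test_that("Cox fit matches grid maximization of the hand-written partial likelihood", {
  s <- three_subject_sample()
  spec <- cox_model_spec("pdi", model = 1)
  expect_warning(
    fit <- fit_cox(s, spec, exposure_override = c(1, 0, 1)),
    "constant")
  beta_hat <- fit$coef_table$coef[fit$coef_table$term == "exposure"]
  beta_grid <- stats::optimize(logpl_3subject, c(-5, 5), maximum = TRUE)$maximum
  expect_equal(beta_hat, beta_grid, tolerance = 1e-6)
  expect_equal(beta_hat, -0.5 * log(2), tolerance = 1e-4)  # closed form
  expect_equal(fit$coef_table$hr[1], exp(beta_hat))
})

test_that("constant covariates are dropped with a warning, never fitted", {
  s <- direct_sample(200, function(z) -0.3 * z, seed = 5)
  s$met <- 100
  spec <- cox_model_spec("pdi", "per_sd", model = 2)
  expect_warning(fit <- fit_cox(s, spec), "met")
  expect_false("met" %in% fit$coef_table$term)
})

test_that("a single-event sample is refused", {
  s <- direct_sample(30, seed = 8)
  s$event <- c(TRUE, rep(FALSE, 29))
  expect_error(fit_cox(s, cox_model_spec("pdi", "per_sd", model = 1)),
               "insufficient events")
})

test_that("null fits are calibrated: |beta| < 3 SE in nearly all replicates", {
  hits <- vapply(1:10, function(r) {
    s <- direct_sample(300, function(z) 0 * z, seed = 100 + r)
    fit <- fit_cox(s, cox_model_spec("pdi", "per_sd", model = 1))
    row <- fit$coef_table[fit$coef_table$term == "exposure", ]
    abs(row$coef) < 3 * row$se
  }, logical(1))
  expect_gte(sum(hits), 9L)
})

test_that("rescaling a covariate rescales its coefficient exactly inversely", {
  s <- direct_sample(250, function(z) -0.4 * z, seed = 3)
  spec <- cox_model_spec("pdi", model = 1)
  f1 <- fit_cox(s, spec, exposure_override = s$pdi_z)
  f2 <- fit_cox(s, spec, exposure_override = 2 * s$pdi_z)
  b1 <- f1$coef_table$coef[f1$coef_table$term == "exposure"]
  b2 <- f2$coef_table$coef[f2$coef_table$term == "exposure"]
  expect_equal(b2, b1 / 2, tolerance = 1e-8)
})

test_that("quintile HRs: Q1 is the reference and a monotone effect orders Q5 below Q2", {
  s <- direct_sample(4000, function(z) -0.35 * z, seed = 7)
  fit <- fit_cox(s, cox_model_spec("pdi", "quintile", model = 1))
  hr <- hr_quintiles(fit)
  expect_identical(hr$hr[1], 1)
  expect_true(is.na(hr$p[1]))
  expect_true(all(hr$hr[2:5] > 0))
  expect_lt(hr$hr[5], hr$hr[2])
  expect_true(all(hr$lower[2:5] < hr$hr[2:5] & hr$hr[2:5] < hr$upper[2:5]))
})

test_that("trend test substitutes each quintile's median score as a continuous exposure", {
  s <- direct_sample(400, function(z) -0.3 * z, seed = 21)
  medians <- c(Q1 = 15, Q2 = 18, Q3 = 20, Q4 = 23, Q5 = 27)
  spec <- cox_model_spec("pdi", model = 1)
  tr <- trend_test(s, spec, medians = medians)
  manual <- fit_cox(s, spec, exposure_override = unname(medians[s$pdi_q]))
  expect_equal(tr$coef,
               manual$coef_table$coef[manual$coef_table$term == "exposure"])
  expect_equal(tr$p_trend,
               manual$coef_table$p[manual$coef_table$term == "exposure"])
  expect_error(trend_test(s, spec, medians = rep(20, 5)), "undefined")
})

test_that("per-SD HR equals the raw-index HR taken to the power of the SD", {
  s <- direct_sample(500, function(z) -0.25 * z, seed = 33)
  spec <- cox_model_spec("pdi", model = 2)
  per_sd <- hr_per_sd(s, spec)
  raw <- fit_cox(s, spec, exposure_override = s$pdi_total)
  b_raw <- raw$coef_table$coef[raw$coef_table$term == "exposure"]
  expect_equal(log(per_sd$hr), b_raw * stats::sd(s$pdi_total),
               tolerance = 1e-6)
})

test_that("spline curve is 1 at the reference and tracks a linear log-hazard", {
  beta <- -0.35
  s <- direct_sample(3000, function(z) beta * z, seed = 9)
  rc <- fit_rcs(s, cox_model_spec("pdi", model = 3, include_bp = TRUE))
  ref <- attr(rc, "ref_value")
  expect_identical(rc$hr[rc$index == ref], 1)
  expect_true(all(rc$lower <= rc$hr & rc$hr <= rc$upper))
  # true per-point log-HR: beta / SD(total); check CI coverage on inner 90%
  slope <- beta / stats::sd(s$pdi_total)
  inner <- rc$index >= stats::quantile(s$pdi_total, 0.05) &
           rc$index <= stats::quantile(s$pdi_total, 0.95)
  true_hr <- exp(slope * (rc$index - ref))
  covered <- rc$lower <= true_hr & true_hr <= rc$upper
  expect_gte(mean(covered[inner]), 0.9)
})

test_that("a U-shaped log-hazard yields a spline minimum interior to the index range", {
  s <- direct_sample(4000, function(z) 0.4 * z^2, seed = 15, base_rate = 0.05)
  rc <- fit_rcs(s, cox_model_spec("pdi", model = 1))
  i_min <- which.min(rc$hr)
  expect_gt(i_min, 1L)
  expect_lt(i_min, nrow(rc))
  inner_range <- stats::quantile(s$pdi_total, c(0.15, 0.85))
  expect_gte(rc$index[i_min], inner_range[[1]])
  expect_lte(rc$index[i_min], inner_range[[2]])
})

test_that("the spline basis spans the same model space as splines::ns", {
  skip_if_not_installed("splines")
  s <- direct_sample(800, function(z) -0.3 * z, seed = 26)
  x <- s$pdi_total
  knots <- unname(quantile(x, c(0.05, 0.35, 0.65, 0.95)))
  b1 <- rcs_basis(x, knots)
  b2 <- splines::ns(x, knots = knots[2:3], Boundary.knots = knots[c(1, 4)])
  surv <- survival::Surv(s$follow_up_years, s$event)
  ll1 <- survival::coxph(surv ~ b1)$loglik[2]
  ll2 <- survival::coxph(surv ~ b2)$loglik[2]
  expect_equal(ll1, ll2, tolerance = 1e-8)
})

test_that("too few distinct index values for the knots is an explicit error", {
  s <- direct_sample(100, seed = 2)
  s$pdi_total <- rep(c(50L, 51L), 50)
  expect_error(fit_rcs(s, cox_model_spec("pdi", model = 1)), "fewer knots")
})

test_that("log-time interactions flag a strongly time-decaying hazard ratio", {
  set.seed(44)
  n <- 1200
  s <- direct_sample(n, seed = 44)
  x <- rep(c(1, 0), n / 2)
  # group 1 has events concentrated early, group 0 late: PH clearly violated
  tt <- ifelse(x == 1, rexp(n, 0.9), 2 + rexp(n, 0.9))
  s$follow_up_years <- pmin(tt, 8)
  s$event <- tt <= 8
  fit <- fit_cox(s, cox_model_spec("pdi", model = 1), exposure_override = x)
  ph <- test_ph(fit)
  expect_lt(ph$p[ph$term == "exposure"], 0.05)
  expect_true(all(c("age", "male") %in% ph$term))
})

test_that("proportional-hazards data rarely trips the PH check", {
  rejections <- vapply(1:20, function(r) {
    s <- direct_sample(250, function(z) -0.2 * z, seed = 200 + r)
    fit <- fit_cox(s, cox_model_spec("pdi", "per_sd", model = 1))
    ph <- test_ph(fit)
    ph$p[ph$term == "exposure"] < 0.05
  }, logical(1))
  expect_lte(sum(rejections), 5L)
})

test_that("strata partition the sample; zero-event strata are skipped with a warning", {
  s <- direct_sample(1500, function(z) -0.3 * z, seed = 18)
  spec <- cox_model_spec("pdi", "quintile", model = 1)
  st <- stratified_analysis(s, spec, by = "age")
  expect_identical(st[[1]]$n + st[[2]]$n, nrow(s))
  expect_identical(st[["age<55"]]$hr$hr[1], 1)
  # within sex strata the sex covariate is constant and dropped (classed warning)
  st_sex <- suppressWarnings(stratified_analysis(s, spec, by = "sex"),
                             classes = "pdicohort_constant_covariate")
  expect_identical(st_sex$male$n + st_sex$female$n, nrow(s))
  s$event[!s$male] <- FALSE
  expect_warning(st2 <- suppressWarnings(
    stratified_analysis(s, spec, by = "sex"),
    classes = "pdicohort_constant_covariate"),
    "skipped")
  expect_true(is.na(st2$female$p_trend))
  expect_null(st2$female$hr)
})
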