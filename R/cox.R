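#' Specification of a Cox model run
#'
#' Encodes the exposure form and the nested covariate sets: model 1 adjusts
#' for urban/rural, age, sex and total energy intake; model 2 additionally
#' for education, physical activity, smoking and alcohol; model 3
#' additionally for BMI (and baseline systolic/diastolic blood pressure when
#' `include_bp = TRUE`, as in the spline and ROC runs).
#'
#' @param index which diet index drives the exposure: `"pdi"` or `"hpdi"`.
#' @param exposure `"quintile"` (categorical, Q1 reference), `"per_sd"`
#'   (standardized continuous) or `"none"` (covariates only).
#' @param model covariate set, 1–3.
#' @param ties tie handling for the partial likelihood; wave-year event
#'   times are heavily tied, so Efron is the default.
#' @param include_bp add baseline SBP/DBP to the model-3 set.
#' @return list of class `cox_model_spec`.
#' @export
cox_model_spec <- function(index = c("pdi", "hpdi"),
                           exposure = c("quintile", "per_sd", "none"),
                           model = 3L,
                           ties = c("efron", "breslow"),
                           include_bp = FALSE) {
  spec <- list(index = match.arg(index), exposure = match.arg(exposure),
               model = as.integer(model), ties = match.arg(ties),
               include_bp = include_bp)
  if (!spec$model %in% 1:3) stop("model must be 1, 2 or 3")
  class(spec) <- "cox_model_spec"
  spec
}

# numeric design matrix for a spec; factors expanded to dummies
build_design <- function(sample, spec, exposure_override = NULL) {
  X <- data.frame(row.names = seq_len(nrow(sample)))
  if (!is.null(exposure_override)) {
    X$exposure <- exposure_override
  } else if (spec$exposure == "quintile") {
    q <- sample[[paste0(spec$index, "_q")]]
    for (k in 2:5) X[[paste0("exposure_Q", k)]] <- as.numeric(q == k)
  } else if (spec$exposure == "per_sd") {
    X$exposure <- sample[[paste0(spec$index, "_z")]]
  }
  X$age <- sample$age
  X$male <- as.numeric(sample$male)
  X$rural <- as.numeric(sample$rural)
  X$total_energy <- sample$total_energy
  if (spec$model >= 2L) {
    for (k in 2:4) X[[paste0("edu_", k)]] <- as.numeric(sample$education == k)
    X$met <- sample$met
    X$smoking <- as.numeric(sample$smoking)
    X$alcohol <- as.numeric(sample$alcohol)
  }
  if (spec$model >= 3L) {
    X$bmi <- sample$bmi
    if (isTRUE(spec$include_bp)) {
      X$sbp <- sample$sbp
      X$dbp <- sample$dbp
    }
  }
  X
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood (Efron tie correction by default)
#' on the follow-up-years time scale, with Wald 95% confidence intervals.
#' Constant covariates are dropped with a warning; coefficients driven to
#' +/- infinity by monotone likelihood are flagged non-estimable.
#'
#' @param sample an `analysis_sample` (or any data frame with
#'   `follow_up_years`, `event` and the spec's covariates).
#' @param spec a [cox_model_spec()].
#' @param exposure_override optional numeric vector replacing the exposure
#'   term (used by the trend test).
#' @return object of class `pdi_coxfit`: the `survival::coxph` fit plus a
#'   coefficient table (`term`, `coef`, `se`, `hr`, `lower`, `upper`, `p`,
#'   `estimable`), the design data, `n`, `events`, `loglik`.
#' @export
fit_cox <- function(sample, spec, exposure_override = NULL) {
  events <- sum(sample$event)
  if (events < 2L) stop("insufficient events to fit a Cox model (need >= 2)")
  X <- build_design(sample, spec, exposure_override)

  constant <- vapply(X, function(x) length(unique(x)) < 2L, logical(1))
  if (any(constant)) {
    warning(warningCondition(
      paste("dropping constant covariate(s):",
            paste(names(X)[constant], collapse = ", ")),
      class = "pdicohort_constant_covariate"))
    X <- X[, !constant, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("no non-constant covariates left to fit")

  dat <- cbind(data.frame(.time = sample$follow_up_years,
                          .event = as.numeric(sample$event)), X)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~", paste(names(X), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = spec$ties)

  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  estimable <- is.finite(beta) & abs(beta) < 15 & is.finite(se)
  if (!all(estimable)) {
    warning("non-estimable coefficient(s) (monotone likelihood?): ",
            paste(names(beta)[!estimable], collapse = ", "))
  }
  tab <- data.frame(
    term = names(beta), coef = unname(beta), se = unname(se),
    hr = exp(unname(beta)),
    lower = exp(unname(beta) - 1.96 * unname(se)),
    upper = exp(unname(beta) + 1.96 * unname(se)),
    p = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
    estimable = unname(estimable)
  )
  structure(list(fit = fit, coef_table = tab, data = dat, spec = spec,
                 n = nrow(dat), events = events,
                 loglik = fit$loglik[length(fit$loglik)]),
            class = "pdi_coxfit")
}

#' @export
print.pdi_coxfit <- function(x, ...) {
  cat(sprintf("Cox fit: n = %d, events = %d, ties = %s\n",
              x$n, x$events, x$spec$ties))
  print(x$coef_table, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Hazard ratios for exposure quintiles Q2..Q5 vs Q1
#'
#' Q1 is the reference (HR exactly 1, no CI). Quintile levels absent from
#' the sample are reported as absent rows (NA), never imputed.
#'
#' @param fit a `pdi_coxfit` with quintile-categorical exposure.
#' @return data frame with rows Q1..Q5: `quintile`, `hr`, `lower`, `upper`,
#'   `p`.
#' @export
hr_quintiles <- function(fit) {
  if (fit$spec$exposure != "quintile") {
    stop("hr_quintiles requires a quintile-categorical fit")
  }
  out <- data.frame(quintile = paste0("Q", 1:5),
                    hr = c(1, rep(NA_real_, 4)),
                    lower = NA_real_, upper = NA_real_, p = NA_real_)
  tab <- fit$coef_table
  for (k in 2:5) {
    row <- tab[tab$term == paste0("exposure_Q", k), ]
    if (nrow(row) == 1L) {
      out[k, c("hr", "lower", "upper", "p")] <-
        row[, c("hr", "lower", "upper", "p")]
    }
  }
  out
}

#' Linear trend test across index quintiles
#'
#' Replaces each participant's exposure by their quintile's median index
#' total and enters that variable continuously into the same-covariate Cox
#' model; the Wald p-value of its coefficient is the p-trend.
#'
#' @param sample an `analysis_sample`.
#' @param spec a [cox_model_spec()] (its `exposure` is ignored).
#' @param medians per-quintile median index totals; defaults to the medians
#'   stored on the sample for the spec's index.
#' @return list: `coef`, `se`, `p_trend`, `medians`, `fit`.
#' @export
trend_test <- function(sample, spec, medians = NULL) {
  if (is.null(medians)) {
    medians <- attr(sample, paste0("medians_", spec$index))
  }
  if (is.null(medians)) stop("no quintile medians available for the trend test")
  if (length(unique(stats::na.omit(medians))) < 2L) {
    stop("all quintile medians equal: trend undefined")
  }
  q <- sample[[paste0(spec$index, "_q")]]
  fit <- fit_cox(sample, spec, exposure_override = unname(medians[q]))
  row <- fit$coef_table[fit$coef_table$term == "exposure", ]
  list(coef = row$coef, se = row$se, p_trend = row$p,
       medians = medians, fit = fit)
}

#' Hazard ratio per 1 SD increase of the index
#'
#' Fits the Cox model on the sample-standardized index; `exp(beta)` is the
#' HR per SD.
#'
#' @inheritParams trend_test
#' @return list: `hr`, `lower`, `upper`, `p`, `fit`.
#' @export
hr_per_sd <- function(sample, spec) {
  spec$exposure <- "per_sd"
  fit <- fit_cox(sample, spec)
  row <- fit$coef_table[fit$coef_table$term == "exposure", ]
  list(hr = row$hr, lower = row$lower, upper = row$upper, p = row$p,
       fit = fit)
}

#' Proportional-hazards check via log-time interactions
#'
#' Augments every model term with a `term * log(t)` time-dependent
#' interaction and reports the Wald p-value per interaction; a small p flags
#' a PH violation for that term.
#'
#' @param fit a `pdi_coxfit`.
#' @return data frame: `term`, `coef_tt`, `se_tt`, `p`.
#' @export
test_ph <- function(fit) {
  terms <- setdiff(names(fit$data), c(".time", ".event"))
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(terms, collapse = " + "), "+",
    paste(sprintf("tt(%s)", terms), collapse = " + ")))
  refit <- survival::coxph(fml, data = fit$data, ties = fit$spec$ties,
                           tt = function(x, t, ...) x * log(t))
  beta <- stats::coef(refit)
  se <- sqrt(diag(stats::vcov(refit)))
  tt_idx <- grep("^tt\\(", names(beta))
  data.frame(
    term = sub("^tt\\((.*)\\)$", "\\1", names(beta)[tt_idx]),
    coef_tt = unname(beta[tt_idx]),
    se_tt = unname(se[tt_idx]),
    p = 2 * stats::pnorm(-abs(unname(beta[tt_idx] / se[tt_idx])))
  )
}

#' Quintile hazard ratios and trend tests within strata
#'
#' Re-runs the quintile Cox model and trend test within each stratum of sex
#' or age (<55 / >=55 years). Exposure quintiles are NOT recomputed within
#' strata: the parent sample's categories are kept so strata remain
#' comparable. Strata with fewer than 2 events are skipped with a warning.
#'
#' @param sample an `analysis_sample`.
#' @param spec a [cox_model_spec()] with quintile exposure.
#' @param by `"sex"` or `"age"`.
#' @param age_cut age threshold (default 55).
#' @return named list per stratum: `n`, `events`, `hr` (quintile table),
#'   `p_trend` (NA when skipped).
#' @export
stratified_analysis <- function(sample, spec, by = c("sex", "age"),
                                age_cut = 55) {
  by <- match.arg(by)
  groups <- if (by == "sex") {
    list(male = sample$male, female = !sample$male)
  } else {
    list(`age<55` = sample$age < age_cut, `age>=55` = sample$age >= age_cut)
  }
  lapply(groups, function(in_stratum) {
    sub <- sample[in_stratum, , drop = FALSE]
    for (a in c("outcome", "medians_pdi", "medians_hpdi")) {
      attr(sub, a) <- attr(sample, a)
    }
    ev <- sum(sub$event)
    if (nrow(sub) == 0L || ev < 2L) {
      warning("stratum with <2 events skipped")
      return(list(n = nrow(sub), events = ev, hr = NULL, p_trend = NA_real_))
    }
    fit <- fit_cox(sub, spec)
    tr <- trend_test(sub, spec)
    list(n = nrow(sub), events = ev, hr = hr_quintiles(fit),
         p_trend = tr$p_trend)
  })
}
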