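#' Generate baseline covariate records
#'
#' Draws the baseline cohort: demographics, lifestyle covariates, prevalent
#' cardiovascular disease / cancer flag, and which of the two baseline diet
#' years each participant attended (a configurable fraction has only one).
#'
#' @param config a [sim_config()].
#' @return data frame, one row per participant: `participant_id`, `male`,
#'   `age`, `rural`, `education` (1–4), `met`, `smoking`, `alcohol`,
#'   `cvd_cancer`, `baseline_year`, `has_year1`, `has_year2`.
#' @export
generate_participants <- function(config) {
  validate_sim_config(config)
  set.seed(sub_seed(config$seed, 1L))
  n <- config$n_participants
  cp <- config$covariate_params
  yrs <- baseline_diet_years(config)

  # truncated-normal ages via inverse CDF
  lo <- stats::pnorm(cp$age_min, cp$age_mean, cp$age_sd)
  hi <- stats::pnorm(cp$age_max, cp$age_mean, cp$age_sd)
  age <- stats::qnorm(stats::runif(n, lo, hi), cp$age_mean, cp$age_sd)

  single <- stats::runif(n) < config$p_single_baseline_year
  which_single <- stats::runif(n) < 0.5
  has_year1 <- !single | which_single
  has_year2 <- !single | !which_single

  data.frame(
    participant_id = sprintf("P%06d", seq_len(n)),
    male = stats::runif(n) < cp$p_male,
    age = round(age, 1),
    rural = stats::runif(n) < cp$p_rural,
    education = sample.int(4L, n, replace = TRUE, prob = cp$p_education),
    met = round(stats::rlnorm(n, cp$met_log_mean, cp$met_log_sd), 1),
    smoking = stats::runif(n) < cp$p_smoking,
    alcohol = stats::runif(n) < cp$p_alcohol,
    cvd_cancer = stats::runif(n) < cp$p_cvd_cancer,
    baseline_year = ifelse(has_year1, yrs[1], yrs[2]),
    has_year1 = has_year1,
    has_year2 = has_year2
  )
}

#' Generate 24-h recall day-records
#'
#' Each participant contributes three recall days per attended baseline year
#' and 17 food-group rows per day (zero rows included). Consumer status is
#' participant-level (zero inflation); consumer amounts are log-normal,
#' shifted by a latent diet-quality factor through each group's
#' `quality_loading`, with day-to-day log-normal noise. Reported daily
#' energy is an intercept plus the energy-slope-weighted sum of that day's
#' intakes plus noise, repeated on each of the day's rows.
#'
#' @param cohort output of [generate_participants()].
#' @param config the same [sim_config()].
#' @return recall table: `participant_id`, `year`, `day`, `group_id`,
#'   `grams`, `kcal`.
#' @export
generate_recalls <- function(cohort, config) {
  validate_sim_config(config)
  if (nrow(cohort) == 0L) stop("empty cohort")
  set.seed(sub_seed(config$seed, 2L))
  n <- nrow(cohort)
  gp <- config$group_params
  G <- nrow(gp)
  yrs <- baseline_diet_years(config)

  u <- stats::rnorm(n)  # latent diet-quality factor
  consumer <- matrix(stats::runif(n * G) >= rep(gp$zero_prob, each = n), n, G)
  lmean <- matrix(rep(gp$log_median, each = n), n, G) +
    outer(u, gp$quality_loading)
  amounts <- consumer *
    exp(lmean + matrix(stats::rnorm(n * G, 0, rep(gp$log_sd, each = n)), n, G))

  # participant-year combos, ordered by participant then year
  combo_pid <- c(rbind(ifelse(cohort$has_year1, seq_len(n), NA),
                       ifelse(cohort$has_year2, seq_len(n), NA)))
  combo_year <- rep(yrs, times = n)[!is.na(combo_pid)]
  combo_pid <- combo_pid[!is.na(combo_pid)]
  n_combo <- length(combo_pid)

  i_vec <- rep(combo_pid, each = 3L * G)
  year_vec <- rep(combo_year, each = 3L * G)
  day_vec <- rep(rep(1:3, each = G), times = n_combo)
  g_vec <- rep(seq_len(G), times = 3L * n_combo)
  N <- length(i_vec)

  grams <- amounts[(g_vec - 1L) * n + i_vec] *
    exp(stats::rnorm(N, 0, config$day_log_sd))
  grams <- round(grams, 1)

  day_key <- (rep(seq_len(n_combo), each = 3L * G) - 1L) * 3L + day_vec
  food_kcal <- rowsum(gp$energy_slope[g_vec] * grams, day_key)
  kcal_day <- pmax(
    config$energy_base + as.numeric(food_kcal) +
      stats::rnorm(n_combo * 3L, 0, config$energy_day_sd),
    150)
  data.frame(
    participant_id = cohort$participant_id[i_vec],
    year = year_vec,
    day = day_vec,
    group_id = gp$group_id[g_vec],
    grams = grams,
    kcal = round(kcal_day[day_key], 1)
  )
}

#' Generate ground truth: true index, latent event times, prevalent flags
#'
#' The true diet-quality exposure is the standardized PDI computed from the
#' generated recalls through the package's own scoring path (full-cohort
#' residual energy adjustment and quintile scoring), so downstream recovery
#' tests exercise the complete observable pipeline. Latent event times are
#' Weibull (exponential by default) with per-outcome log-hazard
#' `index * z + age * (age - 45) + male`, applied on top of the per-outcome
#' baseline hazard. Prevalent-at-baseline flags are independent draws.
#'
#' Ground truth is retained for recovery tests only and is never an input to
#' the analysis stages.
#'
#' @param cohort output of [generate_participants()].
#' @param recalls output of [generate_recalls()].
#' @param config the same [sim_config()].
#' @param groups food-group map used for the true index.
#' @return data frame: `participant_id`, `true_index_z`, per-outcome
#'   `time_<outcome>` (years from baseline) and `prev_<outcome>` flags.
#' @export
generate_truth <- function(cohort, recalls, config,
                           groups = default_food_groups()) {
  validate_sim_config(config)
  set.seed(sub_seed(config$seed, 3L))
  profiles <- build_profiles(recalls, groups,
                             baseline_years = baseline_diet_years(config))
  idx <- compute_index(profiles, index_scheme("PDI", groups))
  z <- as.numeric(scale(idx$total))
  z <- z[match(cohort$participant_id, idx$participant_id)]
  if (anyNA(z)) stop("recalls not aligned to cohort participant_id")

  truth <- data.frame(participant_id = cohort$participant_id,
                      true_index_z = z)
  n <- nrow(cohort)
  k <- config$weibull_shape
  for (oc in OUTCOMES) {
    b <- config$true_loghr[[oc]]
    lp <- b$index * z + b$age * (cohort$age - 45) + b$male * cohort$male
    h0 <- config$baseline_hazard[[oc]]
    tt <- if (h0 > 0) (stats::rexp(n) / (h0 * exp(lp)))^(1 / k) else rep(Inf, n)
    truth[[paste0("time_", oc)]] <- tt
    truth[[paste0("prev_", oc)]] <-
      stats::runif(n) < config$baseline_prevalence[[oc]]
  }
  truth
}

#' Generate wave-indexed outcome measurements
#'
#' Produces the observable measurement table: a complete baseline-year row
#' per participant plus rows for attended follow-up waves. A participant's
#' measurements first satisfy an outcome definition at the first wave year
#' at or after their latent event time; measurements before that stay below
#' the diagnostic thresholds. Prevalent cases exceed thresholds from
#' baseline on. Fasting glucose and HbA1c appear only at biomarker waves;
#' diabetes at other waves is carried by self-report/medication.
#'
#' @param cohort output of [generate_participants()].
#' @param truth output of [generate_truth()] (aligned by `participant_id`).
#' @param config the same [sim_config()].
#' @return waves table: `participant_id`, `wave_year`, `weight`, `height`,
#'   `sbp`, `dbp`, `fpg`, `hba1c`, `self_hypertension`, `htn_medication`,
#'   `self_diabetes`, `diabetes_medication`.
#' @export
generate_outcomes <- function(cohort, truth, config) {
  validate_sim_config(config)
  if (!identical(cohort$participant_id, truth$participant_id)) {
    stop("truth table not aligned to cohort by participant_id")
  }
  set.seed(sub_seed(config$seed, 4L))
  n <- nrow(cohort)
  fw <- followup_wave_years(config)

  height <- round(ifelse(cohort$male,
                         stats::rnorm(n, 1.68, 0.06),
                         stats::rnorm(n, 1.57, 0.06)), 2)
  ltfu <- stats::runif(n) < config$p_loss_followup
  attend <- matrix(stats::runif(n * length(fw)) < config$p_wave_attend,
                   n, length(fw)) & !ltfu

  # long layout: baseline row + attended follow-up rows
  wave_year <- c(cohort$baseline_year,
                 rep(fw, each = n)[as.vector(attend)])
  pid_idx <- c(seq_len(n), rep(seq_len(n), times = length(fw))[as.vector(attend)])
  is_baseline <- c(rep(TRUE, n), rep(FALSE, sum(attend)))
  N <- length(pid_idx)

  years_since <- wave_year - cohort$baseline_year[pid_idx]
  disease <- function(oc) {
    truth[[paste0("prev_", oc)]][pid_idx] |
      (years_since > 0 & truth[[paste0("time_", oc)]][pid_idx] <= years_since)
  }
  d_ow <- disease("overweight_obesity")
  d_ht <- disease("hypertension")
  d_dm <- disease("t2d")

  bmi <- ifelse(d_ow, stats::runif(N, 24.2, 29.5), stats::runif(N, 19.5, 23.8))
  sbp <- ifelse(d_ht, stats::runif(N, 141, 175), stats::runif(N, 105, 138))
  dbp <- ifelse(d_ht, stats::runif(N, 90, 105), stats::runif(N, 65, 88))
  self_ht <- d_ht & stats::runif(N) < 0.3
  med_ht <- d_ht & stats::runif(N) < 0.3
  self_dm <- d_dm   # carried self-report keeps 2015 ascertainment possible
  med_dm <- d_dm & stats::runif(N) < 0.4

  biom <- wave_year %in% config$biomarker_waves
  fpg <- ifelse(d_dm, stats::runif(N, 7.2, 11.0), stats::runif(N, 4.5, 6.5))
  hba1c <- ifelse(d_dm, stats::runif(N, 6.6, 9.0), stats::runif(N, 5.0, 6.2))
  fpg[!biom] <- NA_real_
  hba1c[!biom] <- NA_real_

  waves <- data.frame(
    participant_id = cohort$participant_id[pid_idx],
    wave_year = wave_year,
    weight = round(bmi * height[pid_idx]^2, 1),
    height = height[pid_idx],
    sbp = round(sbp), dbp = round(dbp),
    fpg = round(fpg, 2), hba1c = round(hba1c, 2),
    self_hypertension = self_ht,
    htn_medication = med_ht,
    self_diabetes = self_dm,
    diabetes_medication = med_dm
  )

  # block-wise missingness at attended follow-up waves
  fu <- which(!is_baseline)
  drop_block <- function(cols) {
    miss <- fu[stats::runif(length(fu)) < config$p_measure_missing]
    waves[miss, cols] <<- NA
    invisible(NULL)
  }
  drop_block(c("weight", "height"))
  drop_block(c("sbp", "dbp", "self_hypertension", "htn_medication"))
  drop_block(c("fpg", "hba1c", "self_diabetes", "diabetes_medication"))

  waves[order(waves$participant_id, waves$wave_year), , drop = FALSE]
}

#' Simulate a complete synthetic cohort dataset
#'
#' Runs all generator stages and returns the observable tables (`baseline`,
#' `recalls`, `waves`) together with the retained ground `truth` and the
#' config.
#'
#' @param config a [sim_config()].
#' @return list of class `pdi_dataset`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  cohort <- generate_participants(config)
  recalls <- generate_recalls(cohort, config)
  truth <- generate_truth(cohort, recalls, config)
  waves <- generate_outcomes(cohort, truth, config)
  structure(list(baseline = cohort, recalls = recalls, waves = waves,
                 truth = truth, config = config),
            class = "pdi_dataset")
}
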