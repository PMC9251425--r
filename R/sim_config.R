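#' Outcomes modelled by the pipeline
#' @export
OUTCOMES <- c("overweight_obesity", "hypertension", "t2d")

#' Default intake distribution parameters per food group
#'
#' Consumer intakes are log-normal (`log_median` is the consumer median in
#' g/day, `log_sd` the log-scale SD) with participant-level zero inflation
#' (`zero_prob` = probability of being a non-consumer). `energy_slope`
#' (kcal/g) links group intake to reported daily energy. `quality_loading`
#' shifts a group's log-intake by the participant's latent diet-quality
#' factor, inducing realistic correlation between plant and animal intakes.
#'
#' Defaults are calibrated to the descriptive marginals of a Chinese adult
#' cohort: mean total energy ~2,230 kcal/day, healthy plant ~540 g/day,
#' less-healthy plant ~430 g/day, animal foods ~170 g/day, with heavy zero
#' inflation for tea/coffee, dairy and sugary drinks.
#'
#' @return data frame with one row per food group.
#' @export
default_group_params <- function() {
  data.frame(
    group_id = c("whole_grains", "fruits", "vegetables", "nuts", "legumes",
                 "tea_coffee", "vegetable_oils",
                 "refined_grains", "potatoes", "sugary_drinks",
                 "sweets_desserts", "fermented_preserved",
                 "animal_fats", "dairy", "eggs", "fish_seafood", "meat"),
    log_median = log(c(50, 60, 330, 15, 60, 10, 35,
                       330, 80, 150, 30, 30,
                       15, 150, 50, 40, 70)),
    log_sd = c(0.6, 0.8, 0.4, 0.8, 0.6, 0.7, 0.4,
               0.35, 0.6, 0.7, 0.7, 0.7,
               0.5, 0.6, 0.5, 0.7, 0.6),
    zero_prob = c(0.55, 0.55, 0.00, 0.70, 0.25, 0.80, 0.05,
                  0.00, 0.35, 0.85, 0.70, 0.45,
                  0.45, 0.82, 0.30, 0.45, 0.12),
    energy_slope = c(1.2, 0.55, 0.25, 6.0, 1.2, 0.3, 8.8,
                     1.3, 0.8, 0.45, 3.5, 1.0,
                     8.8, 0.6, 1.5, 1.2, 2.2),
    quality_loading = c(rep(0.25, 7), rep(-0.12, 5), rep(-0.25, 5))
  )
}

#' Default covariate distribution parameters
#' @return named list of marginals for the baseline covariates.
#' @export
default_covariate_params <- function() {
  list(
    p_male = 0.48,
    p_rural = 0.72,
    age_mean = 46, age_sd = 13, age_min = 18, age_max = 80,
    p_education = c(primary = 0.45, junior = 0.34, senior = 0.13,
                    college = 0.08),
    met_log_mean = log(150), met_log_sd = 0.65,
    p_smoking = 0.33,
    p_alcohol = 0.34,
    p_cvd_cancer = 0.0143
  )
}

#' Default true log-hazard coefficients
#'
#' `index` multiplies the standardized diet index (log HR per 1 SD); the
#' defaults are the fully adjusted per-SD hazard ratios reported for a
#' Chinese cohort (0.89, 0.88, 0.93 for overweight/obesity, hypertension and
#' type 2 diabetes). `age` is per year (centred at 45), `male` a contrast.
#'
#' @return named list, one per outcome.
#' @export
default_true_loghr <- function() {
  list(
    overweight_obesity = list(index = log(0.89), age = 0.02, male = 0.10),
    hypertension       = list(index = log(0.88), age = 0.02, male = 0.10),
    t2d                = list(index = log(0.93), age = 0.02, male = 0.10)
  )
}

#' Simulation configuration for a synthetic diet-outcome cohort
#'
#' Bundles and validates every generator knob. All stochastic generator
#' stages derive deterministic sub-streams from `seed`, so identical configs
#' give byte-identical datasets.
#'
#' @param n_participants cohort size (> 0).
#' @param seed integer RNG seed.
#' @param wave_years survey calendar years, strictly increasing; the first
#'   two are the baseline diet years, later ones follow-up waves.
#' @param group_params intake distributions, see [default_group_params()].
#' @param covariate_params see [default_covariate_params()].
#' @param true_loghr per-outcome log-hazard coefficients, see
#'   [default_true_loghr()].
#' @param baseline_hazard per-outcome constant hazard per year (> 0; set 0
#'   for a no-event cohort).
#' @param baseline_prevalence per-outcome fraction prevalent at baseline.
#' @param weibull_shape shape of the latent event-time distribution (1 =
#'   exponential / proportional hazards; other values induce PH violations
#'   against the constant-hazard analysis).
#' @param p_single_baseline_year fraction with recalls in only one of the two
#'   baseline years.
#' @param p_loss_followup fraction never seen at any follow-up wave (study
#'   follow-up rate 73.4% corresponds to the default 0.266).
#' @param p_wave_attend per-wave attendance probability among the followed.
#' @param p_measure_missing probability a measurement block (anthropometry,
#'   blood pressure, glycaemia) is missing at an attended follow-up wave.
#' @param energy_base,energy_day_sd intercept and day-level noise SD of
#'   reported daily energy (kcal).
#' @param day_log_sd day-to-day log-scale variation of group intakes.
#' @param biomarker_waves waves at which fasting glucose / HbA1c are
#'   measured (diabetes at other waves is self-report/medication only).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants,
                       seed = 1L,
                       wave_years = c(2004, 2006, 2009, 2015),
                       group_params = default_group_params(),
                       covariate_params = default_covariate_params(),
                       true_loghr = default_true_loghr(),
                       baseline_hazard = c(overweight_obesity = 0.035,
                                           hypertension = 0.032,
                                           t2d = 0.009),
                       baseline_prevalence = c(overweight_obesity = 0.444,
                                               hypertension = 0.433,
                                               t2d = 0.038),
                       weibull_shape = 1,
                       p_single_baseline_year = 0.30,
                       p_loss_followup = 0.266,
                       p_wave_attend = 0.90,
                       p_measure_missing = 0.05,
                       energy_base = 750,
                       energy_day_sd = 300,
                       day_log_sd = 0.30,
                       biomarker_waves = 2009) {
  cfg <- list(
    n_participants = n_participants, seed = as.integer(seed),
    wave_years = wave_years, group_params = group_params,
    covariate_params = covariate_params, true_loghr = true_loghr,
    baseline_hazard = baseline_hazard,
    baseline_prevalence = baseline_prevalence,
    weibull_shape = weibull_shape,
    p_single_baseline_year = p_single_baseline_year,
    p_loss_followup = p_loss_followup,
    p_wave_attend = p_wave_attend,
    p_measure_missing = p_measure_missing,
    energy_base = energy_base, energy_day_sd = energy_day_sd,
    day_log_sd = day_log_sd, biomarker_waves = biomarker_waves
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Errors name the offending field.
#'
#' @param config a `sim_config`.
#' @return the config, invisibly, if valid.
#' @export
validate_sim_config <- function(config) {
  if (!inherits(config, "sim_config")) stop("not a sim_config object")
  fail <- function(field, why) {
    stop(sprintf("invalid configuration field `%s`: %s", field, why))
  }
  n <- config$n_participants
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n <= 0 || n != floor(n)) {
    fail("n_participants", "must be a positive integer")
  }
  w <- config$wave_years
  if (length(w) < 3L || any(diff(w) <= 0)) {
    fail("wave_years", "need >= 3 strictly increasing years")
  }
  gp <- config$group_params
  if (!is.data.frame(gp) ||
      !all(c("group_id", "log_median", "log_sd", "zero_prob",
             "energy_slope", "quality_loading") %in% names(gp))) {
    fail("group_params", "missing required columns")
  }
  if (any(gp$zero_prob < 0 | gp$zero_prob >= 1)) {
    fail("group_params", "zero_prob must lie in [0, 1)")
  }
  if (any(gp$log_sd < 0)) fail("group_params", "log_sd must be >= 0")
  bh <- config$baseline_hazard
  if (!all(OUTCOMES %in% names(bh))) fail("baseline_hazard", "must name every outcome")
  if (any(bh < 0)) fail("baseline_hazard", "must be >= 0")
  bp <- config$baseline_prevalence
  if (!all(OUTCOMES %in% names(bp))) fail("baseline_prevalence", "must name every outcome")
  if (any(bp < 0 | bp >= 1)) fail("baseline_prevalence", "must lie in [0, 1)")
  if (!all(OUTCOMES %in% names(config$true_loghr))) {
    fail("true_loghr", "must name every outcome")
  }
  for (p in c("p_single_baseline_year", "p_loss_followup", "p_wave_attend",
              "p_measure_missing")) {
    v <- config[[p]]
    if (!is.numeric(v) || v < 0 || v > 1) fail(p, "must lie in [0, 1]")
  }
  if (config$weibull_shape <= 0) fail("weibull_shape", "must be > 0")
  invisible(config)
}

# deterministic sub-stream seed per generator stage
sub_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + stage * 9973) %% 2147483587L)
}

baseline_diet_years <- function(config) config$wave_years[1:2]
followup_wave_years <- function(config) {
  config$wave_years[config$wave_years > baseline_diet_years(config)[2]]
}
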