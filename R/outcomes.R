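#' Body mass index
#'
#' @param weight_kg,height_m positive numerics.
#' @return BMI in kg/m^2.
#' @export
compute_bmi <- function(weight_kg, height_m) {
  bad <- !is.na(weight_kg) & weight_kg <= 0 |
         !is.na(height_m) & height_m <= 0
  if (any(bad)) stop("non-positive weight or height")
  weight_kg / height_m^2
}

#' Overweight/obesity classification (BMI >= 24 kg/m^2)
#'
#' Uses the Chinese Working Group on Obesity threshold for the combined
#' overweight/obesity endpoint.
#'
#' @param bmi numeric BMI.
#' @return logical flag (NA where BMI is missing).
#' @export
classify_overweight <- function(bmi) bmi >= 24

# NA-aware any(): TRUE beats NA, NA beats FALSE
any_criterion <- function(...) {
  m <- cbind(...)
  hit <- rowSums(m, na.rm = TRUE) > 0
  hit[!hit & rowSums(is.na(m)) > 0] <- NA
  hit
}

#' Hypertension classification
#'
#' Positive when any criterion is met: mean systolic blood pressure >= 140
#' mmHg, mean diastolic >= 90 mmHg, or self-reported diagnosis /
#' antihypertensive medication. Returns NA only when every observable
#' criterion is missing.
#'
#' @param sbp,dbp mean seated blood pressures (mmHg).
#' @param self_report,on_medication logical.
#' @return logical flag.
#' @export
classify_hypertension <- function(sbp, dbp, self_report = FALSE,
                                  on_medication = FALSE) {
  any_criterion(sbp >= 140, dbp >= 90, self_report, on_medication)
}

#' Type 2 diabetes classification with wave-specific rules
#'
#' At biomarker waves (2009 in the default design) T2D is fasting glucose
#' >= 7.0 mmol/L, HbA1c >= 6.5%, or self-report/medication. At all other
#' waves (notably 2015) only self-report/medication counts; biomarkers are
#' ignored even if present.
#'
#' @param wave_year calendar year of the wave.
#' @param fpg fasting plasma glucose, mmol/L.
#' @param hba1c HbA1c, percent.
#' @param self_report,on_medication logical.
#' @param biomarker_waves waves at which the biomarker rule applies.
#' @return logical flag.
#' @export
classify_t2d <- function(wave_year, fpg = NA, hba1c = NA,
                         self_report = FALSE, on_medication = FALSE,
                         biomarker_waves = 2009) {
  biom <- wave_year %in% biomarker_waves
  with_biom <- any_criterion(fpg >= 7.0, hba1c >= 6.5,
                             self_report, on_medication)
  without <- any_criterion(self_report, on_medication)
  ifelse(biom, with_biom, without)
}

#' Follow-up time from baseline to onset or censoring
#'
#' @param baseline_year baseline calendar year (2004 or 2006).
#' @param event_wave_year wave year of disease onset, NA if censored.
#' @param censor_wave_year last wave with a usable outcome measurement.
#' @return follow-up in years.
#' @export
compute_follow_up <- function(baseline_year, event_wave_year,
                              censor_wave_year) {
  end <- ifelse(is.na(event_wave_year), censor_wave_year, event_wave_year)
  if (any(!is.na(end) & end <= baseline_year)) {
    stop("event/censoring wave at or before baseline year")
  }
  end - baseline_year
}

#' Total person-years of a sample
#'
#' @param sample data frame with a `follow_up_years` column.
#' @return sum of individual follow-up durations.
#' @export
person_years <- function(sample) {
  stopifnot("follow_up_years" %in% names(sample))
  sum(sample$follow_up_years, na.rm = TRUE)
}

#' Ascertain the three outcomes from wave measurements
#'
#' For every participant and outcome: the baseline-wave measurement decides
#' prevalence; the first follow-up wave whose measurements satisfy the
#' outcome definition is the event wave; participants never meeting it are
#' censored at their last follow-up wave with a usable measurement; those
#' with no usable follow-up measurement are flagged missing.
#'
#' @param waves measurement table (see [generate_outcomes()] for the schema).
#' @param baseline data frame with `participant_id` and `baseline_year`.
#' @param biomarker_waves waves with fasting glucose / HbA1c measurement.
#' @return long data frame: `participant_id`, `outcome`, `prevalent`,
#'   `event`, `event_wave_year`, `censor_wave_year`, `follow_up_years`,
#'   `missing`.
#' @export
ascertain_outcomes <- function(waves, baseline, biomarker_waves = 2009) {
  pidx <- match(waves$participant_id, baseline$participant_id)
  if (anyNA(pidx)) {
    stop("waves contain participant_id absent from baseline")
  }
  waves <- waves[order(pidx, waves$wave_year), , drop = FALSE]
  pidx <- sort(pidx)
  n <- nrow(baseline)
  b_year <- baseline$baseline_year[pidx]
  is_fu <- waves$wave_year > b_year
  is_base <- waves$wave_year == b_year

  flags <- list(
    overweight_obesity = classify_overweight(
      compute_bmi(waves$weight, waves$height)),
    hypertension = classify_hypertension(
      waves$sbp, waves$dbp, waves$self_hypertension, waves$htn_medication),
    t2d = classify_t2d(
      waves$wave_year, waves$fpg, waves$hba1c, waves$self_diabetes,
      waves$diabetes_medication, biomarker_waves)
  )

  out <- lapply(OUTCOMES, function(oc) {
    f <- flags[[oc]]
    usable <- !is.na(f)

    prevalent <- rep(NA, n)
    bi <- which(is_base & usable)
    prevalent[pidx[bi]] <- f[bi]

    event_wave <- rep(NA_real_, n)
    ei <- which(is_fu & usable & f)
    first <- ei[!duplicated(pidx[ei])]          # waves sorted ascending
    event_wave[pidx[first]] <- waves$wave_year[first]

    censor_wave <- rep(NA_real_, n)
    ui <- which(is_fu & usable)
    last <- rev(ui)[!duplicated(pidx[rev(ui)])]
    censor_wave[pidx[last]] <- waves$wave_year[last]

    missing <- is.na(censor_wave)
    fu_years <- rep(NA_real_, n)
    ok <- !missing
    fu_years[ok] <- compute_follow_up(baseline$baseline_year[ok],
                                      event_wave[ok], censor_wave[ok])
    data.frame(
      participant_id = baseline$participant_id,
      outcome = oc,
      prevalent = prevalent,
      event = !is.na(event_wave),
      event_wave_year = event_wave,
      censor_wave_year = censor_wave,
      follow_up_years = fu_years,
      missing = missing
    )
  })
  do.call(rbind, out)
}
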