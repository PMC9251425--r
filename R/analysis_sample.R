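#' Build a per-outcome analysis sample with the exclusion flow
#'
#' Applies, in order: the total-energy filter (<500 or >5,000 kcal/day
#' excluded), prevalent cardiovascular disease / cancer exclusion,
#' loss-to-follow-up exclusion (no follow-up wave attended), prevalent-
#' outcome exclusion, and missing-outcome exclusion (no usable outcome
#' measurement at any attended wave). An exclusion ledger records each
#' step's count; excluded + retained always equals the input count.
#'
#' Both diet indices, their exposure quintiles and z-scores are computed on
#' the retained sample by default (set `quintile_within = "cohort"` to rank
#' within the whole energy-filtered cohort instead).
#'
#' @param dataset a `pdi_dataset` (tables `baseline`, `recalls`, `waves`),
#'   or a list with those elements.
#' @param outcome one of `r paste0('"', OUTCOMES, '"', collapse = ", ")`.
#' @param groups food-group map.
#' @param energy_range inclusive kcal/day retention bounds.
#' @param quintile_within `"sample"` (default) or `"cohort"`.
#' @param biomarker_waves passed to [ascertain_outcomes()].
#' @return data frame of class `analysis_sample`: one row per retained
#'   participant with index totals/quintiles/z-scores, covariates, baseline
#'   anthropometry and blood pressure, `follow_up_years` and `event`.
#'   Attributes: `outcome`, `ledger` (named counts), `medians_pdi`,
#'   `medians_hpdi` (per-quintile median totals).
#' @export
build_analysis_sample <- function(dataset, outcome,
                                  groups = default_food_groups(),
                                  energy_range = c(500, 5000),
                                  quintile_within = c("sample", "cohort"),
                                  biomarker_waves = 2009) {
  outcome <- match.arg(outcome, OUTCOMES)
  quintile_within <- match.arg(quintile_within)
  baseline <- dataset$baseline
  ledger <- c(input = nrow(baseline), energy = 0L, prevalent_cvd_cancer = 0L,
              loss_to_followup = 0L, prevalent_outcome = 0L,
              missing_outcome = 0L, retained = 0L)

  empty_result <- function(ledger) {
    out <- data.frame(participant_id = character(0))
    attr(out, "outcome") <- outcome
    attr(out, "ledger") <- ledger
    class(out) <- c("analysis_sample", "data.frame")
    warning("empty analysis sample for outcome ", outcome)
    out
  }
  if (nrow(baseline) == 0L) return(empty_result(ledger))

  profiles <- build_profiles(dataset$recalls, groups)
  profiles <- profiles[match(baseline$participant_id, profiles$participant_id),
                       , drop = FALSE]
  if (anyNA(profiles$participant_id)) {
    stop("recalls missing for some baseline participants")
  }

  # 1. energy filter
  ef <- filter_energy(profiles, energy_range[1], energy_range[2])
  keep <- profiles$participant_id %in% ef$retained$participant_id
  ledger["energy"] <- sum(!keep)

  # 2. prevalent CVD / cancer
  prev_cc <- !is.na(baseline$cvd_cancer) & baseline$cvd_cancer
  ledger["prevalent_cvd_cancer"] <- sum(keep & prev_cc)
  keep <- keep & !prev_cc

  # outcome ascertainment for the remaining steps
  asc <- ascertain_outcomes(dataset$waves, baseline, biomarker_waves)
  asc <- asc[asc$outcome == outcome, , drop = FALSE]
  asc <- asc[match(baseline$participant_id, asc$participant_id), , drop = FALSE]

  # 3. loss to follow-up: no follow-up wave attended at all
  fu_any <- dataset$waves$wave_year >
    baseline$baseline_year[match(dataset$waves$participant_id,
                                 baseline$participant_id)]
  attended <- baseline$participant_id %in%
    unique(dataset$waves$participant_id[fu_any])
  ledger["loss_to_followup"] <- sum(keep & !attended)
  keep <- keep & attended

  # 4. prevalent outcome at baseline
  prev <- !is.na(asc$prevalent) & asc$prevalent
  ledger["prevalent_outcome"] <- sum(keep & prev)
  keep <- keep & !prev

  # 5. missing outcome (incl. unassessable baseline status)
  miss <- asc$missing | is.na(asc$prevalent)
  ledger["missing_outcome"] <- sum(keep & miss)
  keep <- keep & !miss

  ledger["retained"] <- sum(keep)
  if (!any(keep)) return(empty_result(ledger))

  index_pool <- if (quintile_within == "cohort") {
    ef$retained
  } else {
    profiles[keep, , drop = FALSE]
  }
  pool_idx <- match(baseline$participant_id[keep], index_pool$participant_id)

  score_one <- function(scheme_name) {
    idx <- compute_index(index_pool, index_scheme(scheme_name, groups))
    iq <- index_quintiles(idx$total)
    list(total = idx$total[pool_idx], quintile = iq$quintile[pool_idx],
         z = iq$z[pool_idx], medians = iq$medians)
  }
  scorable <- nrow(index_pool) >= 5L
  if (!scorable) {
    warning("fewer than 5 retained participants: index scores set to NA")
    pdi <- hpdi <- list(total = rep(NA_integer_, sum(keep)),
                        quintile = rep(NA_integer_, sum(keep)),
                        z = rep(NA_real_, sum(keep)),
                        medians = rep(NA_real_, 5))
  } else {
    pdi <- score_one("PDI")
    hpdi <- score_one("hPDI")
  }

  # baseline anthropometry / blood pressure covariates
  wb <- dataset$waves[dataset$waves$wave_year ==
    baseline$baseline_year[match(dataset$waves$participant_id,
                                 baseline$participant_id)], , drop = FALSE]
  wb <- wb[match(baseline$participant_id, wb$participant_id), , drop = FALSE]

  bl <- baseline[keep, , drop = FALSE]
  out <- data.frame(
    participant_id = bl$participant_id,
    pdi_total = pdi$total, pdi_q = pdi$quintile, pdi_z = pdi$z,
    hpdi_total = hpdi$total, hpdi_q = hpdi$quintile, hpdi_z = hpdi$z,
    age = bl$age, male = bl$male, rural = bl$rural,
    education = bl$education, met = bl$met,
    smoking = bl$smoking, alcohol = bl$alcohol,
    total_energy = profiles$total_energy[keep],
    bmi = compute_bmi(wb$weight, wb$height)[keep],
    sbp = wb$sbp[keep], dbp = wb$dbp[keep],
    baseline_year = bl$baseline_year,
    follow_up_years = asc$follow_up_years[keep],
    event = asc$event[keep]
  )
  attr(out, "outcome") <- outcome
  attr(out, "ledger") <- ledger
  attr(out, "medians_pdi") <- pdi$medians
  attr(out, "medians_hpdi") <- hpdi$medians
  class(out) <- c("analysis_sample", "data.frame")
  out
}

#' Exclusion ledger of an analysis sample
#'
#' @param sample an `analysis_sample`.
#' @return named integer vector of exclusion counts.
#' @export
exclusion_ledger <- function(sample) attr(sample, "ledger")
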