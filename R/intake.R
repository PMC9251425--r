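#' Aggregate daily 24-h recalls to participant-year mean intakes
#'
#' Computes, for every participant-year, the arithmetic mean g/day per food
#' group over the available recall days (typically three consecutive days)
#' and the mean total energy (kcal/day). Groups reported on no day get
#' 0 g/day: absence of a record is zero intake. The `kcal` column carries the
#' day's total energy, repeated on each of that day's rows.
#'
#' @param recalls data frame with columns `participant_id`, `year`, `day`,
#'   `group_id`, `grams`, `kcal`.
#' @param groups a `food_group_map`; recall rows must use its `group_id`s.
#' @return data frame with one row per participant-year: `participant_id`,
#'   `year`, `total_energy`, and one g/day column per group (named by
#'   `group_id`).
#' @export
aggregate_recalls <- function(recalls, groups = default_food_groups()) {
  required <- c("participant_id", "year", "day", "group_id", "grams", "kcal")
  missing_cols <- setdiff(required, names(recalls))
  if (length(missing_cols) > 0L) {
    stop("recall table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(recalls) == 0L) stop("no recall day-records to aggregate")
  if (any(recalls$grams < 0)) stop("negative grams in recall table")

  gid <- match(recalls$group_id, groups$group_id)
  if (anyNA(gid)) {
    bad <- unique(recalls$group_id[is.na(gid)])
    stop("recall rows with unmapped group_id: ", paste(bad, collapse = ", "))
  }
  upid <- unique(recalls$participant_id)
  pi <- match(recalls$participant_id, upid)
  uyear <- sort(unique(recalls$year))
  yi <- match(recalls$year, uyear)
  n_y <- length(uyear)

  # compact participant-year index
  py <- (pi - 1L) * n_y + yi
  upy <- sort(unique(py))
  pyi <- match(py, upy)
  n_py <- length(upy)
  n_g <- nrow(groups)

  # distinct recall days per participant-year (denominator of the mean)
  di <- match(recalls$day, sort(unique(recalls$day)))
  first_day_row <- !duplicated((pyi - 1L) * max(di) + di)
  n_days <- tabulate(pyi[first_day_row], nbins = n_py)

  # per-group gram sums, filled into a participant-year x group matrix
  lin <- (gid - 1L) * n_py + pyi
  sums <- rowsum(recalls$grams, lin)
  mat <- matrix(0, nrow = n_py, ncol = n_g)
  mat[as.integer(rownames(sums))] <- sums
  mat <- mat / n_days

  # mean daily energy over distinct days
  esum <- rowsum(recalls$kcal[first_day_row], pyi[first_day_row])
  energy <- numeric(n_py)
  energy[as.integer(rownames(esum))] <- esum
  energy <- energy / n_days

  out <- data.frame(
    participant_id = upid[(upy - 1L) %/% n_y + 1L],
    year = uyear[(upy - 1L) %% n_y + 1L],
    total_energy = energy
  )
  colnames(mat) <- groups$group_id
  cbind(out, as.data.frame(mat))
}

#' Average the two baseline survey years into one intake profile
#'
#' When a participant has profiles for both baseline years, group intakes and
#' total energy are averaged element-wise; participants observed in only one
#' baseline year keep that year's values unchanged. The recorded
#' `baseline_year` is the earliest year present, which drives follow-up time.
#'
#' @param year_profiles output of [aggregate_recalls()] (one row per
#'   participant-year).
#' @param baseline_years the survey years considered baseline.
#' @return one row per participant: `participant_id`, `baseline_year`,
#'   `total_energy`, group columns.
#' @export
average_baseline_years <- function(year_profiles, baseline_years = c(2004, 2006)) {
  keep <- year_profiles$year %in% baseline_years
  prof <- year_profiles[keep, , drop = FALSE]
  if (nrow(prof) == 0L) stop("no baseline-year dietary profiles present")
  value_cols <- setdiff(names(prof), c("participant_id", "year"))
  upid <- unique(prof$participant_id)
  pi <- match(prof$participant_id, upid)
  n_years <- tabulate(pi, nbins = length(upid))
  means <- rowsum(as.matrix(prof[, value_cols]), pi) / n_years
  baseline_year <- vapply(split(prof$year, pi), min, numeric(1))
  out <- data.frame(participant_id = upid,
                    baseline_year = unname(baseline_year))
  cbind(out, as.data.frame(means))
}

#' Build baseline intake profiles from a recall table
#'
#' Convenience wrapper: [aggregate_recalls()] then
#' [average_baseline_years()].
#'
#' @inheritParams aggregate_recalls
#' @inheritParams average_baseline_years
#' @return one `IntakeProfile` row per participant.
#' @export
build_profiles <- function(recalls, groups = default_food_groups(),
                           baseline_years = c(2004, 2006)) {
  average_baseline_years(aggregate_recalls(recalls, groups), baseline_years)
}

#' Exclude implausible total energy intakes
#'
#' Drops profiles with extremely low or high total energy intake. The study
#' rule excludes strictly below `min_kcal` and strictly above `max_kcal`
#' (default <500 or >5,000 kcal/day), so the boundaries themselves are
#' retained.
#'
#' @param profiles profile table with a `total_energy` column.
#' @param min_kcal,max_kcal retention bounds in kcal/day (inclusive).
#' @return list with `retained` (profiles passing the filter) and `excluded`
#'   (a data frame of dropped rows with a `reason` of `"low_energy"` or
#'   `"high_energy"`).
#' @export
filter_energy <- function(profiles, min_kcal = 500, max_kcal = 5000) {
  stopifnot("total_energy" %in% names(profiles))
  low <- profiles$total_energy < min_kcal
  high <- profiles$total_energy > max_kcal
  excluded <- profiles[low | high, , drop = FALSE]
  excluded$reason <- ifelse(excluded$total_energy < min_kcal,
                            "low_energy", "high_energy")
  list(retained = profiles[!(low | high), , drop = FALSE],
       excluded = excluded)
}
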