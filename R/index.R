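#' Scoring scheme for a plant-based diet index
#'
#' `"PDI"` scores every plant group (healthy and less healthy) positively and
#' every animal group negatively; `"hPDI"` scores only the healthy plant
#' groups positively, reverse-scoring less healthy plant and animal groups.
#'
#' @param name `"PDI"`, `"hPDI"`, or `"custom"` (then `directions` required).
#' @param groups a `food_group_map`.
#' @param directions for `"custom"`: named character vector
#'   (`group_id` -> `"positive"`/`"negative"`) covering every group.
#' @return an `index_scheme` data frame with columns `group_id`, `category`,
#'   `direction`.
#' @export
index_scheme <- function(name = c("PDI", "hPDI", "custom"),
                         groups = default_food_groups(),
                         directions = NULL) {
  name <- match.arg(name)
  dir <- switch(name,
    PDI  = ifelse(groups$category %in% c("healthy_plant", "unhealthy_plant"),
                  "positive", "negative"),
    hPDI = ifelse(groups$category == "healthy_plant", "positive", "negative"),
    custom = {
      if (is.null(directions)) stop("custom scheme requires `directions`")
      d <- directions[groups$group_id]
      if (anyNA(d)) {
        stop("directions missing for group(s): ",
             paste(groups$group_id[is.na(d)], collapse = ", "))
      }
      unname(d)
    }
  )
  if (!all(dir %in% c("positive", "negative"))) {
    stop("directions must be 'positive' or 'negative'")
  }
  structure(
    data.frame(group_id = groups$group_id, category = groups$category,
               direction = dir),
    scheme_name = name,
    class = c("index_scheme", "data.frame")
  )
}

#' Flip every scoring direction of a scheme
#'
#' Useful for the mirror property: with 17 groups, flipping all directions
#' maps each participant's total `t` to `102 - t`.
#'
#' @param scheme an `index_scheme`.
#' @return the flipped scheme.
#' @export
flip_scheme <- function(scheme) {
  scheme$direction <- ifelse(scheme$direction == "positive",
                             "negative", "positive")
  attr(scheme, "scheme_name") <- "custom"
  scheme
}

#' Residual-method energy adjustment
#'
#' Regresses a food group's intake on total energy intake across the sample
#' (ordinary least squares) and returns the residual plus the predicted
#' intake at the sample-mean energy, so adjusted values keep the original
#' units and sample mean. With zero energy variance the regression is
#' degenerate: raw intakes are returned with a warning.
#'
#' @param grams numeric vector of group intakes (g/day), one per participant.
#' @param energy numeric vector of total energy intakes (kcal/day).
#' @return numeric vector of energy-adjusted intakes.
#' @export
residual_energy_adjust <- function(grams, energy) {
  if (length(grams) != length(energy)) stop("grams and energy lengths differ")
  if (length(grams) < 3L) stop("residual adjustment needs at least 3 participants")
  if (anyNA(grams) || anyNA(energy)) stop("missing values in intake or energy")
  v <- stats::var(energy)
  if (v == 0) {
    warning("zero energy variance: residual adjustment degenerate, returning raw intakes")
    return(grams)
  }
  b <- stats::cov(grams, energy) / v
  # residual + prediction at mean energy == x - b * (e - mean(e))
  grams - b * (energy - mean(energy))
}

#' Assign sample quintiles by midrank
#'
#' Ranks use midranks for ties, the fractional rank is `(rank - 0.5) / n`,
#' and the quintile is `floor(5 f) + 1` clamped to 5. Identical values always
#' share a quintile, which matters for zero-inflated food groups where naive
#' quantile cut-points collapse.
#'
#' @param values numeric vector (length >= 5).
#' @return integer vector of quintiles in 1..5.
#' @export
assign_quintiles <- function(values) {
  n <- length(values)
  if (n < 5L) stop("quintile assignment needs at least 5 observations")
  if (anyNA(values)) stop("missing values in quintile assignment")
  f <- (rank(values, ties.method = "average") - 0.5) / n
  pmin(as.integer(floor(5 * f)) + 1L, 5L)
}

#' Directional quintile score
#'
#' Positive direction: the fifth quintile scores five points, the first one
#' point (score = quintile). Negative direction: the fifth quintile scores
#' one point (score = 6 - quintile).
#'
#' @param quintile integer vector in 1..5.
#' @param direction `"positive"` or `"negative"` (scalar or vector).
#' @return integer scores in 1..5.
#' @export
score_group <- function(quintile, direction) {
  if (!all(quintile %in% 1:5)) stop("quintile must be in 1..5")
  if (!all(direction %in% c("positive", "negative"))) {
    stop("direction must be 'positive' or 'negative'")
  }
  if (length(direction) == 1L) direction <- rep(direction, length(quintile))
  as.integer(ifelse(direction == "positive", quintile, 6L - quintile))
}

#' Compute a plant-based diet index for every participant
#'
#' Pipeline per food group: residual-method energy adjustment across the
#' sample, midrank quintiles of the adjusted intake, directional 1–5 score;
#' group scores are summed into the index total (range 17–85 with 17
#' groups).
#'
#' @param profiles baseline profile table from [build_profiles()] (already
#'   energy-filtered).
#' @param scheme an `index_scheme`.
#' @param adjust_energy set `FALSE` to skip the residual adjustment (scores
#'   raw g/day).
#' @return data frame `participant_id`, `total`, with the per-group score
#'   matrix attached as attribute `"scores"` and quintile matrix as
#'   `"quintiles"`.
#' @export
compute_index <- function(profiles, scheme, adjust_energy = TRUE) {
  stopifnot(inherits(scheme, "index_scheme"))
  missing_grp <- setdiff(scheme$group_id, names(profiles))
  if (length(missing_grp) > 0L) {
    stop("profiles lack group column(s): ", paste(missing_grp, collapse = ", "))
  }
  n <- nrow(profiles)
  qmat <- smat <- matrix(NA_integer_, n, nrow(scheme),
                         dimnames = list(NULL, scheme$group_id))
  for (j in seq_len(nrow(scheme))) {
    g <- profiles[[scheme$group_id[j]]]
    if (adjust_energy) g <- residual_energy_adjust(g, profiles$total_energy)
    qmat[, j] <- assign_quintiles(g)
    smat[, j] <- score_group(qmat[, j], scheme$direction[j])
  }
  out <- data.frame(participant_id = profiles$participant_id,
                    total = as.integer(rowSums(smat)))
  attr(out, "scores") <- smat
  attr(out, "quintiles") <- qmat
  attr(out, "scheme_name") <- attr(scheme, "scheme_name")
  out
}

#' Exposure quintiles of the index total
#'
#' Divides index totals into quintiles with the same midrank rule as the
#' per-group ranking, and records each quintile's median total (these
#' medians drive the linear trend test).
#'
#' @param totals numeric vector of index totals.
#' @return list with `quintile` (integer vector, 1..5), `medians` (named
#'   numeric vector of per-quintile median totals; NA for empty quintiles)
#'   and `z` (index z-scores using the sample SD).
#' @export
index_quintiles <- function(totals) {
  q <- assign_quintiles(totals)
  medians <- vapply(1:5, function(k) {
    if (any(q == k)) stats::median(totals[q == k]) else NA_real_
  }, numeric(1))
  names(medians) <- paste0("Q", 1:5)
  s <- stats::sd(totals)
  z <- if (s > 0) (totals - mean(totals)) / s else rep(NA_real_, length(totals))
  list(quintile = q, medians = medians, z = z)
}
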