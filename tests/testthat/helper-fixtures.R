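# Shared fixtures and independent oracles, all built in code.

grp_default <- default_food_groups()

# Profiles where participant i has the i-th smallest intake in every plant
# group and the i-th largest in every animal group; constant energy so the
# residual adjustment degenerates to the identity. Participant 1 is then in
# the scoring-unfavorable quintile of every group under PDI (total 17),
# participant n in the favorable one (total 85).
rank_structured_profiles <- function(n = 10) {
  plant <- grp_default$group_id[grp_default$category != "animal"]
  animal <- grp_default$group_id[grp_default$category == "animal"]
  prof <- data.frame(participant_id = sprintf("F%02d", seq_len(n)),
                     baseline_year = 2004,
                     total_energy = rep(2000, n))
  for (g in plant) prof[[g]] <- 10 * seq_len(n)
  for (g in animal) prof[[g]] <- 10 * (n + 1 - seq_len(n))
  prof
}

# iid random profiles (no structure); quick scoring input
random_profiles <- function(n, seed = 1) {
  set.seed(seed)
  prof <- data.frame(participant_id = sprintf("R%04d", seq_len(n)),
                     baseline_year = 2004,
                     total_energy = stats::runif(n, 1200, 3500))
  for (g in grp_default$group_id) {
    prof[[g]] <- stats::rexp(n, 1 / 50) * stats::rbinom(n, 1, 0.8)
  }
  prof
}

# single-participant recall table builder: days is a named list
# day -> data.frame(group_id, grams); kcal is one value per day
recall_rows <- function(pid, year, days, kcal) {
  do.call(rbind, lapply(seq_along(days), function(d) {
    data.frame(participant_id = pid, year = year, day = d,
               group_id = days[[d]]$group_id, grams = days[[d]]$grams,
               kcal = kcal[d])
  }))
}

# hand-written Cox partial likelihood for the canonical 3-subject fixture:
# times {1 event x=1; 2 event x=0; 3 censored x=1}, no ties
logpl_3subject <- function(beta) {
  (beta - log(2 * exp(beta) + 1)) + (0 - log(1 + exp(beta)))
}

# analysis-sample fixture with the 3-subject survival layout and constant
# covariates (dropped by fit_cox), so the exposure term is the sole
# coefficient and matches the hand-written likelihood
three_subject_sample <- function() {
  s <- data.frame(
    participant_id = c("a", "b", "c"),
    follow_up_years = c(1, 2, 3),
    event = c(TRUE, TRUE, FALSE),
    age = 50, male = TRUE, rural = FALSE, total_energy = 2000,
    education = 1L, met = 100, smoking = FALSE, alcohol = FALSE,
    bmi = 22, sbp = 120, dbp = 80
  )
  class(s) <- c("analysis_sample", "data.frame")
  s
}

# synthetic analysis sample built directly (bypassing the generator), with
# continuous event times from a user-supplied log-hazard function of the
# standardized index
direct_sample <- function(n, loghazard = function(z) 0 * z, seed = 1,
                          base_rate = 0.08, admin_censor = 11) {
  set.seed(seed)
  z <- stats::rnorm(n)
  tot <- round(51 + 6 * z)
  iq <- index_quintiles(tot)
  tt <- stats::rexp(n, base_rate * exp(loghazard(z)))
  event <- tt <= admin_censor
  s <- data.frame(
    participant_id = sprintf("D%05d", seq_len(n)),
    pdi_total = tot, pdi_q = iq$quintile, pdi_z = iq$z,
    hpdi_total = tot, hpdi_q = iq$quintile, hpdi_z = iq$z,
    age = stats::runif(n, 20, 75), male = stats::runif(n) < 0.5,
    rural = stats::runif(n) < 0.7,
    education = sample.int(4L, n, replace = TRUE),
    met = stats::rlnorm(n, log(150), 0.6),
    smoking = stats::runif(n) < 0.3, alcohol = stats::runif(n) < 0.3,
    total_energy = stats::runif(n, 1500, 3000),
    bmi = stats::runif(n, 19, 24), sbp = stats::runif(n, 100, 139),
    dbp = stats::runif(n, 60, 89),
    baseline_year = 2004,
    follow_up_years = pmin(tt, admin_censor), event = event
  )
  attr(s, "medians_pdi") <- iq$medians
  attr(s, "medians_hpdi") <- iq$medians
  class(s) <- c("analysis_sample", "data.frame")
  s
}

# exhaustive pair-counting AUC oracle (ties count one half)
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# small synthetic dataset cached per test file run
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(sim_config(n_participants = 800, seed = 99))
    }
    cache
  }
})
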