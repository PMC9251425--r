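test_that("identical config and seed reproduce the dataset exactly", {
  cfg <- sim_config(n_participants = 100, seed = 7)
  d1 <- simulate_cohort(cfg)
  d2 <- simulate_cohort(cfg)
  expect_identical(d1$baseline, d2$baseline)
  expect_identical(d1$recalls, d2$recalls)
  expect_identical(d1$waves, d2$waves)
  expect_identical(d1$truth, d2$truth)
})

test_that("invalid configuration is rejected naming the offending field", {
  expect_error(sim_config(n_participants = 0), "n_participants")
  expect_error(sim_config(n_participants = 10, wave_years = c(2004, 2004, 2009)),
               "wave_years")
  gp <- default_group_params()
  gp$zero_prob[1] <- 1.2
  expect_error(sim_config(n_participants = 10, group_params = gp),
               "zero_prob")
  bh <- c(overweight_obesity = -0.1, hypertension = 0.03, t2d = 0.01)
  expect_error(sim_config(n_participants = 10, baseline_hazard = bh),
               "baseline_hazard")
})

test_that("covariate marginals match the config within sampling error", {
  n <- 10000
  cohort <- generate_participants(sim_config(n_participants = n, seed = 11))
  cp <- default_covariate_params()
  se <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(cohort$male) - cp$p_male), 3 * se(cp$p_male))
  expect_lt(abs(mean(cohort$rural) - cp$p_rural), 3 * se(cp$p_rural))
  expect_lt(abs(mean(cohort$smoking) - cp$p_smoking), 3 * se(cp$p_smoking))
  expect_true(all(cohort$age >= cp$age_min & cohort$age <= cp$age_max))
})

test_that("recall structure: three days per attended baseline year, non-negative grams", {
  cfg <- sim_config(n_participants = 150, seed = 3)
  cohort <- generate_participants(cfg)
  recalls <- generate_recalls(cohort, cfg)
  expect_true(all(recalls$grams >= 0))
  expect_true(all(recalls$kcal > 0))
  per_py <- table(recalls$participant_id, recalls$year)
  expect_true(all(per_py %in% c(0L, 3L * 17L)))
  # single-baseline-year participants have recalls in exactly one year
  n_years <- rowSums(per_py > 0)
  single <- !(cohort$has_year1 & cohort$has_year2)
  expect_identical(unname(n_years[cohort$participant_id]),
                   ifelse(single, 1, 2))
})

test_that("participant-level zero inflation is honored for rare groups", {
  gp <- default_group_params()
  eps <- 0.05
  gp$zero_prob[gp$group_id == "tea_coffee"] <- 1 - eps
  n <- 800
  cfg <- sim_config(n_participants = n, seed = 5, group_params = gp)
  cohort <- generate_participants(cfg)
  recalls <- generate_recalls(cohort, cfg)
  tea <- recalls[recalls$group_id == "tea_coffee", ]
  zero_frac <- mean(tapply(tea$grams, tea$participant_id, max) == 0)
  se <- sqrt(eps * (1 - eps) / n)
  expect_gte(zero_frac, 1 - eps - 3 * se)
})

test_that("zero energy slopes decouple reported energy from intake", {
  gp <- default_group_params()
  gp$energy_slope <- 0
  cfg <- sim_config(n_participants = 600, seed = 13, group_params = gp)
  cohort <- generate_participants(cfg)
  recalls <- generate_recalls(cohort, cfg)
  day_grams <- tapply(recalls$grams, paste(recalls$participant_id,
                                           recalls$year, recalls$day), sum)
  day_kcal <- tapply(recalls$kcal, paste(recalls$participant_id,
                                         recalls$year, recalls$day), max)
  r <- cor(day_grams, day_kcal)
  expect_lt(abs(r), 3 / sqrt(length(day_grams)))
})

test_that("zero baseline hazard yields no incident events", {
  cfg <- sim_config(n_participants = 300, seed = 21,
                    baseline_hazard = c(overweight_obesity = 0,
                                        hypertension = 0, t2d = 0))
  ds <- simulate_cohort(cfg)
  for (oc in OUTCOMES) {
    s <- build_analysis_sample(ds, oc)
    expect_identical(sum(s$event), 0L)
  }
})

test_that("null index effect gives flat incidence across true-index quintiles", {
  lh <- lapply(OUTCOMES, function(o) list(index = 0, age = 0, male = 0))
  names(lh) <- OUTCOMES
  cfg <- sim_config(n_participants = 2500, seed = 31, true_loghr = lh)
  ds <- simulate_cohort(cfg)
  s <- build_analysis_sample(ds, "hypertension")
  truth_z <- ds$truth$true_index_z[match(s$participant_id,
                                         ds$truth$participant_id)]
  q <- assign_quintiles(truth_z)
  p_all <- mean(s$event)
  for (k in 1:5) {
    p_k <- mean(s$event[q == k])
    se <- sqrt(p_all * (1 - p_all) * (1 / sum(q == k) + 1 / length(q)))
    expect_lt(abs(p_k - p_all), 3 * se)
  }
})

test_that("misaligned truth table is rejected", {
  cfg <- sim_config(n_participants = 30, seed = 2)
  cohort <- generate_participants(cfg)
  recalls <- generate_recalls(cohort, cfg)
  truth <- generate_truth(cohort, recalls, cfg)
  expect_error(generate_outcomes(cohort, truth[rev(seq_len(nrow(truth))), ], cfg),
               "aligned")
})

test_that("ground truth is never an input to the analysis stages", {
  ds <- small_dataset()
  stripped <- ds
  stripped$truth <- NULL
  s1 <- build_analysis_sample(stripped, "t2d")
  s2 <- build_analysis_sample(ds, "t2d")
  expect_identical(s1, s2)
})
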