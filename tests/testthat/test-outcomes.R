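test_that("BMI and the >=24 overweight/obesity threshold", {
  expect_equal(compute_bmi(76.8, 1.60), 30)
  expect_true(classify_overweight(compute_bmi(76.8, 1.60)))
  expect_true(classify_overweight(24.0))
  expect_false(classify_overweight(23.9))
  expect_error(compute_bmi(-70, 1.6), "non-positive")
  expect_error(compute_bmi(70, 0), "non-positive")
})

test_that("hypertension: any of SBP>=140, DBP>=90, self-report or medication", {
  expect_true(classify_hypertension(140, 80, FALSE, FALSE))
  expect_true(classify_hypertension(120, 70, TRUE, FALSE))
  expect_true(classify_hypertension(120, 90, FALSE, FALSE))
  expect_false(classify_hypertension(139, 89, FALSE, FALSE))
  expect_true(is.na(classify_hypertension(NA, NA, NA, NA)))
  # a TRUE criterion dominates missing ones
  expect_true(classify_hypertension(NA, NA, TRUE, NA))
})

test_that("T2D rules differ by wave: biomarkers in 2009, self-report only in 2015", {
  expect_true(classify_t2d(2009, fpg = 7.0))
  expect_true(classify_t2d(2009, fpg = 6.0, hba1c = 6.5))
  expect_true(classify_t2d(2009, self_report = TRUE))
  expect_false(classify_t2d(2009, fpg = 6.9, hba1c = 6.4,
                            self_report = FALSE, on_medication = FALSE))
  # 2015: recorded biomarkers are ignored
  expect_false(classify_t2d(2015, fpg = 8.0, self_report = FALSE,
                            on_medication = FALSE))
  expect_true(classify_t2d(2015, self_report = TRUE))
  expect_true(is.na(classify_t2d(2009, NA, NA, NA, NA)))
})

test_that("raising a measurement never flips a positive diagnosis to negative", {
  sbp <- seq(100, 200, by = 5)
  flags <- classify_hypertension(sbp, 70, FALSE, FALSE)
  expect_true(all(diff(flags) >= 0))
  fpg <- seq(4, 12, by = 0.5)
  flags <- classify_t2d(rep(2009, length(fpg)), fpg, 5.5, FALSE, FALSE)
  expect_true(all(diff(flags) >= 0))
  expect_true(all(diff(classify_overweight(seq(18, 35))) >= 0))
})

test_that("follow-up arithmetic and person-years additivity", {
  expect_equal(compute_follow_up(2004, 2009, 2015), 5)
  expect_equal(compute_follow_up(2006, NA, 2015), 9)
  sample <- data.frame(follow_up_years = c(5, 9))
  expect_equal(person_years(sample), 14)
  expect_error(compute_follow_up(2006, 2004, 2015), "before baseline")
})

test_that("ascertainment: prevalence at baseline, events at first qualifying wave", {
  baseline <- data.frame(participant_id = c("A", "B", "C", "D", "E"),
                         baseline_year = c(2004, 2004, 2006, 2004, 2004))
  mk <- function(pid, wy, sbp, dbp, self = FALSE, med = FALSE,
                 fpg = NA, hba1c = NA, sdm = FALSE, mdm = FALSE,
                 wt = 60, ht = 1.65) {
    data.frame(participant_id = pid, wave_year = wy, weight = wt, height = ht,
               sbp = sbp, dbp = dbp, fpg = fpg, hba1c = hba1c,
               self_hypertension = self, htn_medication = med,
               self_diabetes = sdm, diabetes_medication = mdm)
  }
  waves <- rbind(
    mk("A", 2004, 150, 95), mk("A", 2009, 155, 96), mk("A", 2015, 150, 95),
    mk("B", 2004, 120, 75), mk("B", 2009, 145, 92), mk("B", 2015, 150, 95),
    mk("C", 2006, 118, 72), mk("C", 2009, 120, 70), mk("C", 2015, 119, 70, sdm = TRUE),
    mk("D", 2004, 115, 70), mk("D", 2009, 118, 72), mk("D", 2015, 120, 74),
    mk("E", 2004, 125, 80)
  )
  asc <- ascertain_outcomes(waves, baseline)
  ht <- asc[asc$outcome == "hypertension", ]
  rownames(ht) <- ht$participant_id
  expect_true(ht["A", "prevalent"])
  expect_false(ht["B", "prevalent"])
  expect_true(ht["B", "event"])
  expect_equal(ht["B", "event_wave_year"], 2009)
  expect_equal(ht["B", "follow_up_years"], 5)
  expect_false(ht["D", "event"])
  expect_equal(ht["D", "censor_wave_year"], 2015)
  expect_equal(ht["D", "follow_up_years"], 11)
  expect_true(ht["E", "missing"])     # no follow-up wave attended
  dm <- asc[asc$outcome == "t2d", ]
  rownames(dm) <- dm$participant_id
  expect_true(dm["C", "event"])       # detected at 2015 by self-report
  expect_equal(dm["C", "event_wave_year"], 2015)
  expect_equal(dm["C", "follow_up_years"], 9)
})

test_that("exclusion flow on a hand-enumerated 5-row fixture", {
  grp <- default_food_groups()
  one_day <- function(kcal) {
    list(data.frame(group_id = grp$group_id, grams = 50))
  }
  recalls <- do.call(rbind, lapply(1:5, function(i) {
    recall_rows(paste0("p", i), 2004, one_day(),
                kcal = c(400, 2000, 2100, 2200, 2300)[i])
  }))
  baseline <- data.frame(
    participant_id = paste0("p", 1:5), male = TRUE, age = 40, rural = TRUE,
    education = 2L, met = 150, smoking = FALSE, alcohol = FALSE,
    cvd_cancer = FALSE, baseline_year = 2004,
    has_year1 = TRUE, has_year2 = FALSE)
  mkw <- function(pid, wy, bmi, miss = FALSE) {
    data.frame(participant_id = pid, wave_year = wy,
               weight = if (miss) NA else bmi * 1.6^2,
               height = if (miss) NA else 1.6,
               sbp = 120, dbp = 75, fpg = NA, hba1c = NA,
               self_hypertension = FALSE, htn_medication = FALSE,
               self_diabetes = FALSE, diabetes_medication = FALSE)
  }
  waves <- rbind(
    mkw("p1", 2004, 21), mkw("p1", 2009, 21),
    mkw("p2", 2004, 25), mkw("p2", 2009, 26),    # prevalent overweight
    mkw("p3", 2004, 21), mkw("p3", 2009, 21, miss = TRUE),
    mkw("p4", 2004, 21), mkw("p4", 2009, 25),    # incident case
    mkw("p5", 2004, 21), mkw("p5", 2009, 21)
  )
  ds <- list(baseline = baseline, recalls = recalls, waves = waves)
  s <- suppressWarnings(build_analysis_sample(ds, "overweight_obesity"))
  ledger <- exclusion_ledger(s)
  expect_identical(unname(ledger["input"]), 5L)
  expect_identical(unname(ledger["energy"]), 1L)
  expect_identical(unname(ledger["prevalent_outcome"]), 1L)
  expect_identical(unname(ledger["missing_outcome"]), 1L)
  expect_identical(unname(ledger["retained"]), 2L)
  expect_identical(sum(ledger[-1][-6]), ledger[["input"]] - ledger[["retained"]])
  expect_identical(sort(s$participant_id), c("p4", "p5"))
  expect_identical(s$event[s$participant_id == "p4"], TRUE)
})

test_that("prevalence excludes per outcome: hypertensive at baseline stays in the T2D sample", {
  ds <- small_dataset()
  asc <- ascertain_outcomes(ds$waves, ds$baseline)
  prev_ht <- asc$participant_id[asc$outcome == "hypertension" &
                                !is.na(asc$prevalent) & asc$prevalent]
  s_ht <- build_analysis_sample(ds, "hypertension")
  s_dm <- build_analysis_sample(ds, "t2d")
  expect_identical(sum(s_ht$participant_id %in% prev_ht), 0L)
  expect_gt(sum(s_dm$participant_id %in% prev_ht), 0L)
})

test_that("exclusion ledger conserves participants for every outcome", {
  ds <- small_dataset()
  for (oc in OUTCOMES) {
    ledger <- exclusion_ledger(build_analysis_sample(ds, oc))
    excluded <- ledger[c("energy", "prevalent_cvd_cancer", "loss_to_followup",
                         "prevalent_outcome", "missing_outcome")]
    expect_identical(unname(sum(excluded) + ledger["retained"]),
                     ledger[["input"]])
  }
})

test_that("empty input yields an empty sample with an all-zero ledger", {
  ds <- small_dataset()
  empty <- list(baseline = ds$baseline[0, ], recalls = ds$recalls[0, ],
                waves = ds$waves[0, ])
  expect_warning(s <- build_analysis_sample(empty, "t2d"), "empty")
  expect_identical(nrow(s), 0L)
  expect_true(all(exclusion_ledger(s) == 0L))
})

test_that("analysis samples are independent of input row order", {
  ds <- small_dataset()
  set.seed(14)
  shuffled <- ds
  shuffled$waves <- ds$waves[sample(nrow(ds$waves)), ]
  shuffled$recalls <- ds$recalls[sample(nrow(ds$recalls)), ]
  a <- build_analysis_sample(ds, "hypertension")
  b <- build_analysis_sample(shuffled, "hypertension")
  expect_equal(b, a, ignore_attr = FALSE)
})
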