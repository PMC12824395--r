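test_that("dichotomization maps states to treatment/no-treatment", {
  expect_equal(dichotomize(rep("LACK", 12)), rep(0L, 12))
  s <- c("AD_MONO", rep("LACK", 11))
  expect_equal(dichotomize(s), c(1L, rep(0L, 11)))
  s2 <- c(rep("LITHIUM", 4), rep("CENSORED", 8))
  b <- dichotomize(s2)
  expect_equal(b[1:4], rep(1L, 4))
  expect_true(all(is.na(b[5:12])))
  expect_equal(sum(!is.na(b)), 4)
})

test_that("initiation timing uses the period-to-month mapping", {
  b <- function(first_one) {
    x <- rep(0L, 12); if (!is.na(first_one)) x[first_one:12] <- 1L; x
  }
  expect_equal(classify_initiation(b(1)), "early_0_3m")
  expect_equal(classify_initiation(b(2)), "delayed_4_12m")
  expect_equal(classify_initiation(b(4)), "delayed_4_12m")
  expect_equal(classify_initiation(b(5)), "delayed_ge12m")
  expect_equal(classify_initiation(b(12)), "delayed_ge12m")
  expect_equal(classify_initiation(b(NA)), "never")
  # pre-diagnosis AD monotherapy continuing into period 1 forces early
  expect_equal(classify_initiation(b(1), pre_dx_ad_monotherapy = TRUE),
               "early_0_3m")
  # ...but not when period 1 is untreated
  expect_equal(classify_initiation(b(2), pre_dx_ad_monotherapy = TRUE),
               "delayed_4_12m")
})

test_that("discontinuation bins follow the first treatment-to-lack gap", {
  expect_equal(classify_discontinuation(c(1, 1, 0, rep(0, 9))), "within_6m")
  expect_equal(classify_discontinuation(c(1, 0, 1, 0, rep(0, 8))),
               "within_6m")  # first transition governs (u = 2)
  expect_equal(classify_discontinuation(rep(1, 12)), "none")
  expect_equal(classify_discontinuation(rep(0, 12)), "none")
  expect_equal(classify_discontinuation(c(rep(1, 3), 0, rep(0, 8))),
               "within_1y")   # g = 3
  expect_equal(classify_discontinuation(c(rep(1, 5), 0, rep(0, 6))),
               "within_2y")   # g = 5
  expect_equal(classify_discontinuation(c(rep(1, 9), 0, 0, 0)),
               "after_2y")    # g = 9
  # delayed initiation shifts the clock
  expect_equal(classify_discontinuation(c(0, 0, 1, 1, 0, rep(0, 7))),
               "within_6m")   # t = 3, u = 5, g = 2
  # censoring truncates the evaluable window
  expect_equal(classify_discontinuation(c(1, 1, NA, NA, rep(NA, 8))),
               "none")
})

test_that("trajectories form an exhaustive, mutually exclusive partition", {
  set.seed(23)
  cohort <- generate_cohort(generator_config(300, seed = 31,
                                             death_rate = 0.05))
  up <- build_use_periods(cohort$dispensings)
  res <- build_sequences(cohort$persons, up, cohort$hospital_stays)
  rec <- classify_trajectories(res$sequences)
  expect_true(all(rec$trajectory %in% c("early_no_disc", "early_disc",
                                        "delayed_no_disc", "delayed_disc",
                                        "continuous_lack")))
  # never-initiated persons are exactly the continuous-lack trajectory
  expect_identical(rec$trajectory == "continuous_lack", !rec$initiated)
  expect_true(all(rec$discontinuation_class[!rec$initiated] == "none"))
  # early trajectories correspond exactly to early initiation
  early <- rec$initiation_class == "early_0_3m"
  expect_identical(rec$trajectory %in% c("early_no_disc", "early_disc"),
                   early)
  # identity: early initiators = early_no_disc + early_disc
  expect_equal(sum(early),
               sum(rec$trajectory == "early_no_disc") +
                 sum(rec$trajectory == "early_disc"))
})

test_that("trajectory summaries use the documented denominators", {
  groups <- c("a", "a", "a", "b", "b")
  rec <- data.frame(
    person_id = paste0("P", 1:5),
    initiated = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    initiation_class = c("early_0_3m", "delayed_4_12m", "never",
                         "delayed_ge12m", "early_0_3m"),
    discontinued = c(TRUE, FALSE, FALSE, TRUE, TRUE),
    discontinuation_class = c("within_6m", "none", "none", "within_2y",
                              "after_2y"),
    trajectory = c("early_disc", "delayed_no_disc", "continuous_lack",
                   "delayed_disc", "early_disc"),
    stringsAsFactors = FALSE)
  s <- summarize_trajectories(rec, groups)
  pick <- function(section, row, group)
    s[s$section == section & s$row == row & s$group == group, ]
  # initiation over all persons
  expect_equal(pick("initiation", "yes", "a")$n, 2)
  expect_equal(pick("initiation", "yes", "a")$denominator, 3)
  expect_equal(pick("initiation", "yes", "a")$percent, 66.7)
  # time to initiation among initiators
  expect_equal(pick("time_to_initiation", "early_0_3m", "b")$denominator, 2)
  # discontinuation restricted to initiators within one year:
  # person 4 (delayed_ge12m) is excluded from the denominator
  expect_equal(pick("discontinuation", "yes", "b")$denominator, 1)
  expect_equal(pick("discontinuation", "yes", "b")$n, 1)
  # time-to-discontinuation among within-a-year initiators who discontinue
  expect_equal(pick("time_to_discontinuation", "within_6m", "a")$n, 1)
  expect_equal(pick("time_to_discontinuation", "within_2y", "b")$n, 0)
  # per-group trajectory counts sum to group n
  traj <- s[s$section == "trajectory" & s$group == "a", ]
  expect_equal(sum(traj$n), 3)
})

test_that("pre-diagnosis AD monotherapy is detected from use periods", {
  persons <- data.frame(person_id = c("P1", "P2", "P3"),
                        diagnosis_date = as.Date("2010-01-01"))
  up <- rbind(
    data.frame(person_id = "P1", drug_class = "antidepressant",
               start_date = as.Date("2009-11-01"),
               end_date = as.Date("2010-02-01")),
    data.frame(person_id = "P2", drug_class = "antidepressant",
               start_date = as.Date("2009-11-01"),
               end_date = as.Date("2010-02-01")),
    data.frame(person_id = "P2", drug_class = "lithium",
               start_date = as.Date("2009-12-01"),
               end_date = as.Date("2010-02-01")))
  flags <- pre_diagnosis_ad_monotherapy(persons, up)
  expect_identical(flags, c(TRUE, FALSE, FALSE))
})

test_that("percentages round half away from zero", {
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(48.3108, 1), 48.3)
  expect_equal(round_half_up(86.55, 1), 86.6)
  expect_equal(round_half_up(-0.25, 1), -0.3)
})
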