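# Cohort reading, exclusion filtering, synthetic generation.

test_that("read_cohort parses a valid file, applying the dialect map", {
  df <- data.frame(
    id = c("a", "b", "c"), AgeYears = c(45, 70, 19), sex = c("M", "female", "male"),
    race_ethnicity = c("white_nh", "Black_NH", "martian"),
    covid_positive = c("true", "0", "yes"), sofa = c(3, 12, 0),
    elixhauser = c(-2, 0, 14), charlson_points = c(0, 2, 1),
    survived = c("TRUE", "FALSE", "1")
  )
  path <- write_temp_csv(df)
  co <- read_cohort(path, dialect = c(encounter_id = "id", age = "AgeYears"))
  expect_equal(nrow(co), 3L)
  expect_equal(co$age, c(45L, 70L, 19L))
  expect_equal(co$sex, c("male", "female", "male"))
  # unparseable race maps to unknown; case-insensitive otherwise
  expect_equal(co$race_ethnicity, c("white_nh", "black_nh", "unknown"))
  expect_equal(co$covid_positive, c(TRUE, FALSE, TRUE))
  expect_equal(co$survived, c(TRUE, FALSE, TRUE))
  expect_equal(co$elixhauser, c(-2L, 0L, 14L))
})

test_that("read_cohort rejects bad input with named errors", {
  base <- data.frame(
    encounter_id = "a", age = 50, sex = "male", race_ethnicity = "white_nh",
    covid_positive = "true", sofa = 3, elixhauser = 0, charlson_points = 0,
    survived = "true"
  )
  no_col <- base[, setdiff(names(base), "sofa")]
  expect_error(read_cohort(write_temp_csv(no_col)), "sofa")

  bad_sofa <- rbind(base, base)
  bad_sofa$sofa <- c("3", "")
  expect_error(read_cohort(write_temp_csv(bad_sofa)), "sofa in row.*2")

  bad_sex <- base
  bad_sex$sex <- "xy"
  expect_error(read_cohort(write_temp_csv(bad_sex)), "sex")

  bad_outcome <- base
  bad_outcome$survived <- "maybe"
  expect_error(read_cohort(write_temp_csv(bad_outcome)), "survived")

  expect_error(read_cohort(tempfile()), "not found")
})

test_that("apply_exclusions filters by reason with fixed precedence", {
  raw <- data.frame(
    sofa = c(NA, 5, NA, 7, 2),
    discharge_disposition = c("", "", "", "home", "died"),
    has_icd10 = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    has_covid_test = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    ambiguous_intubation = c(TRUE, FALSE, FALSE, TRUE, FALSE)
  )
  out <- apply_exclusions(raw)
  # row 1 matches (i), (ii) and (iii) but is counted once, under (i)
  expect_equal(unname(out$report["no_sofa"]), 2L)
  expect_equal(unname(out$report["no_outcome_data"]), 1L)
  expect_equal(unname(out$report["ambiguous_intubation"]), 1L)
  expect_equal(nrow(out$retained), 1L)
  expect_equal(out$retained$sofa, 2)
})

test_that("apply_exclusions partitions the input and never mutates retained", {
  raw <- data.frame(sofa = c(1, NA, 3), note = c("x", "y", "z"))
  out <- apply_exclusions(raw)
  expect_equal(out$report[["retained"]] +
                 sum(out$report[c("no_sofa", "no_outcome_data",
                                  "ambiguous_intubation")]),
               out$report[["total"]])
  expect_identical(out$retained$note, c("x", "z"))
  expect_identical(out$retained$sofa, c(1, 3))

  empty <- apply_exclusions(raw[0, , drop = FALSE])
  expect_equal(nrow(empty$retained), 0L)
  expect_equal(unname(empty$report[["total"]]), 0L)
})

test_that("apply_exclusions reproduces the study's exclusion accounting", {
  # 4604 admission records with injected reason counts 320/245/332
  n <- 4604L
  raw <- data.frame(
    sofa = rep(1, n), discharge_disposition = rep("home", n),
    has_icd10 = rep(TRUE, n), has_covid_test = rep(TRUE, n),
    ambiguous_intubation = rep(FALSE, n)
  )
  raw$sofa[1:320] <- NA
  i2 <- 321:565  # 245 records with no outcome data at all
  raw$discharge_disposition[i2] <- ""
  raw$has_icd10[i2] <- FALSE
  raw$has_covid_test[i2] <- FALSE
  raw$ambiguous_intubation[566:897] <- TRUE  # 332 ambiguous intubations
  out <- apply_exclusions(raw)
  expect_equal(unname(out$report[c("no_sofa", "no_outcome_data",
                                   "ambiguous_intubation")]),
               c(320L, 245L, 332L))
  expect_equal(nrow(out$retained), 3707L)
})

test_that("cohort_spec validates its inputs before any sampling", {
  expect_error(cohort_spec(race_probs = c(white_nh = 0.5, black_nh = 0.4)),
               "summing to 1")
  expect_error(cohort_spec(covid_fraction_override = 1.5), "\\[0,1\\]")
  expect_error(cohort_spec(survival_model = list(intercept = NA, or_sofa = -1,
                                                 or_age = 1, or_elixhauser = 1)),
               "positive")
  spec <- cohort_spec()
  expect_equal(spec$survival_model$or_sofa, 0.896)
  expect_equal(spec$survival_model$or_age, 0.964)
  expect_equal(spec$survival_model$or_elixhauser, 1.054)
})

test_that("generate_cohort handles n = 0 and is reproducible", {
  expect_equal(nrow(generate_cohort(cohort_spec(n = 0))), 0L)
  a <- generate_cohort(cohort_spec(n = 300, seed = 9))
  b <- generate_cohort(cohort_spec(n = 300, seed = 9))
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_spec(n = 300, seed = 10))
  expect_false(identical(a, c2))
})

test_that("generated cohorts satisfy the encounter invariants", {
  co <- generate_cohort(cohort_spec(n = 3000, seed = 4))
  expect_silent(validate_cohort(co))
  expect_true(all(co$age >= 18 & co$age <= 100))
  expect_true(all(co$sofa >= 0 & co$sofa <= 24))
  expect_true(all(co$charlson_points >= 0))
  # race-conditional structure: Black/Hispanic younger than White
  expect_lt(mean(co$age[co$race_ethnicity == "black_nh"]),
            mean(co$age[co$race_ethnicity == "white_nh"]) - 3)
  expect_gt(mean(co$covid_positive[co$race_ethnicity == "black_nh"]),
            mean(co$covid_positive[co$race_ethnicity == "white_nh"]))
})

test_that("covid_fraction_override pins the COVID+ mix", {
  co <- generate_cohort(cohort_spec(n = 4000, seed = 5,
                                    covid_fraction_override = 0.9))
  expect_gt(mean(co$covid_positive), 0.85)
  expect_lt(mean(co$covid_positive), 0.95)
})

test_that("intercept calibration hits the survival target", {
  co <- generate_cohort(cohort_spec(n = 20000, seed = 6))
  expect_lt(abs(mean(co$survived) - 0.72), 0.02)
  # and an explicit intercept is honored instead of calibrated
  co2 <- generate_cohort(cohort_spec(
    n = 5000, seed = 6,
    survival_model = list(intercept = 10, or_sofa = 1, or_age = 1,
                          or_elixhauser = 1)))
  expect_gt(mean(co2$survived), 0.99)
})

test_that("write_cohort / read_cohort round-trip", {
  co <- generate_cohort(cohort_spec(n = 50, seed = 11))
  co$life_expectancy <- NULL
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back, co)
})
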