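# Metrics: rates, lives and life-years saved, direct age standardization.

test_that("survival and allocation rates match a hand-counted toy result", {
  co <- toy_cohort(sofa = c(1, 2, 3, 4), survived = c(TRUE, TRUE, FALSE, TRUE),
                   life_expectancy = c(40, 30, 20, 10))
  alloc <- rbind(c(TRUE, TRUE, FALSE, FALSE),
                 c(TRUE, FALSE, TRUE, FALSE))
  res <- manual_result(alloc, co, capacity = 0.5)
  sr <- survival_rate(res)
  expect_equal(sr$per_replicate, c(2 / 4, 1 / 4))
  expect_equal(sr$mean, 3 / 8)
  ar <- allocation_rate(res)
  expect_equal(ar$per_replicate, c(0.5, 0.5))
  # all allocated, all survive -> 1
  full <- manual_result(matrix(TRUE, 1, 4),
                        toy_cohort(sofa = 1:4, life_expectancy = rep(10, 4)),
                        0.5)
  expect_equal(survival_rate(full)$mean, 1)
  expect_equal(allocation_rate(full)$mean, 1)
})

test_that("subgroup rates decompose the overall rate", {
  co <- default_test_cohort()
  res <- run_simulation(co, "colorado_20", 0.5, replicates = 25, seed = 14)
  races <- unique(co$race_ethnicity)
  per_rep_sum <- rowSums(vapply(races, function(r) {
    idx <- co$race_ethnicity == r
    survival_rate(res, idx)$per_replicate * sum(idx)
  }, numeric(25)))
  expect_equal(per_rep_sum / nrow(co), survival_rate(res)$per_replicate)
})

test_that("empty subgroups yield an undefined-rate marker, not an error", {
  co <- toy_cohort(sofa = 1:4, life_expectancy = rep(10, 4))
  res <- manual_result(matrix(TRUE, 2, 4), co, 0.5)
  out <- survival_rate(res, rep(FALSE, 4))
  expect_true(out$undefined)
  expect_true(is.na(out$mean))
  expect_true(isTRUE(lives_saved(res, rep(FALSE, 4))$undefined))
})

test_that("lives saved is the survival excess over expected survival", {
  co <- toy_cohort(sofa = 1:4, survived = c(TRUE, TRUE, FALSE, FALSE),
                   life_expectancy = c(10, 10, 10, 10))
  # S_B = 0.5; with c = 0.5 expected survival = 0.25
  alloc <- rbind(c(TRUE, FALSE, TRUE, FALSE),   # S_sim = 0.25 -> LS = 0
                 c(TRUE, TRUE, FALSE, FALSE))   # S_sim = 0.5  -> LS = 0.25
  res <- manual_result(alloc, co, 0.5)
  ls <- lives_saved(res)
  expect_equal(ls$per_replicate, c(0, 0.25))
  expect_equal(ls$per_1000, 125)
})

test_that("life-years saved handles total mortality and missing annotation", {
  co <- toy_cohort(sofa = 1:4, survived = rep(FALSE, 4),
                   life_expectancy = c(10, 20, 30, 40))
  res <- manual_result(matrix(c(TRUE, TRUE, FALSE, FALSE), 1), co, 0.5)
  lys <- life_years_saved(res)
  expect_equal(lys$ly_b, 0)        # nobody survives at baseline either
  expect_equal(lys$mean, 0)
  # survivors: LY_sim counts only allocated survivors
  co2 <- toy_cohort(sofa = 1:4, survived = c(TRUE, FALSE, TRUE, TRUE),
                    life_expectancy = c(10, 20, 30, 40))
  res2 <- manual_result(matrix(c(TRUE, TRUE, FALSE, FALSE), 1), co2, 0.5)
  # LY_B = (10+30+40)/4 = 20; LY_sim = 10/4 = 2.5; LYS = 2.5 - 10
  expect_equal(life_years_saved(res2)$mean, 2.5 - 20 * 0.5)
  co2$life_expectancy[3] <- NA
  res3 <- manual_result(matrix(TRUE, 1, 4), co2, 0.5)
  expect_error(life_years_saved(res3), "toy-003")
})

test_that("lottery saves no lives or life-years in expectation", {
  co <- default_test_cohort()
  res <- run_simulation(co, "lottery", 0.5, replicates = 400, seed = 23)
  ls <- lives_saved(res)
  lys <- life_years_saved(res)
  expect_lt(abs(ls$mean), 3.5 * ls$se)
  expect_lt(abs(lys$mean), 3.5 * lys$se)
})

test_that("directly standardized rate is a weighted stratum mean", {
  expect_equal(age_adjusted_rate(c(20, 40), c(100, 100), c(0.5, 0.5))$rate,
               0.3)
  # invariance: equal stratum rates reproduce the common rate
  out <- age_adjusted_rate(c(30, 60, 90), c(100, 200, 300),
                           c(0.2, 0.3, 0.5))
  expect_equal(out$rate, 0.3)
  expect_lte(out$ci_lower, out$rate)
  expect_gte(out$ci_upper, out$rate)
  # two strata, rates 0.2 / 0.8, equal weights -> 0.5
  expect_equal(age_adjusted_rate(c(20, 80), c(100, 100), c(0.5, 0.5))$rate,
               0.5)
})

test_that("zero-denominator strata are dropped with renormalized weights", {
  expect_warning(
    out <- age_adjusted_rate(c(20, 0), c(100, 0), c(0.5, 0.5)),
    "zero denominator")
  expect_equal(out$rate, 0.2)
})

test_that("the Tiwari modification narrows the Fay-Feuer upper bound", {
  d <- c(5, 10, 3); n <- c(50, 80, 20); w <- c(0.3, 0.5, 0.2)
  tiw <- age_adjusted_rate(d, n, w, method = "tiwari")
  ff <- age_adjusted_rate(d, n, w, method = "fay_feuer")
  expect_equal(tiw$rate, ff$rate)
  expect_lt(tiw$ci_upper, ff$ci_upper)
  expect_equal(tiw$ci_lower, ff$ci_lower)
})

test_that("age-adjusted survival equals the crude rate when the subgroup age
           distribution is the standard", {
  co <- default_test_cohort()
  res <- run_simulation(co, "maryland_21", 0.5, replicates = 30, seed = 9)
  crude <- survival_rate(res)
  adj <- age_adjusted_survival(res)   # standard = full cohort distribution
  expect_equal(adj$per_replicate, crude$per_replicate, tolerance = 1e-12)
})

test_that("baseline age-adjusted survival matches the crude overall rate", {
  co <- default_test_cohort()
  out <- baseline_age_adjusted_survival(co)
  expect_equal(out$rate, mean(co$survived), tolerance = 1e-12)
  expect_true(out$ci_lower < out$rate && out$rate < out$ci_upper)
})

test_that("Monte Carlo CI width shrinks roughly as 1/sqrt(replicates)", {
  co <- default_test_cohort()
  r1 <- run_simulation(co, "age", 0.5, replicates = 50, seed = 3)
  r2 <- run_simulation(co, "age", 0.5, replicates = 450, seed = 3)
  w1 <- with(survival_rate(r1), ci_upper - ci_lower)
  w2 <- with(survival_rate(r2), ci_upper - ci_lower)
  expect_lt(w2, w1 / 1.8)   # expect ~1/3, allow slack
})

test_that("lives and life-years saved correlate across replicates", {
  co <- default_test_cohort()
  res <- run_simulation(co, "pure_sofa", 0.5, replicates = 120, seed = 19)
  ls <- lives_saved(res)$per_replicate
  lys <- life_years_saved(res)$per_replicate
  expect_gt(cor(ls, lys), 0)
})
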