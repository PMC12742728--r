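test_that("percentage error follows the (predicted - actual)/actual convention", {
  expect_equal(percent_error(110, 100), 10)
  expect_equal(percent_error(90, 100), -10)
  expect_equal(percent_error(64.5, 64.5), 0)
  expect_error(percent_error(70, 0), "strictly positive")
  expect_error(percent_error(70, -5), "strictly positive")
})

test_that("within-tolerance percentage counts boundary cases as within", {
  expect_equal(p_within(c(95, 120, 100), c(100, 100, 100), 0.10), 100 * 2 / 3)
  expect_equal(p_within(c(110), c(100), 0.10), 100)  # exactly 10% off counts
  expect_equal(p_within(c(110.0001), c(100), 0.10), 0)
  x <- runif(25, 50, 90)
  expect_equal(p_within(x, x, 0.10), 100)
  expect_error(p_within(numeric(), numeric(), 0.10), "at least")
  expect_error(p_within(1, 1, 0), "positive")
})

test_that("within-tolerance percentage is scale invariant", {
  set.seed(3)
  pred <- runif(40, 40, 120); act <- runif(40, 40, 120)
  for (k in c(0.5, 2, 17.3)) {
    expect_equal(p_within(k * pred, k * act, 0.10), p_within(pred, act, 0.10))
  }
})

test_that("mean percentage error averages signed errors", {
  expect_equal(mean_percentage_error(c(110, 90), c(100, 100)), 0)
  expect_equal(mean_percentage_error(110, 100), 10)
  act <- runif(30, 50, 100)
  expect_equal(mean_percentage_error(1.05 * act, act), 5, tolerance = 1e-12)
})

test_that("Bland-Altman statistics match closed-form and loop oracles", {
  # alternating +/-1 differences: bias 0, s = sqrt(4/3)
  ba <- bland_altman(c(51, 49, 51, 49), c(50, 50, 50, 50))
  s <- sqrt(4 / 3)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, s, tolerance = 1e-9)
  expect_equal(ba$loa_lower, -1.96 * s, tolerance = 1e-9)
  expect_equal(ba$loa_upper, 1.96 * s, tolerance = 1e-9)

  set.seed(99)
  for (i in 1:10) {
    n <- sample(3:20, 1)
    pred <- runif(n, 40, 120); act <- runif(n, 40, 120)
    got <- bland_altman(pred, act)
    want <- oracle_bland_altman(pred, act)
    expect_equal(got$bias, want$bias, tolerance = 1e-12)
    expect_equal(got$sd, want$sd, tolerance = 1e-12)
    expect_equal(got$loa_lower, want$loa_lower, tolerance = 1e-12)
    expect_equal(got$loa_upper, want$loa_upper, tolerance = 1e-12)
    expect_equal(got$bias_ci, want$bias_ci, tolerance = 1e-12)
    expect_equal(got$loa_lower_ci, want$loa_lower_ci, tolerance = 1e-12)
    expect_equal(got$loa_upper_ci, want$loa_upper_ci, tolerance = 1e-12)
    expect_equal(mean_percentage_error(pred, act), oracle_mpe(pred, act),
                 tolerance = 1e-12)
  }
})

test_that("Bland-Altman handles degenerate and tiny inputs explicitly", {
  x <- c(60, 70, 80)
  ba <- bland_altman(x, x)
  expect_true(ba$degenerate)
  expect_equal(ba$loa_lower, 0)
  expect_equal(ba$loa_upper, 0)
  expect_error(bland_altman(c(1, 2), c(1, 2)), "n >= 3")
  # plot points are (pair mean, difference)
  ba <- bland_altman(c(52, 49, 60), c(50, 50, 50))
  expect_equal(ba$points$pair_mean, c(51, 49.5, 55))
  expect_equal(ba$points$difference, c(2, -1, 10))
})

test_that("BMI and WHO nutrition categories use the stated boundaries", {
  expect_equal(bmi(64.5, 162.5), 64.5 / 1.625^2)
  expect_equal(bmi(100, 100), 100)
  expect_equal(bmi(18.5 * 1.60^2, 160), 18.5, tolerance = 1e-12)
  expect_error(bmi(-1, 160), "positive")
  expect_identical(
    as.character(classify_nutrition(c(18.49, 18.5, 24.43, 24.99, 25, 29.99, 30, 45))),
    c("underweight", "normal", "normal", "normal",
      "overweight", "overweight", "obese", "obese")
  )
})

test_that("stratified accuracy partitions counts and keeps P10 <= P20", {
  cohort <- generate_cohort(synthetic_config(n_per_stratum = 10, seed = 5))
  rep <- stratified_accuracy(cohort, "all", axes = c("overall", "sex", "nutrition"))
  expect_equal(nrow(rep), 9 * (1 + 2 + 4))
  ok <- !is.na(rep$p10)
  expect_true(all(rep$p10[ok] <= rep$p20[ok] + 1e-12))
  expect_true(all(rep$ba_loa_lower[ok] <= rep$ba_bias[ok] &
                    rep$ba_bias[ok] <= rep$ba_loa_upper[ok]))

  # within-10% counts add up across any partition axis
  overall <- rep[rep$axis == "overall", ]
  for (ax in c("sex", "nutrition")) {
    part <- rep[rep$axis == ax, ]
    for (id in equation_ids()) {
      o <- overall[overall$equation == id, ]
      p <- part[part$equation == id, ]
      expect_equal(sum(p$n_evaluated), o$n_evaluated)
      expect_equal(sum(p$p10 * p$n_evaluated / 100), o$p10 * o$n_evaluated / 100,
                   tolerance = 1e-9)
    }
  }
})

test_that("empty strata are emitted with n = 0 and NA metrics", {
  cohort <- generate_cohort(synthetic_config(n_per_stratum = 4, seed = 8))
  males <- cohort[cohort$sex == "male", ]
  rep <- stratified_accuracy(males, "R3", axes = "sex")
  fem <- rep[rep$level == "female", ]
  expect_equal(fem$n_evaluated, 0L)
  expect_true(is.na(fem$p10) && is.na(fem$ba_bias))
})

test_that("a zero-noise planted cohort gives the planted equation perfect scores", {
  cfg <- synthetic_config(n_per_stratum = 5, seed = 21,
                          planted_equation = "R3", planted_noise_sd = 0)
  cohort <- plant_equation_truth(cfg)
  rep <- stratified_accuracy(cohort, "all", axes = c("overall", "sex", "nutrition"))
  r3 <- rep[rep$equation == "R3" & rep$n_evaluated > 0, ]
  expect_true(all(r3$p10 == 100))
  expect_true(all(r3$p20 == 100))
  expect_true(all(abs(r3$ba_bias) < 1e-12))
})
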