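# Aggregation, ranked intervals, bootstrap, head counts and valuation.

test_that("ranked summaries follow the ceiling-rank rule", {
  expect_equal(summarize_runs(1:1000),
               c(median = 500, lower95 = 25, upper95 = 975))
  expect_equal(summarize_runs(rep(7, 50)),
               c(median = 7, lower95 = 7, upper95 = 7))
  expect_equal(summarize_runs(1:40),
               c(median = 20, lower95 = 1, upper95 = 39))
  # order-invariant
  set.seed(6)
  v <- rnorm(123)
  expect_equal(summarize_runs(v), summarize_runs(sample(v)))
  s <- summarize_runs(v)
  expect_lte(s[["lower95"]], s[["median"]])
  expect_lte(s[["median"]], s[["upper95"]])
  expect_error(summarize_runs(1:10), "40")
})

test_that("ranked 95% intervals carry about 95% of the outcome distribution", {
  # for a known-distribution toy outcome the interval between the 25th and
  # 975th ranked values of 1000 runs holds ~95% of the outcome mass, and it
  # always contains the true median
  set.seed(7)
  mass <- replicate(200, {
    s <- summarize_runs(rnorm(1000))
    pnorm(s[["upper95"]]) - pnorm(s[["lower95"]])
  })
  expect_gt(mean(mass), 0.93)
  expect_lt(mean(mass), 0.97)
  covered <- replicate(200, {
    s <- summarize_runs(rnorm(1000))
    s[["lower95"]] <= 0 && 0 <= s[["upper95"]]
  })
  expect_gt(mean(covered), 0.95)
})

test_that("aggregation computes working-age outcomes by definition", {
  n <- 100
  snap <- data.frame(
    age = rep(40, n), activity = rep("employed", n),
    in_poverty = rep(FALSE, n), cmd_case = rep(c(TRUE, FALSE), c(30, 70)),
    ghq_likert = seq(0, 36, length.out = n),
    equivalised_income = as.numeric(1:n))
  a <- aggregate_outcomes(snap, scaling_factor = 446)
  expect_equal(a$employment_rate, 1)
  expect_equal(a$cmd_prevalence, 30 / 100)
  q <- quantile(1:100, c(0.1, 0.9), type = 7, names = FALSE)
  expect_equal(a$p90p10, q[2] / q[1])
  expect_equal(a$p90p10, 8.2661, tolerance = 1e-4)
  expect_equal(a$headcount_working_age, 100 * 446)
  expect_error(aggregate_outcomes(snap[0, ], 446), "empty working-age")
})

test_that("paired effects difference observed minus counterfactual", {
  pr <- small_paired()
  expect_equal(paired_effect(pr$observed, pr$counterfactual,
                             "cmd_prevalence", 2019), 0)
  expect_equal(paired_effect(pr$observed, pr$counterfactual,
                             "employment_rate", 2018), 0)
  e20 <- paired_effect(pr$observed, pr$counterfactual, "cmd_prevalence", 2020)
  expect_lt(e20, 0)  # preventative effect is negative
  expect_equal(e20, pr$effects$cmd_prevalence[pr$effects$year == 2020])
  mism <- pr$counterfactual; mism$draw_id <- 999L
  expect_error(paired_effect(pr$observed, mism, "cmd_prevalence", 2020),
               "not paired")
})

test_that("head counts convert rate differences at national scale", {
  expect_equal(headcount(0.021, 77400, 446), 725000)
  expect_equal(headcount(0.034, 77400, 446), 1174000)
  expect_equal(headcount(0, 77400, 446), 0)
  expect_equal(headcount(-0.021, 77400, 446), 725000)  # magnitude
  expect_error(headcount(0.1, 0, 446), "positive")
})

test_that("QALY valuation is the decrement times the tariff, linear in cases", {
  v <- qaly_valuation(1242731)
  expect_equal(v$qalys, 161555, tolerance = 1e-5)
  expect_equal(round(v$value / 1e9, 2), 11.31)
  expect_equal(qaly_valuation(0)$value, 0)
  expect_equal(qaly_valuation(1)$qalys, 0.13)
  expect_equal(qaly_valuation(1)$value, 9100)
  # homogeneous of degree one
  expect_equal(qaly_valuation(700)$value, 7 * qaly_valuation(100)$value)
  expect_error(qaly_valuation(-5), "nonnegative")
})

test_that("zero variance draws reproduce the point estimates", {
  base <- model_coefficients()
  base$mh$step2[grep("_se$", names(base$mh$step2))] <- 1e-12
  base$mh$step1_vcov <- matrix(0, 2, 2)
  base$transitions$intercept_se <- 0
  d <- draw_coefficients(base, seed = 10)
  expect_equal(d$mh$step2$male_likert, model_coefficients()$mh$step2$male_likert,
               tolerance = 1e-6)
  expect_equal(unname(d$mh$step1_likert),
               unname(model_coefficients()$mh$step1_likert))
  bad <- model_coefficients()
  bad$mh$step1_vcov <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(draw_coefficients(bad, seed = 10), "positive semidefinite")
})

test_that("subgroup decomposition is consistent with the overall effect", {
  pr <- small_paired()
  se <- distressim:::subgroup_effects(pr, 2020)
  ov <- se[se$group == "overall", ]
  expect_equal(ov$cmd_prevalence,
               paired_effect(pr$observed, pr$counterfactual,
                             "cmd_prevalence", 2020))
  # complementary sex subgroups person-weighted average to the overall effect
  m <- se[se$group == "males", ]
  f <- se[se$group == "females", ]
  wavg <- (m$cmd_prevalence * m$n_observed + f$cmd_prevalence * f$n_observed) /
    (m$n_observed + f$n_observed)
  expect_equal(wavg, ov$cmd_prevalence, tolerance = 5e-3)
  # identical arms give all-zero subgroup effects
  prid <- pr
  prid$counterfactual <- pr$observed
  seid <- distressim:::subgroup_effects(prid, 2019)
  expect_true(all(seid$cmd_prevalence == 0, na.rm = TRUE))
})
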