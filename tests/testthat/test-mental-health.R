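# Two-step psychological-distress process.

mh <- mh_coefficients()

test_that("transition flags follow their definitions", {
  # no change, income unchanged
  f <- derive_transitions("employed", "employed", TRUE, 0, FALSE, FALSE, 0,
                          10000, 10000)
  expect_false(any(unlist(f[c("emp_exit", "emp_entry", "ne_longterm",
                              "pov_entry", "pov_exit", "pov_longterm",
                              "income_decrease")])))
  expect_equal(f$income_growth, 0)
  # employment exit while at risk
  f <- derive_transitions("employed", "not_employed", TRUE, 0, FALSE, FALSE,
                          0, 10000, 10000)
  expect_true(f$emp_exit); expect_false(f$emp_entry)
  # second consecutive not-employed year: long-term flag
  f <- derive_transitions("not_employed", "not_employed", TRUE, 1, FALSE,
                          FALSE, 0, 10000, 10000)
  expect_true(f$ne_longterm)
  # furlough counts as employment: no exit flag
  f <- derive_transitions("employed", "furlough_full", TRUE, 0, FALSE, FALSE,
                          0, 10000, 9000)
  expect_false(f$emp_exit)
  expect_true(f$income_decrease)
  expect_equal(f$income_growth, -0.1)
  # growth clamped, zero when prior income nonpositive
  f <- derive_transitions("employed", "employed", TRUE, 0, FALSE, FALSE, 0,
                          c(1000, 0), c(5000, 5000))
  expect_equal(f$income_growth, c(1, 0))
})

test_that("flag invariants hold across random inputs", {
  set.seed(2)
  n <- 500
  acts <- c("employed", "not_employed", "furlough_full", "student")
  f <- derive_transitions(sample(acts, n, TRUE), sample(acts, n, TRUE),
                          sample(c(TRUE, FALSE), n, TRUE),
                          sample(0:3, n, TRUE),
                          sample(c(TRUE, FALSE), n, TRUE),
                          sample(c(TRUE, FALSE), n, TRUE),
                          sample(0:3, n, TRUE),
                          runif(n, -1000, 30000), runif(n, 0, 30000))
  expect_false(any(f$emp_exit & f$emp_entry))
  expect_false(any(f$pov_entry & f$pov_exit))
  expect_true(all(f$income_growth >= -1 & f$income_growth <= 1))
  expect_identical(f$income_decrease, f$income_growth < 0)
})

test_that("step 1 is the configured autoregression with clamping", {
  ident <- mh_coefficients(step1_likert = c(intercept = 0, persistence = 1),
                           step1_likert_sd = 0)
  expect_equal(step1_predict(c(3, 11.3, 36), ident, noise = 0)$likert,
               c(3, 11.3, 36))
  # the shipped intercept makes the pre-crisis median a fixed point
  expect_equal(step1_predict(11.3, mh, noise = 0)$likert, 11.3)
  # clamped to [0, 36]
  expect_equal(step1_predict(36, mh, noise = 100)$likert, 36)
  expect_equal(step1_predict(0, mh, noise = -100)$likert, 0)
})

test_that("step 2 applies the configured additive effects", {
  none <- derive_transitions("employed", "employed", TRUE, 0, FALSE, FALSE,
                             0, 1e4, 1e4)
  exit <- derive_transitions("employed", "not_employed", TRUE, 0, FALSE,
                             FALSE, 0, 1e4, 1e4)
  # male employment exit, non-pandemic year
  s <- step2_update(10, 0, exit, "male", 2018, mh, caseness_u = 1)
  expect_equal(s$likert - 10, 2.74)
  # female, no flags, 2020: non-economic pandemic pathway alone
  s <- step2_update(10, 0, none, "female", 2020, mh, caseness_u = 1)
  expect_equal(s$likert - 10, 1.41)
  # caseness log-odds arithmetic: baseline probability 0.2 plus male exit
  s <- step2_update(10, qlogis(0.2), exit, "male", 2018, mh, caseness_u = 1)
  expect_equal(s$cmd_prob, plogis(qlogis(0.2) + 1.46))
  expect_equal(s$cmd_prob, 0.5184, tolerance = 1e-4)
  # income growth term only
  grow <- none; grow$income_growth <- 0.10
  s <- step2_update(10, 0, grow, "female", 2018, mh, caseness_u = 1)
  expect_equal(s$likert - 10, -0.12 * 0.10)
  expect_error(step2_update(10, 0, none, "male", 1800, mh), "year")
})

test_that("exit followed by re-entry nets to zero for males", {
  exit <- derive_transitions("employed", "not_employed", TRUE, 0, FALSE,
                             FALSE, 0, 1e4, 1e4)
  entry <- derive_transitions("not_employed", "employed", TRUE, 0, FALSE,
                              FALSE, 0, 1e4, 1e4)
  a <- step2_update(10, 0, exit, "male", 2018, mh, caseness_u = 1)
  b <- step2_update(a$likert, 0, entry, "male", 2019, mh, caseness_u = 1)
  expect_equal(b$likert, 10)
})

test_that("income losses outweigh equivalent gains for both sexes", {
  none <- derive_transitions("employed", "employed", TRUE, 0, FALSE, FALSE,
                             0, 1e4, 1e4)
  for (sex in c("male", "female")) {
    for (g in seq(0.02, 1, by = 0.07)) {
      up <- none; up$income_growth <- g
      dn <- none; dn$income_growth <- -g; dn$income_decrease <- TRUE
      du <- step2_update(15, 0, up, sex, 2018, mh, caseness_u = 1)$likert - 15
      dd <- step2_update(15, 0, dn, sex, 2018, mh, caseness_u = 1)$likert - 15
      expect_gt(abs(dd), abs(du))
    }
  }
})

test_that("distress outputs stay within bounds for arbitrary inputs", {
  set.seed(3)
  n <- 300
  flags <- derive_transitions(sample(c("employed", "not_employed"), n, TRUE),
                              sample(c("employed", "not_employed"), n, TRUE),
                              TRUE, sample(0:2, n, TRUE),
                              sample(c(TRUE, FALSE), n, TRUE),
                              sample(c(TRUE, FALSE), n, TRUE),
                              sample(0:2, n, TRUE),
                              runif(n, 1, 2e4), runif(n, 1, 2e4))
  s1 <- step1_predict(runif(n, 0, 36), mh, seed = 4)
  expect_true(all(s1$likert >= 0 & s1$likert <= 36))
  s2 <- step2_update(s1$likert, s1$caseness_logodds, flags,
                     sample(c("male", "female"), n, TRUE), 2020, mh,
                     caseness_u = runif(n))
  expect_true(all(s2$likert >= 0 & s2$likert <= 36))
  expect_true(all(s2$cmd_prob > 0 & s2$cmd_prob < 1))
  expect_type(s2$cmd_case, "logical")
})

test_that("the 0-12 caseness threshold is four or more", {
  expect_true(caseness_from_likert(4))
  expect_false(caseness_from_likert(3))
  expect_false(caseness_from_likert(0))
  expect_true(caseness_from_likert(12))
  expect_error(caseness_from_likert(13), "0, 12")
})

test_that("coefficient files load with positive standard errors", {
  expect_s3_class(mh, "mh_coefficients")
  ses <- distressim:::step2_ses(mh, "likert", "male")
  expect_true(all(ses > 0))
  bad <- mh$step2; bad$male_likert_se[1] <- -1
  expect_error(mh_coefficients(step2 = bad), "positive")
})
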