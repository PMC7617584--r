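# Structural and reduced-form labour supply.

test_that("potential wages are deterministic, education-ordered and floored", {
  expect_equal(potential_wage(40, "male", "medium", 0.1),
               potential_wage(40, "male", "medium", 0.1))
  expect_gte(potential_wage(40, "female", "high"),
             potential_wage(40, "female", "low"))
  expect_gte(potential_wage(16, "female", "low", -3), 8)  # minimum wage
  expect_error(potential_wage(40, "male", "low", at_risk = FALSE),
               "at risk")
})

test_that("utility is monotone in income and hours", {
  prefs <- preference_coefficients()
  expect_gt(labour_utility(20000, 20, 0, prefs),
            labour_utility(15000, 20, 0, prefs))
  expect_lt(labour_utility(20000, 30, 0, prefs),
            labour_utility(20000, 20, 0, prefs))
  z <- preference_coefficients(income_weight = 1e-12, hours_weight = -1e-12,
                               female_shift = 0, children_shift = 0,
                               edu_high_shift = 0, state_dependence = 0)
  expect_equal(labour_utility(20000, 40, 0, z), 0, tolerance = 1e-6)
})

test_that("with no taste shock the unique maximiser is always chosen", {
  prefs <- preference_coefficients(error_scale = 0)
  b <- budget_set(14, system = uk2019_baseline())
  idx <- choose_labour_supply(b, prefs, n_draws = 10)
  v <- labour_utility(b$disposable, b$hours1, b$hours2, prefs)
  expect_true(all(idx == which.max(v)))
})

test_that("ties at zero shock break toward lowest total hours", {
  prefs <- preference_coefficients(error_scale = 0,
                                   income_weight = 1e-9,
                                   hours_weight = -1e-12)
  b <- data.frame(hours1 = c(0, 20, 40), hours2 = NA,
                  gross = c(0, 0, 0), disposable = c(0, 0, 0))
  expect_equal(choose_labour_supply(b, prefs), 1L)
})

test_that("choice frequencies match conditional-logit probabilities", {
  prefs <- preference_coefficients(error_scale = 1)
  b <- data.frame(hours1 = c(0, 20, 40), hours2 = NA, gross = c(0, 1, 2),
                  disposable = c(5000, 12000, 18000))
  v <- labour_utility(b$disposable, b$hours1, b$hours2, prefs)
  p <- exp(v) / sum(exp(v))
  n <- 1e5
  ch <- choose_labour_supply(b, prefs, n_draws = n, seed = 13)
  emp <- tabulate(ch, 3) / n
  mcse <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(emp - p) < 3 * mcse))
  # two equal-utility alternatives split evenly
  b2 <- data.frame(hours1 = c(10, 30), hours2 = NA, gross = 0:1,
                   disposable = c(10000, 10000 + 20 * 1000 *
                                    -prefs$hours_weight / prefs$income_weight))
  ch2 <- choose_labour_supply(b2, prefs, n_draws = n, seed = 14)
  expect_lt(abs(mean(ch2 == 1) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("implied transition rows always sum to one", {
  tm <- transition_model()
  for (y21 in 0:1) {
    X <- covariate_grid(y21)
    for (s in tm$states) {
      for (sc in c("observed", "counterfactual")) {
        P <- transition_probs(s, X, tm, sc)
        expect_equal(unname(rowSums(P)), rep(1, nrow(X)))
        expect_true(all(P >= 0))
      }
    }
  }
})

test_that("zero coefficients give uniform sampling over allowed end states", {
  tm <- transition_model()
  tm$coef$employed <- lapply(tm$coef$employed, function(b) { b[] <- 0; b })
  X <- data.frame(female = rep(0, 1e5))
  end <- pandemic_transition("employed", X, tm, "observed", seed = 15)
  freq <- table(end) / 1e5
  expect_equal(length(freq), 4)
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 1e5)))
})

test_that("counterfactual reassigns furlough mass to non-employment exactly", {
  tm <- transition_model()
  X <- covariate_grid()
  for (s in c("employed", "furlough_full", "furlough_partial")) {
    po <- transition_probs(s, X, tm, "observed")
    pcf <- transition_probs(s, X, tm, "counterfactual")
    fur <- intersect(colnames(po), c("furlough_full", "furlough_partial"))
    expect_false(any(fur %in% colnames(pcf)))
    expect_equal(pcf[, "not_employed"],
                 po[, "not_employed"] + rowSums(po[, fur, drop = FALSE]))
    expect_equal(pcf[, "employed"], po[, "employed"])
  }
  expect_error(transition_probs("zombie", X, tm), "unknown starting state")
})

test_that("pandemic hours respect the end state", {
  n <- 2000
  end <- rep(c("furlough_full", "employed", "not_employed",
               "furlough_partial"), n / 4)
  prior <- rep(40, n)
  h <- pandemic_hours(end, prior, seed = 16)
  expect_true(all(h[end == "furlough_full"] == 0))
  expect_true(all(h[end == "not_employed"] == 0))
  expect_true(all(h[end == "employed"] == 40))  # persistence
  hp <- h[end == "furlough_partial"]
  expect_true(all(hp >= 1 & hp <= 39))
  # entrants draw positive structural hour points
  h0 <- pandemic_hours(rep("employed", 100), rep(0, 100), seed = 17)
  expect_true(all(h0 %in% c(10, 20, 30, 40)))
})

test_that("the diagnostic transition table covers the covariate grid", {
  tab <- transition_matrix(scenario = "counterfactual")
  expect_false(any(grepl("furlough", tab$end)))
  agg <- tapply(tab$probability,
                paste(tab$start, tab$female, tab$age50, tab$edu_low,
                      tab$edu_high, tab$children), sum)
  expect_equal(as.vector(agg), rep(1, length(agg)))
})
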