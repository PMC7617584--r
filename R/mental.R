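# Two-step psychological-distress process (GHQ-12).
# Step 1 predicts a baseline from lagged distress and demographics, excluding
# current-period economic outcomes.  Step 2 applies additive effects of
# economic transitions (Likert points / caseness log-odds) plus non-economic
# pandemic-year constants.

.MH_EFFECTS <- c("emp_exit", "emp_entry", "ne_longterm", "pov_entry",
                 "pov_exit", "pov_longterm", "income_growth",
                 "income_decrease", "pandemic_2020", "pandemic_2021")

#' Mental-health coefficient set
#'
#' Bundles the step-1 prediction coefficients (linear for the 0-36 Likert
#' outcome, logistic for caseness) with the step-2 effect table: for each sex,
#' additive Likert-point and caseness log-odds effects of six economic
#' transitions, an income-growth-rate coefficient, an income-decrease
#' constant, and non-economic pandemic constants for 2020 and 2021.  The
#' shipped default step-2 table is read from
#' `inst/extdata/mental_health_coefficients.csv`; step-1 defaults use
#' persistence 0.5 with the intercept set so the pre-crisis working-age
#' median of 11.3 is a fixed point, and a caseness predictor calibrated to a
#' 20% pre-crisis prevalence.
#'
#' @param step2 data frame of step-2 effects (as in the shipped CSV); if
#'   `NULL` the shipped defaults are loaded.
#' @param step1_likert named vector with elements `intercept` and
#'   `persistence` (coefficient on the lagged Likert score).
#' @param step1_likert_sd standard deviation of the step-1 residual draw
#'   (Likert points).
#' @param step1_caseness named vector `intercept`, `slope` for the logistic
#'   predictor of caseness from the lagged Likert score.
#' @param step1_vcov 2x2 variance-covariance matrix for the step-1 Likert
#'   coefficients (used by the coefficient bootstrap).
#' @param caseness_mode `"bernoulli"` (draw the binary caseness state from the
#'   updated probability) or `"expected"` (carry the probability itself).
#' @return an object of class `mh_coefficients`.
#' @export
mh_coefficients <- function(step2 = NULL,
                            step1_likert = c(intercept = 5.65,
                                             persistence = 0.5),
                            step1_likert_sd = 4.5,
                            step1_caseness = c(intercept = -3.80,
                                               slope = 0.185),
                            step1_vcov = diag(c(0.05^2, 0.005^2)),
                            caseness_mode = c("bernoulli", "expected")) {
  if (is.null(step2)) {
    step2 <- utils::read.csv(system.file("extdata",
                                         "mental_health_coefficients.csv",
                                         package = "distressim"),
                             stringsAsFactors = FALSE)
  }
  stopifnot(all(.MH_EFFECTS %in% step2$effect))
  se_cols <- grep("_se$", names(step2), value = TRUE)
  if (any(unlist(step2[se_cols]) <= 0)) stop("standard errors must be positive")
  structure(list(
    step2 = step2,
    step1_likert = step1_likert,
    step1_likert_sd = step1_likert_sd,
    step1_caseness = step1_caseness,
    step1_vcov = step1_vcov,
    caseness_mode = match.arg(caseness_mode)
  ), class = "mh_coefficients")
}

#' Read a mental-health coefficient file
#' @param path CSV file in the shipped format.
#' @param ... passed to [mh_coefficients()].
#' @return an `mh_coefficients` object.
#' @export
read_mh_coefficients <- function(path, ...) {
  mh_coefficients(step2 = utils::read.csv(path, stringsAsFactors = FALSE), ...)
}

#' @export
print.mh_coefficients <- function(x, ...) {
  cat("Mental-health coefficient set\n")
  cat(sprintf("  step 1 (Likert): intercept %.2f, persistence %.2f, sd %.2f\n",
              x$step1_likert["intercept"], x$step1_likert["persistence"],
              x$step1_likert_sd))
  cat(sprintf("  step 1 (caseness): logit = %.2f + %.3f x lagged Likert\n",
              x$step1_caseness["intercept"], x$step1_caseness["slope"]))
  cat("  step 2 effects:\n")
  print(x$step2[, c("effect", "male_likert", "female_likert",
                    "male_caseness", "female_caseness")], row.names = FALSE)
  invisible(x)
}

# named effect vector for one (outcome, sex)
step2_effects <- function(coefficients, outcome = c("likert", "caseness"),
                          sex = c("male", "female")) {
  outcome <- match.arg(outcome)
  sex <- match.arg(sex)
  col <- paste0(sex, "_", outcome)
  stats::setNames(coefficients$step2[[col]],
                  coefficients$step2$effect)[.MH_EFFECTS]
}

step2_ses <- function(coefficients, outcome = c("likert", "caseness"),
                      sex = c("male", "female")) {
  outcome <- match.arg(outcome)
  sex <- match.arg(sex)
  col <- paste0(sex, "_", outcome, "_se")
  stats::setNames(coefficients$step2[[col]],
                  coefficients$step2$effect)[.MH_EFFECTS]
}

#' Derive economic-transition flags between two consecutive years
#'
#' Computes the six transition indicators used by the step-2 update, plus the
#' growth rate of equivalised household disposable income and the
#' income-decrease indicator.  Employment transitions are defined for persons
#' at risk of work; the furlough states count as employment (the employment
#' contract is preserved).  Entry into a "long-term" state is the second
#' consecutive year in the state (the year counter moves from 1 to 2).  The
#' growth rate is clamped to `[-1, 1]` and set to 0 when prior income is
#' nonpositive.
#'
#' All arguments are vectorised over persons.
#'
#' @param prev_activity,activity activity state at t-1 and t.
#' @param at_risk at risk of work at t?
#' @param prev_years_not_employed consecutive not-employed years as of t-1.
#' @param prev_in_poverty,in_poverty poverty status at t-1 and t.
#' @param prev_years_in_poverty consecutive poverty years as of t-1.
#' @param prev_eq_income,eq_income equivalised household disposable income at
#'   t-1 and t (GBP/year).
#' @return data frame of class `transition_flags` with logical columns
#'   `emp_exit`, `emp_entry`, `ne_longterm`, `pov_entry`, `pov_exit`,
#'   `pov_longterm`, `income_decrease` and numeric `income_growth`.
#' @export
derive_transitions <- function(prev_activity, activity, at_risk,
                               prev_years_not_employed,
                               prev_in_poverty, in_poverty,
                               prev_years_in_poverty,
                               prev_eq_income, eq_income) {
  employed_states <- c("employed", "furlough_full", "furlough_partial")
  prev_emp <- prev_activity %in% employed_states
  now_emp <- activity %in% employed_states
  prev_ne <- prev_activity == "not_employed"
  now_ne <- activity == "not_employed"

  growth <- ifelse(prev_eq_income > 0,
                   (eq_income - prev_eq_income) / prev_eq_income, 0)
  growth <- clamp(growth, -1, 1)

  out <- data.frame(
    emp_exit = prev_emp & now_ne & at_risk,
    emp_entry = prev_ne & now_emp,
    ne_longterm = prev_ne & now_ne & at_risk & prev_years_not_employed == 1,
    pov_entry = !prev_in_poverty & in_poverty,
    pov_exit = prev_in_poverty & !in_poverty,
    pov_longterm = prev_in_poverty & in_poverty & prev_years_in_poverty == 1,
    income_growth = growth,
    income_decrease = growth < 0
  )
  class(out) <- c("transition_flags", "data.frame")
  out
}

#' Step-1 baseline prediction of psychological distress
#'
#' Predicts a baseline Likert score (linear) and caseness log-odds (logistic)
#' from the lagged Likert score and demographics, excluding current-period
#' economic outcomes.  A mean-zero normal residual with the configured sd is
#' added to the Likert prediction, which is then clamped to `[0, 36]`.
#'
#' @param lagged_likert previous-year Likert score (vectorised).
#' @param coefficients an [mh_coefficients()] object.
#' @param noise residual draw(s) to add (Likert points); if `NULL`, drawn
#'   internally as `rnorm(n, 0, step1_likert_sd)` (optionally under `seed`).
#' @param seed optional seed for the internal residual draw.
#' @return list with elements `likert` (baseline score in `[0, 36]`) and
#'   `caseness_logodds`.
#' @export
step1_predict <- function(lagged_likert, coefficients = mh_coefficients(),
                          noise = NULL, seed = NULL) {
  n <- length(lagged_likert)
  if (is.null(noise)) {
    noise <- if (is.null(seed))
      stats::rnorm(n, 0, coefficients$step1_likert_sd)
    else with_seed(seed, stats::rnorm(n, 0, coefficients$step1_likert_sd))
  }
  b <- coefficients$step1_likert
  likert <- clamp(b[["intercept"]] + b[["persistence"]] * lagged_likert +
                    noise, 0, 36)
  cc <- coefficients$step1_caseness
  logodds <- cc[["intercept"]] + cc[["slope"]] * lagged_likert
  list(likert = likert, caseness_logodds = logodds)
}

#' Step-2 update of psychological distress from economic transitions
#'
#' Adds to the step-1 baseline the sex-specific effects of the flagged
#' economic transitions, the income-growth term, the income-decrease constant
#' and, in pandemic years, the non-economic pandemic constant.  The Likert
#' score is clamped to `[0, 36]`; the caseness log-odds receive the analogous
#' log-odds effects and are converted to a probability.
#'
#' @param baseline_likert step-1 Likert baseline (vectorised).
#' @param baseline_logodds step-1 caseness log-odds.
#' @param flags a [derive_transitions()] result (or compatible data frame).
#' @param sex `"male"`/`"female"`, vectorised.
#' @param year simulation year (pandemic constants apply when `year` is in
#'   `pandemic_years`).
#' @param coefficients an [mh_coefficients()] object.
#' @param pandemic_years years in which the non-economic constants apply.
#' @param caseness_u optional uniforms in `[0,1]` for the Bernoulli caseness
#'   draw (common-random-number callers supply these); drawn internally if
#'   `NULL` and `caseness_mode` is `"bernoulli"`.
#' @return list with `likert`, `cmd_prob`, `cmd_case`.
#' @export
step2_update <- function(baseline_likert, baseline_logodds, flags, sex,
                         year, coefficients = mh_coefficients(),
                         pandemic_years = c(2020, 2021),
                         caseness_u = NULL) {
  if (length(year) != 1 || year < 1990 || year > 2100)
    stop("year outside the supported simulation range")
  n <- length(baseline_likert)
  sex <- rep_len(sex, n)
  delta_l <- numeric(n)
  delta_c <- numeric(n)
  for (s in c("male", "female")) {
    idx <- sex == s
    if (!any(idx)) next
    el <- step2_effects(coefficients, "likert", s)
    ec <- step2_effects(coefficients, "caseness", s)
    m <- sum(idx)
    p2020 <- as.numeric(length(pandemic_years) >= 1 && year == pandemic_years[1])
    p2021 <- as.numeric(length(pandemic_years) >= 2 && year == pandemic_years[2])
    X <- cbind(flags$emp_exit[idx], flags$emp_entry[idx],
               flags$ne_longterm[idx], flags$pov_entry[idx],
               flags$pov_exit[idx], flags$pov_longterm[idx],
               flags$income_growth[idx], flags$income_decrease[idx],
               rep(p2020, m), rep(p2021, m))
    keys <- c("emp_exit", "emp_entry", "ne_longterm", "pov_entry", "pov_exit",
              "pov_longterm", "income_growth", "income_decrease",
              "pandemic_2020", "pandemic_2021")
    delta_l[idx] <- as.numeric(X %*% el[keys])
    delta_c[idx] <- as.numeric(X %*% ec[keys])
  }
  likert <- clamp(baseline_likert + delta_l, 0, 36)
  logodds <- baseline_logodds + delta_c
  prob <- stats::plogis(logodds)
  case <- if (coefficients$caseness_mode == "expected") {
    prob >= 0.5
  } else {
    if (is.null(caseness_u)) caseness_u <- stats::runif(n)
    caseness_u < prob
  }
  list(likert = likert, cmd_prob = prob, cmd_case = case)
}

#' Caseness threshold on the 0-12 GHQ scoring
#'
#' On the 0-12 caseness scoring of the GHQ-12, a score of four or more
#' indicates a potential common mental disorder.  Used for synthetic-data
#' initialisation and documentation of the measure; within the simulation the
#' binary state follows the log-odds pathway.
#'
#' @param score GHQ-12 caseness score, 0-12 (vectorised).
#' @return logical.
#' @export
caseness_from_likert <- function(score) {
  if (any(score < 0 | score > 12)) stop("caseness score must be in [0, 12]")
  score >= 4
}
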