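# Synthetic initial population, alignment targets and estimation panels.
# Stands in for restricted-access household microdata: a household-structured
# agent population with demographics, activity states, wages, hours and GHQ-12
# distress, calibrated to printed pre-crisis aggregates.

.REGIONS <- c("UKC", "UKD", "UKE", "UKF", "UKG", "UKH", "UKI", "UKJ",
              "UKK", "UKL", "UKM", "UKN")
.REGION_SHARES <- c(0.040, 0.110, 0.082, 0.072, 0.089, 0.093, 0.134, 0.137,
                    0.084, 0.047, 0.082, 0.028)
# five-year age-band weights of a mature-population pyramid (0-4 ... 80-84, 85+)
.AGE_BAND_W <- c(0.059, 0.063, 0.060, 0.056, 0.063, 0.068, 0.068, 0.066,
                 0.062, 0.065, 0.068, 0.065, 0.055, 0.049, 0.048, 0.033,
                 0.024, 0.028)
.ALIGN_BANDS <- c(0, 16, 25, 35, 45, 55, 65, 75, Inf)

align_band <- function(age) {
  cut(age, breaks = .ALIGN_BANDS, right = FALSE,
      labels = c("0-15", "16-24", "25-34", "35-44", "45-54", "55-64",
                 "65-74", "75+"))
}

#' Population configuration
#'
#' @param n_individuals number of simulated agents (desk default 20,000; the
#'   full-scale configuration uses 150,000).
#' @param national_population population represented (66.9 million).
#' @param scaling_factor persons represented per agent; defaults to
#'   `national_population / n_individuals` (446 at full scale).
#' @param seed RNG seed for population generation.
#' @param employment_anchor,poverty_anchor,cmd_anchor,likert_anchor pre-crisis
#'   (2019) calibration anchors: working-age employment rate, poverty rate,
#'   prevalence of common mental disorders, and median GHQ-12 Likert score.
#' @param growth_rate annual growth applied to alignment targets.
#' @return object of class `population_config`.
#' @export
population_config <- function(n_individuals = 20000,
                              national_population = 66.9e6,
                              scaling_factor = round(national_population /
                                                       n_individuals),
                              seed = 1,
                              employment_anchor = 0.75,
                              poverty_anchor = 0.09,
                              cmd_anchor = 0.20,
                              likert_anchor = 11.3,
                              growth_rate = 0.005) {
  if (n_individuals < 100) stop("n_individuals must be at least 100")
  stopifnot(employment_anchor > 0, employment_anchor < 1,
            poverty_anchor > 0, poverty_anchor < 1,
            cmd_anchor > 0, cmd_anchor < 1,
            likert_anchor >= 0, likert_anchor <= 36)
  structure(list(n_individuals = n_individuals,
                 national_population = national_population,
                 scaling_factor = scaling_factor, seed = seed,
                 employment_anchor = employment_anchor,
                 poverty_anchor = poverty_anchor,
                 cmd_anchor = cmd_anchor, likert_anchor = likert_anchor,
                 growth_rate = growth_rate),
            class = "population_config")
}

#' Generate the synthetic initial population
#'
#' Draws a full age pyramid (ages 0 to 85+) with sex, region and education
#' margins, partitions adults and children into benefit units (couples formed
#' with age-band-specific probability, children attached to family units),
#' assigns activity states so the working-age (25-64) employment rate matches
#' the configured anchor, draws persistent wage components and hours, and
#' initialises GHQ-12 distress so the working-age median Likert score and CMD
#' prevalence match their anchors.  Initial incomes and poverty status are
#' computed once under `system` so that first-year transitions have coherent
#' lags.  Identical seeds give identical populations.
#'
#' @param config a [population_config()].
#' @param system policy system used to initialise incomes (defaults to the
#'   pre-crisis baseline).
#' @param mh an [mh_coefficients()] set (supplies the caseness slope used in
#'   the initial caseness calibration).
#' @return object of class `simpop`: list with `persons` and `units` data
#'   frames and the `config`.
#' @export
generate_population <- function(config = population_config(),
                                system = uk2019_baseline(),
                                mh = mh_coefficients()) {
  with_seed(config$seed, generate_population_impl(config, system, mh))
}

generate_population_impl <- function(config, system, mh) {
  n <- config$n_individuals

  band <- sample(seq_along(.AGE_BAND_W), n, TRUE,
                 .AGE_BAND_W / sum(.AGE_BAND_W))
  age <- ifelse(band < 18, (band - 1) * 5 + sample(0:4, n, TRUE),
                85 + sample(0:10, n, TRUE))
  sex <- sample(c("male", "female"), n, TRUE, c(0.49, 0.51))
  region <- sample(.REGIONS, n, TRUE, .REGION_SHARES)
  education <- ifelse(age < 16, "low",
                      sample(c("low", "medium", "high"), n, TRUE,
                             c(0.20, 0.45, 0.35)))

  # activity states and at-risk status
  long_term_sick <- age >= 16 & age < 65 &
    stats::runif(n) < (0.02 + 0.0015 * pmax(0, age - 25))
  student <- age < 16 |
    (age >= 16 & age <= 24 & !long_term_sick &
       stats::runif(n) < c(rep(0.9, 2), rep(0.45, 3), rep(0.15, 4))[
         pmin(pmax(age - 15, 1), 9)]) |
    (age >= 25 & age < 65 & !long_term_sick & stats::runif(n) < 0.01)
  activity <- rep("not_employed", n)
  activity[student] <- "student"
  activity[age >= 65] <- "retired"
  at_risk <- !(activity %in% c("student", "retired")) & !long_term_sick

  # employment: hit the working-age anchor exactly, then employ younger
  # at-risk adults at a similar rate
  wa <- age >= 25 & age <= 64
  target_emp <- round(config$employment_anchor * sum(wa))
  cand <- which(wa & at_risk)
  if (length(cand) < target_emp)
    stop("population too small or too sick to reach the employment anchor")
  employed <- logical(n)
  employed[sample(cand, target_emp)] <- TRUE
  young <- which(!wa & age >= 16 & age < 25 & at_risk)
  employed[young] <- stats::runif(length(young)) < 0.62
  activity[employed] <- "employed"

  hours <- numeric(n)
  hours[employed] <- sample(c(10, 20, 30, 40), sum(employed), TRUE,
                            c(0.08, 0.12, 0.15, 0.65))

  wage_draw <- stats::rnorm(n, 0, wage_coefficients()$draw_sd)

  # GHQ-12 Likert: right-skewed scaled Beta calibrated so the working-age
  # median matches the anchor
  a <- stats::uniroot(function(a) stats::qbeta(0.5, a, 5) -
                        config$likert_anchor / 36,
                      c(0.05, 30))$root
  ghq_likert <- 36 * stats::rbeta(n, a, 5)
  # caseness probability: logistic in the Likert score, intercept solved so
  # working-age prevalence matches the anchor
  slope <- mh$step1_caseness[["slope"]]
  alpha <- stats::uniroot(function(al)
    mean(stats::plogis(al + slope * ghq_likert[wa])) - config$cmd_anchor,
    c(-15, 5))$root
  cmd_prob <- stats::plogis(alpha + slope * ghq_likert)
  cmd_case <- stats::runif(n) < cmd_prob

  persons <- data.frame(
    person_id = seq_len(n), age = age, sex = sex, region = region,
    education = education, activity = activity,
    long_term_sick = long_term_sick,
    self_rated_health = sample(1:5, n, TRUE, c(0.04, 0.10, 0.22, 0.36, 0.28)),
    at_risk_of_work = at_risk,
    wage_draw = wage_draw, potential_wage = NA_real_,
    hours = hours, usual_hours = ifelse(hours > 0, hours, 40),
    ghq_likert = ghq_likert, cmd_prob = cmd_prob, cmd_case = cmd_case,
    years_not_employed = ifelse(activity == "not_employed" & at_risk, 1L, 0L),
    years_in_poverty = 0L,
    unit_id = NA_integer_, partner_id = NA_integer_,
    stringsAsFactors = FALSE
  )
  persons$potential_wage <- potential_wage(persons$age, persons$sex,
                                           persons$education,
                                           persons$wage_draw)

  persons <- assign_units(persons)

  # initial incomes/poverty under the pre-crisis system so year-1 transition
  # lags are coherent
  persons$equivalised_income <- NA_real_
  persons$in_poverty <- NA
  inc <- unit_incomes(persons, system)
  persons$equivalised_income <- inc$eq_income[match(persons$unit_id,
                                                    inc$unit_id)]
  line <- 0.6 * stats::median(persons$equivalised_income)
  persons$in_poverty <- poverty_status(persons$equivalised_income, line)
  persons$years_in_poverty <- ifelse(persons$in_poverty, 1L, 0L)

  structure(list(persons = persons, units = build_units(persons),
                 config = config, poverty_line = line),
            class = "simpop")
}

# couple formation and child attachment; operates inside the generation seed
assign_units <- function(persons) {
  n <- nrow(persons)
  adult <- persons$age >= 18
  p_couple <- ifelse(persons$age < 25, 0.20,
                     ifelse(persons$age < 65, 0.60, 0.55))
  wants <- adult & stats::runif(n) < p_couple
  males <- which(wants & persons$sex == "male")
  females <- which(wants & persons$sex == "female")
  males <- males[order(persons$age[males])]
  females <- females[order(persons$age[females])]
  k <- min(length(males), length(females))
  males <- males[seq_len(k)]; females <- females[seq_len(k)]
  persons$partner_id[males] <- persons$person_id[females]
  persons$partner_id[females] <- persons$person_id[males]

  unit_id <- rep(NA_integer_, n)
  unit_id[males] <- seq_len(k)
  unit_id[females] <- unit_id[males]
  singles <- which(adult & is.na(unit_id))
  unit_id[singles] <- k + seq_along(singles)
  # attach children to family-capable units (an adult aged 22-55), couples
  # first; attachment probability 0.4, count 1-3
  children <- which(!adult)
  fam_adult <- adult & persons$age >= 22 & persons$age <= 55
  fam_units <- unique(unit_id[fam_adult])
  couple_units <- unique(unit_id[males])
  fam_units <- fam_units[order(!(fam_units %in% couple_units),
                               stats::runif(length(fam_units)))]
  pool <- sample(children)
  for (uid in fam_units) {
    if (!length(pool)) break
    if (stats::runif(1) < 0.4) {
      take <- min(sample(1:3, 1, prob = c(0.45, 0.40, 0.15)), length(pool))
      unit_id[pool[seq_len(take)]] <- uid
      pool <- pool[-seq_len(take)]
    }
  }
  if (length(pool) && length(fam_units)) {
    unit_id[pool] <- rep_len(fam_units, length(pool))
  } else if (length(pool)) {
    unit_id[pool] <- rep_len(unique(unit_id[adult]), length(pool))
  }
  persons$unit_id <- unit_id
  persons
}

#' Benefit-unit table derived from the person table
#'
#' One row per benefit unit: its one or two adults, counts of dependent
#' children (under 18) by age group.
#' @param persons the person data frame of a `simpop`.
#' @return data frame keyed by `unit_id`.
#' @export
build_units <- function(persons) {
  adult <- persons$age >= 18
  ord <- order(persons$unit_id[adult], persons$person_id[adult])
  uid <- persons$unit_id[adult][ord]
  pid <- persons$person_id[adult][ord]
  first <- !duplicated(uid)
  units <- data.frame(unit_id = uid[first], adult1 = pid[first],
                      adult2 = NA_integer_)
  second <- uid[!first]
  units$adult2[match(second, units$unit_id)] <- pid[!first]
  ch <- persons[!adult, c("unit_id", "age")]
  tab <- function(sel) {
    t <- table(factor(ch$unit_id[sel], levels = units$unit_id))
    as.integer(t)
  }
  units$n_children_u14 <- tab(ch$age < 14)
  units$n_children_14plus <- tab(ch$age >= 14)
  units$n_children <- units$n_children_u14 + units$n_children_14plus
  units$n_adults <- 1L + !is.na(units$adult2)
  units
}

#' @export
print.simpop <- function(x, ...) {
  p <- x$persons
  wa <- p$age >= 25 & p$age <= 64
  cat(sprintf("Synthetic population: %d persons (%d benefit units), scaling factor %d\n",
              nrow(p), nrow(x$units), x$config$scaling_factor))
  cat(sprintf("  working age 25-64: %d; employment %.1f%%, CMD prevalence %.1f%%, median Likert %.1f\n",
              sum(wa),
              100 * mean(p$activity[wa] %in%
                           c("employed", "furlough_full", "furlough_partial")),
              100 * mean(p$cmd_case[wa]), stats::median(p$ghq_likert[wa])))
  invisible(x)
}

#' Alignment targets from the initial population margins
#'
#' Per (year, sex, age band, region) population counts: the initial margins
#' grown smoothly at the configured annual rate, standing in for official
#' population projections.
#'
#' @param config a [population_config()].
#' @param years year range (within 2017-2025).
#' @param persons optional person table supplying the initial margins; when
#'   `NULL` the population is generated from `config`.
#' @return data frame of class `alignment_targets` with columns `year`,
#'   `sex`, `age_band`, `region`, `count`.
#' @export
generate_alignment_targets <- function(config, years, persons = NULL) {
  if (!length(years)) stop("empty year range")
  if (any(years < 2017 | years > 2025)) stop("years must lie within 2017-2025")
  if (is.null(persons)) persons <- generate_population(config)$persons
  base <- as.data.frame(table(sex = persons$sex,
                              age_band = align_band(persons$age),
                              region = persons$region),
                        stringsAsFactors = FALSE)
  names(base)[4] <- "count0"
  out <- do.call(rbind, lapply(years, function(y) {
    g <- (1 + config$growth_rate)^(y - min(years))
    # cumulative rounding preserves the year total despite small cells
    count <- diff(c(0, round(cumsum(base$count0 * g))))
    data.frame(year = y, sex = base$sex, age_band = base$age_band,
               region = base$region, count = count)
  }))
  class(out) <- c("alignment_targets", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# estimation panel + fixed-effects recovery harness

#' Generate a longitudinal estimation panel
#'
#' Builds a balanced panel in which the GHQ-12 Likert outcome is constructed
#' additively from configured true effects (individual fixed effects + wave
#' effects + transition effects + income terms + i.i.d. noise), for
#' parameter-recovery checks of the fixed-effects estimator that produces the
#' step-2 inputs.
#'
#' @param n_persons persons (half male, half female).
#' @param n_waves waves (at least 3); transitions occur from wave 2 on.
#' @param true_effects an [mh_coefficients()] set supplying the sex-specific
#'   Likert effects.
#' @param seed RNG seed.
#' @param noise_sd sd of the i.i.d. outcome noise.
#' @param fe_sd,wave_sd sds of the individual and wave effects.
#' @param employment_probs probabilities of (none, exit, entry, long-term)
#'   employment events per person-wave.
#' @param poverty_probs probabilities of (none, entry, exit, long-term)
#'   poverty events per person-wave.
#' @param growth_sd sd of the income growth rate.
#' @return long data frame, one row per person-wave.
#' @export
generate_estimation_panel <- function(n_persons, n_waves,
                                      true_effects = mh_coefficients(),
                                      seed = 1, noise_sd = 2,
                                      fe_sd = 2, wave_sd = 0.5,
                                      employment_probs = c(0.85, 0.05, 0.06,
                                                           0.04),
                                      poverty_probs = c(0.89, 0.04, 0.04,
                                                        0.03),
                                      growth_sd = 0.12) {
  if (n_waves < 3) stop("n_waves must be at least 3")
  if (sum(employment_probs[-1]) <= 0 && sum(poverty_probs[-1]) <= 0)
    stop("degenerate transition frequencies: no transitions would ever occur")
  with_seed(seed, {
    N <- n_persons * n_waves
    person <- rep(seq_len(n_persons), each = n_waves)
    wave <- rep(seq_len(n_waves), n_persons)
    sex <- rep(rep(c("male", "female"), length.out = n_persons),
               each = n_waves)
    alpha <- rep(stats::rnorm(n_persons, 0, fe_sd), each = n_waves)
    tau <- stats::rnorm(n_waves, 0, wave_sd)[wave]
    emp_ev <- sample(c("none", "emp_exit", "emp_entry", "ne_longterm"),
                     N, TRUE, employment_probs)
    pov_ev <- sample(c("none", "pov_entry", "pov_exit", "pov_longterm"),
                     N, TRUE, poverty_probs)
    emp_ev[wave == 1] <- "none"
    pov_ev[wave == 1] <- "none"
    growth <- clamp(stats::rnorm(N, 0, growth_sd), -1, 1)
    growth[wave == 1] <- 0
    pan <- data.frame(
      person = person, wave = wave, sex = sex,
      emp_exit = emp_ev == "emp_exit", emp_entry = emp_ev == "emp_entry",
      ne_longterm = emp_ev == "ne_longterm",
      pov_entry = pov_ev == "pov_entry", pov_exit = pov_ev == "pov_exit",
      pov_longterm = pov_ev == "pov_longterm",
      income_growth = growth, income_decrease = growth < 0,
      stringsAsFactors = FALSE
    )
    y <- 11 + alpha + tau + stats::rnorm(N, 0, noise_sd)
    for (s in c("male", "female")) {
      idx <- pan$sex == s
      ef <- step2_effects(true_effects, "likert", s)
      X <- as.matrix(pan[idx, c("emp_exit", "emp_entry", "ne_longterm",
                                "pov_entry", "pov_exit", "pov_longterm",
                                "income_growth", "income_decrease")]) * 1
      y[idx] <- y[idx] + as.numeric(X %*% ef[colnames(X)])
    }
    pan$ghq_likert <- y
    pan
  })
}

#' Two-way fixed-effects estimation on an estimation panel
#'
#' Recovers the transition and income effects by sex via the two-way within
#' transformation (double demeaning over persons and waves, exact for a
#' balanced panel) followed by OLS.
#'
#' @param panel a [generate_estimation_panel()] result.
#' @return data frame with `sex`, `effect`, `estimate`, `se`.
#' @export
estimate_panel_effects <- function(panel) {
  vars <- c("emp_exit", "emp_entry", "ne_longterm", "pov_entry", "pov_exit",
            "pov_longterm", "income_growth", "income_decrease")
  out <- list()
  for (s in unique(panel$sex)) {
    d <- panel[panel$sex == s, ]
    demean <- function(v) {
      v <- as.numeric(v)
      v - stats::ave(v, d$person) - stats::ave(v, d$wave) + mean(v)
    }
    y <- demean(d$ghq_likert)
    X <- vapply(d[vars], demean, numeric(nrow(d)))
    fit <- stats::lm(y ~ X - 1)
    # correct dof for the absorbed person/wave effects
    k <- length(unique(d$person)) + length(unique(d$wave)) - 1 + ncol(X)
    resc <- sqrt((nrow(d) - ncol(X)) / max(1, nrow(d) - k))
    cf <- summary(fit)$coefficients
    out[[s]] <- data.frame(sex = s, effect = vars,
                           estimate = unname(cf[, 1]),
                           se = unname(cf[, 2]) * resc)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---------------------------------------------------------------------------
# delimited-text input/output

#' Write / read a population as delimited text
#'
#' Tab-separated, one row per person, with the column dictionary documented in
#' the package vignette.
#' @param pop a `simpop` object (for writing).
#' @param path file path.
#' @return `read_population` returns a `simpop`.
#' @export
write_population <- function(pop, path) {
  utils::write.table(pop$persons, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @param config the [population_config()] to attach on read.
#' @export
read_population <- function(path, config = population_config()) {
  persons <- utils::read.table(path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  structure(list(persons = persons, units = build_units(persons),
                 config = config,
                 poverty_line = 0.6 * stats::median(persons$equivalised_income)),
            class = "simpop")
}
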