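# Simulation engine: annual cycle 2017-2025 with alignment, simplified
# demographic/education/health processes, labour supply, tax-benefit
# interaction and the two-step distress update; paired scenario runs with
# common random numbers.

#' Scenario configuration
#'
#' @param scenario `"observed"` (crisis-response systems in the pandemic
#'   years) or `"counterfactual"` (pre-crisis systems throughout).
#' @param start_year,end_year simulated period (2017-2025).
#' @param pandemic_years years using the reduced-form labour module and the
#'   non-economic distress constants.
#' @param population a [population_config()].
#' @param seed seed driving all simulation random streams (population
#'   generation uses `population$seed`).
#' @param baseline_system,response_system the two policy systems; the year
#'   schedule is derived from `scenario`.
#' @param poverty_anchor_year year whose 60%-of-median equivalised income
#'   fixes the poverty line thereafter.
#' @param inflation_rate annual price growth used only to express reported
#'   incomes in 2015 prices (default 0: the simulation is in constant prices).
#' @param mortality_scale multiplier on mortality rates (0 disables deaths).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("observed", "counterfactual"),
                            start_year = 2017, end_year = 2025,
                            pandemic_years = c(2020, 2021),
                            population = population_config(),
                            seed = 1,
                            baseline_system = uk2019_baseline(),
                            response_system = uk2020_response(),
                            poverty_anchor_year = 2019,
                            inflation_rate = 0,
                            mortality_scale = 1) {
  scenario <- match.arg(scenario)
  stopifnot(start_year <= end_year)
  structure(list(scenario = scenario, start_year = start_year,
                 end_year = end_year, pandemic_years = pandemic_years,
                 population = population, seed = seed,
                 baseline_system = baseline_system,
                 response_system = response_system,
                 poverty_anchor_year = poverty_anchor_year,
                 inflation_rate = inflation_rate,
                 mortality_scale = mortality_scale),
            class = "scenario_config")
}

system_for_year <- function(config, year) {
  if (config$scenario == "observed" && year %in% config$pandemic_years)
    config$response_system
  else config$baseline_system
}

price_deflator <- function(config, year) {
  (1 + config$inflation_rate)^(year - 2015)
}

# ---------------------------------------------------------------------------
# alignment

#' Align the population to external targets
#'
#' Deterministically duplicates or removes persons within each
#' (sex, age band, region) cell so that cell counts match the year's targets
#' exactly; selection within a cell uses the year's common-random-number
#' stream, so paired scenario arms make identical alignment choices.  If a
#' cell has a positive target but no source persons, donors are borrowed from
#' the nearest age band (with their age recoded into the target band).
#'
#' @param persons person table.
#' @param targets an [generate_alignment_targets()] data frame.
#' @param year year to align to.
#' @param base_seed simulation seed (stream key).
#' @return the aligned person table.
#' @export
align_population <- function(persons, targets, year, base_seed = 1) {
  tg <- targets[targets$year == year, ]
  if (!nrow(tg)) stop("alignment targets do not cover year ", year)
  u <- crn_runif(persons$person_id, base_seed, year, "align")
  band <- as.character(align_band(persons$age))
  key <- paste(persons$sex, band, persons$region, sep = "|")
  tkey <- paste(tg$sex, tg$age_band, tg$region, sep = "|")
  tcount <- stats::setNames(tg$count, tkey)
  idx_by_cell <- split(seq_len(nrow(persons)), key)

  bands <- levels(align_band(0))
  drop <- integer(0)
  clone_src <- integer(0)
  clone_age <- integer(0)
  for (ck in sort(names(tcount))) {
    tgt <- tcount[[ck]]
    idx <- idx_by_cell[[ck]]
    cur <- length(idx)
    if (tgt == cur) next
    if (tgt < cur) {
      sel <- idx[order(u[idx])][seq_len(cur - tgt)]
      drop <- c(drop, sel)
    } else {
      need <- tgt - cur
      src <- idx
      parts <- strsplit(ck, "|", fixed = TRUE)[[1]]
      if (!length(src)) {  # borrow nearest age band, same sex/region
        b0 <- match(parts[2], bands)
        for (off in order(abs(seq_along(bands) - b0))) {
          alt <- paste(parts[1], bands[off], parts[3], sep = "|")
          if (length(idx_by_cell[[alt]])) { src <- idx_by_cell[[alt]]; break }
        }
        if (!length(src)) next
        message("alignment: borrowing donors for empty cell ", ck)
      }
      sel <- src[order(u[src])]
      sel <- rep_len(sel, need)
      clone_src <- c(clone_src, sel)
      # recode borrowed ages into the target band midpoint
      lo <- .ALIGN_BANDS[match(parts[2], bands)]
      hi <- min(.ALIGN_BANDS[match(parts[2], bands) + 1] - 1, 90)
      mid <- floor((lo + hi) / 2)
      in_band <- persons$age[sel] >= lo & persons$age[sel] <= hi
      clone_age <- c(clone_age, ifelse(in_band, persons$age[sel], mid))
    }
  }

  out <- persons
  if (length(clone_src)) {
    clones <- persons[clone_src, ]
    clones$age <- clone_age
    nid <- max(persons$person_id)
    clones$person_id <- nid + seq_len(nrow(clones))
    clones$partner_id <- NA_integer_
    adult <- clones$age >= 18
    if (any(adult)) {
      nuid <- max(persons$unit_id, na.rm = TRUE)
      clones$unit_id[adult] <- nuid + seq_len(sum(adult))
    }
    # child clones keep their source unit
    out <- rbind(out, clones)
  }
  if (length(drop)) out <- remove_persons(out, drop_rows = drop)
  rownames(out) <- NULL
  out
}

# remove persons by row index, repairing partner links and orphaned children
remove_persons <- function(persons, ids = NULL, drop_rows) {
  gone_pid <- persons$person_id[drop_rows]
  out <- persons[-drop_rows, ]
  out$partner_id[out$partner_id %in% gone_pid] <- NA_integer_
  reattach_orphans(out)
}

# children whose unit has no adults are reattached to existing adult units;
# processed in person-id order so the outcome is row-order invariant
reattach_orphans <- function(persons) {
  adult_units <- unique(persons$unit_id[persons$age >= 18])
  orphan <- which(persons$age < 18 & !(persons$unit_id %in% adult_units))
  if (length(orphan)) {
    orphan <- orphan[order(persons$person_id[orphan])]
    persons$unit_id[orphan] <- rep_len(sort(adult_units), length(orphan))
  }
  persons
}

# ---------------------------------------------------------------------------
# demographic / education / health processes (simplified, config-table rates)

mortality_rate <- function(age, sex, scale = 1) {
  q <- 1e-5 * exp(0.105 * age) * ifelse(sex == "male", 1.4, 1.0)
  pmin(scale * q, 0.5)
}

#' Simplified demographic, education and health step
#'
#' Ages everyone one year; applies age-sex mortality; retires adults at 65;
#' turns 16-year-olds into students and moves new 18-year-olds into their own
#' benefit unit; students complete education by age-dependent probabilities
#' and draw an attainment level; self-rated health follows a bounded
#' categorical walk; long-term-sickness status flips with small hazards.
#' All draws use common-random-number streams keyed by person id.
#'
#' @param persons person table.
#' @param year current year.
#' @param base_seed simulation seed.
#' @param mortality_scale multiplier on mortality rates (0 disables deaths).
#' @return updated person table.
#' @export
demographic_step <- function(persons, year, base_seed = 1,
                             mortality_scale = 1) {
  p <- persons
  p$age <- p$age + 1L

  if (mortality_scale > 0) {
    u <- crn_runif(p$person_id, base_seed, year, "mortality")
    die <- u < mortality_rate(p$age, p$sex, mortality_scale)
    if (any(die)) p <- remove_persons(p, drop_rows = which(die))
  }

  # retirement
  ret <- p$age >= 65 & p$activity != "retired"
  p$activity[ret] <- "retired"
  p$hours[ret] <- 0

  # children become students at 16 (they already are); new 18-year-olds
  # leave the parental unit
  j18 <- which(p$age == 18)
  if (length(j18)) {
    j18 <- j18[order(p$person_id[j18])]  # id order: row-order invariant
    nuid <- max(p$unit_id, na.rm = TRUE)
    p$unit_id[j18] <- nuid + seq_along(j18)
  }

  # education completion for students aged 17+
  stud <- p$activity == "student" & p$age >= 17 & p$age < 65
  if (any(stud)) {
    u <- crn_runif(p$person_id, base_seed, year, "education")
    leave_p <- c(`17` = 0.25, `18` = 0.45, `19` = 0.35, `20` = 0.40,
                 `21` = 0.50, `22` = 0.60, `23` = 0.80)[
                   as.character(pmin(p$age, 23))]
    leave_p[p$age >= 24] <- 1
    leave <- stud & u[seq_len(nrow(p))] < leave_p
    if (any(leave)) {
      u2 <- crn_runif(p$person_id, base_seed, year, "misc")
      lv_age <- p$age[leave]
      edu <- character(sum(leave))
      young <- lv_age <= 17
      midl <- lv_age >= 18 & lv_age <= 20
      edu[young] <- ifelse(u2[leave][young] < 0.7, "low", "medium")
      edu[midl] <- as.character(cut(u2[leave][midl], c(0, 0.15, 0.85, 1),
                                    labels = c("low", "medium", "high")))
      edu[!young & !midl] <- ifelse(u2[leave][!young & !midl] < 0.25,
                                    "medium", "high")
      p$education[leave] <- edu
      p$activity[leave] <- "not_employed"
      p$years_not_employed[leave] <- 0L
      p$potential_wage[leave] <- potential_wage(p$age[leave], p$sex[leave],
                                                p$education[leave],
                                                p$wage_draw[leave])
    }
  }

  # self-rated health: bounded categorical walk
  uh <- crn_runif(p$person_id, base_seed, year, "health")
  p$self_rated_health <- clamp(p$self_rated_health +
                                 (uh < 0.08) - (uh > 0.92), 1L, 5L)

  # long-term sickness onset/recovery among working-age non-students
  us <- crn_runif(p$person_id, base_seed, year, "ltsick")
  eligible <- p$age >= 16 & p$age < 65 & p$activity != "student"
  onset <- eligible & !p$long_term_sick &
    us < (0.006 + 0.0004 * pmax(0, p$age - 25))
  recover <- eligible & p$long_term_sick & us > 1 - 0.20
  p$long_term_sick[onset] <- TRUE
  p$activity[onset & p$activity %in%
               c("employed", "furlough_full", "furlough_partial")] <-
    "not_employed"
  p$hours[onset] <- 0
  p$long_term_sick[recover] <- FALSE

  p$at_risk_of_work <- !(p$activity %in% c("student", "retired")) &
    !p$long_term_sick
  p <- reattach_orphans(p)
  rownames(p) <- NULL
  p
}

# ---------------------------------------------------------------------------
# incomes

# per-person annual gross income given current activity/hours
person_gross <- function(persons, system) {
  g <- numeric(nrow(persons))
  emp <- persons$activity == "employed"
  g[emp] <- persons$potential_wage[emp] * persons$hours[emp] * 52
  ful <- persons$activity == "furlough_full"
  if (any(ful)) {
    usual_m <- persons$potential_wage[ful] * persons$usual_hours[ful] * 52 / 12
    g[ful] <- 12 * furlough_pay(usual_m, system)
  }
  par <- persons$activity == "furlough_partial"
  if (any(par)) {
    w <- persons$potential_wage[par]
    uh <- pmax(persons$usual_hours[par], persons$hours[par])
    hw <- persons$hours[par]
    sub <- pmin(system$furlough$replacement_rate * w * (uh - hw) * 52 / 12,
                system$furlough$monthly_cap * (uh - hw) / pmax(uh, 1))
    g[par] <- w * hw * 52 + 12 * sub
  }
  ret <- persons$activity == "retired"
  g[ret] <- system$state_pension
  g
}

# unit-level disposable and equivalised income
unit_incomes <- function(persons, system) {
  units <- build_units(persons)
  g <- person_gross(persons, system)
  g1 <- g[match(units$adult1, persons$person_id)]
  g2 <- g[match(units$adult2, persons$person_id)]
  disp <- disposable_income(g1, g2, n_adults = units$n_adults,
                            n_children = units$n_children, system = system)
  eq <- equivalise(disp, units$n_adults, units$n_children_u14,
                   units$n_children_14plus)
  data.frame(unit_id = units$unit_id, gross = g1 + ifelse(is.na(g2), 0, g2),
             disposable = disp, eq_income = eq)
}

# ---------------------------------------------------------------------------
# labour-supply steps

structural_labour <- function(persons, year, system, prefs, base_seed) {
  prev_work <- persons$activity %in% c("employed", "furlough_full",
                                       "furlough_partial")
  ar <- persons$at_risk_of_work & persons$age >= 18
  units <- build_units(persons)
  pid <- persons$person_id
  i1 <- match(units$adult1, pid)
  i2 <- match(units$adult2, pid)
  ar1 <- ar[i1]
  ar2 <- ifelse(is.na(i2), FALSE, ar[i2])
  act <- which(ar1 | ar2)
  if (!length(act)) return(persons)

  nu <- length(act)
  alt <- .ALT25
  na_alt <- nrow(alt)  # 25, sorted by total hours then first adult
  h1 <- matrix(alt$h1, nu, na_alt, byrow = TRUE)
  h2 <- matrix(alt$h2, nu, na_alt, byrow = TRUE)
  A1 <- matrix(ar1[act], nu, na_alt)
  A2 <- matrix(ar2[act], nu, na_alt)
  valid <- (A1 | h1 == 0) & (A2 | h2 == 0)
  # fixed income of adults not at risk (pension); at-risk earnings from hours
  fg <- person_gross(persons, system)
  w1 <- persons$potential_wage[i1][act]
  w2 <- persons$potential_wage[i2][act]
  couple <- !is.na(i2[act])
  g1 <- ifelse(A1, h1 * 52 * w1, fg[i1][act])
  g2 <- ifelse(matrix(couple, nu, na_alt),
               ifelse(A2, h2 * 52 * w2, fg[i2][act]), NA)
  disp <- disposable_income(as.numeric(g1), as.numeric(g2),
                            n_adults = rep(units$n_adults[act], na_alt),
                            n_children = rep(units$n_children[act], na_alt),
                            system = system)
  eh1 <- ifelse(A1, h1, 0)
  eh2 <- ifelse(A2 & matrix(couple, nu, na_alt), h2, 0)
  f1 <- persons$sex[i1][act] == "female"
  f2 <- ifelse(couple, persons$sex[i2][act] == "female", FALSE)
  e1 <- persons$education[i1][act] == "high"
  e2 <- ifelse(couple, persons$education[i2][act] == "high", FALSE)
  pw1 <- prev_work[i1][act]
  pw2 <- ifelse(couple, prev_work[i2][act], NA)
  v <- labour_utility(disp, as.numeric(eh1), as.numeric(eh2), prefs,
                      female1 = rep(f1, na_alt), female2 = rep(f2, na_alt),
                      children_u14 = rep(units$n_children_u14[act], na_alt),
                      edu_high1 = rep(e1, na_alt), edu_high2 = rep(e2, na_alt),
                      prev_work1 = rep(ifelse(A1[, 1], pw1, NA), na_alt),
                      prev_work2 = rep(ifelse(A2[, 1] & couple, pw2, NA),
                                       na_alt))
  V <- matrix(v, nu, na_alt)
  V[!valid] <- -Inf
  if (prefs$error_scale > 0) {
    U <- crn_runif(units$unit_id[act], base_seed, year, "labour_gumbel",
                   k = na_alt)
    V <- V + prefs$error_scale * (-log(-log(U)))
    V[!valid] <- -Inf
  }
  choice <- max.col(V, ties.method = "first")
  ch1 <- alt$h1[choice]
  ch2 <- alt$h2[choice]

  set_adult <- function(p, rows, hrs, is_ar) {
    rows <- rows[is_ar]
    hrs <- hrs[is_ar]
    p$hours[rows] <- hrs
    p$activity[rows] <- ifelse(hrs > 0, "employed", "not_employed")
    p$usual_hours[rows] <- ifelse(hrs > 0, hrs, p$usual_hours[rows])
    p
  }
  persons <- set_adult(persons, i1[act], ch1, ar1[act])
  persons <- set_adult(persons, i2[act][couple], ch2[couple],
                       ar2[act][couple])
  persons
}

pandemic_labour <- function(persons, year, config, model, base_seed) {
  ar <- which(persons$at_risk_of_work & persons$age >= 18)
  if (!length(ar)) return(persons)
  units <- build_units(persons)
  has_child <- units$n_children[match(persons$unit_id[ar],
                                      units$unit_id)] > 0
  X <- data.frame(
    female = as.numeric(persons$sex[ar] == "female"),
    age50 = as.numeric(persons$age[ar] >= 50),
    edu_low = as.numeric(persons$education[ar] == "low"),
    edu_high = as.numeric(persons$education[ar] == "high"),
    children = as.numeric(has_child),
    year2021 = as.numeric(length(config$pandemic_years) >= 2 &&
                            year == config$pandemic_years[2])
  )
  start <- persons$activity[ar]
  start[!start %in% model$states] <- "other"
  u <- crn_runif(persons$person_id[ar], base_seed, year,
                 "pandemic_transition")
  # furlough states exist only where the year's system runs a furlough
  # scheme; otherwise their probability mass shifts to non-employment
  variant <- if (system_for_year(config, year)$furlough$exists)
    "observed" else "counterfactual"
  end <- character(length(ar))
  for (s in unique(start)) {
    idx <- start == s
    end[idx] <- pandemic_transition(s, X[idx, , drop = FALSE], model,
                                    variant, u = u[idx])
  }
  up <- crn_runif(persons$person_id[ar], base_seed, year, "pandemic_hours")
  un <- crn_runif(persons$person_id[ar], base_seed, year, "new_hours")
  hrs <- pandemic_hours(end, persons$hours[ar], u_part = up, u_new = un)
  persons$activity[ar] <- end
  persons$hours[ar] <- hrs
  emp <- ar[end == "employed"]
  persons$usual_hours[emp] <- ifelse(persons$hours[emp] > 0,
                                     persons$hours[emp],
                                     persons$usual_hours[emp])
  persons
}

# ---------------------------------------------------------------------------
# annual cycle

#' Run one simulated year
#'
#' Executes, in order: alignment, the demographic/education/health step, the
#' labour-supply module (structural in normal years; reduced-form multinomial
#' transitions in pandemic years -- with furlough states admissible only in
#' the observed scenario), the tax-benefit interaction (disposable and
#' equivalised income, poverty status), and the two-step distress update.
#' Year counters are updated after the year's outcomes.
#'
#' @param pop a `simpop` state object (with `targets` attached by
#'   [run_scenario()]).
#' @param year the year to simulate.
#' @param config a [scenario_config()].
#' @param coefficients a [model_coefficients()] bundle (point estimates or a
#'   bootstrap draw).
#' @return the updated `simpop` state.
#' @export
run_year <- function(pop, year, config, coefficients = model_coefficients()) {
  persons <- pop$persons
  system <- system_for_year(config, year)
  base_seed <- config$seed

  persons <- align_population(persons, pop$targets, year, base_seed)
  persons <- demographic_step(persons, year, base_seed,
                              config$mortality_scale)

  prev_activity <- persons$activity
  prev_eq <- persons$equivalised_income
  prev_pov <- persons$in_poverty
  prev_yrs_ne <- persons$years_not_employed
  prev_yrs_pov <- persons$years_in_poverty
  prev_likert <- persons$ghq_likert

  adult <- persons$age >= 18
  persons$potential_wage[adult] <- potential_wage(
    persons$age[adult], persons$sex[adult], persons$education[adult],
    persons$wage_draw[adult], coefficients$wage)

  if (year %in% config$pandemic_years) {
    persons <- pandemic_labour(persons, year, config,
                               coefficients$transitions, base_seed)
  } else {
    # furlough contracts resume as employment before a structural choice
    fur <- persons$activity %in% c("furlough_full", "furlough_partial")
    if (any(fur)) {
      persons$activity[fur] <- "employed"
      persons$hours[fur] <- persons$usual_hours[fur]
    }
    persons <- structural_labour(persons, year, system,
                                 coefficients$preferences, base_seed)
  }

  inc <- unit_incomes(persons, system)
  persons$equivalised_income <- inc$eq_income[match(persons$unit_id,
                                                    inc$unit_id)]
  if (year <= config$poverty_anchor_year) {
    line <- 0.6 * stats::median(persons$equivalised_income)
    if (year == config$poverty_anchor_year) pop$poverty_line <- line
  } else {
    line <- pop$poverty_line
  }
  persons$in_poverty <- poverty_status(persons$equivalised_income, line)

  flags <- derive_transitions(prev_activity, persons$activity,
                              persons$at_risk_of_work, prev_yrs_ne,
                              prev_pov, persons$in_poverty, prev_yrs_pov,
                              prev_eq, persons$equivalised_income)

  mh <- coefficients$mh
  noise <- crn_rnorm(persons$person_id, base_seed, year, "mh_step1",
                     sd = mh$step1_likert_sd)
  s1 <- step1_predict(prev_likert, mh, noise = noise)
  uc <- crn_runif(persons$person_id, base_seed, year, "mh_caseness")
  s2 <- step2_update(s1$likert, s1$caseness_logodds, flags, persons$sex,
                     year, mh, pandemic_years = config$pandemic_years,
                     caseness_u = uc)
  upd <- persons$age >= 16
  persons$ghq_likert[upd] <- s2$likert[upd]
  persons$cmd_prob[upd] <- s2$cmd_prob[upd]
  persons$cmd_case[upd] <- s2$cmd_case[upd]

  ne <- persons$activity == "not_employed" & persons$at_risk_of_work
  persons$years_not_employed <- ifelse(ne, prev_carry(persons$years_not_employed) + 1L, 0L)
  persons$years_in_poverty <- ifelse(persons$in_poverty,
                                     persons$years_in_poverty + 1L, 0L)

  pop$persons <- persons
  pop$units <- build_units(persons)
  pop
}

# identity; kept separate so the counter rule reads explicitly
prev_carry <- function(x) x

#' Bundle of model coefficients for one run
#'
#' @param mh an [mh_coefficients()] set.
#' @param preferences a [preference_coefficients()] set.
#' @param transitions a [transition_model()].
#' @param wage wage-equation coefficients ([wage_coefficients()]).
#' @param draw_id bootstrap draw identifier (0 = point estimates).
#' @return object of class `model_coefficients`.
#' @export
model_coefficients <- function(mh = mh_coefficients(),
                               preferences = preference_coefficients(),
                               transitions = transition_model(),
                               wage = wage_coefficients(),
                               draw_id = 0L) {
  structure(list(mh = mh, preferences = preferences,
                 transitions = transitions, wage = wage, draw_id = draw_id),
            class = "model_coefficients")
}

#' Run a full scenario trajectory
#'
#' Sequentially simulates every year from `start_year` to `end_year` under the
#' configured policy schedule; fully reproducible given the configuration
#' seed and coefficient draw.
#'
#' @param config a [scenario_config()].
#' @param coefficients a [model_coefficients()] bundle.
#' @param population optional pre-generated [generate_population()] result
#'   (shared across bootstrap runs); generated from `config$population` if
#'   `NULL`.
#' @param targets optional [generate_alignment_targets()]; derived from the
#'   initial population if `NULL`.
#' @param keep_person_data keep a per-person-year outcome table (needed for
#'   subgroup analysis)?
#' @return object of class `scenario_run` with the per-year aggregate
#'   outcomes (`$aggregates`), the final population, and metadata.
#' @export
run_scenario <- function(config, coefficients = model_coefficients(),
                         population = NULL, targets = NULL,
                         keep_person_data = FALSE) {
  if (is.null(population)) population <- generate_population(config$population)
  years <- seq(config$start_year, config$end_year)
  if (is.null(targets))
    targets <- generate_alignment_targets(config$population, years,
                                          population$persons)
  pop <- population
  pop$targets <- targets
  agg <- vector("list", length(years))
  per <- if (keep_person_data) vector("list", length(years)) else NULL
  for (i in seq_along(years)) {
    pop <- run_year(pop, years[i], config, coefficients)
    agg[[i]] <- cbind(year = years[i],
                      aggregate_outcomes(pop$persons,
                                         config$population$scaling_factor,
                                         price_deflator(config, years[i])))
    if (keep_person_data) {
      p <- pop$persons
      has_child <- pop$units$n_children[match(p$unit_id,
                                              pop$units$unit_id)] > 0
      per[[i]] <- data.frame(year = years[i], person_id = p$person_id,
                             age = p$age, sex = p$sex,
                             education = p$education,
                             has_children = has_child,
                             activity = p$activity,
                             eq_income = p$equivalised_income,
                             in_poverty = p$in_poverty,
                             ghq_likert = p$ghq_likert,
                             cmd_case = p$cmd_case,
                             stringsAsFactors = FALSE)
    }
  }
  structure(list(aggregates = do.call(rbind, agg),
                 person_data = if (keep_person_data) do.call(rbind, per),
                 final_population = pop,
                 scenario = config$scenario, seed = config$seed,
                 draw_id = coefficients$draw_id, config = config),
            class = "scenario_run")
}

#' Paired observed/counterfactual run
#'
#' Runs both policy scenarios with the same coefficient draw and common
#' random numbers (streams keyed by person id, year and process), so that
#' persons differ across arms only through policy-mediated pathways.
#'
#' @inheritParams run_scenario
#' @return object of class `paired_run` with `$observed`, `$counterfactual`
#'   and the per-year paired effects `$effects`
#'   (observed minus counterfactual).
#' @export
run_paired <- function(config, coefficients = model_coefficients(),
                       population = NULL, targets = NULL,
                       keep_person_data = FALSE) {
  if (is.null(population)) population <- generate_population(config$population)
  years <- seq(config$start_year, config$end_year)
  if (is.null(targets))
    targets <- generate_alignment_targets(config$population, years,
                                          population$persons)
  cfg_obs <- config; cfg_obs$scenario <- "observed"
  cfg_cf <- config; cfg_cf$scenario <- "counterfactual"
  obs <- run_scenario(cfg_obs, coefficients, population, targets,
                      keep_person_data)
  cf <- run_scenario(cfg_cf, coefficients, population, targets,
                     keep_person_data)
  eff <- obs$aggregates
  num <- setdiff(names(eff), "year")
  eff[num] <- obs$aggregates[num] - cf$aggregates[num]
  structure(list(observed = obs, counterfactual = cf, effects = eff,
                 draw_id = coefficients$draw_id),
            class = "paired_run")
}
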