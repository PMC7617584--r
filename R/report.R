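# Uncertainty and reporting: coefficient bootstrap, repeated paired runs,
# ranked uncertainty intervals, headline outcome tables, head counts and QALY
# valuation.

#' Aggregate a population snapshot to per-year outcomes
#'
#' All outcomes are computed on the working-age population (ages 25-64).
#' The employment rate counts the furlough states as employment (the contract
#' is preserved); income quantities are equivalised disposable incomes,
#' deflated to 2015 prices; the P90/P10 ratio uses `stats::quantile` type 7
#' interpolation (the documented convention).
#'
#' @param persons person table of a snapshot.
#' @param scaling_factor persons represented per agent.
#' @param deflator price deflator dividing nominal incomes.
#' @return one-row data frame: `employment_rate`, `poverty_rate`,
#'   `cmd_prevalence`, `median_likert`, `median_income`, `p90p10`,
#'   `n_working_age` (agents), `headcount_working_age` (persons).
#' @export
aggregate_outcomes <- function(persons, scaling_factor = 446, deflator = 1) {
  wa <- persons$age >= 25 & persons$age <= 64
  if (!any(wa)) stop("empty working-age population")
  p <- persons[wa, ]
  inc <- p$eq_income %||% p$equivalised_income
  inc <- inc / deflator
  q <- stats::quantile(inc, c(0.1, 0.9), type = 7, names = FALSE)
  data.frame(
    employment_rate = mean(p$activity %in% c("employed", "furlough_full",
                                             "furlough_partial")),
    poverty_rate = mean(p$in_poverty),
    cmd_prevalence = mean(p$cmd_case),
    median_likert = stats::median(p$ghq_likert),
    median_income = stats::median(inc),
    p90p10 = q[2] / q[1],
    n_working_age = nrow(p),
    headcount_working_age = nrow(p) * scaling_factor
  )
}

#' Ranked median and 95% uncertainty interval
#'
#' Sorts the per-run values and reports the ranks `ceiling(0.025 n)`,
#' `ceiling(0.5 n)` and `ceiling(0.975 n)` -- the 25th, 500th and 975th
#' ranked outcomes at n = 1000.
#'
#' @param values per-run outcome values.
#' @param n_runs number of runs (defaults to `length(values)`), at least 40.
#' @return named numeric: `median`, `lower95`, `upper95`.
#' @export
summarize_runs <- function(values, n_runs = length(values)) {
  if (n_runs < 40) stop("at least 40 runs are needed for ranked intervals")
  s <- sort(values)
  c(median = s[ceiling(0.5 * n_runs)],
    lower95 = s[ceiling(0.025 * n_runs)],
    upper95 = s[ceiling(0.975 * n_runs)])
}

#' Paired within-draw effect of the policy response
#'
#' Observed-arm outcome minus counterfactual-arm outcome for one year; a
#' preventative effect on an adverse outcome is negative.
#'
#' @param observed,counterfactual `scenario_run` objects from the same
#'   coefficient draw.
#' @param outcome aggregate outcome name (a column of `$aggregates`).
#' @param year year.
#' @return numeric difference.
#' @export
paired_effect <- function(observed, counterfactual, outcome, year) {
  if (!identical(observed$draw_id, counterfactual$draw_id))
    stop("runs are not paired: coefficient draw ids differ")
  o <- observed$aggregates
  c0 <- counterfactual$aggregates
  o[[outcome]][o$year == year] - c0[[outcome]][c0$year == year]
}

#' Convert a rate difference to a national head count
#'
#' `|rate difference| x working-age agents x scaling factor`, rounded to the
#' nearest thousand persons.
#'
#' @param rate_difference difference in a rate (fraction).
#' @param working_age_n number of working-age agents.
#' @param scaling_factor persons represented per agent.
#' @return persons (rounded to the nearest thousand).
#' @export
headcount <- function(rate_difference, working_age_n, scaling_factor = 446) {
  if (any(working_age_n <= 0)) stop("working_age_n must be positive")
  round(abs(rate_difference) * working_age_n * scaling_factor / 1000) * 1000
}

#' QALY valuation of prevented CMD cases
#'
#' Each prevented case-year is valued at a health-state utility decrement of
#' 0.13, monetised at 70,000 GBP per quality-adjusted life year.
#'
#' @param prevented_cases prevented cases (persons).
#' @param utility_decrement QALY decrement per case-year.
#' @param qaly_value GBP per QALY.
#' @return list with `qalys` and `value` (GBP).
#' @export
qaly_valuation <- function(prevented_cases, utility_decrement = 0.13,
                           qaly_value = 70000) {
  if (any(prevented_cases < 0) || utility_decrement < 0 || qaly_value < 0)
    stop("inputs must be nonnegative")
  qalys <- prevented_cases * utility_decrement
  list(qalys = qalys, value = qalys * qaly_value)
}

#' Bootstrap draw of all model coefficients
#'
#' Samples every regression coefficient from a multivariate normal centred at
#' the point estimates: the step-2 distress effects from their (diagonal)
#' variance, the step-1 block from its variance-covariance matrix, and the
#' transition-model and preference intercepts from their configured sds.
#'
#' @param points a [model_coefficients()] bundle of point estimates.
#' @param seed RNG seed of the draw.
#' @param draw_id identifier recorded on the draw.
#' @return a [model_coefficients()] bundle with perturbed values.
#' @export
draw_coefficients <- function(points = model_coefficients(), seed = 1,
                              draw_id = seed) {
  with_seed(seed, {
    mh <- points$mh
    s2 <- mh$step2
    for (col in c("male_likert", "female_likert", "male_caseness",
                  "female_caseness")) {
      s2[[col]] <- s2[[col]] + stats::rnorm(nrow(s2)) * s2[[paste0(col, "_se")]]
    }
    ev <- eigen(mh$step1_vcov, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-8))
      stop("step-1 variance-covariance matrix is not positive semidefinite")
    b1 <- MASS::mvrnorm(1, mh$step1_likert, mh$step1_vcov)
    names(b1) <- names(mh$step1_likert)
    mh2 <- mh
    mh2$step2 <- s2
    mh2$step1_likert <- b1

    tm <- points$transitions
    if (tm$intercept_se > 0) {
      for (s in names(tm$coef)) {
        for (e in names(tm$coef[[s]])) {
          tm$coef[[s]][[e]][["intercept"]] <-
            tm$coef[[s]][[e]][["intercept"]] +
            stats::rnorm(1, 0, tm$intercept_se)
        }
      }
    }
    pf <- points$preferences
    if ((pf$intercept_se %||% 0) > 0) {
      pf$income_weight <- pf$income_weight + stats::rnorm(1, 0, pf$intercept_se)
      pf$hours_weight <- pf$hours_weight - abs(stats::rnorm(1, 0, pf$intercept_se))
    }
    model_coefficients(mh = mh2, preferences = pf, transitions = tm,
                       wage = points$wage, draw_id = draw_id)
  })
}

#' Repeated paired runs with bootstrapped coefficients
#'
#' Runs `n_runs` paired observed/counterfactual simulations.  The initial
#' population is generated once and shared; each run uses its own coefficient
#' draw and simulation random stream, and both arms of a run share both
#' (paired design).
#'
#' @param config a [scenario_config()] (its `scenario` field is ignored; both
#'   arms are run).
#' @param n_runs number of paired runs (desk default 100; the full design
#'   uses 1000).
#' @param coefficients point estimates to bootstrap around.
#' @param subgroup_years years for which subgroup paired effects are
#'   computed (`NULL` to skip; requires keeping person-level data per run).
#' @param progress print one line per run?
#' @return object of class `paired_experiment`: long data frames `$observed`,
#'   `$counterfactual`, `$effects` (one row per run-year) and, if requested,
#'   `$subgroup_effects`.
#' @export
run_experiment <- function(config, n_runs = 100,
                           coefficients = model_coefficients(),
                           subgroup_years = NULL, progress = FALSE) {
  population <- generate_population(config$population)
  years <- seq(config$start_year, config$end_year)
  targets <- generate_alignment_targets(config$population, years,
                                        population$persons)
  obs <- cf <- eff <- vector("list", n_runs)
  sub <- if (!is.null(subgroup_years)) vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    draw <- draw_coefficients(coefficients,
                              seed = stream_seed(config$seed, 2000 + r,
                                                 "misc"),
                              draw_id = r)
    cfg <- config
    cfg$seed <- stream_seed(config$seed, 3000 + r, "misc")
    pr <- run_paired(cfg, draw, population, targets,
                     keep_person_data = !is.null(subgroup_years))
    obs[[r]] <- cbind(run = r, pr$observed$aggregates)
    cf[[r]] <- cbind(run = r, pr$counterfactual$aggregates)
    eff[[r]] <- cbind(run = r, pr$effects)
    if (!is.null(subgroup_years))
      sub[[r]] <- cbind(run = r, subgroup_effects(pr, subgroup_years))
    if (progress)
      message(sprintf("run %d/%d: 2020 CMD effect %.3f", r, n_runs,
                      pr$effects$cmd_prevalence[pr$effects$year == 2020]))
  }
  structure(list(observed = do.call(rbind, obs),
                 counterfactual = do.call(rbind, cf),
                 effects = do.call(rbind, eff),
                 subgroup_effects = if (!is.null(subgroup_years))
                   do.call(rbind, sub),
                 n_runs = n_runs, config = config),
            class = "paired_experiment")
}

# subgroup paired effects for one paired run (requires person-level data);
# income-quintile membership is fixed at the counterfactual arm's
# poverty-anchor-year income distribution
subgroup_effects <- function(pr, years) {
  po <- pr$observed$person_data
  pc <- pr$counterfactual$person_data
  stopifnot(!is.null(po), !is.null(pc))
  anchor <- pr$observed$config$poverty_anchor_year
  base <- pc[pc$year == anchor & pc$age >= 25 & pc$age <= 64, ]
  qb <- stats::quantile(base$eq_income, c(0.2, 0.8), type = 7)
  q1_ids <- base$person_id[base$eq_income <= qb[1]]
  q5_ids <- base$person_id[base$eq_income > qb[2]]
  out <- list()
  for (y in years) {
    oy <- po[po$year == y & po$age >= 25 & po$age <= 64, ]
    cy <- pc[pc$year == y & pc$age >= 25 & pc$age <= 64, ]
    groups <- list(
      overall = function(d) rep(TRUE, nrow(d)),
      males = function(d) d$sex == "male",
      females = function(d) d$sex == "female",
      with_children = function(d) d$has_children,
      without_children = function(d) !d$has_children,
      high_education = function(d) d$education == "high",
      low_education = function(d) d$education == "low",
      lowest_quintile = function(d) d$person_id %in% q1_ids,
      highest_quintile = function(d) d$person_id %in% q5_ids
    )
    for (g in names(groups)) {
      so <- groups[[g]](oy); sc <- groups[[g]](cy)
      if (!any(so) || !any(sc)) {
        out[[length(out) + 1L]] <- data.frame(
          year = y, group = g, cmd_prevalence = NA_real_,
          median_likert = NA_real_, n_observed = sum(so))
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        year = y, group = g,
        cmd_prevalence = mean(oy$cmd_case[so]) - mean(cy$cmd_case[sc]),
        median_likert = stats::median(oy$ghq_likert[so]) -
          stats::median(cy$ghq_likert[sc]),
        n_observed = sum(so))
    }
  }
  do.call(rbind, out)
}

#' Subgroup effect table for one year
#'
#' Paired effects of the policy response within population subgroups (sex,
#' children in the household, education, baseline income quintile),
#' summarised across runs by ranked median and 95% uncertainty interval.
#'
#' @param experiment a [run_experiment()] result built with
#'   `subgroup_years` covering `year`.
#' @param year year to tabulate.
#' @return data frame: group, outcome, median, lower95, upper95.
#' @export
subgroup_table <- function(experiment, year) {
  se <- experiment$subgroup_effects
  if (is.null(se)) stop("experiment was run without subgroup_years")
  se <- se[se$year == year, ]
  out <- list()
  for (g in unique(se$group)) {
    for (oc in c("cmd_prevalence", "median_likert")) {
      v <- se[[oc]][se$group == g]
      if (all(is.na(v))) {
        out[[length(out) + 1L]] <- data.frame(group = g, outcome = oc,
                                              median = NA_real_,
                                              lower95 = NA_real_,
                                              upper95 = NA_real_)
        next
      }
      s <- summarize_runs(v[!is.na(v)], max(40, sum(!is.na(v))))
      out[[length(out) + 1L]] <- data.frame(group = g, outcome = oc,
                                            median = s[["median"]],
                                            lower95 = s[["lower95"]],
                                            upper95 = s[["upper95"]])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summary table of a paired experiment
#'
#' @param object a [run_experiment()] result.
#' @param ... unused.
#' @return long data frame: year, outcome, series (observed, counterfactual,
#'   effect), ranked median and 95% uncertainty interval.
#' @export
summary.paired_experiment <- function(object, ...) {
  outcomes <- c("employment_rate", "poverty_rate", "cmd_prevalence",
                "median_likert", "median_income", "p90p10")
  series <- list(observed = object$observed,
                 counterfactual = object$counterfactual,
                 effect = object$effects)
  out <- list()
  for (sn in names(series)) {
    d <- series[[sn]]
    for (y in unique(d$year)) {
      for (oc in outcomes) {
        s <- summarize_runs(d[[oc]][d$year == y])
        out[[length(out) + 1L]] <- data.frame(
          year = y, outcome = oc, series = sn, median = s[["median"]],
          lower95 = s[["lower95"]], upper95 = s[["upper95"]])
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.paired_experiment <- function(x, ...) {
  cat(sprintf("Paired microsimulation experiment: %d runs, %d-%d\n",
              x$n_runs, x$config$start_year, x$config$end_year))
  ef <- x$effects
  for (y in intersect(x$config$pandemic_years, ef$year)) {
    s <- summarize_runs(ef$cmd_prevalence[ef$year == y])
    cat(sprintf("  %d CMD-prevalence effect: %+.1f%%pt [%.1f, %.1f]\n", y,
                100 * s[["median"]], 100 * s[["lower95"]],
                100 * s[["upper95"]]))
  }
  invisible(x)
}

#' @export
print.scenario_run <- function(x, ...) {
  cat(sprintf("Scenario run (%s), seed %s, draw %s\n", x$scenario,
              format(x$seed), format(x$draw_id)))
  print(cbind(year = x$aggregates$year,
              round(x$aggregates[, c("employment_rate", "poverty_rate",
                                     "cmd_prevalence", "median_likert")], 3)),
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.scenario_run <- function(object, ...) object$aggregates

#' @export
print.paired_run <- function(x, ...) {
  cat("Paired scenario run (observed vs counterfactual), draw",
      format(x$draw_id), "\n")
  ef <- x$effects
  print(cbind(year = ef$year,
              round(ef[, c("employment_rate", "poverty_rate",
                           "cmd_prevalence")], 4)), row.names = FALSE)
  invisible(x)
}

#' Plot a scenario run or a paired run
#'
#' Time series of an aggregate outcome (both arms for a paired run).
#' @param x a `scenario_run` or `paired_run`.
#' @param outcome aggregate outcome name.
#' @param ... passed to [graphics::plot()].
#' @export
plot.scenario_run <- function(x, outcome = "cmd_prevalence", ...) {
  a <- x$aggregates
  graphics::plot(a$year, a[[outcome]], type = "b", xlab = "year",
                 ylab = outcome, ...)
  invisible(x)
}

#' @rdname plot.scenario_run
#' @export
plot.paired_run <- function(x, outcome = "cmd_prevalence", ...) {
  o <- x$observed$aggregates
  c0 <- x$counterfactual$aggregates
  ylim <- range(o[[outcome]], c0[[outcome]])
  graphics::plot(o$year, o[[outcome]], type = "b", xlab = "year",
                 ylab = outcome, ylim = ylim, ...)
  graphics::lines(c0$year, c0[[outcome]], type = "b", lty = 2, pch = 2)
  graphics::legend("topleft", c("observed", "counterfactual"),
                   lty = 1:2, pch = 1:2, bty = "n")
  invisible(x)
}

#' Histogram of paired effects across runs
#'
#' @param x a `paired_experiment`.
#' @param outcome aggregate outcome name.
#' @param year year.
#' @param ... passed to [graphics::hist()].
#' @export
plot.paired_experiment <- function(x, outcome = "cmd_prevalence",
                                   year = 2020, ...) {
  v <- x$effects[[outcome]][x$effects$year == year]
  graphics::hist(v, xlab = sprintf("%s effect, %d", outcome, year),
                 main = "", ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Write experiment outputs as delimited text
#'
#' Writes `summary.csv`, `paired_effects.csv` and (when present)
#' `subgroups.csv` into a directory.
#' @param experiment a [run_experiment()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(summary(experiment), file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(experiment$effects, file.path(dir, "paired_effects.csv"),
                   row.names = FALSE)
  if (!is.null(experiment$subgroup_effects))
    utils::write.csv(experiment$subgroup_effects,
                     file.path(dir, "subgroups.csv"), row.names = FALSE)
  invisible(dir)
}
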