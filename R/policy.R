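# Parametric tax-benefit policy engine: converts gross earnings to disposable
# income at the benefit-unit level, including Universal Credit (with optional
# uplift) and the furlough wage subsidy; builds discrete budget sets.

#' Construct a parametric policy system
#'
#' A policy system is a parametric description of one tax/benefit regime:
#' a banded income tax, a flat National Insurance contribution above a floor,
#' a Universal-Credit-style means-tested benefit withdrawn at a constant taper,
#' and (optionally) a furlough wage-subsidy scheme.  All monetary parameters
#' are in the natural units they are quoted in (weekly for benefit rates,
#' monthly for the furlough cap); internally everything is converted to
#' pounds per year.
#'
#' @param name label for the system.
#' @param tax_thresholds strictly increasing annual thresholds (GBP/year) above
#'   which the corresponding marginal rate applies.  The first threshold plays
#'   the role of the personal allowance.
#' @param tax_rates marginal rates, one per threshold, each in `[0, 1]`.
#' @param ni_rate flat National Insurance rate on gross earnings above
#'   `ni_floor`.
#' @param ni_floor annual earnings floor (GBP/year) below which no NI is due.
#' @param uc_standard_allowance weekly standard allowance (GBP/week) for a
#'   single adult aged 25 or over (73 in the 2019 system).
#' @param uc_standard_allowance_couple weekly standard allowance for a couple.
#' @param uc_uplift weekly uplift added to the standard allowance (20 during
#'   2020-21 in the observed response; 0 in the pre-crisis system).
#' @param uc_child_element weekly amount per dependent child.
#' @param uc_taper fraction of net earnings withdrawn from the maximum award.
#' @param furlough_exists does a furlough scheme exist under this system?
#' @param furlough_rate replacement rate on usual wages (0.8).
#' @param furlough_cap monthly cap on the subsidy (GBP/month, 2500).
#' @param state_pension annual pension income assigned to retired adults
#'   (GBP/year); a supporting simplification, not a policy lever studied here.
#' @return an object of class `policy_system`.
#' @seealso [uk2019_baseline()], [uk2020_response()], [read_policy_system()]
#' @export
policy_system <- function(name = "custom",
                          tax_thresholds = c(12500, 50000, 150000),
                          tax_rates = c(0.20, 0.40, 0.45),
                          ni_rate = 0.12, ni_floor = 8632,
                          uc_standard_allowance = 73,
                          uc_standard_allowance_couple = 114.85,
                          uc_uplift = 0,
                          uc_child_element = 53.5,
                          uc_taper = 0.63,
                          furlough_exists = FALSE,
                          furlough_rate = 0.8,
                          furlough_cap = 2500,
                          state_pension = 8767) {
  stopifnot(length(tax_thresholds) == length(tax_rates),
            all(diff(tax_thresholds) > 0),
            all(tax_rates >= 0 & tax_rates <= 1),
            ni_rate >= 0, ni_rate <= 1,
            uc_taper >= 0, uc_taper <= 1,
            furlough_rate >= 0, furlough_rate <= 1)
  structure(list(
    name = name,
    tax_thresholds = tax_thresholds, tax_rates = tax_rates,
    ni_rate = ni_rate, ni_floor = ni_floor,
    uc_standard_allowance = uc_standard_allowance,
    uc_standard_allowance_couple = uc_standard_allowance_couple,
    uc_uplift = uc_uplift, uc_child_element = uc_child_element,
    uc_taper = uc_taper,
    furlough = list(exists = furlough_exists, replacement_rate = furlough_rate,
                    monthly_cap = furlough_cap),
    state_pension = state_pension
  ), class = "policy_system")
}

#' Read a policy system from a YAML file
#' @param path path to a YAML file with keys matching [policy_system()]
#'   arguments.
#' @return a `policy_system`.
#' @export
read_policy_system <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(policy_system, y)
}

#' Shipped pre-crisis (2019 baseline) policy system
#'
#' The tax/benefit rules in place before the COVID-19 crisis: 73 GBP/week
#' Universal Credit standard allowance for a single adult 25+, no uplift,
#' no furlough scheme.
#' @return a `policy_system`.
#' @export
uk2019_baseline <- function() {
  read_policy_system(system.file("extdata", "uk2019_baseline.yaml",
                                 package = "distressim"))
}

#' Shipped crisis-response (2020-21) policy system
#'
#' The 2019 baseline plus the 20 GBP/week Universal Credit uplift and the
#' job-retention (furlough) scheme paying 80% of usual wages up to 2500
#' GBP/month.
#' @return a `policy_system`.
#' @export
uk2020_response <- function() {
  read_policy_system(system.file("extdata", "uk2020_response.yaml",
                                 package = "distressim"))
}

#' @export
print.policy_system <- function(x, ...) {
  cat("Policy system:", x$name, "\n")
  cat("  income tax: rates", paste(sprintf("%.0f%%", 100 * x$tax_rates),
                                   collapse = "/"),
      "above", paste(x$tax_thresholds, collapse = "/"), "GBP/yr\n")
  cat(sprintf("  NI: %.0f%% above %s GBP/yr\n", 100 * x$ni_rate, x$ni_floor))
  cat(sprintf("  UC: %.2f GBP/wk single (+%.0f uplift), taper %.2f\n",
              x$uc_standard_allowance, x$uc_uplift, x$uc_taper))
  cat("  furlough:", if (x$furlough$exists)
    sprintf("%.0f%% of usual wages capped at %.0f GBP/month",
            100 * x$furlough$replacement_rate, x$furlough$monthly_cap)
    else "none", "\n")
  invisible(x)
}

#' Furlough pay for a given usual wage
#'
#' The scheme pays `replacement_rate` times the usual monthly wage, capped at
#' `monthly_cap` (80% up to 2500 GBP/month when first introduced).
#'
#' @param usual_monthly_wage usual gross wage, GBP/month (vectorised).
#' @param system a `policy_system` with an active furlough scheme.
#' @return furlough pay, GBP/month.
#' @export
furlough_pay <- function(usual_monthly_wage, system) {
  if (!isTRUE(system$furlough$exists))
    stop("policy system '", system$name, "' has no furlough scheme")
  if (any(usual_monthly_wage < 0)) stop("usual wage must be nonnegative")
  pmin(system$furlough$replacement_rate * usual_monthly_wage,
       system$furlough$monthly_cap)
}

# banded income tax on annual gross, vectorised
income_tax <- function(gross, system) {
  tax <- numeric(length(gross))
  th <- c(system$tax_thresholds, Inf)
  for (i in seq_along(system$tax_rates)) {
    tax <- tax + system$tax_rates[i] * pmax(0, pmin(gross, th[i + 1]) - th[i])
  }
  tax
}

ni_contrib <- function(gross, system) {
  system$ni_rate * pmax(0, gross - system$ni_floor)
}

#' Disposable income of a benefit unit
#'
#' Converts per-adult gross incomes to unit-level disposable income:
#' `disposable = gross - income tax - NI + UC`, with
#' `UC = max(0, 52 * (standard allowance + uplift + child elements)
#'            - taper * net earnings)`.
#' Tax and NI are assessed per adult; the means test is at the unit level on
#' net earnings.  All arguments are vectorised over units.
#'
#' @param gross_adult1,gross_adult2 annual gross income (GBP/year) of each
#'   adult; use `gross_adult2 = NA` (or 0 with `n_adults = 1`) for singles.
#' @param n_adults 1 or 2.
#' @param n_children number of dependent children in the unit.
#' @param system a `policy_system`.
#' @param components return a list with tax/NI/UC components instead of just
#'   the disposable total?
#' @return disposable income, GBP/year (or a list of components).
#' @export
disposable_income <- function(gross_adult1, gross_adult2 = NA, n_adults = 1,
                              n_children = 0, system, components = FALSE) {
  if (any(n_adults < 1 | n_adults > 2)) stop("benefit units have 1 or 2 adults")
  g2 <- ifelse(is.na(gross_adult2), 0, gross_adult2)
  if (any(gross_adult1 < 0) || any(g2 < 0))
    stop("gross income components must be nonnegative")
  gross <- gross_adult1 + g2
  tax <- income_tax(gross_adult1, system) + income_tax(g2, system)
  ni <- ni_contrib(gross_adult1, system) + ni_contrib(g2, system)
  net_earn <- pmax(0, gross - tax - ni)
  allowance <- ifelse(n_adults == 2, system$uc_standard_allowance_couple,
                      system$uc_standard_allowance)
  uc_max <- 52 * (allowance + system$uc_uplift +
                    system$uc_child_element * n_children)
  uc <- pmax(0, uc_max - system$uc_taper * net_earn)
  disp <- gross - tax - ni + uc
  if (components) list(disposable = disp, tax = tax, ni = ni, uc = uc,
                       gross = gross)
  else disp
}

# canonical orderings of the discrete hour points; couple alternatives sorted
# by total hours then first adult's hours (the documented tie-break order)
.HOUR_POINTS <- c(0, 10, 20, 30, 40)
.ALT25 <- {
  g <- expand.grid(h1 = c(0, 10, 20, 30, 40), h2 = c(0, 10, 20, 30, 40))
  g[order(g$h1 + g$h2, g$h1, g$h2), ]
}

#' Discrete budget set of a benefit unit
#'
#' Enumerates the admissible hours alternatives (five hour points 0/10/20/30/40
#' per at-risk adult, so 5 rows for a single at-risk adult and 25 for a couple
#' with both at risk; an adult not at risk of work contributes a single fixed
#' row) and computes gross and disposable income for each.
#'
#' @param wage1,wage2 potential hourly wages (GBP/hour); `wage2 = NA` for a
#'   single-adult unit.
#' @param at_risk1,at_risk2 is each adult at risk of work?  Adults not at risk
#'   are held at `fixed_hours`/`fixed_gross`.
#' @param fixed_gross1,fixed_gross2 annual gross income of an adult not at
#'   risk (e.g. pension), GBP/year.
#' @param n_children number of dependent children.
#' @param system a `policy_system`.
#' @return a data frame with columns `hours1`, `hours2`, `gross`, `disposable`,
#'   ordered by total hours then first adult's hours.
#' @export
budget_set <- function(wage1, wage2 = NA, at_risk1 = TRUE, at_risk2 = NA,
                       fixed_gross1 = 0, fixed_gross2 = 0,
                       n_children = 0, system) {
  couple <- !is.na(wage2) || isTRUE(at_risk2) || identical(at_risk2, FALSE)
  if (isTRUE(at_risk1) && (is.na(wage1) || wage1 <= 0))
    stop("at-risk adults need a positive potential wage")
  if (isTRUE(at_risk2) && (is.na(wage2) || wage2 <= 0))
    stop("at-risk adults need a positive potential wage")
  h1 <- if (isTRUE(at_risk1)) .HOUR_POINTS else 0
  h2 <- if (!couple) NA else if (isTRUE(at_risk2)) .HOUR_POINTS else 0
  grid <- expand.grid(hours1 = h1, hours2 = h2)
  grid <- grid[order(grid$hours1 + ifelse(is.na(grid$hours2), 0, grid$hours2),
                     grid$hours1), , drop = FALSE]
  g1 <- if (isTRUE(at_risk1)) grid$hours1 * wage1 * 52 else fixed_gross1
  g2 <- if (!couple) NA
        else if (isTRUE(at_risk2)) grid$hours2 * wage2 * 52 else fixed_gross2
  disp <- disposable_income(g1, g2, n_adults = if (couple) 2 else 1,
                            n_children = n_children, system = system)
  out <- data.frame(hours1 = grid$hours1, hours2 = grid$hours2,
                    gross = g1 + ifelse(is.na(g2), 0, g2), disposable = disp)
  rownames(out) <- NULL
  out
}

#' Equivalise a disposable income
#'
#' Divides by the modified-OECD scale: 1.0 for the first adult, 0.5 for a
#' second adult, 0.3 per child under 14 and 0.5 per child aged 14 or over.
#'
#' @param disposable annual disposable income, GBP/year (may be negative).
#' @param n_adults 1 or 2.
#' @param n_children_u14 children under 14.
#' @param n_children_14plus children aged 14+.
#' @return equivalised income, GBP/year.
#' @export
equivalise <- function(disposable, n_adults = 1, n_children_u14 = 0,
                       n_children_14plus = 0) {
  factor <- 1 + 0.5 * (n_adults - 1) + 0.3 * n_children_u14 +
    0.5 * n_children_14plus
  disposable / factor
}

#' Poverty classification
#'
#' A unit is in poverty iff its equivalised disposable income is strictly
#' below the poverty line (income exactly at the line is not in poverty).
#'
#' @param equivalised equivalised income, GBP/year (vectorised).
#' @param poverty_line positive poverty line, GBP/year.
#' @return logical vector.
#' @export
poverty_status <- function(equivalised, poverty_line) {
  if (any(poverty_line <= 0)) stop("poverty line must be positive")
  equivalised < poverty_line
}
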