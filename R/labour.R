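# Labour supply.  In structural years hours are chosen by discrete-choice
# random utility over the budget set (joint maximisation at the benefit-unit
# level, Gumbel taste shocks).  In the pandemic years 2020-2021 a reduced-form
# module applies multinomial-logit transitions between employment states.

#' Labour-supply preference coefficients
#'
#' Systematic utility is `income_weight * disposable/1000` plus, per at-risk
#' adult, `hours * (hours_weight + shifters)` and a `state_dependence` bonus
#' when the alternative keeps the adult's previous work status (working vs not
#' working).  The Gumbel taste shock has scale `error_scale`.
#'
#' @param path YAML file of coefficients; `NULL` loads the shipped defaults.
#' @param ... named overrides of individual coefficients (e.g.
#'   `error_scale = 0`).
#' @return object of class `preference_coefficients`.
#' @export
preference_coefficients <- function(path = NULL, ...) {
  if (is.null(path))
    path <- system.file("extdata", "preferences.yaml", package = "distressim")
  p <- yaml::read_yaml(path)
  dots <- list(...)
  p[names(dots)] <- dots
  stopifnot(p$income_weight > 0, p$hours_weight < 0, p$error_scale >= 0)
  structure(p, class = "preference_coefficients")
}

#' Potential hourly wage
#'
#' Log-normal Mincer-style equation: `log(wage) = b0 + b_edu + b_age * age +
#' b_age2 * age^2 + b_male * male + draw`, where `draw` is a persistent
#' person-specific component, clamped below at the minimum wage.  Coefficients
#' are configuration, not estimates.
#'
#' @param age,sex,education person covariates (vectorised); `sex` is
#'   `"male"`/`"female"`, `education` `"low"`/`"medium"`/`"high"`.
#' @param draw persistent person-specific normal component (sd already
#'   applied); defaults to 0.
#' @param coefficients named list of wage-equation coefficients.
#' @param at_risk is each person at risk of work?  Potential wages are only
#'   defined for persons at risk; any `FALSE` is an error.
#' @return hourly wage, GBP/hour, `>= min_wage`.
#' @export
potential_wage <- function(age, sex, education, draw = 0,
                           coefficients = wage_coefficients(),
                           at_risk = TRUE) {
  if (!all(at_risk)) stop("potential wages are defined only for persons at risk of work")
  b <- coefficients
  edu <- c(low = 0, medium = b$edu_medium, high = b$edu_high)[education]
  lw <- b$intercept + edu + b$age * age + b$age2 * age^2 +
    b$male * (sex == "male") + draw
  pmax(exp(lw), b$min_wage)
}

#' Default wage-equation coefficients
#'
#' Chosen so median full-time earnings are about 28,000 GBP/year.
#' @param sd standard deviation of the persistent person draw.
#' @return named list.
#' @export
wage_coefficients <- function(sd = 0.35) {
  list(intercept = 1.59, edu_medium = 0.20, edu_high = 0.45,
       age = 0.035, age2 = -0.0004, male = 0.10, draw_sd = sd, min_wage = 8)
}

#' Systematic utility of a labour-supply alternative
#'
#' @param disposable unit disposable income of the alternative, GBP/year.
#' @param hours1,hours2 weekly hours of each at-risk adult (`hours2 = 0` or
#'   `NA` when absent).
#' @param prefs [preference_coefficients()].
#' @param female1,female2 sex of each adult.
#' @param children_u14 number of children under 14 in the unit.
#' @param edu_high1,edu_high2 high education indicators.
#' @param prev_work1,prev_work2 previous-year work status (`TRUE` if working);
#'   `NA` disables the state-dependence term.
#' @return numeric utility (vectorised over alternatives).
#' @export
labour_utility <- function(disposable, hours1, hours2 = 0, prefs,
                           female1 = FALSE, female2 = FALSE,
                           children_u14 = 0,
                           edu_high1 = FALSE, edu_high2 = FALSE,
                           prev_work1 = NA, prev_work2 = NA) {
  h2 <- ifelse(is.na(hours2), 0, hours2)
  w1 <- prefs$hours_weight + prefs$female_shift * female1 +
    prefs$children_shift * female1 * (children_u14 > 0) +
    prefs$edu_high_shift * edu_high1
  w2 <- prefs$hours_weight + prefs$female_shift * female2 +
    prefs$children_shift * female2 * (children_u14 > 0) +
    prefs$edu_high_shift * edu_high2
  v <- prefs$income_weight * disposable / 1000 + hours1 * w1 + h2 * w2
  if (!all(is.na(prev_work1))) {
    b <- prefs$state_dependence * ((hours1 > 0) == prev_work1)
    v <- v + ifelse(is.na(b), 0, b)
  }
  if (!all(is.na(prev_work2))) {
    b <- prefs$state_dependence * ((h2 > 0) == prev_work2)
    v <- v + ifelse(is.na(b), 0, b)
  }
  v
}

#' Choose labour supply for one benefit unit
#'
#' Adds i.i.d. Gumbel(0, `error_scale`) shocks to the systematic utility of
#' each alternative of a budget set and returns the maximiser.  With
#' `error_scale = 0` ties are broken by lowest total hours then alternative
#' order (budget sets are already sorted this way).
#'
#' @param budget a [budget_set()] data frame.
#' @param prefs [preference_coefficients()].
#' @param n_draws number of replicate choices (for diagnostics).
#' @param seed optional RNG seed.
#' @param ... passed to [labour_utility()].
#' @return integer vector of chosen row indices (length `n_draws`).
#' @export
choose_labour_supply <- function(budget, prefs, n_draws = 1, seed = NULL, ...) {
  v <- labour_utility(budget$disposable, budget$hours1, budget$hours2,
                      prefs, ...)
  k <- length(v)
  if (prefs$error_scale == 0) return(rep(which.max(v), n_draws))
  draw <- function() {
    u <- matrix(stats::runif(n_draws * k), n_draws, k)
    g <- -log(-log(u))
    max.col(matrix(v, n_draws, k, byrow = TRUE) + prefs$error_scale * g,
            ties.method = "first")
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# ---------------------------------------------------------------------------
# reduced-form pandemic transition model

.END_ORDER <- c("employed", "not_employed", "furlough_full", "furlough_partial")
.TM_COVARS <- c("female", "age50", "edu_low", "edu_high", "children",
                "year2021")

#' Pandemic-year employment-state transition model
#'
#' One multinomial logit per starting state (employed, not_employed,
#' furlough_full, furlough_partial, other), with log-odds relative to
#' remaining in the starting state, on covariates sex, age band, education,
#' household type and pandemic year.  The allowed-transitions map is part of
#' the configuration.
#'
#' @param path YAML configuration; `NULL` loads the shipped calibrated
#'   defaults.
#' @return object of class `transition_model`.
#' @export
transition_model <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "transition_model.yaml",
                        package = "distressim")
  y <- yaml::read_yaml(path)
  states <- names(y$states)
  allowed <- lapply(y$states, function(s) {
    ends <- union(s$base, names(s$ends))
    intersect(.END_ORDER, ends)  # canonical interval order
  })
  coef <- lapply(y$states, function(s) {
    lapply(s$ends, function(e) {
      b <- stats::setNames(numeric(length(.TM_COVARS) + 1),
                           c("intercept", .TM_COVARS))
      b[names(e)] <- unlist(e)
      b
    })
  })
  base <- vapply(y$states, function(s) s$base, "")
  structure(list(states = states, allowed = allowed, coef = coef,
                 base = base, intercept_se = y$intercept_se %||% 0),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat("Pandemic transition model (multinomial logit per starting state)\n")
  for (s in x$states)
    cat(sprintf("  %-16s -> %s\n", s, paste(x$allowed[[s]], collapse = ", ")))
  invisible(x)
}

#' Transition probabilities implied by the model
#'
#' @param start_state single starting state.
#' @param X data frame of covariates with columns `female`, `age50`,
#'   `edu_low`, `edu_high`, `children`, `year2021` (0/1, vectorised over
#'   persons; missing columns are treated as 0).
#' @param model a [transition_model()].
#' @param scenario `"observed"` or `"counterfactual"`.  In the counterfactual
#'   the furlough states do not exist: their probability mass is reassigned to
#'   non-employment.
#' @return matrix of probabilities, one row per person, columns named by end
#'   state (rows sum to 1).
#' @export
transition_probs <- function(start_state, X, model = transition_model(),
                             scenario = c("observed", "counterfactual")) {
  scenario <- match.arg(scenario)
  if (!start_state %in% model$states)
    stop("unknown starting state: ", start_state)
  allowed <- model$allowed[[start_state]]
  n <- nrow(X)
  Xm <- matrix(0, n, length(.TM_COVARS), dimnames = list(NULL, .TM_COVARS))
  for (v in intersect(.TM_COVARS, names(X))) Xm[, v] <- as.numeric(X[[v]])
  U <- matrix(0, n, length(allowed), dimnames = list(NULL, allowed))
  for (e in allowed) {
    b <- model$coef[[start_state]][[e]]
    if (!is.null(b)) U[, e] <- b[["intercept"]] + Xm %*% b[.TM_COVARS]
  }
  P <- exp(U)
  P <- P / rowSums(P)
  if (scenario == "counterfactual") {
    fur <- intersect(colnames(P), c("furlough_full", "furlough_partial"))
    if (length(fur)) {
      if (!"not_employed" %in% colnames(P))
        stop("counterfactual reassignment needs a non-employment end state")
      P[, "not_employed"] <- P[, "not_employed"] +
        rowSums(P[, fur, drop = FALSE])
      P <- P[, setdiff(colnames(P), fur), drop = FALSE]
    }
  }
  P
}

#' Sample pandemic-year end states
#'
#' Samples each person's end state from the multinomial implied by the
#' starting-state logit, via inverse CDF over end states in the canonical
#' order (employed, not_employed, furlough states).  Under common random
#' numbers this ordering guarantees that a person furloughed in the observed
#' arm is non-employed, never employed, in the paired counterfactual.
#'
#' @inheritParams transition_probs
#' @param u uniforms in `[0,1]`, one per person (common-random-number callers
#'   supply these); drawn internally if `NULL`.
#' @param seed optional seed for the internal draw.
#' @return character vector of end states.
#' @export
pandemic_transition <- function(start_state, X, model = transition_model(),
                                scenario = c("observed", "counterfactual"),
                                u = NULL, seed = NULL) {
  P <- transition_probs(start_state, X, model, scenario)
  n <- nrow(P)
  if (is.null(u)) u <- if (is.null(seed)) stats::runif(n)
                       else with_seed(seed, stats::runif(n))
  cum <- t(apply(P, 1, cumsum))
  idx <- rowSums(u > cum[, -ncol(cum), drop = FALSE]) + 1L
  colnames(P)[idx]
}

#' Weekly hours implied by a pandemic-year end state
#'
#' Non-employment and full furlough imply 0 hours; continuing employment
#' retains prior hours; entrants to employment draw from the structural hour
#' points; partial furlough draws an integer in 1-39 from a symmetric Beta
#' shape centred near half-time.
#'
#' @param end_state end states (vectorised).
#' @param prior_hours previous weekly hours.
#' @param u_part,u_new optional uniforms for the partial-furlough and
#'   new-entrant draws (common-random-number callers supply these).
#' @param entrant_probs probabilities over hour points 10/20/30/40 for
#'   entrants.
#' @param seed optional seed.
#' @return numeric weekly hours.
#' @export
pandemic_hours <- function(end_state, prior_hours, u_part = NULL, u_new = NULL,
                           entrant_probs = c(0.08, 0.12, 0.15, 0.65),
                           seed = NULL) {
  n <- length(end_state)
  if (is.null(u_part) || is.null(u_new)) {
    uu <- if (is.null(seed)) stats::runif(2 * n)
          else with_seed(seed, stats::runif(2 * n))
    if (is.null(u_part)) u_part <- uu[seq_len(n)]
    if (is.null(u_new)) u_new <- uu[n + seq_len(n)]
  }
  hours <- numeric(n)
  entrant_draw <- c(10, 20, 30, 40)[
    findInterval(u_new, cumsum(entrant_probs / sum(entrant_probs)),
                 left.open = TRUE) + 1L]
  emp <- end_state == "employed"
  hours[emp] <- ifelse(prior_hours[emp] > 0, prior_hours[emp],
                       entrant_draw[emp])
  part <- end_state == "furlough_partial"
  hours[part] <- 1 + floor(stats::qbeta(u_part[part], 2.5, 2.5) * 38.999)
  hours  # not_employed / furlough_full stay at 0
}

#' Tabulate implied transition matrices over a covariate grid
#'
#' Diagnostic: for every starting state and every combination of the model
#' covariates, the implied end-state probabilities.
#'
#' @param model a [transition_model()].
#' @param scenario `"observed"` or `"counterfactual"`.
#' @param year2021 tabulate the second pandemic year?
#' @return long data frame (start, covariates, end, probability).
#' @export
transition_matrix <- function(model = transition_model(),
                              scenario = "observed", year2021 = FALSE) {
  grid <- expand.grid(female = 0:1, age50 = 0:1, edu_low = 0:1,
                      edu_high = 0:1, children = 0:1)
  grid <- grid[!(grid$edu_low & grid$edu_high), ]
  grid$year2021 <- as.numeric(year2021)
  out <- list()
  for (s in model$states) {
    P <- transition_probs(s, grid, model, scenario)
    for (e in colnames(P)) {
      out[[length(out) + 1L]] <- cbind(data.frame(start = s, end = e,
                                                  probability = P[, e]),
                                       grid)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
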