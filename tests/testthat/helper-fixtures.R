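# Shared fixtures, built in code and cached for the duration of the run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

small_config <- function(n = 4000, seed = 5) {
  population_config(n_individuals = n, seed = seed)
}

small_population <- function(n = 4000, seed = 5) {
  fixture(paste0("pop_", n, "_", seed),
          function() generate_population(small_config(n, seed)))
}

# a paired run at modest scale, ending in the first pandemic year, with
# person-level data kept; reused by engine and reporting tests
small_paired <- function() {
  fixture("paired_small", function() {
    pc <- small_config()
    cfg <- scenario_config(population = pc, seed = 31, end_year = 2020)
    run_paired(cfg, model_coefficients(),
               population = small_population(), keep_person_data = TRUE)
  })
}

# transition-model covariate grid used by probability-conservation checks
covariate_grid <- function(year2021 = 0) {
  g <- expand.grid(female = 0:1, age50 = 0:1, edu_low = 0:1, edu_high = 0:1,
                   children = 0:1)
  g <- g[!(g$edu_low & g$edu_high), ]
  g$year2021 <- year2021
  g
}
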