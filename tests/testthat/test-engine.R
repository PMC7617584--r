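# Annual cycle, alignment, demographic step and paired-run machinery.

test_that("alignment is a fixed point when targets equal current margins", {
  pop <- small_population(1500, seed = 9)
  pc0 <- pop$config; pc0$growth_rate <- 0
  tg <- generate_alignment_targets(pc0, 2017:2018, pop$persons)
  out <- align_population(pop$persons, tg, 2017, base_seed = 1)
  expect_equal(nrow(out), nrow(pop$persons))
  expect_identical(out$person_id, pop$persons$person_id)
})

test_that("alignment reproduces target cell counts exactly", {
  pop <- small_population(1500, seed = 9)
  tg <- generate_alignment_targets(pop$config, 2017:2018, pop$persons)
  # double one cell, shrink another
  k1 <- which(tg$year == 2017 & tg$count > 20)[1]
  k2 <- which(tg$year == 2017 & tg$count > 20)[2]
  tg$count[k1] <- 2 * tg$count[k1]
  tg$count[k2] <- tg$count[k2] - 10
  out <- align_population(pop$persons, tg, 2017, base_seed = 1)
  band <- distressim:::align_band(out$age)
  key <- paste(out$sex, band, out$region, sep = "|")
  cnt <- table(key)
  tk <- paste(tg$sex, tg$age_band, tg$region, sep = "|")[tg$year == 2017]
  tv <- tg$count[tg$year == 2017]
  for (i in c(k1, k2, 3, 50)) {
    expect_equal(unname(cnt[tk[i]]), tv[i])
  }
  expect_equal(nrow(out), sum(tv))
  expect_error(align_population(pop$persons, tg, 2024), "cover")
})

test_that("the demographic step applies its rules", {
  pop <- small_population(1500, seed = 9)
  p0 <- pop$persons
  # zero mortality: size constant
  p1 <- demographic_step(p0, 2017, base_seed = 2, mortality_scale = 0)
  expect_equal(nrow(p1), nrow(p0))
  expect_equal(p1$age, p0$age + 1L)
  # a 64-year-old retires at 65
  i64 <- which(p0$age == 64)
  expect_true(all(p1$activity[match(p0$person_id[i64], p1$person_id)] ==
                    "retired"))
  # at-risk rule maintained
  expect_identical(p1$at_risk_of_work,
                   !(p1$activity %in% c("student", "retired")) &
                     !p1$long_term_sick)
  # with mortality, only deaths change the census
  p2 <- demographic_step(p0, 2017, base_seed = 2, mortality_scale = 1)
  expect_lte(nrow(p2), nrow(p0))
  expect_true(all(p2$person_id %in% p0$person_id))
})

test_that("poverty and non-employment counters accumulate consecutive years", {
  pr <- small_paired()
  pd <- pr$observed$person_data
  fin <- pr$observed$final_population$persons
  # anyone with a 2-year poverty streak at the end has counter >= 2
  p19 <- pd[pd$year == 2019, ]
  p20 <- pd[pd$year == 2020, ]
  both <- intersect(p19$person_id[p19$in_poverty], p20$person_id[p20$in_poverty])
  got <- fin$years_in_poverty[match(both, fin$person_id)]
  expect_true(all(got >= 2))
  ne <- fin$years_not_employed
  expect_true(all(ne[fin$activity != "not_employed"] == 0L))
})

test_that("scenario runs are reproducible and order-invariant", {
  pc <- small_config(1500, seed = 9)
  cfg <- scenario_config(population = pc, seed = 3, end_year = 2018)
  r1 <- run_scenario(cfg)
  r2 <- run_scenario(cfg)
  expect_identical(r1$aggregates, r2$aggregates)
  # permuting person order leaves aggregates unchanged
  pop <- generate_population(pc)
  tg <- generate_alignment_targets(pc, 2017:2018, pop$persons)
  perm <- pop
  set.seed(99)
  perm$persons <- perm$persons[sample(nrow(perm$persons)), ]
  r3 <- run_scenario(cfg, population = pop, targets = tg)
  r4 <- run_scenario(cfg, population = perm, targets = tg)
  expect_equal(r3$aggregates, r4$aggregates)
})

test_that("paired arms are bit-identical before the pandemic diverges them", {
  pr <- small_paired()
  po <- pr$observed$person_data
  pc0 <- pr$counterfactual$person_data
  pre <- po$year <= 2019
  expect_identical(po[pre, ], pc0[pc0$year <= 2019, ])
  expect_identical(pr$observed$aggregates[1:3, ],
                   pr$counterfactual$aggregates[1:3, ])
  # and identical policy schedules give bit-identical output everywhere
  cfg <- scenario_config(population = small_config(), seed = 31,
                         end_year = 2020)
  cfg$response_system <- cfg$baseline_system
  cfg$scenario <- "observed"
  cfg2 <- cfg; cfg2$scenario <- "counterfactual"
  pop <- small_population()
  a <- run_scenario(cfg, population = pop)
  b <- run_scenario(cfg2, population = pop)
  expect_identical(a$aggregates, b$aggregates)
})

test_that("furlough states exist only in observed-scenario pandemic years", {
  pr <- small_paired()
  po <- pr$observed$person_data
  pc0 <- pr$counterfactual$person_data
  expect_false(any(grepl("furlough", pc0$activity)))
  expect_false(any(grepl("furlough", po$activity[po$year < 2020])))
  p20 <- po[po$year == 2020, ]
  expect_gt(mean(grepl("furlough", p20$activity[p20$age >= 25 &
                                                  p20$age <= 64])), 0.05)
  # full furlough means zero hours worked
  fin <- pr$observed$final_population$persons
  expect_true(all(fin$hours[fin$activity == "furlough_full"] == 0))
})

test_that("common random numbers couple furlough to counterfactual non-employment", {
  pr <- small_paired()
  po <- pr$observed$person_data
  pc0 <- pr$counterfactual$person_data
  o20 <- po[po$year == 2020, ]
  c20 <- pc0[pc0$year == 2020, ]
  fur <- o20$person_id[grepl("furlough", o20$activity)]
  cf_state <- c20$activity[match(fur, c20$person_id)]
  expect_true(all(cf_state == "not_employed"))
})

test_that("pre-crisis aggregates hit the calibration anchors", {
  run <- fixture("run20k_2019", function() {
    pc <- population_config(n_individuals = 20000, seed = 1)
    cfg <- scenario_config(population = pc, seed = 7, end_year = 2019)
    run_scenario(cfg)
  })
  a <- run$aggregates[run$aggregates$year == 2019, ]
  expect_gte(a$employment_rate, 0.73); expect_lte(a$employment_rate, 0.77)
  expect_gte(a$cmd_prevalence, 0.19); expect_lte(a$cmd_prevalence, 0.21)
  expect_lt(abs(a$median_likert - 11.3), 0.3)
})

test_that("missing policy coverage and empty targets fail loudly", {
  pc <- small_config(1500, seed = 9)
  cfg <- scenario_config(population = pc, seed = 3, end_year = 2018)
  pop <- generate_population(pc)
  pop$targets <- generate_alignment_targets(pc, 2017, pop$persons)
  expect_error(run_year(pop, 2018, cfg), "cover")
})
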