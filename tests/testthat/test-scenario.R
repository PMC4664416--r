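test_that("scenario presets encode the standard what-if grid", {
  A <- build_scenario("A")
  expect_equal(A$incidence_trend, 0)
  expect_equal(A$mortality_trend, "declining")
  expect_equal(build_scenario("B")$incidence_trend, 0.01)
  expect_equal(build_scenario("C")$incidence_trend, -0.01)
  D <- build_scenario("D")
  expect_equal(D$incidence_trend, 0)
  expect_equal(D$mortality_trend, "constant")
  custom <- build_scenario("steep", incidence_trend = 0.02,
                           mortality_trend = "constant")
  expect_equal(custom$incidence_trend, 0.02)
  expect_equal(custom$mortality_trend, "constant")
  expect_error(build_scenario("Z"), "unknown scenario")
  expect_error(build_scenario("x", 1.5, "constant"), "incidence_trend")
  expect_error(build_scenario("A", horizon_end = 2000), "horizon_end")
})

test_that("a one-step projection reduces to a single forward step", {
  tc <- toy_country(ages = 99:100, years = 2013:2014,
                    N_top = 1000, p_base = 0.05, p_age_step = 0.02,
                    i_level = 0.01, rr = 2)
  # empty the top bin so the pooled cohort is just the age-99 survivors
  counts <- tc$pop$counts
  counts$value[counts$age == 100] <- 0
  pop <- population_frame(counts)
  sc <- build_scenario("A", base_year = 2013, horizon_end = 2014)
  run <- project(tc$prev, tc$inc, tc$em, pop, tc$mort, sc)

  p99 <- 0.05
  m <- tc$mort$value[tc$mort$year == 2014 & tc$mort$age == 100 &
                       tc$mort$sex == "female"]
  rr1 <- 1 + (2 - 1) * (1 - 0.016)^1
  m0 <- m / (1 - p99 + rr1 * p99)
  by_hand <- ((1 - rr1 * m0) * p99 +
                ((1 - m) - (1 - rr1 * m0) * p99) * 0.01) / (1 - m)
  got <- run$prevalence$value[run$prevalence$year == 2014 &
                                run$prevalence$age == 100 &
                                run$prevalence$sex == "female"]
  expect_equal(got, by_hand, tolerance = 1e-14)
})

test_that("two chained yearly steps match the hand-evaluated recurrence", {
  # two ages, two projected years, all inputs spelled out, no migration,
  # empty top bin start, zero entrants; follow the age-99 cohort by hand
  ages <- 98:100
  y <- 2013:2015
  m_val <- 0.1
  counts <- toy_table(2013, ages, c(500, 400, 0))
  mort <- agesex_table(toy_table(y, ages, m_val), "risk")
  prev <- agesex_table(toy_table(2013, ages, c(0.04, 0.06, 0)), "proportion")
  inc <- toy_table(2013, ages, 0.02)[c("sex", "age", "value")]
  em <- excess_mortality_model(1.5, annual_decline = 0, reference_year = 2013)
  sc <- build_scenario("A", base_year = 2013, horizon_end = 2015)
  run <- project(prev, inc, em,
                 population_frame(agesex_table(counts, "count")), mort, sc)

  step <- function(p, m, rr, i) {
    m0 <- m / (1 - p + rr * p)
    m1 <- rr * m0
    ((1 - m1) * p + ((1 - m) - (1 - m1) * p) * i) / (1 - m)
  }
  # cohort aged 99 in 2013 -> age 100 in 2014 (pool holds only this cohort,
  # since the 100 bin starts empty) -> stays 100 in 2015, now pooled with
  # the cohort that was 98 in 2013 and 99 in 2014
  p100_14 <- step(0.06, m_val, 1.5, 0.02)
  p99_14 <- step(0.04, m_val, 1.5, 0.02)
  got14 <- run$prevalence[run$prevalence$year == 2014 &
                            run$prevalence$sex == "male", ]
  expect_equal(got14$value[got14$age == 100], p100_14, tolerance = 1e-14)
  expect_equal(got14$value[got14$age == 99], p99_14, tolerance = 1e-14)

  # survivors entering 2015's pool: cohorts aged 99 and 100 in 2014
  # (counts at 2013: age 98 -> 500, age 99 -> 400, age 100 -> 0)
  s_from99 <- 400 * (1 - m_val)            # alive at start of 2014, age 100
  s_from98 <- 500 * (1 - m_val)            # alive at start of 2014, age 99
  w100 <- s_from99 * (1 - m_val) + s_from98 * (1 - m_val)
  p_pool <- (s_from99 * (1 - m_val) * p100_14 +
               s_from98 * (1 - m_val) * p99_14) / w100
  p100_15 <- step(p_pool, m_val, 1.5, 0.02)
  got15 <- run$prevalence[run$prevalence$year == 2015 &
                            run$prevalence$sex == "male", ]
  expect_equal(got15$value[got15$age == 100], p100_15, tolerance = 1e-13)
})

test_that("a closed cohort with no incidence and no excess risk is static", {
  tc <- toy_country(i_level = 0, rr = 1, p_base = 0.07, p_age_step = 0)
  sc <- build_scenario("A", base_year = 2013, horizon_end = 2023)
  run <- project(tc$prev, tc$inc, tc$em, tc$pop, tc$mort, sc)
  expect_lt(max(abs(run$prevalence$value - 0.07)), 1e-13)
  expect_lt(diff(range(run$annual$prevalence_total)), 1e-13)
})

test_that("summaries aggregate counts and age shares correctly", {
  tc <- toy_country(ages = 95:100, years = 2013:2015)
  sc <- build_scenario("A", base_year = 2013, horizon_end = 2015)
  run <- project(tc$prev, tc$inc, tc$em, tc$pop, tc$mort, sc)
  smry <- summarize_projection(run, bands = "95+")
  # all cases are 65 or older in this toy
  expect_equal(smry$headline$share65_base, 1)
  expect_equal(smry$headline$share65_horizon, 1)
  # counts are sum of p * N over cohorts, by hand
  pN <- merge(run$prevalence[run$prevalence$year == 2015, ],
              run$population$counts[run$population$counts$year == 2015, ],
              by = c("year", "sex", "age"))
  expect_equal(smry$headline$cases_total, sum(pN$value.x * pN$value.y),
               tolerance = 1e-12)
  expect_equal(smry$headline$prevalence_total,
               sum(pN$value.x * pN$value.y) / sum(pN$value.y),
               tolerance = 1e-12)
  expect_equal(nrow(smry$annual), 3)
})

test_that("scenario ordering is monotone in the incidence trend and rr trend", {
  cc <- default_country()
  base <- agesex_table(
    cc$prevalence[cc$prevalence$year == 2013, ], "proportion")
  runs <- lapply(c("A", "B", "C", "D"), function(s) {
    project(base, cc$incidence, cc$excess_mortality, cc$population,
            cc$mortality, build_scenario(s, base_year = 2013,
                                         horizon_end = 2028))
  })
  names(runs) <- c("A", "B", "C", "D")
  pa <- runs$A$annual$prevalence_total
  expect_true(all(runs$B$annual$prevalence_total >= pa))
  expect_true(all(pa >= runs$C$annual$prevalence_total))
  expect_true(all(pa >= runs$D$annual$prevalence_total))
  # prevalence bounded in [0, 1] everywhere
  for (r in runs) {
    expect_true(all(r$prevalence$value >= 0 & r$prevalence$value <= 1))
  }
})

test_that("results are invariant to population scale", {
  tc <- toy_country(entrant_level = 200)
  k <- 3
  scaled_counts <- tc$pop$counts
  scaled_counts$value <- scaled_counts$value * k
  entrants_k <- tc$pop$entrants
  entrants_k$value <- entrants_k$value * k
  pop_k <- population_frame(scaled_counts, entrants = entrants_k)
  sc <- build_scenario("A", base_year = 2013, horizon_end = 2023)
  run1 <- project(tc$prev, tc$inc, tc$em, tc$pop, tc$mort, sc)
  runk <- project(tc$prev, tc$inc, tc$em, pop_k, tc$mort, sc)
  expect_lt(max(abs(runk$annual$prevalence_total -
                      run1$annual$prevalence_total)), 1e-12)
  expect_equal(runk$annual$cases_total, k * run1$annual$cases_total,
               tolerance = 1e-12)
})
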