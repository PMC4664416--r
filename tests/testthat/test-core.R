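test_that("forward prevalence step matches hand-evaluated cases", {
  # no deaths, no incidence: unchanged
  expect_equal(forward_prevalence_step(0.05, 0, 0, 0), 0.05)
  # incidence only, starting from zero prevalence
  expect_equal(forward_prevalence_step(0, 0, 0.7, 0.004), 0.004)
  # full formula, evaluated by hand:
  # (0.98*0.05 + (0.99 - 0.98*0.05) * 0.004) / 0.99
  expect_equal(forward_prevalence_step(0.05, 0.01, 0.02, 0.004),
               (0.98 * 0.05 + (0.99 - 0.98 * 0.05) * 0.004) / 0.99)
  expect_equal(forward_prevalence_step(0.05, 0.01, 0.02, 0.004),
               0.05329697, tolerance = 1e-7)
  expect_error(forward_prevalence_step(0.05, 1, 0.02, 0.004), "division")
  # diseased survivors cannot exceed all survivors
  expect_error(forward_prevalence_step(0.9, 0.5, 0.0, 0), "consistency")
})

test_that("incidence back-calculation inverts the forward step", {
  # stationary prevalence with equal mortality implies zero incidence
  expect_equal(backcalc_incidence(0.05, 0.05, 0.01, 0.01), 0)
  # degenerate empty cohort: incidence is the new prevalence itself
  expect_equal(backcalc_incidence(0.037, 0, 0, 0.5), 0.037)
  # exact round trip of the worked forward example
  p1 <- forward_prevalence_step(0.05, 0.01, 0.02, 0.004)
  expect_equal(backcalc_incidence(p1, 0.05, 0.01, 0.02), 0.004,
               tolerance = 1e-14)
  expect_warning(backcalc_incidence(0, 0.5, 0, 0), "negative")
  expect_error(backcalc_incidence(0.1, 1, 0.5, 0), "degenerate")
})

test_that("round trip is exact over randomized valid inputs", {
  set.seed(7)
  n <- 2000
  p <- runif(n); m <- runif(n, 0, 0.6); i <- runif(n)
  m1 <- m + runif(n) * (1 - m) * runif(n, 0, 0.5)  # m1 >= m, < 1
  ok <- (1 - m1) * p <= (1 - m) & (1 - m) - (1 - m1) * p > 0.01
  p <- p[ok]; m <- m[ok]; m1 <- m1[ok]; i <- i[ok]
  i_hat <- backcalc_incidence(forward_prevalence_step(p, m, m1, i), p, m, m1)
  expect_lt(max(abs(i_hat - i)), 1e-12)
})

test_that("forward step is monotone in its drivers", {
  set.seed(11)
  p <- runif(200, 0, 0.5); m <- runif(200, 0, 0.3)
  m1 <- pmin(m * 1.5, 0.9); i <- runif(200, 0, 0.1)
  base <- forward_prevalence_step(p, m, m1, i)
  expect_true(all(forward_prevalence_step(p, m, m1, i + 0.01) >= base))
  expect_true(all(forward_prevalence_step(pmin(p + 0.01, 1), m, m1, i) >= base))
  # raising diseased mortality (m fixed) never raises prevalence
  expect_true(all(forward_prevalence_step(p, m, pmin(m1 + 0.05, 1), i) <= base))
  # with no incidence and no excess mortality the state is a fixed point
  expect_equal(forward_prevalence_step(p, m, m, 0), p, tolerance = 1e-15)
})

test_that("death-risk split preserves the population mortality budget", {
  # no excess risk: both groups share the total risk
  s <- diabetic_death_risk(0.02, 0.1, 1)
  expect_equal(s$m1, 0.02); expect_equal(s$m0, 0.02)
  # empty diseased group: m0 equals m
  s <- diabetic_death_risk(0.02, 0, 3)
  expect_equal(s$m0, 0.02); expect_equal(s$m1, 0.06)
  # hand-solved mixture: m=0.01, p=0.05, rr=3
  s <- diabetic_death_risk(0.01, 0.05, 3)
  expect_equal(s$m0, 0.01 / 1.1, tolerance = 1e-12)
  expect_equal(s$m1, 0.03 / 1.1, tolerance = 1e-12)
  # mixture identity holds exactly across random draws (where no clamping
  # of m1 at 1 is needed)
  set.seed(3)
  m <- runif(500, 0, 0.5); p <- runif(500); rr <- 1 + rexp(500)
  ok <- rr * m / (1 - p + rr * p) <= 1
  m <- m[ok]; p <- p[ok]; rr <- rr[ok]
  s <- diabetic_death_risk(m, p, rr)
  expect_gt(length(m), 300)
  expect_lt(max(abs(p * s$m1 + (1 - p) * s$m0 - m)), 1e-15)
  # vs_total convention
  s <- diabetic_death_risk(0.01, 0.05, 3, reference = "vs_total")
  expect_equal(s$m1, 0.03)
  expect_equal(0.05 * s$m1 + 0.95 * s$m0, 0.01, tolerance = 1e-15)
  expect_error(diabetic_death_risk(0.5, 0.9, 3, reference = "vs_total"),
               "consistency")
  expect_error(diabetic_death_risk(0.1, 0.1, 0.5), "rr")
})

test_that("relative-risk trend declines as specified and never crosses 1", {
  em <- excess_mortality_model(3, annual_decline = 0.016)
  expect_equal(rr_at_year(em, 0), 3)
  expect_equal(rr_at_year(em, 1), 1 + 2 * 0.984)
  expect_equal(rr_at_year(em, 1), 2.968)
  expect_lt(rr_at_year(em, 2000) - 1, 1e-10)
  # ratio convention floors at 1
  emr <- excess_mortality_model(3, annual_decline = 0.016,
                                convention = "ratio")
  expect_equal(rr_at_year(emr, 1), 3 * 0.984)
  expect_equal(rr_at_year(emr, 500), 1)
  # age-specific curves keep their shape
  rr0 <- tibble::tibble(sex = rep(c("female", "male"), each = 2),
                        age = rep(99:100, 2), rr = c(2, 1.5, 2, 1.5))
  emt <- excess_mortality_model(rr0, annual_decline = 0.5)
  expect_equal(rr_at_year(emt, 1)$rr, c(1.5, 1.25, 1.5, 1.25))
  expect_error(excess_mortality_model(0.9), "rr0")
})

test_that("amplification factor rescales ascertained counts", {
  expect_equal(round(amplification_factor(treatment_share(0.226)), 3), 1.292)
  expect_equal(amplification_factor(0), 1)
  expect_equal(amplification_factor(0.5), 2)
  expect_error(amplification_factor(1), "share")
  expect_error(treatment_share(1.2), "nonpharm_share")
  # exact identity: factor * (1 - share) = 1
  s <- seq(0, 0.99, by = 0.01)
  expect_equal(amplification_factor(s) * (1 - s), rep(1, length(s)),
               tolerance = 1e-15)
})

test_that("undiagnosed adjustment follows the declared convention", {
  expect_equal(as.numeric(apply_undiagnosed(0.1, 0)), 0.1)
  expect_equal(as.numeric(apply_undiagnosed(0.1, 0.366, "of_total")),
               0.1 / 0.634)
  expect_equal(as.numeric(apply_undiagnosed(0.1, 0.366, "of_diagnosed")),
               0.1366)
  expect_equal(attr(apply_undiagnosed(0.1, 0.366), "convention"), "of_total")
  expect_error(apply_undiagnosed(0.1, 1), "undiag_share")
})

test_that("baseline estimation recovers a known surface and flags impossibilities", {
  tc <- toy_country(years = 2013:2016)
  sc <- build_scenario("baseline", incidence_trend = 0,
                       mortality_trend = "declining",
                       base_year = 2013, horizon_end = 2016)
  run <- project(tc$prev, tc$inc, tc$em, tc$pop, tc$mort, sc)
  est <- estimate_baseline(agesex_table(run$prevalence, "proportion"),
                           tc$mort, tc$em)
  truth <- tc$inc$value[match(paste(est$sex, est$age),
                              paste(tc$inc$sex, tc$inc$age))]
  expect_lt(max(abs(est$value - truth)), 1e-12)
  expect_false(any(est$negative))
  # ages outside the invertible range are absent
  expect_false(any(est$age %in% c(min(tc$ages), 100)))

  # constant prevalence with rr = 1 implies ... incidence that offsets deaths
  # of the diseased exactly; with m = 0 it is exactly zero
  flatprev <- agesex_table(toy_table(2013:2014, 95:100, 0.08), "proportion")
  zero_m <- agesex_table(toy_table(2013:2014, 95:100, 0), "risk")
  em1 <- excess_mortality_model(1, reference_year = 2013)
  est0 <- estimate_baseline(flatprev, zero_m, em1)
  expect_equal(est0$value, rep(0, nrow(est0)), tolerance = 1e-15)

  # prevalence collapsing to zero without mortality is impossible: flagged
  drop <- rbind(toy_table(2013, 95:100, 0.3), toy_table(2014, 95:100, 0))
  suppressWarnings(
    estd <- estimate_baseline(agesex_table(drop, "proportion"), zero_m, em1))
  expect_true(all(estd$negative))

  gap <- rbind(toy_table(2013, 95:100, 0.1), toy_table(2015, 95:100, 0.1))
  expect_error(estimate_baseline(agesex_table(gap, "proportion"), zero_m, em1),
               "gap")
})

test_that("incidence surfaces extend to boundary ages by nearest value", {
  inc <- tibble::tibble(sex = rep(c("female", "male"), each = 3),
                        age = rep(96:98, 2), value = c(1:3, 4:6) / 100)
  full <- extend_incidence(inc, ages = 95:100)
  expect_equal(nrow(full), 12)
  f <- full[full$sex == "female", ]
  expect_equal(f$value, c(0.01, 0.01, 0.02, 0.03, 0.03, 0.03))
})
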