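# Small fully-specified fixtures, built in code.

# tidy table over an age span for both sexes, one value vector recycled
toy_table <- function(years, ages, value) {
  g <- expand.grid(age = ages, sex = c("female", "male"), year = years,
                   stringsAsFactors = FALSE)
  g$value <- rep_len(value, nrow(g))
  tibble::as_tibble(g[c("year", "sex", "age", "value")])
}

# a compact old-age country: short axis, improving mortality, rising-with-age
# prevalence, declining relative risk -- enough structure for every driver
toy_country <- function(ages = 95:100, years = 2013:2023,
                        m_base = 0.08, m_age_step = 0.02, improvement = 0.02,
                        N_top = 1000, p_base = 0.05, p_age_step = 0.01,
                        i_level = 0.01, rr = 2, rr_decline = 0.016,
                        entrant_level = NULL) {
  y0 <- years[1]
  m_age <- m_base + m_age_step * (ages - min(ages))
  mort <- do.call(rbind, lapply(years, function(y) {
    toy_table(y, ages, m_age * (1 - improvement)^(y - y0))
  }))
  mort <- agesex_table(mort, "risk")
  N_age <- N_top * (1 - 0.1 * (ages - min(ages)))
  counts <- agesex_table(toy_table(y0, ages, N_age), "count")
  entrants <- NULL
  if (!is.null(entrant_level)) {
    entrants <- tibble::tibble(
      year = rep(years[-1], each = 2),
      sex = rep(c("female", "male"), length(years) - 1),
      value = entrant_level
    )
  }
  pop <- population_frame(counts, entrants = entrants)
  prev <- agesex_table(toy_table(y0, ages, p_base + p_age_step * (ages - min(ages))),
                       "proportion")
  inc <- toy_table(y0, ages, i_level)[c("sex", "age", "value")]
  em <- excess_mortality_model(rr, annual_decline = rr_decline,
                               reference_year = y0)
  list(pop = pop, mort = mort, prev = prev, inc = inc, em = em,
       years = years, ages = ages)
}

# shared default synthetic country for the heavier tests (built once per run)
default_country <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_country(synthetic_spec())
    cache
  }
})

expect_within <- function(x, lo, hi) {
  testthat::expect_gte(x, lo)
  testthat::expect_lte(x, hi)
}
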