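#' Define a projection scenario
#'
#' Four named scenarios cover the usual what-if grid: A (incidence constant,
#' relative mortality keeps declining), B (incidence +1%/yr, mortality
#' declining), C (incidence -1%/yr, mortality declining) and D (incidence
#' constant, relative mortality frozen at its base-year level). Custom
#' combinations are built by passing the fields directly.
#'
#' @param name `"A"`, `"B"`, `"C"`, `"D"`, or a custom label (in which case
#'   `incidence_trend` and `mortality_trend` must be supplied).
#' @param incidence_trend Signed annual multiplicative change in incidence
#'   (e.g. `+0.01` for a 1% annual increase); `|trend| < 1`.
#' @param mortality_trend `"declining"` (the excess-mortality model's annual
#'   decline applies) or `"constant"` (relative risk frozen at base year).
#' @param base_year Last observed year; trends count years from here (the
#'   first projected year has `t = 1`).
#' @param horizon_end Final projected year.
#' @return A list of class `scenario_spec`.
#' @export
build_scenario <- function(name = "A", incidence_trend = NULL,
                           mortality_trend = NULL, base_year = 2013L,
                           horizon_end = 2050L) {
  presets <- list(
    A = list(incidence_trend = 0.0, mortality_trend = "declining"),
    B = list(incidence_trend = +0.01, mortality_trend = "declining"),
    C = list(incidence_trend = -0.01, mortality_trend = "declining"),
    D = list(incidence_trend = 0.0, mortality_trend = "constant")
  )
  if (is.null(incidence_trend) && is.null(mortality_trend)) {
    if (!name %in% names(presets)) {
      stop("unknown scenario '", name, "'; use A, B, C, D or supply ",
           "incidence_trend and mortality_trend", call. = FALSE)
    }
    incidence_trend <- presets[[name]]$incidence_trend
    mortality_trend <- presets[[name]]$mortality_trend
  }
  mortality_trend <- match.arg(mortality_trend, c("declining", "constant"))
  if (abs(incidence_trend) >= 1) stop("|incidence_trend| must be < 1", call. = FALSE)
  if (horizon_end <= base_year) stop("horizon_end must exceed base_year", call. = FALSE)
  structure(
    list(name = name, incidence_trend = incidence_trend,
         mortality_trend = mortality_trend, base_year = as.integer(base_year),
         horizon_end = as.integer(horizon_end)),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec>", x$name, "| incidence", sprintf("%+.1f%%/yr,", 100 * x$incidence_trend),
      "relative mortality", x$mortality_trend, "|", x$base_year, "->",
      x$horizon_end, "\n")
  invisible(x)
}

#' Project prevalence and case counts forward under a scenario
#'
#' Runs the illness-death recurrence year by year for every birth cohort and
#' sex from the base year to the horizon. Each year, the base-year incidence
#' surface is scaled by `(1 + incidence_trend)^t`, the excess-mortality model
#' supplies the relative risk at trend time `t` (frozen at `t = 0` when
#' `mortality_trend = "constant"`), the diseased/disease-free death-risk split
#' keeps the population mortality budget exact, and cohorts age through the
#' cohort-component bookkeeping (entrants at the entry age, migrants joining
#' with their cohort's prevalence by default, survivors of the two oldest ages
#' pooling into the absorbing 100+ bin).
#'
#' @param base An [agesex_table()] of prevalence proportions containing the
#'   base year (additional years are ignored).
#' @param inc0 Base-year incidence surface: a tibble with columns `sex`,
#'   `age`, `value` covering the full age axis (a `year` column, if present,
#'   is ignored).
#' @param em An [excess_mortality_model()].
#' @param pop A [population_frame()]; counts are advanced on the fly for
#'   years not already present.
#' @param mort An [agesex_table()] of total-population death risks covering
#'   `base_year .. horizon_end`.
#' @param spec A [build_scenario()] specification.
#' @param migrant_prevalence `"match"` (migrants carry the prevalence of the
#'   cohort they join; the default, which keeps results population-size
#'   invariant) or `"zero"` (migrants arrive disease-free; for sensitivity
#'   runs).
#' @param entrant_scaling If `TRUE` (default), entrant cohorts receive the
#'   base-year entry-age prevalence scaled by the cumulative incidence-trend
#'   factor; if `FALSE`, the unscaled base-year value.
#' @param keep_rates If `TRUE`, the per-year age-by-sex matrices of the
#'   transition risks actually applied (`m0`, `m1`, `i`) are kept in the
#'   result (`$rates`), e.g. to drive a microsimulation with identical rates.
#' @return A list of class `projection_result` with elements
#'   `prevalence` (tidy per-cohort end-of-year prevalence for every year),
#'   `annual` (per-year totals: prevalence % overall and by sex, case
#'   counts, share of cases aged 65+), `population` (the frame actually
#'   used), and `spec`.
#' @export
project <- function(base, inc0, em, pop, mort, spec,
                    migrant_prevalence = c("match", "zero"),
                    entrant_scaling = TRUE, keep_rates = FALSE) {
  migrant_prevalence <- match.arg(migrant_prevalence)
  y0 <- spec$base_year
  yN <- spec$horizon_end
  ages <- seq.int(min(base$age[base$year == y0]), .AGE_MAX)
  n <- length(ages)
  if (n < 2) stop("age axis must span at least two ages", call. = FALSE)

  P <- ast_matrix(base, y0, ages = ages, what = "base prevalence")
  inc0 <- tibble::as_tibble(inc0)
  I0 <- ast_matrix(tibble::tibble(year = y0, sex = inc0$sex, age = inc0$age,
                                  value = inc0$value),
                   y0, ages = ages, what = "base incidence")
  pop <- project_population(pop, mort, yN)
  p20_base <- P[1, ]

  prev_rows <- vector("list", yN - y0 + 1)
  prev_rows[[1]] <- matrix_ast(P, y0)
  annual <- vector("list", yN - y0 + 1)
  N0 <- ast_matrix(pop$counts, y0, ages = ages, what = "population")
  annual[[1]] <- annual_summary(P, N0, y0)
  rates <- if (keep_rates) vector("list", yN - y0) else NULL

  for (y in (y0 + 1L):yN) {
    t <- y - y0
    f <- (1 + spec$incidence_trend)^t
    I <- pmin(pmax(I0 * f, 0), 1)
    t_rr <- if (spec$mortality_trend == "constant") 0L else t
    RR <- rr_matrix(em, t_rr + (y0 - em$reference_year), ages = ages)
    M <- ast_matrix(mort, y, ages = ages, what = "mortality")
    N_prev <- ast_matrix(pop$counts, y - 1L, ages = ages, what = "population")
    M_prevyr <- ast_matrix(mort, y - 1L, ages = ages, what = "mortality")
    S <- N_prev * (1 - M_prevyr)          # survivors entering year y
    MIG <- migration_matrix(pop, y, ages = ages)

    # effective previous prevalence per cohort aged a at start of year y
    p_eff <- matrix(NA_real_, n, 2, dimnames = list(ages, .SEXES))
    w_surv <- matrix(0, n, 2)
    p_eff[2:n, ] <- P[1:(n - 1), ]
    w_surv[2:n, ] <- S[1:(n - 1), ]
    # absorbing 100+: pool survivors of ages 99 and 100, survivor-weighted
    w100 <- S[n - 1, ] + S[n, ]
    p100 <- ifelse(w100 > 0,
                   (S[n - 1, ] * P[n - 1, ] + S[n, ] * P[n, ]) / w100,
                   P[n, ])
    p_eff[n, ] <- p100
    w_surv[n, ] <- w100
    if (migrant_prevalence == "zero") {
      mig_in <- pmax(MIG, 0)
      tot <- w_surv + mig_in
      p_eff[-1, ] <- ifelse(tot[-1, ] > 0,
                            w_surv[-1, ] * p_eff[-1, ] / tot[-1, ],
                            p_eff[-1, ])
    }

    P_new <- matrix(NA_real_, n, 2, dimnames = list(ages, .SEXES))
    split <- diabetic_death_risk(M[-1, ], p_eff[-1, ], RR[-1, ],
                                 reference = em$reference)
    m1 <- matrix(split$m1, n - 1, 2)
    P_new[-1, ] <- forward_prevalence_step(p_eff[-1, ], M[-1, ], m1, I[-1, ])
    if (keep_rates) {
      m0_full <- m1_full <- matrix(NA_real_, n, 2, dimnames = list(ages, .SEXES))
      m1_full[-1, ] <- m1
      m0_full[-1, ] <- matrix(split$m0, n - 1, 2)
      rates[[t]] <- list(year = y, m0 = m0_full, m1 = m1_full, i = I)
    }
    # entrant cohort at the entry age
    ent_f <- if (entrant_scaling) f else 1
    P_new[1, ] <- pmin(p20_base * ent_f, 1)

    P <- P_new
    prev_rows[[t + 1]] <- matrix_ast(P, y)
    Ny <- ast_matrix(pop$counts, y, ages = ages, what = "population")
    annual[[t + 1]] <- annual_summary(P, Ny, y)
  }

  structure(
    list(prevalence = dplyr::bind_rows(prev_rows),
         annual = dplyr::bind_rows(annual),
         population = pop,
         spec = spec,
         rates = rates),
    class = "projection_result"
  )
}

# per-year headline numbers from a prevalence matrix and population matrix
annual_summary <- function(P, N, year) {
  cases <- P * N
  old <- as.integer(rownames(P)) >= 65L
  tot_cases <- sum(cases)
  tibble::tibble(
    year = year,
    prevalence_total = tot_cases / sum(N),
    prevalence_female = sum(cases[, "female"]) / sum(N[, "female"]),
    prevalence_male = sum(cases[, "male"]) / sum(N[, "male"]),
    cases_total = tot_cases,
    cases_female = sum(cases[, "female"]),
    cases_male = sum(cases[, "male"]),
    share65 = if (tot_cases > 0) sum(cases[old, ]) / tot_cases else NA_real_
  )
}

#' @export
print.projection_result <- function(x, ...) {
  first <- x$annual[1, ]
  last <- x$annual[nrow(x$annual), ]
  cat("<projection_result> scenario", x$spec$name, "|", first$year, "->",
      last$year, "\n")
  cat(sprintf("  prevalence %.2f%% -> %.2f%%; cases %.0f -> %.0f; share 65+ %.0f%% -> %.0f%%\n",
              100 * first$prevalence_total, 100 * last$prevalence_total,
              first$cases_total, last$cases_total,
              100 * first$share65, 100 * last$share65))
  invisible(x)
}

#' Headline summary of a projection
#'
#' @param result A [project()] result.
#' @param bands Age-band labels for a banded final-year prevalence table
#'   (passed to [band_aggregate()]); `NULL` to skip.
#' @return A list with `headline` (one row: final-year prevalence overall and
#'   by sex, final-year case counts, share of cases aged 65+ at base and
#'   horizon), `annual` (the full yearly series), and `banded` (final-year
#'   banded prevalence, if requested).
#' @export
summarize_projection <- function(result, bands = c("20-44", "45-64", "65+")) {
  ann <- result$annual
  first <- ann[1, ]
  last <- ann[nrow(ann), ]
  headline <- tibble::tibble(
    scenario = result$spec$name,
    base_year = first$year,
    horizon = last$year,
    prevalence_total = last$prevalence_total,
    prevalence_female = last$prevalence_female,
    prevalence_male = last$prevalence_male,
    cases_total = last$cases_total,
    cases_female = last$cases_female,
    cases_male = last$cases_male,
    share65_base = first$share65,
    share65_horizon = last$share65
  )
  banded <- NULL
  if (!is.null(bands)) {
    final_prev <- result$prevalence[result$prevalence$year == last$year, ]
    banded <- band_aggregate(final_prev, result$population, bands)
  }
  list(headline = headline, annual = ann, banded = banded)
}
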