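#' Specification of a synthetic country
#'
#' Parameters for a self-contained synthetic input set with known ground
#' truth: a stylized stable-population age structure, Gompertz death risks
#' improving over time, a logistic-in-age prevalence curve at the first
#' baseline year, a log-linear-in-age incidence surface (with small seeded
#' cell-level noise so the inverse problem is not artificially smooth), and
#' an age-declining relative-mortality curve for the diseased. The baseline
#' prevalence series is generated *forward* from the incidence surface with
#' the same recurrence the package projects with, so back-calculation faces a
#' genuine inverse problem with an exactly known answer.
#'
#' Defaults describe an adult (20-100+) population of 7.5 million whose 2013
#' banded prevalences and overall incidence sit near published Swedish
#' registry values (roughly 1.4/5.2/12.8% for women and 1.6/8.3/18.8% for
#' men in the 20-44/45-64/65+ bands, and total incidence near 4.4 per 1000).
#'
#' @param seed Integer seed; the same seed gives bit-identical outputs.
#' @param n_individuals Number of simulated persons for [microsimulate()].
#' @param baseline_start,base_year,horizon_end Calendar years delimiting the
#'   observed baseline and the projection horizon.
#' @param total_adults Total adult population at `baseline_start`.
#' @param stable_growth Growth rate shaping the initial age pyramid.
#' @param entrant_growth Annual growth of the entrant (age-20) cohort size.
#' @param migration_rate,migration_age_mode,migration_age_sd Net in-migration
#'   as a share of the receiving cohort, with a Gaussian age profile.
#' @param gompertz_intercept,gompertz_slope Named vectors (`female`, `male`)
#'   of log death-risk at age 0 and its slope in age.
#' @param mortality_improvement Annual proportional decline of all-cause
#'   death risks over calendar time.
#' @param prev_max,prev_midpoint,prev_scale Named vectors: logistic
#'   prevalence curve at `baseline_start` (asymptote, midpoint age, width).
#' @param prev_floor Named vector: age-flat young-adult prevalence component
#'   added to the logistic (early-onset disease).
#' @param inc_level Named vector: incidence risk at age 60 by sex.
#' @param inc_slope Log-linear slope of incidence in age (per year of age).
#' @param inc_noise_sd SD of seeded log-normal cell noise on incidence.
#' @param rr_excess0,rr_decay Relative-risk curve `1 + rr_excess0 *
#'   exp(-rr_decay * (age - 20))` at the reference year.
#' @param rr_annual_decline Annual decline of the relative excess mortality
#'   (default 0.016).
#' @param nonpharm_share Share of disease not pharmacologically treated
#'   (default 0.226).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_individuals = 2e5,
                           baseline_start = 2007L,
                           base_year = 2013L,
                           horizon_end = 2050L,
                           total_adults = 7.5e6,
                           stable_growth = 0.004,
                           entrant_growth = 0.003,
                           migration_rate = 0.004,
                           migration_age_mode = 32,
                           migration_age_sd = 12,
                           gompertz_intercept = c(female = -10.9, male = -10.3),
                           gompertz_slope = c(female = 0.092, male = 0.088),
                           mortality_improvement = 0.01,
                           prev_max = c(female = 0.10, male = 0.15),
                           prev_midpoint = c(female = 56, male = 54),
                           prev_scale = c(female = 12, male = 8),
                           prev_floor = c(female = 0.001, male = 0.003),
                           inc_level = c(female = 0.0033, male = 0.005),
                           inc_slope = 0.055,
                           inc_noise_sd = 0.03,
                           rr_excess0 = 3.5,
                           rr_decay = 0.035,
                           rr_annual_decline = 0.016,
                           nonpharm_share = 0.226) {
  spec <- list(seed = as.integer(seed), n_individuals = n_individuals,
               baseline_start = as.integer(baseline_start),
               base_year = as.integer(base_year),
               horizon_end = as.integer(horizon_end),
               total_adults = total_adults, stable_growth = stable_growth,
               entrant_growth = entrant_growth, migration_rate = migration_rate,
               migration_age_mode = migration_age_mode,
               migration_age_sd = migration_age_sd,
               gompertz_intercept = gompertz_intercept,
               gompertz_slope = gompertz_slope,
               mortality_improvement = mortality_improvement,
               prev_max = prev_max, prev_midpoint = prev_midpoint,
               prev_scale = prev_scale, prev_floor = prev_floor,
               inc_level = inc_level,
               inc_slope = inc_slope, inc_noise_sd = inc_noise_sd,
               rr_excess0 = rr_excess0, rr_decay = rr_decay,
               rr_annual_decline = rr_annual_decline,
               nonpharm_share = nonpharm_share)
  stopifnot(spec$baseline_start < spec$base_year,
            spec$base_year < spec$horizon_end)
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic country with known ground truth
#'
#' Builds every input the projection pipeline needs — population frame,
#' mortality schedule, observed baseline prevalence series, the true incidence
#' surface that generated it, and the excess-mortality model — deterministic
#' given the spec's seed. Risks or proportions that leave \[0, 1\] raise a
#' validation error naming the offending cells.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `population` ([population_frame()]),
#'   `mortality` (risk [agesex_table()] covering
#'   `baseline_start..horizon_end`), `prevalence` (proportion `agesex_table`
#'   over the baseline years), `incidence` (tibble `sex`, `age`, `value`: the
#'   true surface, constant over baseline years), `excess_mortality`
#'   ([excess_mortality_model()]), and `spec`.
#' @export
generate_country <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  ages <- .AGES
  years <- spec$baseline_start:spec$horizon_end

  # all-cause death risks, improving over calendar time
  mort_rows <- lapply(years, function(y) {
    f <- (1 - spec$mortality_improvement)^(y - spec$baseline_start)
    m <- sapply(.SEXES, function(s) {
      pmin(exp(spec$gompertz_intercept[s] + spec$gompertz_slope[s] * ages) * f,
           0.7)
    })
    dimnames(m) <- list(ages, .SEXES)
    matrix_ast(m, y)
  })
  mortality <- agesex_table(dplyr::bind_rows(mort_rows), role = "risk")

  # initial age pyramid: survivorship discounted by a stable growth rate
  M0 <- ast_matrix(mortality, spec$baseline_start, what = "mortality")
  shape <- apply(M0, 2, function(m) {
    l <- cumprod(c(1, (1 - m)[-length(m)]))
    l * exp(-spec$stable_growth * (ages - .AGE_MIN))
  })
  N0 <- shape * spec$total_adults / sum(shape)
  dimnames(N0) <- list(ages, .SEXES)

  entrants <- tidyr::expand_grid(year = years[-1], sex = .SEXES)
  entrants$value <- N0[1, entrants$sex] *
    (1 + spec$entrant_growth)^(entrants$year - spec$baseline_start)

  mig_w <- spec$migration_rate *
    exp(-((ages - spec$migration_age_mode) / spec$migration_age_sd)^2)
  migration <- dplyr::bind_rows(lapply(years[-1], function(y) {
    m <- N0 * mig_w
    matrix_ast(m, y)
  }))

  population <- population_frame(matrix_ast(N0, spec$baseline_start),
                                 entrants = entrants, migration = migration)
  population <- project_population(population, mortality, spec$horizon_end)

  # true incidence surface: log-linear in age with seeded cell noise
  noise <- matrix(rnorm(length(ages) * 2, 0, spec$inc_noise_sd),
                  nrow = length(ages), ncol = 2, dimnames = list(ages, .SEXES))
  I <- sapply(.SEXES, function(s) {
    spec$inc_level[s] * exp(spec$inc_slope * (ages - 60))
  })
  dimnames(I) <- list(ages, .SEXES)
  I <- I * exp(noise)
  if (any(I < 0 | I > 1)) {
    bad <- which(I > 1, arr.ind = TRUE)
    stop("validation error: incidence outside [0, 1] at age(s) ",
         paste(ages[bad[, 1]], collapse = ", "), call. = FALSE)
  }
  incidence <- tibble::tibble(sex = rep(.SEXES, each = length(ages)),
                              age = rep(ages, 2),
                              value = c(I[, "female"], I[, "male"]))

  rr0 <- tibble::tibble(
    sex = rep(.SEXES, each = length(ages)),
    age = rep(ages, 2),
    rr = 1 + spec$rr_excess0 * exp(-spec$rr_decay * (rep(ages, 2) - .AGE_MIN))
  )
  em <- excess_mortality_model(rr0, annual_decline = spec$rr_annual_decline,
                               convention = "excess",
                               reference = "vs_nondiabetic",
                               reference_year = spec$base_year)

  # prevalence curve at the first baseline year, then forward via the
  # recurrence so the incidence surface is the exact ground truth
  P0 <- sapply(.SEXES, function(s) {
    spec$prev_floor[s] +
      spec$prev_max[s] * plogis((ages - spec$prev_midpoint[s]) / spec$prev_scale[s])
  })
  dimnames(P0) <- list(ages, .SEXES)
  base0 <- agesex_table(matrix_ast(P0, spec$baseline_start),
                        role = "proportion")
  baseline_spec <- build_scenario("baseline", incidence_trend = 0,
                                  mortality_trend = "declining",
                                  base_year = spec$baseline_start,
                                  horizon_end = spec$base_year)
  run <- project(base0, incidence, em, population, mortality, baseline_spec)
  prevalence <- agesex_table(run$prevalence, role = "proportion")

  list(population = population, mortality = mortality,
       prevalence = prevalence, incidence = incidence,
       excess_mortality = em, spec = spec)
}

#' Overall incidence rate per 1000 disease-free adults
#'
#' Expected new cases during `year` divided by disease-free person-years at
#' risk (approximated by the start-of-year disease-free population), times
#' 1000. Follows cohorts exactly as the recurrence does.
#'
#' @param country A [generate_country()] result.
#' @param year Year to evaluate (default the spec's base year).
#' @return Cases per 1000 disease-free adults.
#' @export
baseline_incidence_rate <- function(country, year = country$spec$base_year) {
  ages <- .AGES
  n <- length(ages)
  P0 <- ast_matrix(country$prevalence, year - 1L, what = "prevalence")
  N <- ast_matrix(country$population$counts, year, what = "population")
  M <- ast_matrix(country$mortality, year, what = "mortality")
  I <- ast_matrix(tibble::tibble(year = year, sex = country$incidence$sex,
                                 age = country$incidence$age,
                                 value = country$incidence$value),
                  year, what = "incidence")
  # previous end-of-year prevalence seen by each cohort (shifted one age)
  p_eff <- rbind(P0[1, , drop = FALSE] * 0, P0[-n, ])
  p_eff[n, ] <- P0[n, ]
  em <- country$excess_mortality
  RR <- rr_matrix(em, year - em$reference_year)
  split <- diabetic_death_risk(M, p_eff, RR, reference = em$reference)
  m1 <- matrix(split$m1, n, 2)
  new_cases <- N * ((1 - M) - (1 - m1) * p_eff) * I
  at_risk <- N * (1 - p_eff)
  1000 * sum(new_cases) / sum(at_risk)
}

#' Write a synthetic country to CSV inputs plus a ground-truth manifest
#'
#' Exports the generated tables in the tidy CSV schema the pipeline reads
#' (`population.csv`, `mortality.csv`, `prevalence.csv`, `entrants.csv`,
#' `migration.csv`, `incidence_truth.csv`, `rr0.csv`) plus
#' `ground_truth.json` recording every generator parameter.
#'
#' @param country A [generate_country()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_country <- function(country, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_agesex_csv(country$population$counts, file.path(dir, "population.csv"))
  readr::write_csv(country$population$entrants, file.path(dir, "entrants.csv"),
                   progress = FALSE)
  readr::write_csv(country$population$migration,
                   file.path(dir, "migration.csv"), progress = FALSE)
  write_agesex_csv(country$mortality, file.path(dir, "mortality.csv"))
  write_agesex_csv(country$prevalence, file.path(dir, "prevalence.csv"))
  readr::write_csv(country$incidence, file.path(dir, "incidence_truth.csv"),
                   progress = FALSE)
  readr::write_csv(country$excess_mortality$rr0, file.path(dir, "rr0.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    c(unclass(country$spec),
      list(rr_convention = country$excess_mortality$convention,
           rr_reference = country$excess_mortality$reference)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA
  )
  invisible(dir)
}

#' Individual-level microsimulation oracle
#'
#' Simulates every person one year at a time with exactly the transition
#' risks the deterministic projection applies (obtained from
#' [project()] with `keep_rates = TRUE` on a closed cohort): a person with
#' the disease dies with probability `m1`, a disease-free person dies with
#' probability `m0`, and disease-free survivors of the year acquire the
#' disease with probability `i` — the same within-year ordering as the
#' recurrence, so the deterministic path is the simulation's expectation.
#'
#' The initial age/sex allocation is deterministic (largest-remainder
#' rounding of the base-year population composition); initial disease status
#' and all yearly events are random, seeded from the spec.
#'
#' @param spec A [synthetic_spec()].
#' @param scenario A [build_scenario()] specification (its `base_year` and
#'   `horizon_end` delimit the simulation).
#' @param n_individuals Number of persons (default from `spec`).
#' @param country Optionally, a pre-generated [generate_country()] result for
#'   the same spec (avoids regenerating).
#' @return A list with `observed` (tibble: `year`, `n_alive`, `n_cases`,
#'   `deaths`, `prevalence` among the living), `expected` (tibble: `year`,
#'   `prevalence`, `se`: the deterministic expectation among end-of-year
#'   survivors and its binomial Monte-Carlo standard error), and
#'   `deterministic` (the closed-cohort [project()] result used for rates).
#' @export
microsimulate <- function(spec, scenario = build_scenario("A",
                                                          base_year = spec$base_year,
                                                          horizon_end = spec$horizon_end),
                          n_individuals = spec$n_individuals,
                          country = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(country)) country <- generate_country(spec)
  ages <- .AGES
  n_age <- length(ages)
  y0 <- scenario$base_year
  yN <- scenario$horizon_end

  # closed cohort: base-year counts only, no entrants or migration
  base_counts <- country$population$counts
  closed <- population_frame(base_counts[base_counts$year == y0, ])
  base_prev <- country$prevalence[country$prevalence$year == y0, ]
  det <- project(agesex_table(base_prev, "proportion"), country$incidence,
                 country$excess_mortality, closed, country$mortality,
                 scenario, keep_rates = TRUE)

  # deterministic largest-remainder allocation of persons to (age, sex)
  N0 <- ast_matrix(closed$counts, y0, what = "population")
  w <- as.vector(N0) / sum(N0)
  target <- w * n_individuals
  alloc <- floor(target)
  rem <- n_individuals - sum(alloc)
  if (rem > 0) {
    extra <- order(target - alloc, decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1
  }
  cell_age <- rep(rep(ages, 2), times = alloc)
  cell_sex <- rep(rep(1:2, each = n_age), times = alloc)

  set.seed(spec$seed + 104729L)  # separate stream from the generator
  P_base <- ast_matrix(det$prevalence, y0, what = "prevalence")
  p_init <- P_base[cbind(match(cell_age, ages), cell_sex)]
  sick <- runif(n_individuals) < p_init
  alive <- rep(TRUE, n_individuals)
  age <- cell_age

  observed <- vector("list", yN - y0 + 1)
  observed[[1]] <- tibble::tibble(year = y0, n_alive = sum(alive),
                                  n_cases = sum(sick), deaths = 0L,
                                  prevalence = mean(sick))
  for (y in (y0 + 1L):yN) {
    r <- det$rates[[y - y0]]
    age[alive] <- pmin(age[alive] + 1L, .AGE_MAX)
    idx <- cbind(match(age, ages), cell_sex)
    risk_die <- ifelse(sick, r$m1[idx], r$m0[idx])
    u <- runif(n_individuals)
    died <- alive & (u < risk_die)
    alive <- alive & !died
    # incidence among the year's disease-free survivors
    free_surv <- alive & !sick
    conv <- free_surv & (runif(n_individuals) < r$i[idx])
    sick <- sick | conv
    observed[[y - y0 + 1]] <- tibble::tibble(
      year = y, n_alive = sum(alive), n_cases = sum(sick & alive),
      deaths = sum(died),
      prevalence = if (any(alive)) sum(sick & alive) / sum(alive) else NA_real_
    )
  }
  observed <- dplyr::bind_rows(observed)

  # deterministic expectation among end-of-year survivors: advance the
  # initial allocation with the same timing as the simulation (the base year
  # is the initial state; the first transition happens the following year)
  expected <- vector("list", yN - y0 + 1)
  W <- N0
  for (y in y0:yN) {
    P <- ast_matrix(det$prevalence, y, what = "prevalence")
    if (y > y0) {
      My <- ast_matrix(country$mortality, y, what = "mortality")
      Wnew <- matrix(0, n_age, 2, dimnames = dimnames(N0))
      Wnew[2:n_age, ] <- W[1:(n_age - 1), ]
      Wnew[n_age, ] <- Wnew[n_age, ] + W[n_age, ]
      W <- Wnew * (1 - My)
    }
    p_exp <- sum(P * W) / sum(W)
    n_exp <- observed$n_alive[observed$year == y]
    expected[[y - y0 + 1]] <- tibble::tibble(
      year = y, prevalence = p_exp,
      se = sqrt(p_exp * (1 - p_exp) / max(n_exp, 1))
    )
  }
  list(observed = observed, expected = dplyr::bind_rows(expected),
       deterministic = det)
}
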