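#' Bundle population counts, entrants and net migration
#'
#' Holds everything the cohort-component bookkeeping needs: start-of-year
#' person counts by single-year age and sex, the number of people reaching
#' the minimum age each year (entrants), and signed net migration counts.
#'
#' @param counts An [agesex_table()] of counts (start-of-year population).
#' @param entrants Optional tibble with columns `year`, `sex`, `value`: the
#'   count of people entering the table at age 20 at the start of `year`.
#'   Defaults to zero.
#' @param migration Optional [agesex_table()]-shaped table of signed counts:
#'   net migrants joining the cohort aged `age` at the start of `year`.
#'   Defaults to zero.
#' @return A list of class `population_frame`.
#' @export
population_frame <- function(counts, entrants = NULL, migration = NULL) {
  counts <- if (inherits(counts, "agesex_table")) counts else
    agesex_table(counts, role = "count")
  if (!is.null(entrants)) {
    entrants <- tibble::as_tibble(entrants)
    stopifnot(all(c("year", "sex", "value") %in% names(entrants)))
    if (any(entrants$value < 0)) stop("entrants must be >= 0", call. = FALSE)
  }
  if (!is.null(migration)) {
    migration <- tibble::as_tibble(migration)
    stopifnot(all(c("year", "sex", "age", "value") %in% names(migration)))
  }
  structure(list(counts = counts, entrants = entrants, migration = migration),
            class = "population_frame")
}

#' @export
print.population_frame <- function(x, ...) {
  cat("<population_frame> years", paste(range(x$counts$year), collapse = "-"),
      "|", nrow(x$counts), "count cells;",
      if (is.null(x$entrants)) "no entrants;" else "entrants;",
      if (is.null(x$migration)) "no migration\n" else "migration\n")
  invisible(x)
}

entrants_for <- function(pop, year) {
  out <- setNames(numeric(2), .SEXES)
  if (!is.null(pop$entrants)) {
    e <- pop$entrants[pop$entrants$year == year, ]
    out[e$sex] <- e$value
  }
  out
}

# migration matrix (age x sex) for people joining cohorts at start of `year`
migration_matrix <- function(pop, year, ages = .AGES) {
  m <- matrix(0, nrow = length(ages), ncol = 2, dimnames = list(ages, .SEXES))
  if (!is.null(pop$migration)) {
    mg <- pop$migration[pop$migration$year == year, ]
    if (nrow(mg) > 0) {
      m[cbind(match(mg$age, ages), match(mg$sex, .SEXES))] <- mg$value
    }
  }
  m
}

#' Advance a population one year
#'
#' Cohort-component step: survivors of age `a` in `year` become age `a + 1`
#' at the start of `year + 1`, plus net migration; survivors of ages 99 and
#' 100 pool into the absorbing 100+ bin; entrants fill age 20. Formally
#' `N(year+1, s, a+1) = N(year, s, a) * (1 - m(year, s, a)) + M(year+1, s, a+1)`.
#'
#' @param pop A [population_frame()] with counts for `year`.
#' @param mort An [agesex_table()] of death risks covering `year`.
#' @param year The year whose counts are advanced.
#' @return The `population_frame` with counts for `year + 1` appended.
#' @export
advance_cohorts <- function(pop, mort, year) {
  year <- as.integer(year)
  if (any(pop$counts$year == year + 1L)) {
    stop("counts for year ", year + 1L, " already present", call. = FALSE)
  }
  ages <- sort(unique(pop$counts$age[pop$counts$year == year]))
  N <- ast_matrix(pop$counts, year, ages = ages, what = "population")
  M <- ast_matrix(mort, year, ages = ages, what = "mortality")
  S <- N * (1 - M)
  nxt <- matrix(0, nrow = length(ages), ncol = 2, dimnames = list(ages, .SEXES))
  n <- length(ages)
  if (n < 2) stop("age axis must span at least two ages", call. = FALSE)
  nxt[2:n, ] <- S[1:(n - 1), ]      # age a -> a+1
  nxt[n, ] <- nxt[n, ] + S[n, ]     # 100+ absorbs its own survivors
  nxt[1, ] <- entrants_for(pop, year + 1L)
  nxt <- nxt + migration_matrix(pop, year + 1L, ages = ages)
  if (any(nxt < 0)) {
    nxt[nxt < 0] <- 0  # net out-migration cannot exceed a cohort
  }
  new_counts <- agesex_table(
    dplyr::bind_rows(tibble::as_tibble(pop$counts), matrix_ast(nxt, year + 1L)),
    role = "count"
  )
  pop$counts <- new_counts
  pop
}

#' Project a population frame over a span of years
#'
#' Repeated [advance_cohorts()] from the last year present in `pop` up to
#' `to_year`.
#'
#' @inheritParams advance_cohorts
#' @param to_year Final year to produce counts for.
#' @return The extended `population_frame`.
#' @export
project_population <- function(pop, mort, to_year) {
  last <- max(pop$counts$year)
  while (last < to_year) {
    pop <- advance_cohorts(pop, mort, last)
    last <- last + 1L
  }
  pop
}
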