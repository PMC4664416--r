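#' One-year forward prevalence step of the illness-death recurrence
#'
#' Advances a birth cohort's end-of-year prevalence by one year. Surviving
#' cases carry over with the diseased death risk `m1`; new cases arise among
#' the year's disease-free survivors with risk `i`; the result is expressed
#' per end-of-year survivor (the total survival chance is `1 - m`):
#' \deqn{p_y = \frac{(1-m_1)\,p_{y-1} + \big((1-m) - (1-m_1)\,p_{y-1}\big)\, i}{1-m}}
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param p_prev Prevalence at the end of the previous year, in \[0, 1\].
#' @param m Death risk during the year in the whole cohort, in \[0, 1).
#' @param m1 Death risk during the year among those with the disease.
#' @param i Cumulative incidence (risk) among the disease-free, in \[0, 1\].
#' @return The end-of-year prevalence, in \[0, 1\].
#' @seealso [backcalc_incidence()] for the exact inverse.
#' @export
forward_prevalence_step <- function(p_prev, m, m1, i) {
  check_unit_interval(p_prev, "p_prev")
  check_unit_interval(m, "m")
  check_unit_interval(m1, "m1")
  check_unit_interval(i, "i")
  if (any(m >= 1)) stop("division error: m = 1 leaves no survivors", call. = FALSE)
  sick_surv <- (1 - m1) * p_prev
  free_surv <- (1 - m) - sick_surv
  if (any(free_surv < -1e-12)) {
    stop("consistency error: surviving cases exceed total survivors ",
         "((1 - m1) * p_prev > 1 - m)", call. = FALSE)
  }
  free_surv <- pmax(free_surv, 0)
  (sick_surv + free_surv * i) / (1 - m)
}

#' Back-calculate incidence from two consecutive prevalences
#'
#' Solves the forward recurrence for the cumulative incidence that must have
#' occurred between two end-of-year prevalence observations of the same
#' cohort, given total and diseased death risks:
#' \deqn{i = \frac{(1-m)\,p_{now} - (1-m_1)\,p_{prev}}{(1-m) - (1-m_1)\,p_{prev}}}
#'
#' A negative result means observed prevalence fell faster than excess
#' mortality can explain; it is returned as-is (a warning is raised) so data
#' inconsistencies stay visible.
#'
#' @param p_now Prevalence at the end of the current year.
#' @param p_prev Prevalence at the end of the previous year.
#' @inheritParams forward_prevalence_step
#' @return The implied incidence risk; may be negative (flagged by warning).
#' @export
backcalc_incidence <- function(p_now, p_prev, m, m1) {
  check_unit_interval(p_now, "p_now")
  check_unit_interval(p_prev, "p_prev")
  check_unit_interval(m, "m")
  check_unit_interval(m1, "m1")
  denom <- (1 - m) - (1 - m1) * p_prev
  if (any(denom <= 0)) {
    stop("degenerate cohort: (1 - m) - (1 - m1) * p_prev must be > 0",
         call. = FALSE)
  }
  i <- ((1 - m) * p_now - (1 - m1) * p_prev) / denom
  if (any(i < 0)) {
    warning("negative back-calculated incidence in ", sum(i < 0), " cell(s)",
            call. = FALSE)
  }
  i
}

#' Split a total death risk into diseased and disease-free risks
#'
#' Given the total-population death risk `m`, the prevalence `p` at the start
#' of the risk interval, and a relative mortality risk `rr`, derives the death
#' risks `m1` (with disease) and `m0` (without). Under
#' `reference = "vs_nondiabetic"` the pair solves the mixture identity
#' `p * m1 + (1 - p) * m0 = m` exactly with `m1 = rr * m0`; under
#' `"vs_total"`, `m1 = rr * m` directly and `m0` absorbs the remainder.
#'
#' @param m Total death risk, in \[0, 1).
#' @param p Disease prevalence among those at risk, in \[0, 1\].
#' @param rr Relative mortality risk, `>= 1`.
#' @param reference `"vs_nondiabetic"` (ratio to the disease-free) or
#'   `"vs_total"` (ratio to the whole population).
#' @return A list with vectors `m1` and `m0`, both clamped to \[0, 1\].
#' @export
diabetic_death_risk <- function(m, p, rr,
                                reference = c("vs_nondiabetic", "vs_total")) {
  reference <- match.arg(reference)
  check_unit_interval(m, "m")
  check_unit_interval(p, "p")
  if (any(rr < 1)) stop("rr must be >= 1", call. = FALSE)
  if (reference == "vs_nondiabetic") {
    m0 <- m / (1 - p + rr * p)
    m1 <- rr * m0
  } else {
    m1 <- pmin(rr * m, 1)
    m0 <- ifelse(p < 1, (m - p * m1) / (1 - p), 0)
    if (any(m0 < -1e-12)) {
      stop("consistency error: vs_total split implies negative disease-free ",
           "death risk", call. = FALSE)
    }
    m0 <- pmax(m0, 0)
  }
  list(m1 = pmin(pmax(m1, 0), 1), m0 = pmin(pmax(m0, 0), 1))
}

#' Excess-mortality model for the diseased population
#'
#' Baseline relative mortality risk by sex and age at a reference year, plus
#' an annual improvement trend. Two trend conventions are supported because
#' published phrasing is often ambiguous: `"excess"` shrinks the excess
#' `rr - 1` by `annual_decline` per year (never crossing `rr = 1`), while
#' `"ratio"` shrinks `rr` itself (floored at 1).
#'
#' @param rr0 Baseline relative risk: either a single number or a tibble with
#'   columns `sex`, `age`, `rr` (all `>= 1`).
#' @param annual_decline Annual proportional decline of the excess (default
#'   0.016, i.e. 1.6% per year).
#' @param convention `"excess"` or `"ratio"` (see Details).
#' @param reference `"vs_nondiabetic"` or `"vs_total"`: which population the
#'   relative risk compares against (passed to [diabetic_death_risk()]).
#' @param reference_year Calendar year `rr0` refers to.
#' @return A list of class `excess_mortality_model`.
#' @export
excess_mortality_model <- function(rr0, annual_decline = 0.016,
                                   convention = c("excess", "ratio"),
                                   reference = c("vs_nondiabetic", "vs_total"),
                                   reference_year = 2013L) {
  convention <- match.arg(convention)
  reference <- match.arg(reference)
  if (annual_decline < 0 || annual_decline >= 1) {
    stop("annual_decline must be in [0, 1)", call. = FALSE)
  }
  if (is.data.frame(rr0)) {
    stopifnot(all(c("sex", "age", "rr") %in% names(rr0)))
    if (any(rr0$rr < 1)) stop("rr0 must be >= 1 everywhere", call. = FALSE)
    rr0 <- tibble::as_tibble(rr0)
  } else {
    if (any(rr0 < 1)) stop("rr0 must be >= 1", call. = FALSE)
  }
  structure(
    list(rr0 = rr0, annual_decline = annual_decline, convention = convention,
         reference = reference, reference_year = as.integer(reference_year)),
    class = "excess_mortality_model"
  )
}

#' @export
print.excess_mortality_model <- function(x, ...) {
  cat("<excess_mortality_model>", x$convention, "convention,",
      sprintf("%.1f%%/yr decline,", 100 * x$annual_decline),
      x$reference, "reference, anchored at", x$reference_year, "\n")
  invisible(x)
}

#' Relative mortality risk after a number of elapsed years
#'
#' Applies the model's annual decline for `years_elapsed` years (negative
#' values rewind before the reference year). Under the `"excess"` convention
#' `rr(t) = 1 + (rr0 - 1)(1 - d)^t`; under `"ratio"`,
#' `rr(t) = max(rr0 (1 - d)^t, 1)`. Never below 1.
#'
#' @param model An [excess_mortality_model()].
#' @param years_elapsed Integer years since the reference year.
#' @return Same shape as `model$rr0`: a number, or a tibble with `rr` updated.
#' @export
rr_at_year <- function(model, years_elapsed) {
  f <- (1 - model$annual_decline)^years_elapsed
  decay <- function(rr) {
    if (model$convention == "excess") 1 + (rr - 1) * f else pmax(rr * f, 1)
  }
  if (is.data.frame(model$rr0)) {
    out <- model$rr0
    out$rr <- decay(out$rr)
    out
  } else {
    decay(model$rr0)
  }
}

# rr curve as an age x sex matrix at trend time t
rr_matrix <- function(model, t, ages = .AGES) {
  rr <- rr_at_year(model, t)
  if (is.data.frame(rr)) {
    ast_matrix(tibble::tibble(year = 0L, sex = rr$sex, age = rr$age,
                              value = rr$rr),
               year = 0L, ages = ages, what = "rr0 curve")
  } else {
    matrix(rr, nrow = length(ages), ncol = 2, dimnames = list(ages, .SEXES))
  }
}

#' Share of disease not captured by the ascertainment source
#'
#' @param nonpharm_share Proportion of all disease that is not
#'   pharmacologically treated and therefore missed by a prescription-based
#'   count (default 0.226).
#' @return A list of class `treatment_share`.
#' @export
treatment_share <- function(nonpharm_share = 0.226) {
  if (nonpharm_share < 0 || nonpharm_share >= 1) {
    stop("nonpharm_share must be in [0, 1)", call. = FALSE)
  }
  structure(list(nonpharm_share = nonpharm_share), class = "treatment_share")
}

#' Count amplification factor for under-ascertained disease
#'
#' The multiplier `1 / (1 - s)` that scales a pharmacologically treated count
#' up to all disease when a share `s` of cases is not pharmacologically
#' treated.
#'
#' @param share A [treatment_share()] or a bare proportion in \[0, 1).
#' @return The amplification factor, `>= 1`.
#' @export
amplification_factor <- function(share) {
  s <- if (inherits(share, "treatment_share")) share$nonpharm_share else share
  if (any(s < 0) || any(s >= 1)) stop("share must be in [0, 1)", call. = FALSE)
  1 / (1 - s)
}

#' Adjust diagnosed prevalence for undiagnosed disease
#'
#' @param prevalence Diagnosed prevalence proportion(s).
#' @param undiag_share Undiagnosed share, in \[0, 1).
#' @param convention `"of_total"` if the share is of all (diagnosed plus
#'   undiagnosed) disease, so `p / (1 - u)`; `"of_diagnosed"` if it is
#'   expressed relative to diagnosed disease, so `p * (1 + u)`.
#' @return Adjusted prevalence with attribute `convention`.
#' @export
apply_undiagnosed <- function(prevalence, undiag_share,
                              convention = c("of_total", "of_diagnosed")) {
  convention <- match.arg(convention)
  if (undiag_share < 0 || undiag_share >= 1) {
    stop("undiag_share must be in [0, 1)", call. = FALSE)
  }
  out <- if (convention == "of_total") prevalence / (1 - undiag_share)
         else prevalence * (1 + undiag_share)
  attr(out, "convention") <- convention
  out
}

check_unit_interval <- function(x, name) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(name, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

#' Back-calculate an incidence surface from an observed prevalence series
#'
#' Follows every birth cohort through consecutive observed years (age `a` at
#' year `y - 1` becomes age `a + 1` at year `y`) and applies
#' [backcalc_incidence()] with the cohort's total death risk and the
#' excess-mortality model evaluated at that year. Cells at the entry age
#' (no previous-year link) and in the absorbing 100+ bin (cohorts merge, so
#' the link is not invertible) are skipped.
#'
#' @param prev An [agesex_table()] of observed prevalence proportions covering
#'   two or more consecutive years.
#' @param mort An [agesex_table()] of total-population death risks covering
#'   all but the first observed year.
#' @param em An [excess_mortality_model()].
#' @return A tibble with columns `year`, `sex`, `age`, `value` (the implied
#'   incidence risk for that cohort-year) and `negative` (flag for cells where
#'   observed prevalence fell faster than mortality explains). Attribute
#'   `skipped` counts cohort links that could not be formed.
#' @export
estimate_baseline <- function(prev, mort, em) {
  years <- sort(unique(prev$year))
  if (length(years) < 2) stop("need at least two observed years", call. = FALSE)
  if (any(diff(years) != 1L)) {
    stop("gap in observed years: ", paste(years, collapse = ", "), call. = FALSE)
  }
  ages_prev <- sort(unique(prev$age))
  lo <- min(ages_prev)
  out <- vector("list", length(years) - 1)
  skipped <- 0L
  for (k in 2:length(years)) {
    y <- years[k]
    P0 <- ast_matrix(prev, y - 1L, ages = ages_prev, what = "prevalence")
    P1 <- ast_matrix(prev, y, ages = ages_prev, what = "prevalence")
    M <- ast_matrix(mort, y, ages = ages_prev, what = "mortality")
    RR <- rr_matrix(em, y - em$reference_year, ages = ages_prev)
    # cohort aged a at y-1 is aged a+1 at y; target ages lo+1 .. 99
    a_to <- (lo + 1L):(.AGE_MAX - 1L)
    a_from <- a_to - 1L
    i_to <- match(a_to, ages_prev)
    i_from <- match(a_from, ages_prev)
    p_prev <- P0[cbind(rep(i_from, 2), rep(1:2, each = length(a_to)))]
    p_now <- P1[cbind(rep(i_to, 2), rep(1:2, each = length(a_to)))]
    m <- M[cbind(rep(i_to, 2), rep(1:2, each = length(a_to)))]
    rr <- RR[cbind(rep(i_to, 2), rep(1:2, each = length(a_to)))]
    split <- diabetic_death_risk(m, p_prev, rr, reference = em$reference)
    i_hat <- suppressWarnings(
      backcalc_incidence(p_now, p_prev, m, split$m1)
    )
    skipped <- skipped + 4L  # entry-age and 100+ cells per sex per year
    out[[k - 1]] <- tibble::tibble(
      year = y,
      sex = rep(.SEXES, each = length(a_to)),
      age = rep(a_to, 2),
      value = i_hat,
      negative = i_hat < 0
    )
  }
  res <- dplyr::arrange(dplyr::bind_rows(out), .data$year, .data$sex, .data$age)
  attr(res, "skipped") <- skipped
  res
}

#' Fill boundary ages of an incidence surface
#'
#' Back-calculation cannot identify incidence at the entry age or in the
#' absorbing top bin; this copies the nearest identified age's value outward
#' so the surface covers a full age axis and can drive a projection.
#'
#' @param inc A tibble with columns `sex`, `age`, `value` (and optionally
#'   `year`, which is preserved).
#' @param ages Full age axis to cover (default 20..100).
#' @return The completed surface, sorted.
#' @export
extend_incidence <- function(inc, ages = .AGES) {
  inc <- tibble::as_tibble(inc)
  has_year <- "year" %in% names(inc)
  grp <- if (has_year) c("year", "sex") else "sex"
  filled <- dplyr::group_modify(
    dplyr::group_by(inc, dplyr::across(dplyr::all_of(grp))),
    function(df, key) {
      lo_missing <- ages[ages < min(df$age)]
      hi_missing <- ages[ages > max(df$age)]
      dplyr::bind_rows(
        tibble::tibble(age = lo_missing,
                       value = df$value[which.min(df$age)]),
        df[c("age", "value")],
        tibble::tibble(age = hi_missing,
                       value = df$value[which.max(df$age)])
      )
    }
  )
  dplyr::arrange(dplyr::ungroup(filled), dplyr::across(dplyr::all_of(grp)),
                 .data$age)
}
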