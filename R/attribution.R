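#' Decompose a projected case increase into demographic and survival drivers
#'
#' Attributes the change in final-year case counts (relative to the base
#' year) to three substitutable drivers by sequential counterfactual
#' substitution: rescaling the final-year population total back to the
#' base-year total (*population size*), replacing the final-year age/sex
#' composition by the base-year composition (*age structure*), and freezing
#' the relative-mortality trend at its base-year value (*relative survival*).
#' Whatever remains — chiefly falling general-population mortality carried
#' through the recurrence — is reported as a residual, so the components add
#' up to the total increase exactly.
#'
#' Because the drivers interact, the sequential components depend on the
#' substitution order; the order used is recorded in the result, and
#' `mode = "shapley"` averages each driver's marginal contribution over all
#' six orders instead.
#'
#' @inheritParams project
#' @param order Character permutation of
#'   `c("population_size", "age_structure", "relative_survival")`.
#' @param mode `"sequential"` (default) or `"shapley"`.
#' @return A list of class `attribution_result` with `total_increase` (count
#'   and % of base), a `components` tibble (count and share of the total for
#'   each driver plus the residual), the `order`/`mode` used, and the base and
#'   final case counts.
#' @export
decompose_increase <- function(base, inc0, em, pop, mort, spec,
                               order = c("population_size", "age_structure",
                                         "relative_survival"),
                               mode = c("sequential", "shapley"),
                               migrant_prevalence = "match") {
  mode <- match.arg(mode)
  drivers <- c("population_size", "age_structure", "relative_survival")
  if (!setequal(order, drivers)) {
    stop("order must be a permutation of ", paste(drivers, collapse = ", "),
         call. = FALSE)
  }

  run_full <- project(base, inc0, em, pop, mort, spec,
                      migrant_prevalence = migrant_prevalence)
  spec_frozen <- spec
  spec_frozen$mortality_trend <- "constant"
  run_frozen <- project(base, inc0, em, pop, mort, spec_frozen,
                        migrant_prevalence = migrant_prevalence)

  y0 <- spec$base_year
  yN <- spec$horizon_end
  ages <- seq.int(min(base$age[base$year == y0]), 100L)
  pop_used <- run_full$population
  N_base <- ast_matrix(pop_used$counts, y0, ages = ages, what = "population")
  N_final <- ast_matrix(pop_used$counts, yN, ages = ages, what = "population")
  P_base <- ast_matrix(base, y0, ages = ages, what = "base prevalence")
  P_full <- ast_matrix(run_full$prevalence, yN, ages = ages,
                       what = "prevalence")
  P_frozen <- ast_matrix(run_frozen$prevalence, yN, ages = ages,
                         what = "prevalence")

  T_base <- sum(N_base); T_final <- sum(N_final)
  shares_base <- N_base / T_base
  shares_final <- N_final / T_final

  # final-year case count under a subset of substitutions applied
  cases_under <- function(subs) {
    P <- if ("relative_survival" %in% subs) P_frozen else P_full
    shares <- if ("age_structure" %in% subs) shares_base else shares_final
    total <- if ("population_size" %in% subs) T_base else T_final
    sum(P * shares * total)
  }

  cases_base <- sum(P_base * N_base)
  cases_full <- cases_under(character(0))
  total_increase <- cases_full - cases_base

  marginal_along <- function(ord) {
    comp <- numeric(3); names(comp) <- ord
    applied <- character(0)
    prev_val <- cases_full
    for (d in ord) {
      applied <- c(applied, d)
      val <- cases_under(applied)
      comp[d] <- prev_val - val
      prev_val <- val
    }
    comp[drivers]
  }

  if (mode == "sequential") {
    comp <- marginal_along(order)
  } else {
    perms <- list(
      drivers, drivers[c(1, 3, 2)], drivers[c(2, 1, 3)],
      drivers[c(2, 3, 1)], drivers[c(3, 1, 2)], drivers[c(3, 2, 1)]
    )
    comp <- Reduce(`+`, lapply(perms, marginal_along)) / length(perms)
  }
  residual <- total_increase - sum(comp)

  counts <- unname(c(comp[drivers], residual))
  components <- tibble::tibble(
    component = c(drivers, "residual_general_mortality"),
    count = counts,
    share = if (total_increase != 0) counts / total_increase
            else rep(NA_real_, 4)
  )
  structure(
    list(total_increase = total_increase,
         total_increase_pct = if (cases_base > 0)
           100 * total_increase / cases_base else NA_real_,
         components = components,
         order = order, mode = mode,
         cases_base = cases_base, cases_final = cases_full),
    class = "attribution_result"
  )
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("<attribution_result> cases %.0f -> %.0f (%+.0f, %+.0f%% of base), mode %s\n",
              x$cases_base, x$cases_final, x$total_increase,
              x$total_increase_pct, x$mode))
  print(x$components)
  invisible(x)
}

#' Annual incidence decline required to keep prevalence flat
#'
#' Finds, by bisection, the constant annual incidence decline `delta` such
#' that the projected total adult prevalence (both sexes combined) at the
#' horizon equals its base-year value. Projected horizon prevalence is
#' monotone decreasing in `delta`, which makes the bracket valid.
#'
#' @inheritParams project
#' @param bracket Search interval for the annual decline (default
#'   `c(0, 0.2)`).
#' @param tol Convergence tolerance on the prevalence gap, absolute on the
#'   proportion scale (default `1e-6`).
#' @param max_iter Bisection iteration cap.
#' @return A list with `delta` (the annual decline; 0 if prevalence does not
#'   rise without intervention), `prevalence_base`, `prevalence_horizon` (at
#'   the solution), and `trace` (a tibble of bisection iterates).
#' @export
required_incidence_decline <- function(base, inc0, em, pop, mort, spec,
                                       bracket = c(0, 0.2), tol = 1e-6,
                                       max_iter = 100L,
                                       migrant_prevalence = "match") {
  horizon_prev <- function(delta) {
    s <- spec
    s$incidence_trend <- -delta
    run <- project(base, inc0, em, pop, mort, s,
                   migrant_prevalence = migrant_prevalence)
    run$annual$prevalence_total[nrow(run$annual)]
  }
  target <- {
    run0 <- project(base, inc0, em, pop, mort, spec,
                    migrant_prevalence = migrant_prevalence)
    run0$annual$prevalence_total[1]
  }
  gap <- function(delta) horizon_prev(delta) - target

  lo <- bracket[1]; hi <- bracket[2]
  g_lo <- gap(lo)
  if (g_lo <= tol) {
    return(list(delta = 0, prevalence_base = target,
                prevalence_horizon = g_lo + target,
                trace = tibble::tibble(iter = 0L, lo = lo, hi = hi,
                                       mid = lo, gap = g_lo)))
  }
  g_hi <- gap(hi)
  if (g_hi > tol) {
    stop("bracket error: horizon prevalence still above base at delta = ", hi,
         " (gap ", signif(g_hi, 4), "); widen the bracket", call. = FALSE)
  }
  trace <- vector("list", max_iter)
  mid <- NA_real_; g_mid <- NA_real_
  for (k in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    g_mid <- gap(mid)
    trace[[k]] <- tibble::tibble(iter = k, lo = lo, hi = hi, mid = mid,
                                 gap = g_mid)
    if (abs(g_mid) <= tol) break
    if (g_mid > 0) lo <- mid else hi <- mid
  }
  list(delta = mid, prevalence_base = target,
       prevalence_horizon = g_mid + target,
       trace = dplyr::bind_rows(trace))
}
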