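#' Read a pipeline run configuration
#'
#' @param path Path to a YAML file; see [run_pipeline()] for the recognised
#'   fields.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = c("run_config", "list"))
}

default_config <- function() {
  list(
    inputs = list(population = NULL, mortality = NULL, prevalence = NULL,
                  entrants = NULL, migration = NULL),
    scenarios = list("A"),
    base_year = 2013L,
    horizon_end = 2050L,
    excess_mortality = list(rr0 = 2.0, annual_decline = 0.016,
                            convention = "excess",
                            reference = "vs_nondiabetic"),
    amplification = list(enabled = FALSE, nonpharm_share = 0.226),
    undiagnosed = list(enabled = FALSE, share = 0.366,
                       convention = "of_total"),
    decompose = list(enabled = FALSE,
                     order = c("population_size", "age_structure",
                               "relative_survival"),
                     mode = "sequential"),
    solve_decline = list(enabled = FALSE, bracket = c(0, 0.2), tol = 1e-6),
    migrant_prevalence = "match",
    bands = c("20-44", "45-64", "65+"),
    output_dir = "results",
    seed = 1L,
    log_level = "INFO"
  )
}

pipe_log <- function(level, cfg, ...) {
  levels <- c(DEBUG = 1, INFO = 2, WARN = 3, ERROR = 4)
  if (levels[level] >= levels[cfg$log_level %||% "INFO"]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full back-calculate / project / decompose / solve pipeline
#'
#' Executes the end-to-end analysis: read and validate the input tables,
#' optionally amplify the ascertained prevalence for untreated cases,
#' back-calculate baseline incidence, project each requested scenario,
#' optionally decompose the first scenario's case increase and solve for the
#' incidence decline that keeps prevalence flat, and write every stage's
#' output (tidy CSVs, a scenario headline table, and a JSON manifest
#' recording parameters, convention flags and warnings).
#'
#' @param config A list or [read_run_config()] result. Recognised fields (all
#'   optional except `inputs`): `inputs` (paths: `population`, `mortality`,
#'   `prevalence` CSVs, optional `entrants`, `migration`), `scenarios`
#'   (character vector or list of custom scenario lists), `base_year`,
#'   `horizon_end`, `excess_mortality` (`rr0` scalar or path to a
#'   `sex,age,rr` CSV; `annual_decline`; `convention`; `reference`),
#'   `amplification` (`enabled`, `nonpharm_share`), `undiagnosed` (`enabled`,
#'   `share`, `convention`), `decompose` (`enabled`, `order`, `mode`),
#'   `solve_decline` (`enabled`, `bracket`, `tol`), `migrant_prevalence`,
#'   `bands`, `output_dir`, `seed`, `log_level`.
#' @return Invisibly, a list with `status` (0 on success), `manifest` (also
#'   written to `manifest.json`), and the per-stage objects.
#' @export
run_pipeline <- function(config) {
  cfg <- modifyList(default_config(), unclass(config))
  warnings_log <- character(0)

  # --- stage 0: validation -------------------------------------------------
  for (nm in c("population", "mortality", "prevalence")) {
    p <- cfg$inputs[[nm]]
    if (is.null(p)) stop("config error: inputs$", nm, " is required", call. = FALSE)
    if (!file.exists(p)) stop("validation failure: ", nm, " file not found: ",
                              p, call. = FALSE)
  }
  pipe_log("INFO", cfg, "reading inputs")
  counts <- read_agesex_csv(cfg$inputs$population, "count")
  mort <- read_agesex_csv(cfg$inputs$mortality, "risk")
  prev <- read_agesex_csv(cfg$inputs$prevalence, "proportion")
  entrants <- if (!is.null(cfg$inputs$entrants))
    readr::read_csv(cfg$inputs$entrants, show_col_types = FALSE) else NULL
  migration <- if (!is.null(cfg$inputs$migration))
    readr::read_csv(cfg$inputs$migration, show_col_types = FALSE) else NULL
  pop <- population_frame(counts, entrants = entrants, migration = migration)

  emc <- cfg$excess_mortality
  rr0 <- emc$rr0
  if (is.character(rr0)) rr0 <- readr::read_csv(rr0, show_col_types = FALSE)
  em <- excess_mortality_model(rr0, annual_decline = emc$annual_decline,
                               convention = emc$convention,
                               reference = emc$reference,
                               reference_year = cfg$base_year)

  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$output_dir, f)
  artifacts <- character(0)

  # --- stage 1: amplification ----------------------------------------------
  if (isTRUE(cfg$amplification$enabled)) {
    fac <- amplification_factor(cfg$amplification$nonpharm_share)
    pipe_log("INFO", cfg, sprintf("amplifying prevalence by %.3f", fac))
    prev$value <- pmin(prev$value * fac, 1)
  }

  # --- stage 2: incidence back-calculation ---------------------------------
  pipe_log("INFO", cfg, "back-calculating baseline incidence")
  inc <- estimate_baseline(prev, mort, em)
  n_neg <- sum(inc$negative)
  if (n_neg > 0) {
    warnings_log <- c(warnings_log,
                      sprintf("%d negative back-calculated incidence cells", n_neg))
    pipe_log("WARN", cfg, warnings_log[length(warnings_log)])
  }
  write_agesex_csv(inc, out("baseline_incidence.csv"))
  artifacts <- c(artifacts, "baseline_incidence.csv")

  # projections use the latest baseline year's surface, clamped at 0 and
  # extended to the full age axis
  inc_base <- inc[inc$year == max(inc$year), c("sex", "age", "value")]
  inc_base$value <- pmax(inc_base$value, 0)
  inc0 <- extend_incidence(inc_base)

  # --- stage 3: scenario projections ---------------------------------------
  base_state <- prev[prev$year == cfg$base_year, ]
  if (nrow(base_state) == 0) {
    stop("validation failure: prevalence has no rows for base year ",
         cfg$base_year, call. = FALSE)
  }
  base_state <- agesex_table(base_state, "proportion")
  headlines <- list()
  runs <- list()
  for (sc in cfg$scenarios) {
    spec <- if (is.character(sc)) {
      build_scenario(sc, base_year = cfg$base_year,
                     horizon_end = cfg$horizon_end)
    } else {
      build_scenario(sc$name %||% "custom",
                     incidence_trend = sc$incidence_trend,
                     mortality_trend = sc$mortality_trend,
                     base_year = cfg$base_year, horizon_end = cfg$horizon_end)
    }
    pipe_log("INFO", cfg, "projecting scenario ", spec$name)
    run <- project(base_state, inc0, em, pop, mort, spec,
                   migrant_prevalence = cfg$migrant_prevalence)
    smry <- summarize_projection(run, bands = cfg$bands)
    f_annual <- paste0("annual_", spec$name, ".csv")
    readr::write_csv(smry$annual, out(f_annual), progress = FALSE)
    artifacts <- c(artifacts, f_annual)
    headlines[[spec$name]] <- smry$headline
    runs[[spec$name]] <- run
  }
  headline <- dplyr::bind_rows(headlines)
  if (isTRUE(cfg$undiagnosed$enabled)) {
    headline$prevalence_total_incl_undiagnosed <- as.numeric(
      apply_undiagnosed(headline$prevalence_total, cfg$undiagnosed$share,
                        cfg$undiagnosed$convention))
  }
  readr::write_csv(headline, out("headline.csv"), progress = FALSE)
  artifacts <- c(artifacts, "headline.csv")

  # --- stage 4: optional decomposition and solver --------------------------
  decomposition <- NULL
  if (isTRUE(cfg$decompose$enabled)) {
    first_spec <- runs[[1]]$spec
    pipe_log("INFO", cfg, "decomposing case increase (scenario ",
             first_spec$name, ")")
    decomposition <- decompose_increase(base_state, inc0, em, pop, mort,
                                        first_spec,
                                        order = cfg$decompose$order,
                                        mode = cfg$decompose$mode,
                                        migrant_prevalence = cfg$migrant_prevalence)
    readr::write_csv(decomposition$components, out("decomposition.csv"),
                     progress = FALSE)
    artifacts <- c(artifacts, "decomposition.csv")
  }
  solution <- NULL
  if (isTRUE(cfg$solve_decline$enabled)) {
    first_spec <- runs[[1]]$spec
    pipe_log("INFO", cfg, "solving for the flat-prevalence incidence decline")
    solution <- required_incidence_decline(base_state, inc0, em, pop, mort,
                                           first_spec,
                                           bracket = as.numeric(cfg$solve_decline$bracket),
                                           tol = cfg$solve_decline$tol,
                                           migrant_prevalence = cfg$migrant_prevalence)
    readr::write_csv(solution$trace, out("decline_trace.csv"), progress = FALSE)
    artifacts <- c(artifacts, "decline_trace.csv")
  }

  manifest <- list(
    package = "prevcast",
    seed = cfg$seed,
    base_year = cfg$base_year,
    horizon_end = cfg$horizon_end,
    conventions = list(
      rr_convention = em$convention,
      rr_reference = em$reference,
      rr_annual_decline = em$annual_decline,
      migrant_prevalence = cfg$migrant_prevalence,
      amplification = cfg$amplification,
      undiagnosed = cfg$undiagnosed,
      decomposition_order = cfg$decompose$order,
      decomposition_mode = cfg$decompose$mode
    ),
    scenarios = names(runs),
    artifacts = artifacts,
    warnings = warnings_log,
    solution_delta = if (!is.null(solution)) solution$delta else NULL
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  pipe_log("INFO", cfg, "wrote ", length(artifacts), " artifacts to ",
           cfg$output_dir)
  invisible(list(status = 0L, manifest = manifest, headline = headline,
                 incidence = inc, runs = runs, decomposition = decomposition,
                 solution = solution))
}

#' Render projection report figures
#'
#' Plots the annual prevalence and case-count series of one or more
#' projections (the shapes of the usual prevalence-vs-year and
#' counts-vs-year report figures). Requires ggplot2.
#'
#' @param annual A tibble binding one or more `annual` series from
#'   [summarize_projection()], with an added `scenario` column, or a single
#'   [project()] result.
#' @param path Optional file to save the figure to (PDF recommended).
#' @return The ggplot object, invisibly.
#' @export
report_figures <- function(annual, path = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for report figures", call. = FALSE)
  }
  if (inherits(annual, "projection_result")) {
    ann <- annual$annual
    ann$scenario <- annual$spec$name
  } else {
    ann <- annual
    if (!"scenario" %in% names(ann)) ann$scenario <- "run"
  }
  long <- tidyr::pivot_longer(
    ann[c("year", "scenario", "prevalence_total", "prevalence_female",
          "prevalence_male")],
    dplyr::starts_with("prevalence"), names_to = "series",
    names_prefix = "prevalence_", values_to = "prevalence"
  )
  g <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$year, y = 100 * .data$prevalence,
                                    colour = .data$scenario,
                                    linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "year", y = "prevalence (%)", colour = "scenario",
                  linetype = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(path)) ggplot2::ggsave(path, g, width = 7, height = 4.5)
  invisible(g)
}
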