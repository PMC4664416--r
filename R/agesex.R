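#' Construct a validated year/sex/age value table
#'
#' The universal currency of the pipeline: one `value` per
#' (`year`, `sex`, `age`) key. The `role` declares what the value is and
#' drives range checks: counts must be non-negative, proportions and risks
#' must lie in \[0, 1\].
#'
#' @param x A data frame with columns `year`, `sex`, `age`, `value`.
#' @param role One of `"count"`, `"proportion"`, `"risk"`.
#' @return A tibble of class `agesex_table` with attribute `role`.
#' @details Invariants enforced: unique keys; `sex` in `"female"`/`"male"`;
#'   integer ages in \[20, 100\] (100 means "100 and above"); for every
#'   (`year`, `sex`) present, the age axis is contiguous from its minimum age
#'   up to 100.
#' @export
agesex_table <- function(x, role = c("count", "proportion", "risk")) {
  role <- match.arg(role)
  required <- c("year", "sex", "age", "value")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("format error: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- tibble::as_tibble(x)[required]
  x$year <- as.integer(x$year)
  x$age <- as.integer(x$age)
  x$sex <- as.character(x$sex)
  x$value <- as.double(x$value)

  bad_sex <- !x$sex %in% .SEXES
  if (any(bad_sex)) {
    stop("validation error: sex must be 'female' or 'male'; first offending row: ",
         which(bad_sex)[1], call. = FALSE)
  }
  bad_age <- is.na(x$age) | x$age < .AGE_MIN | x$age > .AGE_MAX
  if (any(bad_age)) {
    stop("validation error: age must be an integer in [", .AGE_MIN, ", ",
         .AGE_MAX, "]; first offending row: ", which(bad_age)[1], call. = FALSE)
  }
  if (anyNA(x$value)) {
    stop("validation error: value contains NA; first offending row: ",
         which(is.na(x$value))[1], call. = FALSE)
  }
  bad_val <- if (role == "count") x$value < 0 else x$value < 0 | x$value > 1
  if (any(bad_val)) {
    i <- which(bad_val)[1]
    stop("validation error: value ", x$value[i], " out of range for role '",
         role, "' at (year=", x$year[i], ", sex=", x$sex[i], ", age=",
         x$age[i], ")", call. = FALSE)
  }
  key <- paste(x$year, x$sex, x$age)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop("validation error: duplicated key (year=", x$year[i], ", sex=",
         x$sex[i], ", age=", x$age[i], ")", call. = FALSE)
  }
  # Contiguity of the age axis per (year, sex)
  chk <- dplyr::summarise(
    dplyr::group_by(x, .data$year, .data$sex),
    ok = all(sort(.data$age) == seq.int(min(.data$age), .AGE_MAX)),
    .groups = "drop"
  )
  if (!all(chk$ok)) {
    bad <- chk[!chk$ok, ][1, ]
    stop("validation error: age axis not contiguous up to ", .AGE_MAX,
         " for (year=", bad$year, ", sex=", bad$sex, ")", call. = FALSE)
  }
  x <- dplyr::arrange(x, .data$year, .data$sex, .data$age)
  structure(x, class = c("agesex_table", class(x)), role = role)
}

#' Read a tidy year/sex/age CSV
#'
#' @param path Path to a comma-separated UTF-8 file with a header row and
#'   columns `year,sex,age,value`.
#' @inheritParams agesex_table
#' @return An [agesex_table()].
#' @export
read_agesex_csv <- function(path, role = c("count", "proportion", "risk")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  agesex_table(x, role = role)
}

#' Write a year/sex/age table to CSV
#'
#' @param x A data frame with columns `year,sex,age,value` (extra columns are
#'   kept).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_agesex_csv <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' @export
print.agesex_table <- function(x, ...) {
  cat("<agesex_table> role =", attr(x, "role"), "|", nrow(x), "cells, years",
      paste(range(x$year), collapse = "-"), "\n")
  NextMethod()
}

#' Population-weighted aggregation of proportions into age bands
#'
#' Collapses a single-year-of-age proportion table into age bands (e.g.
#' 20-44, 45-64, 65+) using population counts as weights, the layout in which
#' registry prevalence is usually reported.
#'
#' @param table An [agesex_table()] of proportions.
#' @param pop A [population_frame()] (or a count `agesex_table`) covering the
#'   same (year, sex, age) keys.
#' @param bands Character vector of band labels such as
#'   `c("20-44", "45-64", "65+")`; bands are closed on both ends, the last
#'   band may be open above (`"65+"`).
#' @return A tibble with columns `year`, `sex`, `age_band`, `value`, where
#'   `value` is the population-weighted mean proportion in the band.
#' @export
band_aggregate <- function(table, pop, bands = c("20-44", "45-64", "65+")) {
  counts <- if (inherits(pop, "population_frame")) pop$counts else pop
  spec <- parse_bands(bands)
  tab <- dplyr::inner_join(
    tibble::as_tibble(table),
    dplyr::rename(tibble::as_tibble(counts), n = "value"),
    by = c("year", "sex", "age")
  )
  out <- lapply(seq_len(nrow(spec)), function(k) {
    sub <- tab[tab$age >= spec$lo[k] & tab$age <= spec$hi[k], ]
    if (nrow(sub) == 0) {
      stop("empty band: ", spec$label[k], call. = FALSE)
    }
    dplyr::summarise(
      dplyr::group_by(sub, .data$year, .data$sex),
      age_band = spec$label[k],
      value = sum(.data$value * .data$n) / sum(.data$n),
      .groups = "drop"
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$year, .data$sex)
}

# "20-44" -> [20,44]; "65+" -> [65, 100]
parse_bands <- function(bands) {
  lo <- hi <- integer(length(bands))
  for (k in seq_along(bands)) {
    b <- bands[k]
    if (grepl("^\\d+\\+$", b)) {
      lo[k] <- as.integer(sub("\\+$", "", b))
      hi[k] <- .AGE_MAX
    } else if (grepl("^\\d+-\\d+$", b)) {
      parts <- as.integer(strsplit(b, "-", fixed = TRUE)[[1]])
      lo[k] <- parts[1]; hi[k] <- parts[2]
    } else {
      stop("cannot parse age band '", b, "'", call. = FALSE)
    }
  }
  tibble::tibble(label = bands, lo = lo, hi = hi)
}

# --- internal matrix views ---------------------------------------------------

# One year of an agesex table as an age x sex matrix (rows = ages lo..100).
ast_matrix <- function(x, year, ages = .AGES, what = "table") {
  sub <- x[x$year == year, ]
  if (nrow(sub) == 0) {
    stop("coverage error: ", what, " has no rows for year ", year, call. = FALSE)
  }
  m <- matrix(NA_real_, nrow = length(ages), ncol = 2,
              dimnames = list(ages, .SEXES))
  for (s in .SEXES) {
    ss <- sub[sub$sex == s, ]
    idx <- match(ages, ss$age)
    m[, s] <- ss$value[idx]
  }
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("coverage error: ", what, " missing (year=", year, ", sex=",
         .SEXES[miss[2]], ", age=", ages[miss[1]], ")", call. = FALSE)
  }
  m
}

# age x sex matrix back to tidy rows for one year
matrix_ast <- function(m, year) {
  ages <- as.integer(rownames(m))
  tibble::tibble(
    year = year,
    sex = rep(.SEXES, each = length(ages)),
    age = rep(ages, times = 2),
    value = unname(c(m[, "female"], m[, "male"]))
  )
}
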