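# Assembly and validation of the model-ready county-year-age-sex panel.

#' Build the model-ready stratum panel
#'
#' Inner-joins mortality, population, covariate and exposure tables on their
#' shared keys, restricted to counties present in the exposure panel (i.e.
#' within the inclusion radius of an eligible plant; such counties stay in for
#' all years, including years with exposure 0). Rows with zero or missing
#' population are dropped (the log-population offset is undefined), as are
#' rows with missing covariates; both drop counts are reported via a message
#' and attached as attributes. Zero-death rows are retained.
#'
#' @param mortality Tibble `fips, year, age_group, sex, deaths`.
#' @param populations Tibble `fips, year, age_group, sex, population`.
#' @param covariates Tibble `fips, year, <covariate columns>`.
#' @param exposure Exposure panel tibble `fips, year, exposure`.
#' @return Stratum panel tibble `fips, year, age_group, sex, deaths,
#'   population, exposure, <covariates>` with attributes
#'   `n_dropped_population` and `n_dropped_covariates`.
#' @export
build_panel <- function(mortality, populations, covariates, exposure) {
  check_labels(mortality$age_group, AGE_GROUPS, "age group")
  check_labels(mortality$sex, SEXES, "sex")
  key4 <- c("fips", "year", "age_group", "sex")
  if (anyDuplicated(mortality[, key4])) abort("duplicate keys in mortality table")
  if (anyDuplicated(populations[, key4])) abort("duplicate keys in population table")
  if (anyDuplicated(covariates[, c("fips", "year")])) {
    abort("duplicate keys in covariate table")
  }
  if (anyDuplicated(exposure[, c("fips", "year")])) {
    abort("duplicate keys in exposure panel")
  }
  cov_cols <- setdiff(names(covariates), c("fips", "year"))
  panel <- mortality |>
    dplyr::inner_join(populations, by = key4) |>
    dplyr::inner_join(exposure[, c("fips", "year", "exposure")],
                      by = c("fips", "year")) |>
    dplyr::left_join(covariates, by = c("fips", "year"))
  bad_pop <- is.na(panel$population) | panel$population <= 0
  n_pop <- sum(bad_pop)
  panel <- panel[!bad_pop, ]
  bad_cov <- if (length(cov_cols) > 0) {
    !stats::complete.cases(panel[, cov_cols])
  } else {
    rep(FALSE, nrow(panel))
  }
  n_cov <- sum(bad_cov)
  panel <- panel[!bad_cov, ]
  if (n_pop > 0) inform(sprintf("dropped %d row(s) with zero or missing population", n_pop))
  if (n_cov > 0) inform(sprintf("dropped %d row(s) with missing covariates", n_cov))
  panel <- dplyr::arrange(panel, .data$fips, .data$year, .data$age_group, .data$sex)
  attr(panel, "n_dropped_population") <- n_pop
  attr(panel, "n_dropped_covariates") <- n_cov
  panel
}

#' Validate a stratum panel and summarise its structure
#'
#' Fails on structural violations (empty panel, duplicate keys, negative
#' counts, non-positive population); otherwise returns a report of row counts
#' per age-sex stratum, exposure range, zero-death fraction and years covered.
#'
#' @param panel Stratum panel tibble.
#' @return List of class `panel_report` with elements `n_rows`, `n_counties`,
#'   `years`, `exposure_range`, `zero_death_fraction` and `strata` (a tibble
#'   of per-stratum row counts).
#' @export
validate_panel <- function(panel) {
  if (nrow(panel) == 0) abort("panel is empty")
  key4 <- c("fips", "year", "age_group", "sex")
  miss <- setdiff(c(key4, "deaths", "population", "exposure"), names(panel))
  if (length(miss) > 0) {
    abort(paste0("panel is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(panel[, key4])) abort("duplicate (fips, year, age_group, sex) keys in panel")
  if (any(panel$deaths < 0)) abort("negative death counts in panel")
  if (any(panel$population <= 0)) abort("non-positive population in panel")
  if (any(panel$exposure < 0)) abort("negative exposure in panel")
  strata <- panel |>
    dplyr::count(.data$age_group, .data$sex, name = "n_rows")
  structure(list(
    n_rows = nrow(panel),
    n_counties = dplyr::n_distinct(panel$fips),
    years = range(panel$year),
    exposure_range = range(panel$exposure),
    zero_death_fraction = mean(panel$deaths == 0),
    strata = strata
  ), class = "panel_report")
}

#' @export
print.panel_report <- function(x, ...) {
  cat(sprintf("Stratum panel: %d rows, %d counties, years %d-%d\n",
              x$n_rows, x$n_counties, x$years[1], x$years[2]))
  cat(sprintf("  exposure range: [%.5f, %.5f] 1/km; zero-death fraction: %.3f\n",
              x$exposure_range[1], x$exposure_range[2], x$zero_death_fraction))
  print(x$strata, n = Inf)
  invisible(x)
}
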