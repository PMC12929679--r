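# Relative risk, attributable fraction and attributable-death accounting.

#' Relative risk at an exposure level
#'
#' `RR = exp(E * beta_e)`: the multiplicative effect of aggregated proximity
#' `E` (1/km) on the mortality rate, given the fitted exposure coefficient.
#'
#' @param E Exposure values (1/km).
#' @param beta_e Exposure coefficient on the log-rate scale.
#' @return Relative risks, recycled over the longer argument.
#' @export
relative_risk <- function(E, beta_e) {
  if (any(!is.finite(E)) || any(!is.finite(beta_e))) {
    abort("relative_risk requires finite inputs")
  }
  exp(E * beta_e)
}

#' Attributable fraction from a relative risk
#'
#' `AF = (RR - 1) / RR`, the share of deaths in an exposed stratum
#' attributable to the exposure under a causal reading; negative when RR < 1.
#'
#' @param rr Relative risks (> 0).
#' @return Attributable fractions in (-Inf, 1).
#' @export
attributable_fraction <- function(rr) {
  if (any(rr <= 0, na.rm = TRUE)) abort("relative risk must be > 0")
  (rr - 1) / rr
}

round_half_up <- function(x) floor(x + 0.5)

#' Per-row attributable deaths with propagated confidence bounds
#'
#' For every panel row, computes `RR = exp(E * beta_e)` from that row's
#' stratum fit, the attributable fraction, and `AF * deaths`. Confidence
#' bounds substitute the robust Wald CI endpoints of `beta_e` through
#' RR then AF then cases; since exposure is nonnegative, each step is
#' monotone in `beta_e`, so the endpoints map to endpoint bounds.
#'
#' @param panel Stratum panel tibble.
#' @param fits A `gee_fits` tibble from [fit_all_strata()] or a single
#'   `gee_fit` (then applied to all rows, which must be one stratum).
#' @param conf.level Confidence level for the propagated bounds.
#' @return The panel keys plus `rr`, `af`, `attributable`,
#'   `attributable_low`, `attributable_high`.
#' @export
attributable_cases <- function(panel, fits, conf.level = 0.95) {
  if (inherits(fits, "gee_fit")) {
    fits <- tibble::tibble(age_group = fits$stratum[["age_group"]],
                           sex = fits$stratum[["sex"]], fit = list(fits))
  }
  betas <- purrr::map2_dfr(seq_len(nrow(fits)), fits$fit, function(i, fit) {
    ci <- wald_ci(fit, "exposure", level = conf.level)
    tibble::tibble(age_group = fits$age_group[i], sex = fits$sex[i],
                   beta_e = ci[["estimate"]], beta_low = ci[["low"]],
                   beta_high = ci[["high"]])
  })
  missing_fit <- dplyr::anti_join(
    dplyr::distinct(panel[, c("age_group", "sex")]), betas,
    by = c("age_group", "sex")
  )
  if (nrow(missing_fit) > 0) {
    abort(paste0("no fit available for stratum ",
                 missing_fit$age_group[1], "/", missing_fit$sex[1]))
  }
  panel |>
    dplyr::inner_join(betas, by = c("age_group", "sex")) |>
    dplyr::mutate(
      rr = relative_risk(.data$exposure, .data$beta_e),
      af = attributable_fraction(.data$rr),
      attributable = .data$af * .data$deaths,
      attributable_low = attributable_fraction(
        relative_risk(.data$exposure, .data$beta_low)) * .data$deaths,
      attributable_high = attributable_fraction(
        relative_risk(.data$exposure, .data$beta_high)) * .data$deaths
    ) |>
    dplyr::select("fips", "year", "age_group", "sex", "deaths", "exposure",
                  "rr", "af", "attributable", "attributable_low",
                  "attributable_high")
}

#' Aggregate attributable deaths into a burden table
#'
#' Sums point estimates and CI endpoint bounds over counties and years within
#' each age-sex stratum, appends a grand-total row whose point estimate and
#' bounds are the column sums of the stratum rows, and recomputes the
#' stratum-level attributable fraction as attributable deaths over total
#' deaths.
#'
#' @param cases Per-row table from [attributable_cases()].
#' @param study_years Number of study years (for [annualize()]); inferred from
#'   the data when `NULL`.
#' @return Tibble of class `burden_table` with per-stratum rows and a
#'   `Total`/`All` row; attribute `study_years`.
#' @export
aggregate_burden <- function(cases, study_years = NULL) {
  study_years <- study_years %||% dplyr::n_distinct(cases$year)
  strata <- cases |>
    dplyr::group_by(.data$age_group, .data$sex) |>
    dplyr::summarise(
      attributable = sum(.data$attributable),
      attributable_low = sum(.data$attributable_low),
      attributable_high = sum(.data$attributable_high),
      total_deaths = sum(.data$deaths),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      af = .data$attributable / .data$total_deaths,
      af_low = .data$attributable_low / .data$total_deaths,
      af_high = .data$attributable_high / .data$total_deaths
    ) |>
    dplyr::arrange(.data$sex, .data$age_group)
  total <- strata |>
    dplyr::summarise(
      age_group = "Total", sex = "All",
      attributable = sum(.data$attributable),
      attributable_low = sum(.data$attributable_low),
      attributable_high = sum(.data$attributable_high),
      total_deaths = sum(.data$total_deaths)
    ) |>
    dplyr::mutate(
      af = .data$attributable / .data$total_deaths,
      af_low = .data$attributable_low / .data$total_deaths,
      af_high = .data$attributable_high / .data$total_deaths
    )
  out <- dplyr::bind_rows(strata, total)
  attr(out, "study_years") <- study_years
  class(out) <- c("burden_table", class(out))
  out
}

#' Annualized death count
#'
#' Average deaths per year over the study period, rounded half-up to a whole
#' number of deaths for reporting (so 12.5 reports as 13).
#'
#' @param total Total deaths over the period.
#' @param years Number of study years (>= 1).
#' @return Whole-number deaths per year.
#' @export
annualize <- function(total, years) {
  if (any(years < 1)) abort("years must be >= 1")
  round_half_up(total / years)
}
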