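# Inverse-distance exposure construction: operational masking, latency
# averaging, summation over plants, equivalent-distance transform.

#' Annual inverse-distance series per plant-county pair
#'
#' For each (plant, county) pair, the series over `years` takes the value
#' `1/distance_km` in every year the plant is operational and 0 otherwise.
#' The operational convention is `start_year <= year < end_year`: from the year
#' of decommissioning onward the value is 0. An `NA` end year means the plant
#' is still operating at the end of the series.
#'
#' @param pairs Tibble of `plant_id`, `fips`, `distance_km` (e.g. from
#'   [pairs_within_radius()]).
#' @param plants Plant registry tibble supplying `start_year`/`end_year`.
#' @param years Integer vector of calendar years (non-empty).
#' @return Tibble with columns `plant_id`, `fips`, `year`, `inv_d` (1/km).
#' @export
annual_inverse_distance <- function(pairs, plants, years) {
  if (length(years) == 0) abort("years must be a non-empty year range")
  years <- sort(unique(as.integer(years)))
  if (any(pairs$distance_km <= 0)) abort("distance_km must be > 0 (1/d undefined at 0)")
  pairs |>
    dplyr::inner_join(plants[, c("plant_id", "start_year", "end_year")],
                      by = "plant_id") |>
    tidyr::expand_grid(year = years) |>
    dplyr::mutate(
      operational = .data$year >= .data$start_year &
        (is.na(.data$end_year) | .data$year < .data$end_year),
      inv_d = ifelse(.data$operational, 1 / .data$distance_km, 0)
    ) |>
    dplyr::select("plant_id", "fips", "year", "inv_d")
}

#' Trailing mean of a plant-year series
#'
#' Right-aligned rolling mean over `window_years` consecutive years including
#' the current year: the output at year t averages the input over
#' `[t - window_years + 1, t]`. The first `window_years - 1` years of each
#' series are consumed as history, so the output starts `window_years - 1`
#' years after the input does; requesting earlier output is an error that
#' names the earliest computable year.
#'
#' @param series Tibble of `plant_id`, `fips`, `year`, `inv_d` with contiguous
#'   years within each pair.
#' @param window_years Window length in years (>= 1); 1 is the identity.
#' @param out_years Optional years the caller needs in the output; an error is
#'   raised if the series history is too short for them.
#' @return Tibble with columns `plant_id`, `fips`, `year`, `value` (1/km),
#'   restricted to computable years.
#' @export
trailing_mean <- function(series, window_years, out_years = NULL) {
  if (!is.numeric(window_years) || window_years < 1) {
    abort("window_years must be >= 1")
  }
  window_years <- as.integer(window_years)
  earliest <- min(series$year) + window_years - 1L
  if (!is.null(out_years) && min(out_years) < earliest) {
    abort(sprintf(
      "insufficient history for a %d-year window: earliest computable year is %d (requested %d)",
      window_years, earliest, min(out_years)
    ))
  }
  out <- series |>
    dplyr::group_by(.data$plant_id, .data$fips) |>
    dplyr::arrange(.data$year, .by_group = TRUE) |>
    dplyr::mutate(value = {
      if (any(diff(.data$year) != 1L)) {
        abort("series years must be contiguous within each plant-county pair")
      }
      as.numeric(stats::filter(.data$inv_d, rep(1 / window_years, window_years),
                               sides = 1))
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::select("plant_id", "fips", "year", "value")
  if (!is.null(out_years)) out <- dplyr::filter(out, .data$year %in% out_years)
  out
}

#' Aggregate smoothed series into a county-year exposure panel
#'
#' Sums the smoothed per-plant contributions within each county-year. Counties
#' with no contributing plant are absent from the panel.
#'
#' @param smoothed Tibble of `plant_id`, `fips`, `year`, `value` from
#'   [trailing_mean()]. Duplicate (plant, county, year) rows are an error.
#' @param years Optional years to restrict the panel to.
#' @return Tibble with columns `fips`, `year`, `exposure` (1/km).
#' @export
aggregate_exposure <- function(smoothed, years = NULL) {
  if (anyDuplicated(smoothed[, c("plant_id", "fips", "year")])) {
    abort("duplicate (plant_id, fips, year) rows in smoothed series")
  }
  if (!is.null(years)) smoothed <- dplyr::filter(smoothed, .data$year %in% years)
  smoothed |>
    dplyr::group_by(.data$fips, .data$year) |>
    dplyr::summarise(exposure = sum(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$fips, .data$year)
}

#' Equivalent single-plant distance
#'
#' The distance at which one always-operational plant would produce the same
#' aggregated proximity: `1/E` kilometres. Zero exposure has no equivalent
#' distance and maps to `NA` (with a warning) rather than infinity.
#'
#' @param E Exposure values in 1/km (>= 0).
#' @return Kilometres, same length as `E`.
#' @export
equivalent_distance <- function(E) {
  if (any(E < 0, na.rm = TRUE)) abort("exposure must be >= 0")
  if (any(E == 0, na.rm = TRUE)) {
    warn("equivalent distance is undefined at zero exposure; returning NA")
  }
  ifelse(E > 0, 1 / E, NA_real_)
}

#' Compute the county-year exposure panel from registries
#'
#' End-to-end exposure construction: restrict to plants operational during the
#' eligibility window, find plant-county pairs within `radius_km`, build the
#' masked annual 1/d series (extended back `window_years - 1` years for
#' history), smooth each pair's series with a trailing mean, and sum over
#' plants. Counties within the radius of an eligible plant are kept for all
#' study years, with exposure 0 where no plant contributes.
#'
#' @param plants,counties Registry tibbles.
#' @param years Study years for the output panel (default 2000:2018).
#' @param radius_km Inclusion radius in kilometres (default 200).
#' @param window_years Trailing averaging window in years (default 10).
#' @param eligibility_window Length-2 integer vector: plants must be
#'   operational for at least one year in this window (default `c(1990, 2018)`).
#' @param min_distance_km Passed to [pairs_within_radius()].
#' @return Exposure panel tibble (`fips`, `year`, `exposure`) with attributes
#'   `radius_km` and `window_years`.
#' @export
compute_exposure <- function(plants, counties, years = 2000:2018,
                             radius_km = 200, window_years = 10,
                             eligibility_window = c(1990, 2018),
                             min_distance_km = 0) {
  years <- sort(unique(as.integer(years)))
  elig <- eligible_plants(plants, eligibility_window[1], eligibility_window[2])
  pairs <- pairs_within_radius(counties, elig, radius_km = radius_km,
                               min_distance_km = min_distance_km)
  if (nrow(pairs) == 0) {
    panel <- tibble::tibble(fips = character(), year = integer(),
                            exposure = double())
    attr(panel, "radius_km") <- radius_km
    attr(panel, "window_years") <- window_years
    return(panel)
  }
  series_years <- (min(years) - window_years + 1L):max(years)
  panel <- pairs |>
    annual_inverse_distance(elig, series_years) |>
    trailing_mean(window_years, out_years = years) |>
    aggregate_exposure(years = years)
  # retain every in-radius county for every study year, exposure 0 if no
  # plant contributes that year
  full <- tidyr::expand_grid(fips = sort(unique(pairs$fips)), year = years)
  panel <- full |>
    dplyr::left_join(panel, by = c("fips", "year")) |>
    dplyr::mutate(exposure = dplyr::coalesce(.data$exposure, 0))
  attr(panel, "radius_km") <- radius_km
  attr(panel, "window_years") <- window_years
  panel
}
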