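# Derived curves: cumulative population by proximity level, and relative risk
# as a function of equivalent single-plant distance.

#' Cumulative population at or above each proximity level
#'
#' For each level `p` of the grid, the total population (summed over strata)
#' of counties whose exposure in the chosen year is at least `p` — i.e. the
#' population living at the corresponding equivalent distance `1/p` or closer.
#' The curve is a non-increasing, right-continuous step function of the level.
#'
#' @param exposure Exposure panel tibble.
#' @param populations Stratified population tibble.
#' @param year Calendar year for the snapshot; defaults to the final panel
#'   year (the study uses its last year).
#' @param grid Strictly increasing proximity levels (1/km); defaults to 50
#'   log-spaced levels spanning the positive exposures present.
#' @return Tibble of class `cumpop_curve` with `level`,
#'   `equivalent_distance_km` and `population`.
#' @export
cumulative_population_curve <- function(exposure, populations, year = NULL,
                                        grid = NULL) {
  year <- year %||% max(exposure$year)
  ex <- dplyr::filter(exposure, .data$year == !!year)
  pop <- populations |>
    dplyr::filter(.data$year == !!year) |>
    dplyr::group_by(.data$fips) |>
    dplyr::summarise(population = sum(.data$population), .groups = "drop")
  county <- dplyr::inner_join(ex, pop, by = "fips")
  if (is.null(grid)) {
    pos <- county$exposure[county$exposure > 0]
    if (length(pos) == 0) abort("no positive exposures; supply a grid explicitly")
    grid <- exp(seq(log(min(pos)), log(max(pos)), length.out = 50))
  }
  if (any(diff(grid) <= 0)) abort("grid must be strictly increasing")
  out <- tibble::tibble(
    level = grid,
    equivalent_distance_km = equivalent_distance(grid),
    population = purrr::map_dbl(grid, function(p) {
      sum(county$population[county$exposure >= p])
    })
  )
  class(out) <- c("cumpop_curve", class(out))
  out
}

#' Relative risk versus equivalent plant distance
#'
#' Model-predicted `RR(d) = exp(beta_e / d)` over a grid of equivalent
#' single-plant distances, with a confidence band obtained by substituting the
#' robust Wald CI endpoints of the exposure coefficient. Decreasing in `d`
#' when the coefficient is positive.
#'
#' @param fit A converged `gee_fit`.
#' @param distances Equivalent distances in km (> 0).
#' @param conf.level Confidence level for the band.
#' @return Tibble of class `rr_curve` with `distance_km`, `rr`, `rr_low`,
#'   `rr_high` and the stratum labels.
#' @export
rr_distance_curve <- function(fit, distances, conf.level = 0.95) {
  if (any(distances <= 0)) abort("distances must be > 0")
  if (!isTRUE(fit$converged)) abort("fit did not converge")
  ci <- wald_ci(fit, "exposure", level = conf.level)
  out <- tibble::tibble(
    age_group = fit$stratum[["age_group"]], sex = fit$stratum[["sex"]],
    distance_km = distances,
    rr = relative_risk(1 / distances, ci[["estimate"]]),
    rr_low = relative_risk(1 / distances, ci[["low"]]),
    rr_high = relative_risk(1 / distances, ci[["high"]])
  )
  class(out) <- c("rr_curve", class(out))
  out
}

#' @rdname cumulative_population_curve
#' @param object A `cumpop_curve`.
#' @param ... Unused.
#' @export
autoplot.cumpop_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$equivalent_distance_km,
                                       y = .data$population / 1e6)) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Equivalent distance (km)",
                  y = "Cumulative population (millions)",
                  title = "Population at or above each proximity level") +
    ggplot2::theme_minimal()
}

#' @rdname rr_distance_curve
#' @param object An `rr_curve`.
#' @param ... Unused.
#' @export
autoplot.rr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance_km, y = .data$rr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rr_low, ymax = .data$rr_high),
                         fill = "grey80") +
    ggplot2::geom_line(colour = "firebrick", linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Equivalent plant distance (km)", y = "Relative risk",
                  title = sprintf("RR vs equivalent distance (%s, %s)",
                                  object$age_group[1], object$sex[1])) +
    ggplot2::theme_minimal()
}
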