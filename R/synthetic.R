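# Synthetic studies: plants, counties, stratified populations, covariates and
# correlated Poisson death counts with a known exposure effect, so the whole
# inference pipeline can be validated without confidential mortality records.

#' Configuration for a synthetic study
#'
#' Bundles every knob of the generator. All randomness downstream flows from
#' `seed`; identical configurations produce identical output.
#'
#' Defaults emulate the structure of the motivating study: 19 study years
#' (2000-2018), six adult age groups by two sexes, county populations spanning
#' two orders of magnitude, a county-level log-normal frailty inducing
#' exchangeable-type within-county correlation, and an exposure coefficient
#' sized so that a county at 50 km equivalent distance (exposure 0.02 km^-1)
#' has relative risk 1.2 versus an unexposed county.
#'
#' @param seed Integer seed driving all random draws.
#' @param n_counties,n_plants Registry sizes (`n_plants = 0` gives a null
#'   geography with all exposures 0).
#' @param years Study years for the mortality panel.
#' @param age_groups,sexes Stratum labels.
#' @param true_beta_e Exposure coefficient on the log-rate scale (per 1/km).
#' @param baseline_log_rate Named vector of baseline log death rates per
#'   person-year, one per age group.
#' @param male_log_rate_shift Additive log-rate shift for males.
#' @param covariate_effects Coefficients for the standard-normal county-year
#'   covariates; the length sets the number of covariates.
#' @param frailty_sd Standard deviation of the county-level normal random
#'   effect on the log-rate scale (0 gives independent Poisson rows).
#' @param population_range Range of total county population; county sizes are
#'   drawn log-uniformly over it.
#' @param radius_km,window_years,eligibility_window Exposure-construction
#'   settings passed through to [compute_exposure()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_counties = 400L,
                       n_plants = 16L,
                       years = 2000:2018,
                       age_groups = AGE_GROUPS,
                       sexes = SEXES,
                       true_beta_e = log(1.2) / 0.02,
                       baseline_log_rate = c(
                         "35-44" = log(6e-5), "45-54" = log(2.5e-4),
                         "55-64" = log(7e-4), "65-74" = log(1.7e-3),
                         "75-84" = log(3.2e-3), "85+" = log(4.5e-3)
                       ),
                       male_log_rate_shift = log(1.2),
                       covariate_effects = c(0.10, -0.08, 0.05),
                       frailty_sd = 0.2,
                       population_range = c(5e4, 5e5),
                       radius_km = 200,
                       window_years = 10,
                       eligibility_window = c(1990, 2018)) {
  if (n_counties < 1) abort("n_counties must be >= 1")
  if (n_plants < 0) abort("n_plants must be >= 0")
  miss <- setdiff(age_groups, names(baseline_log_rate))
  if (length(miss) > 0) {
    abort(paste0("baseline_log_rate missing age group(s): ",
                 paste(miss, collapse = ", ")))
  }
  structure(list(
    seed = as.integer(seed), n_counties = as.integer(n_counties),
    n_plants = as.integer(n_plants), years = as.integer(years),
    age_groups = age_groups, sexes = sexes, true_beta_e = true_beta_e,
    baseline_log_rate = baseline_log_rate,
    male_log_rate_shift = male_log_rate_shift,
    covariate_effects = covariate_effects, frailty_sd = frailty_sd,
    population_range = population_range, radius_km = radius_km,
    window_years = window_years, eligibility_window = eligibility_window
  ), class = "sim_config")
}

# Age-group shares of county population (roughly U.S.-like for adults).
AGE_SHARES <- c("35-44" = 0.125, "45-54" = 0.13, "55-64" = 0.12,
                "65-74" = 0.09, "75-84" = 0.055, "85+" = 0.02)

#' Simulate plant and county registries
#'
#' Scatters county centroids uniformly over a bounded region (roughly 900 by
#' 900 km, giving U.S.-like county density at the default 400 counties) and
#' places plants 20-80 km from randomly chosen centroids, enforcing a minimum
#' 15 km separation from every county centroid (plants are sited away from
#' population centers), so that county exposures span the study's range of
#' equivalent distances from near 12 km out to the inclusion radius. Most
#' plants run throughout; a minority decommission mid-study to exercise the
#' taper. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return List with elements `plants` and `counties` (validated tibbles).
#' @export
simulate_geography <- function(config) {
  set.seed(config$seed)
  lon_range <- c(-90, -80)
  lat_range <- c(35, 43)
  counties <- tibble::tibble(
    fips = sprintf("%05d", seq_len(config$n_counties)),
    lat = runif(config$n_counties, lat_range[1], lat_range[2]),
    lon = runif(config$n_counties, lon_range[1], lon_range[2])
  )
  if (config$n_plants == 0) {
    plants <- tibble::tibble(plant_id = character(), name = character(),
                             lat = double(), lon = double(),
                             start_year = integer(), end_year = integer())
  } else {
    np <- config$n_plants
    host <- counties[sample.int(config$n_counties, np,
                                replace = np > config$n_counties), ]
    # offset plants 20-80 km from the host centroid; plants are sited away
    # from population centers, so enforce a minimum separation from every
    # county centroid (siting exclusion), redrawing offenders
    plat <- rep(NA_real_, np)
    plon <- rep(NA_real_, np)
    redo <- rep(TRUE, np)
    for (attempt in 1:100) {
      bearing <- runif(np, 0, 2 * pi)
      dist_deg <- runif(np, 0.2, 0.7)
      plat[redo] <- host$lat[redo] + dist_deg[redo] * sin(bearing[redo])
      plon[redo] <- host$lon[redo] + dist_deg[redo] * cos(bearing[redo])
      dmin <- vapply(seq_len(np), function(i) {
        min(great_circle_km(plat[i], plon[i], counties$lat, counties$lon))
      }, numeric(1))
      redo <- dmin < 15
      if (!any(redo)) break
    }
    closes <- runif(np) < 0.2
    plants <- tibble::tibble(
      plant_id = sprintf("P%03d", seq_len(np)),
      name = sprintf("Plant %03d", seq_len(np)),
      lat = pmin(pmax(plat, -90), 90),
      lon = plon,
      start_year = sample(1960:1985, np, replace = TRUE),
      end_year = ifelse(closes, sample(2005:2015, np, replace = TRUE),
                        NA_integer_)
    )
    plants$end_year <- as.integer(plants$end_year)
  }
  validate_counties(counties)
  validate_plants(plants)
  list(plants = plants, counties = counties)
}

#' Simulate stratified county populations
#'
#' Total county population is log-uniform over `population_range`; stratum
#' populations follow fixed adult age-group shares split evenly by sex, and
#' are held constant over the study years.
#'
#' @param config A [sim_config()].
#' @param counties County registry tibble.
#' @return Tibble `fips, year, age_group, sex, population`.
#' @export
simulate_populations <- function(config, counties) {
  set.seed(config$seed + 1L)
  lo <- log(config$population_range[1])
  hi <- log(config$population_range[2])
  base <- exp(runif(nrow(counties), lo, hi))
  shares <- AGE_SHARES[config$age_groups]
  shares[is.na(shares)] <- mean(AGE_SHARES)
  tibble::tibble(fips = counties$fips, total = base) |>
    tidyr::expand_grid(year = config$years, age_group = config$age_groups,
                       sex = config$sexes) |>
    dplyr::mutate(
      population = pmax(round(.data$total * shares[.data$age_group] /
                                length(config$sexes)), 1)
    ) |>
    dplyr::select("fips", "year", "age_group", "sex", "population")
}

#' Simulate county-year covariates
#'
#' Independent standard-normal draws per county-year for each covariate
#' (stand-ins for socioeconomic, behavioral and environmental adjustment
#' variables; columns `X1..Xp` with `p = length(covariate_effects)`).
#'
#' @param config A [sim_config()].
#' @param counties County registry tibble.
#' @return Tibble `fips, year, X1..Xp`.
#' @export
simulate_covariates <- function(config, counties) {
  set.seed(config$seed + 2L)
  p <- length(config$covariate_effects)
  grid <- tidyr::expand_grid(fips = counties$fips, year = config$years)
  if (p > 0) {
    X <- matrix(rnorm(nrow(grid) * p), ncol = p,
                dimnames = list(NULL, paste0("X", seq_len(p))))
    grid <- dplyr::bind_cols(grid, tibble::as_tibble(X))
  }
  grid
}

#' Simulate correlated Poisson death counts
#'
#' For each county-year-age-sex row, deaths are drawn as
#' `Poisson(population * exp(baseline + covariate effects + beta_e * E + u))`
#' where `u` is a county-level normal random effect (sd `frailty_sd`) shared
#' across all of a county's rows, inducing exchangeable-type within-county
#' correlation.
#'
#' @param config A [sim_config()].
#' @param exposure Exposure panel tibble (`fips`, `year`, `exposure`) covering
#'   all county-years to simulate.
#' @param populations Stratified population tibble.
#' @param covariates County-year covariate tibble.
#' @return A model-ready stratum panel tibble: `fips, year, age_group, sex,
#'   deaths, population, exposure, X1..Xp`.
#' @export
simulate_counts <- function(config, exposure, populations, covariates) {
  if (any(populations$population < 0)) abort("negative population")
  set.seed(config$seed + 3L)
  fips_levels <- sort(unique(exposure$fips))
  u <- setNames(rnorm(length(fips_levels), 0, config$frailty_sd), fips_levels)
  p <- length(config$covariate_effects)
  panel <- populations |>
    dplyr::inner_join(exposure, by = c("fips", "year")) |>
    dplyr::inner_join(covariates, by = c("fips", "year"))
  xb <- if (p > 0) {
    as.matrix(panel[, paste0("X", seq_len(p))]) %*% config$covariate_effects
  } else {
    0
  }
  log_rate <- config$baseline_log_rate[panel$age_group] +
    config$male_log_rate_shift * (panel$sex == "M") +
    as.numeric(xb) + config$true_beta_e * panel$exposure + u[panel$fips]
  panel$deaths <- rpois(nrow(panel), panel$population * exp(log_rate))
  dplyr::select(panel, "fips", "year", "age_group", "sex", "deaths",
                "population", "exposure", dplyr::any_of(paste0("X", seq_len(p))))
}

#' Simulate a complete study
#'
#' Runs geography, exposure construction, populations, covariates and counts
#' in sequence and returns every intermediate product plus the model-ready
#' panel restricted to counties within the exposure radius.
#'
#' @param config A [sim_config()].
#' @return List with `config`, `plants`, `counties`, `populations`,
#'   `covariates`, `exposure`, `mortality` and `panel`.
#' @export
simulate_study <- function(config) {
  geo <- simulate_geography(config)
  exposure <- compute_exposure(
    geo$plants, geo$counties, years = config$years,
    radius_km = config$radius_km, window_years = config$window_years,
    eligibility_window = config$eligibility_window
  )
  populations <- simulate_populations(config, geo$counties)
  covariates <- simulate_covariates(config, geo$counties)
  if (nrow(exposure) == 0) {
    # null geography: every county retained with zero exposure
    exposure <- tidyr::expand_grid(fips = geo$counties$fips,
                                   year = config$years) |>
      dplyr::mutate(exposure = 0)
  }
  panel <- simulate_counts(config, exposure, populations, covariates)
  mortality <- dplyr::select(panel, "fips", "year", "age_group", "sex", "deaths")
  list(config = config, plants = geo$plants, counties = geo$counties,
       populations = populations, covariates = covariates,
       exposure = exposure, mortality = mortality, panel = panel)
}

#' Write a simulated study to CSV files
#'
#' Emits the same schemas the real-data readers consume (`plants.csv`,
#' `counties.csv`, `populations.csv`, `covariates.csv`, `mortality.csv`), so a
#' simulated study can stand in for real inputs anywhere in the pipeline.
#'
#' @param study Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_csv <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(study$plants, file.path(dir, "plants.csv"))
  readr::write_csv(study$counties, file.path(dir, "counties.csv"))
  readr::write_csv(study$populations, file.path(dir, "populations.csv"))
  readr::write_csv(study$covariates, file.path(dir, "covariates.csv"))
  readr::write_csv(study$mortality, file.path(dir, "mortality.csv"))
  invisible(dir)
}
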