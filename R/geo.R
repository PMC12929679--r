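# Plant/county registries and great-circle geometry.

# Mean earth radius (km), IUGG mean radius R1.
EARTH_RADIUS_KM <- 6371.0088

AGE_GROUPS <- c("35-44", "45-54", "55-64", "65-74", "75-84", "85+")
SEXES <- c("F", "M")

check_coords <- function(lat, lon, what = "coordinate") {
  bad_lat <- !is.finite(lat) | lat < -90 | lat > 90
  bad_lon <- !is.finite(lon) | lon < -180 | lon > 180
  if (any(bad_lat | bad_lon)) {
    abort(sprintf(
      "%s out of range: latitude must lie in [-90, 90] and longitude in [-180, 180] (%d offending value(s))",
      what, sum(bad_lat | bad_lon)
    ))
  }
  invisible(TRUE)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of mean radius 6371.0088 km. Vectorised over
#' all four coordinate arguments (recycled as usual).
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84 latitudes
#'   in \[-90, 90\], longitudes in \[-180, 180\]).
#' @return Numeric vector of distances in kilometres.
#' @examples
#' great_circle_km(42, -71, 41, -72)
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1, "first point")
  check_coords(lat2, lon2, "second point")
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  as.numeric(geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM))
}

#' Validate a plant registry
#'
#' Checks coordinate bounds, start/end year ordering (an `NA` end year means
#' the plant is still operating) and uniqueness of `plant_id`.
#'
#' @param plants Tibble with columns `plant_id`, `name`, `lat`, `lon`,
#'   `start_year`, `end_year`.
#' @return The input, invisibly, after validation.
#' @export
validate_plants <- function(plants) {
  req <- c("plant_id", "lat", "lon", "start_year", "end_year")
  miss <- setdiff(req, names(plants))
  if (length(miss) > 0) {
    abort(paste0("plant registry is missing column(s): ", paste(miss, collapse = ", ")))
  }
  check_coords(plants$lat, plants$lon, "plant location")
  if (anyDuplicated(plants$plant_id)) abort("duplicate plant_id in plant registry")
  closed <- !is.na(plants$end_year)
  if (any(closed & plants$end_year < plants$start_year)) {
    abort("plant registry has end_year earlier than start_year")
  }
  invisible(plants)
}

#' Validate a county registry
#'
#' @param counties Tibble with columns `fips`, `lat`, `lon`.
#' @return The input, invisibly, after validation.
#' @export
validate_counties <- function(counties) {
  miss <- setdiff(c("fips", "lat", "lon"), names(counties))
  if (length(miss) > 0) {
    abort(paste0("county registry is missing column(s): ", paste(miss, collapse = ", ")))
  }
  check_coords(counties$lat, counties$lon, "county centroid")
  if (anyDuplicated(counties$fips)) abort("duplicate fips in county registry")
  invisible(counties)
}

#' Plants operational during a window
#'
#' Keeps plants whose operational interval `[start_year, end_year]` (open-ended
#' when `end_year` is `NA`) intersects the closed window
#' `[first_year, last_year]`. The default window matches the study eligibility
#' rule: operational for at least one year between 1990 and 2018.
#'
#' @param plants Plant registry tibble.
#' @param first_year,last_year Integer calendar years, `first_year <= last_year`.
#' @return Tibble of eligible plants.
#' @export
eligible_plants <- function(plants, first_year = 1990, last_year = 2018) {
  if (first_year > last_year) abort("first_year must not exceed last_year")
  validate_plants(plants)
  dplyr::filter(
    plants,
    .data$start_year <= last_year,
    is.na(.data$end_year) | .data$end_year >= first_year
  )
}

#' Plant-county pairs within a radius
#'
#' All (plant, county) pairs whose centroid great-circle distance is at most
#' `radius_km`, with the distance attached. A plant coincident with a county
#' centroid (distance 0, or below `min_distance_km` when set) is an error,
#' because the inverse-distance kernel 1/d is undefined there.
#'
#' @param counties County registry tibble (`fips`, `lat`, `lon`).
#' @param plants Plant registry tibble.
#' @param radius_km Inclusion radius in kilometres (default 200).
#' @param min_distance_km Optional hard floor; any pair closer than this errors.
#'   Default 0, i.e. only exactly-coincident points are rejected.
#' @return Tibble with columns `plant_id`, `fips`, `distance_km`.
#' @export
pairs_within_radius <- function(counties, plants, radius_km = 200,
                                min_distance_km = 0) {
  if (!is.numeric(radius_km) || radius_km <= 0) abort("radius_km must be > 0")
  validate_plants(plants)
  validate_counties(counties)
  if (nrow(plants) == 0 || nrow(counties) == 0) {
    return(tibble::tibble(plant_id = character(), fips = character(),
                          distance_km = double()))
  }
  grid <- tidyr::expand_grid(
    counties[, c("fips", "lat", "lon")],
    dplyr::rename(plants[, c("plant_id", "lat", "lon")],
                  plat = "lat", plon = "lon")
  )
  grid$distance_km <- great_circle_km(grid$lat, grid$lon, grid$plat, grid$plon)
  too_close <- grid$distance_km <= min_distance_km | grid$distance_km == 0
  hits <- grid$distance_km <= radius_km
  if (any(too_close & hits)) {
    bad <- grid[too_close & hits, ]
    abort(sprintf(
      "plant %s coincides with (or is within the minimum distance of) county %s centroid; 1/d is undefined",
      bad$plant_id[1], bad$fips[1]
    ))
  }
  out <- grid[hits, c("plant_id", "fips", "distance_km")]
  dplyr::arrange(tibble::as_tibble(out), .data$plant_id, .data$fips)
}

#' Read a plant registry CSV
#'
#' Expected columns: `plant_id,name,lat,lon,start_year,end_year`; an empty
#' `end_year` means the plant is still operating.
#'
#' @param path Path to a CSV file.
#' @return Validated plant tibble.
#' @export
read_plants <- function(path) {
  plants <- readr::read_csv(
    path,
    col_types = readr::cols(
      plant_id = readr::col_character(), name = readr::col_character(),
      lat = readr::col_double(), lon = readr::col_double(),
      start_year = readr::col_integer(), end_year = readr::col_integer()
    )
  )
  validate_plants(plants)
  plants
}

#' Read a county registry CSV
#'
#' Expected columns: `fips,lat,lon` where `fips` is the 5-character county code
#' and `lat`/`lon` the geographic centroid supplied by the source (centroids
#' are not computed from polygons here).
#'
#' @param path Path to a CSV file.
#' @return Validated county tibble.
#' @export
read_counties <- function(path) {
  counties <- readr::read_csv(
    path,
    col_types = readr::cols(fips = readr::col_character(),
                            lat = readr::col_double(),
                            lon = readr::col_double())
  )
  validate_counties(counties)
  counties
}

check_labels <- function(x, allowed, what) {
  bad <- setdiff(unique(x), allowed)
  if (length(bad) > 0) {
    abort(sprintf("unknown %s label(s): %s (allowed: %s)", what,
                  paste(bad, collapse = ", "), paste(allowed, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Read a stratified population CSV
#'
#' Expected columns: `fips,year,age_group,sex,population` with age groups among
#' `35-44, 45-54, 55-64, 65-74, 75-84, 85+` and sexes `F`/`M`.
#'
#' @param path Path to a CSV file.
#' @return Population tibble.
#' @export
read_populations <- function(path) {
  pop <- readr::read_csv(
    path,
    col_types = readr::cols(fips = readr::col_character(),
                            year = readr::col_integer(),
                            age_group = readr::col_character(),
                            sex = readr::col_character(),
                            population = readr::col_double())
  )
  check_labels(pop$age_group, AGE_GROUPS, "age group")
  check_labels(pop$sex, SEXES, "sex")
  if (any(pop$population < 0, na.rm = TRUE)) abort("negative population")
  pop
}

#' Read a stratified mortality CSV
#'
#' Expected columns: `fips,year,age_group,sex,deaths`. Counts are assumed to be
#' pre-aggregated cancer deaths (for the motivating application, deaths whose
#' underlying-cause ICD-10 code begins with "C", i.e. all malignant neoplasms);
#' record-level filtering happens upstream of this package.
#'
#' @param path Path to a CSV file.
#' @return Mortality tibble.
#' @export
read_mortality <- function(path) {
  mort <- readr::read_csv(
    path,
    col_types = readr::cols(fips = readr::col_character(),
                            year = readr::col_integer(),
                            age_group = readr::col_character(),
                            sex = readr::col_character(),
                            deaths = readr::col_double())
  )
  check_labels(mort$age_group, AGE_GROUPS, "age group")
  check_labels(mort$sex, SEXES, "sex")
  if (any(mort$deaths < 0, na.rm = TRUE)) abort("negative death count")
  mort
}

#' Read a county-year covariate CSV
#'
#' Expected columns: `fips,year` plus one column per covariate.
#'
#' @param path Path to a CSV file.
#' @return Covariate tibble.
#' @export
read_covariates <- function(path) {
  cov <- readr::read_csv(path, col_types = readr::cols(
    fips = readr::col_character(), year = readr::col_integer(),
    .default = readr::col_double()
  ))
  if (!all(c("fips", "year") %in% names(cov))) {
    abort("covariate table must have fips and year columns")
  }
  cov
}
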