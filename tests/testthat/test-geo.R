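test_that("great-circle distance: identity, antipodes, fixed oracle, symmetry", {
  expect_equal(great_circle_km(42, -71, 42, -71), 0)
  expect_equal(great_circle_km(0, 0, 0, 180), pi * 6371.0088, tolerance = 1e-10)
  # independent spherical-law-of-cosines oracle, frozen: 138.9218102506 km
  expect_equal(great_circle_km(42, -71, 41, -72), 138.9218102506,
               tolerance = 1e-3 / 138.9)  # < 1 m
  set.seed(11)
  for (i in 1:20) {
    a <- c(runif(1, -90, 90), runif(1, -180, 180))
    b <- c(runif(1, -90, 90), runif(1, -180, 180))
    cc <- c(runif(1, -90, 90), runif(1, -180, 180))
    dab <- great_circle_km(a[1], a[2], b[1], b[2])
    dba <- great_circle_km(b[1], b[2], a[1], a[2])
    expect_equal(dab, dba)
    expect_equal(dab, slc_km(a[1], a[2], b[1], b[2]), tolerance = 1e-6)
    dac <- great_circle_km(a[1], a[2], cc[1], cc[2])
    dcb <- great_circle_km(cc[1], cc[2], b[1], b[2])
    expect_lte(dab, dac + dcb + 1e-9)
  }
  expect_error(great_circle_km(91, 0, 0, 0), "out of range")
  expect_error(great_circle_km(0, 0, 0, 181), "out of range")
})

test_that("pairs_within_radius matches brute force, is monotone, no cross-talk", {
  counties <- county_at_origin()
  expect_equal(nrow(pairs_within_radius(counties, plant_at_km(100), 200)), 1)
  expect_equal(pairs_within_radius(counties, plant_at_km(100), 200)$distance_km,
               100, tolerance = 1e-9)
  expect_equal(nrow(pairs_within_radius(counties, plant_at_km(250), 200)), 0)

  set.seed(21)
  lattice <- tidyr::expand_grid(i = 1:5, j = 1:5) |>
    dplyr::mutate(fips = sprintf("%02d%03d", i, j), lat = 35 + i, lon = -90 + j) |>
    dplyr::select(fips, lat, lon)
  plants <- tibble::tibble(
    plant_id = paste0("P", 1:3), name = plant_id,
    lat = runif(3, 35, 41), lon = runif(3, -90, -84),
    start_year = 1970L, end_year = NA_integer_
  )
  got <- pairs_within_radius(lattice, plants, 200)
  # exhaustive all-pairs oracle
  brute <- tidyr::expand_grid(fips = lattice$fips, plant_id = plants$plant_id) |>
    dplyr::left_join(lattice, by = "fips") |>
    dplyr::left_join(plants, by = "plant_id", suffix = c("", ".p")) |>
    dplyr::mutate(d = mapply(slc_km, lat, lon, lat.p, lon.p)) |>
    dplyr::filter(d <= 200)
  expect_setequal(paste(got$plant_id, got$fips),
                  paste(brute$plant_id, brute$fips))
  # monotone in radius
  got100 <- pairs_within_radius(lattice, plants, 100)
  expect_true(all(paste(got100$plant_id, got100$fips) %in%
                    paste(got$plant_id, got$fips)))
  # doubling the county set leaves existing distances unchanged
  lattice2 <- dplyr::bind_rows(
    lattice, dplyr::mutate(lattice, fips = paste0("X", substr(fips, 2, 5)),
                           lat = lat + 20)
  )
  both <- pairs_within_radius(lattice2, plants, 200)
  merged <- dplyr::inner_join(got, both, by = c("plant_id", "fips"))
  expect_equal(merged$distance_km.x, merged$distance_km.y)
  # coincident plant and centroid is a hard error
  atop <- tibble::tibble(plant_id = "P0", name = "P0", lat = lattice$lat[1],
                         lon = lattice$lon[1], start_year = 1970L,
                         end_year = NA_integer_)
  expect_error(pairs_within_radius(lattice, atop, 200), "undefined")
})

test_that("eligible_plants keeps exactly the plants whose interval overlaps the window", {
  old <- plant_at_km(100, "P1", 1970, 1985)
  late <- plant_at_km(100, "P2", 2017, NA)
  expect_equal(nrow(eligible_plants(old, 1990, 2018)), 0)
  expect_equal(nrow(eligible_plants(late, 1990, 2018)), 1)
  set.seed(31)
  mixed <- tibble::tibble(
    plant_id = sprintf("P%02d", 1:10), name = plant_id,
    lat = 0, lon = lon_at_km(seq(50, 500, by = 50)),
    start_year = sample(1950:2015, 10, replace = TRUE)
  ) |>
    dplyr::mutate(end_year = as.integer(
      ifelse(runif(10) < 0.5, NA, start_year + sample(1:40, 10, replace = TRUE))
    ))
  got <- eligible_plants(mixed, 1990, 2018)$plant_id
  # brute-force interval-overlap oracle
  want <- mixed$plant_id[vapply(seq_len(10), function(i) {
    yrs <- mixed$start_year[i]:(ifelse(is.na(mixed$end_year[i]), 3000,
                                       mixed$end_year[i]))
    any(yrs >= 1990 & yrs <= 2018)
  }, logical(1))]
  expect_setequal(got, want)
  expect_error(eligible_plants(mixed, 2018, 1990), "first_year")
})

test_that("registry readers round-trip the CSV schemas and validate labels", {
  dir <- withr::local_tempdir()
  study <- small_study()
  write_study_csv(study, dir)
  expect_equal(read_plants(file.path(dir, "plants.csv")), study$plants)
  expect_equal(read_counties(file.path(dir, "counties.csv")), study$counties)
  pops <- read_populations(file.path(dir, "populations.csv"))
  expect_equal(nrow(pops), nrow(study$populations))
  bad <- study$mortality
  bad$age_group[1] <- "0-34"
  f <- file.path(dir, "bad.csv")
  readr::write_csv(bad, f)
  expect_error(read_mortality(f), "unknown age group")
})
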