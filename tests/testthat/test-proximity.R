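test_that("annual 1/d series follows the operational mask and decommission zeroing", {
  county <- county_at_origin()
  always <- plant_at_km(100)
  pairs <- pairs_within_radius(county, always, 200)
  s <- annual_inverse_distance(pairs, always, 1991:2018)
  expect_equal(nrow(s), 28)
  expect_equal(s$inv_d, rep(0.01, 28), tolerance = 1e-9)

  closing <- plant_at_km(50, "P002", 1950, 2009)
  s2 <- annual_inverse_distance(pairs_within_radius(county, closing, 200),
                                closing, 2000:2018)
  expect_equal(s2$inv_d[s2$year < 2009], rep(0.02, 9), tolerance = 1e-9)
  expect_equal(s2$inv_d[s2$year >= 2009], rep(0, 10))

  # mid-range start: year-by-year indicator oracle
  mid <- plant_at_km(80, "P003", 2005, 2012)
  s3 <- annual_inverse_distance(pairs_within_radius(county, mid, 200),
                                mid, 1995:2018)
  d <- pairs_within_radius(county, mid, 200)$distance_km
  oracle <- vapply(1995:2018, function(t) if (t >= 2005 && t < 2012) 1 / d else 0,
                   numeric(1))
  expect_equal(s3$inv_d, oracle)
  expect_error(annual_inverse_distance(pairs, always, integer(0)), "non-empty")
})

test_that("trailing mean: constants, identity window, decommission taper, history", {
  county <- county_at_origin()
  always <- plant_at_km(100)
  s <- annual_inverse_distance(pairs_within_radius(county, always, 200),
                               always, 1991:2018)
  sm <- trailing_mean(s, 10, out_years = 2000:2018)
  expect_equal(sm$value, rep(0.01, 19), tolerance = 1e-12)
  expect_equal(trailing_mean(s, 1)$value, s$inv_d)

  # taper: plant at 100 km, last operational year 2008 (decommission year
  # 2009): k years after the last full year the value is (10 - k)/10 * 0.01,
  # by explicit enumeration of the window contents
  closing <- plant_at_km(100, "P002", 1950, 2009)
  s2 <- annual_inverse_distance(pairs_within_radius(county, closing, 200),
                                closing, 1991:2025)
  sm2 <- trailing_mean(s2, 10)
  for (k in 0:10) {
    expect_equal(sm2$value[sm2$year == 2008 + k], (10 - k) / 10 * 0.01,
                 tolerance = 1e-12)
  }
  expect_equal(sm2$value[sm2$year == 2021], 0)

  expect_error(trailing_mean(s, 10, out_years = 1995:2018), "2000")
  expect_error(trailing_mean(s, 0), "window_years")
})

test_that("exposure aggregation is additive and matches a brute-force triple loop", {
  county <- county_at_origin()
  two <- dplyr::bind_rows(plant_at_km(100, "A"),
                          plant_at_km(100, "B") |> dplyr::mutate(lon = -lon))
  sm <- pairs_within_radius(county, two, 200) |>
    annual_inverse_distance(two, 1991:2018) |>
    trailing_mean(10, out_years = 2000:2018)
  E <- aggregate_exposure(sm, years = 2000:2018)
  expect_equal(E$exposure, rep(0.02, 19), tolerance = 1e-9)

  one <- plant_at_km(73, "C")
  sm1 <- pairs_within_radius(county, one, 200) |>
    annual_inverse_distance(one, 1991:2018) |>
    trailing_mean(10)
  E1 <- aggregate_exposure(sm1)
  expect_equal(E1$exposure, sm1$value)

  # random registry vs brute-force loop over plants x counties x years
  set.seed(41)
  counties <- tibble::tibble(fips = sprintf("%05d", 1:6),
                             lat = runif(6, 38, 41), lon = runif(6, -88, -84))
  plants <- tibble::tibble(
    plant_id = paste0("P", 1:4), name = plant_id,
    lat = runif(4, 38, 41), lon = runif(4, -88, -84),
    start_year = sample(1960:2005, 4, replace = TRUE),
    end_year = as.integer(c(NA, NA, 2008, 2013))
  )
  years <- 2000:2018
  window <- 10
  E <- compute_exposure(plants, counties, years, radius_km = 200,
                        window_years = window)
  brute <- matrix(0, nrow(counties), length(years),
                  dimnames = list(counties$fips, years))
  for (ci in seq_len(nrow(counties))) {
    for (pi in seq_len(nrow(plants))) {
      d <- slc_km(counties$lat[ci], counties$lon[ci],
                  plants$lat[pi], plants$lon[pi])
      if (d > 200) next
      for (t in years) {
        vals <- vapply((t - window + 1):t, function(yr) {
          on <- yr >= plants$start_year[pi] &&
            (is.na(plants$end_year[pi]) || yr < plants$end_year[pi])
          if (on) 1 / d else 0
        }, numeric(1))
        brute[ci, as.character(t)] <- brute[ci, as.character(t)] + mean(vals)
      }
    }
  }
  for (ci in counties$fips) {
    got <- E$exposure[E$fips == ci]
    expect_equal(got, unname(brute[ci, ]), tolerance = 1e-9)
  }

  dup <- dplyr::bind_rows(sm1, sm1)
  expect_error(aggregate_exposure(dup), "duplicate")
})

test_that("equivalent distance inverts the aggregated proximity", {
  expect_equal(equivalent_distance(0.02), 50)
  expect_equal(equivalent_distance(0.01), 100)
  expect_equal(equivalent_distance(0.01 + 0.005), 200 / 3, tolerance = 1e-12)
  expect_warning(out <- equivalent_distance(c(0.02, 0)), "undefined")
  expect_equal(out, c(50, NA))
  expect_error(equivalent_distance(-1), ">= 0")
})

test_that("exposure invariants: additivity, monotonicity, smoothing linearity, round trip", {
  set.seed(51)
  county <- county_at_origin()
  kms <- c(60, 110, 170)
  plants <- dplyr::bind_rows(lapply(seq_along(kms), function(i) {
    plant_at_km(kms[i], paste0("P", i), sample(1950:1995, 1),
                ifelse(i == 2, 2010L, NA_integer_))
  }))
  E_all <- compute_exposure(plants, county, 2000:2018)
  E_a <- compute_exposure(plants[1:2, ], county, 2000:2018)
  E_b <- compute_exposure(plants[3, ], county, 2000:2018)
  # additivity over disjoint plant sets
  expect_equal(E_all$exposure, E_a$exposure + E_b$exposure, tolerance = 1e-12)
  # adding a plant never decreases E
  expect_true(all(E_all$exposure >= E_a$exposure - 1e-12))
  # smooth-then-sum equals sum-then-smooth
  pairs <- pairs_within_radius(county, plants, 200)
  ann <- annual_inverse_distance(pairs, plants, 1991:2018)
  sum_then_smooth <- ann |>
    dplyr::group_by(fips, year) |>
    dplyr::summarise(inv_d = sum(inv_d), .groups = "drop") |>
    dplyr::mutate(plant_id = "ALL") |>
    trailing_mean(10, out_years = 2000:2018)
  expect_equal(E_all$exposure, sum_then_smooth$value, tolerance = 1e-12)
  # single always-operational plant: exact round trip to the plant distance
  single <- plant_at_km(137.5, "S", 1950)
  E1 <- compute_exposure(single, county, 2000:2018)
  d0 <- pairs_within_radius(county, single, 200)$distance_km
  expect_equal(equivalent_distance(E1$exposure), rep(d0, 19), tolerance = 1e-9)
})
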