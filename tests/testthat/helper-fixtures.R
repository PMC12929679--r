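# Shared fixture builders and independent oracles.

# longitude offset (degrees) giving an exact great-circle distance along the
# equator: arc length = R * dlambda
lon_at_km <- function(km) km / proxburden:::EARTH_RADIUS_KM * 180 / pi

# a county at the origin and plants at exact equatorial distances
county_at_origin <- function(fips = "00001") {
  tibble::tibble(fips = fips, lat = 0, lon = 0)
}

plant_at_km <- function(km, plant_id = "P001", start_year = 1950,
                        end_year = NA_integer_) {
  tibble::tibble(plant_id = plant_id, name = plant_id, lat = 0,
                 lon = lon_at_km(km), start_year = as.integer(start_year),
                 end_year = as.integer(end_year))
}

# independent spherical law-of-cosines distance (different formula from the
# haversine used by the implementation)
slc_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371.0088
  p1 <- c(lat1, lon1) * pi / 180
  p2 <- c(lat2, lon2) * pi / 180
  r * acos(pmin(1, sin(p1[1]) * sin(p2[1]) +
                  cos(p1[1]) * cos(p2[1]) * cos(p2[2] - p1[2])))
}

# independently coded dense GEE estimating-equation oracle: builds each
# cluster's working covariance explicitly and solves with generic linear
# algebra; shares no code path with gee_poisson()
gee_oracle <- function(y, X, offset, cluster, maxit = 200, tol = 1e-10) {
  cl <- factor(cluster)
  idx <- split(seq_along(y), cl)
  p <- ncol(X)
  beta <- coef(glm.fit(X, y, offset = offset, family = poisson()))
  alpha <- 0
  for (it in seq_len(maxit)) {
    mu <- exp(as.numeric(X %*% beta) + offset)
    r <- (y - mu) / sqrt(mu)
    phi <- sum(r^2) / (length(y) - p)
    num <- 0; den <- 0
    for (ii in idx) {
      ri <- r[ii]; ni <- length(ri)
      if (ni > 1) {
        num <- num + (sum(ri)^2 - sum(ri^2)) / 2
        den <- den + ni * (ni - 1) / 2
      }
    }
    alpha <- num / (phi * (den - p))
    B <- matrix(0, p, p); g <- numeric(p)
    for (ii in idx) {
      ni <- length(ii)
      Ri <- matrix(alpha, ni, ni); diag(Ri) <- 1
      Ai <- diag(mu[ii], ni)
      Vi <- phi * sqrt(Ai) %*% Ri %*% sqrt(Ai)
      Di <- Ai %*% X[ii, , drop = FALSE]
      Wi <- solve(Vi)
      B <- B + t(Di) %*% Wi %*% Di
      g <- g + t(Di) %*% Wi %*% (y[ii] - mu[ii])
    }
    delta <- solve(B, g)
    beta <- beta + as.numeric(delta)
    if (max(abs(delta)) < tol) break
  }
  mu <- exp(as.numeric(X %*% beta) + offset)
  B <- matrix(0, p, p); M <- matrix(0, p, p)
  for (ii in idx) {
    ni <- length(ii)
    Ri <- matrix(alpha, ni, ni); diag(Ri) <- 1
    Ai <- diag(mu[ii], ni)
    Vi <- phi * sqrt(Ai) %*% Ri %*% sqrt(Ai)
    Di <- Ai %*% X[ii, , drop = FALSE]
    Wi <- solve(Vi)
    gi <- t(Di) %*% Wi %*% (y[ii] - mu[ii])
    B <- B + t(Di) %*% Wi %*% Di
    M <- M + gi %*% t(gi)
  }
  Binv <- solve(B)
  list(beta = beta, vcov_robust = Binv %*% M %*% Binv, alpha = alpha)
}

# minimal gee_fit stand-in with a chosen exposure coefficient and SE, for
# exercising downstream burden arithmetic in isolation
fake_fit <- function(beta_e, se_e, age_group = "65-74", sex = "F") {
  beta <- c("(Intercept)" = -6, exposure = beta_e)
  V <- diag(c(1e-4, se_e^2))
  dimnames(V) <- list(names(beta), names(beta))
  structure(list(beta = beta, vcov_robust = V, vcov_naive = V, alpha = 0,
                 phi = 1, n_iter = 1L, converged = TRUE, n = 1L,
                 n_clusters = 2L,
                 stratum = c(age_group = age_group, sex = sex),
                 corstr = "exchangeable", dropped = character(),
                 covariates = character()),
            class = "gee_fit")
}

# small complete study for reuse across tests (cheap: ~60 counties)
small_study <- function(seed = 101, n_counties = 60, n_plants = 4, ...) {
  simulate_study(sim_config(seed = seed, n_counties = n_counties,
                            n_plants = n_plants, ...))
}
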