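stratum_panel <- function(seed = 101, ...) {
  st <- small_study(seed = seed, ...)
  dplyr::filter(st$panel, age_group == "65-74", sex == "F")
}

test_that("independence GEE equals the Poisson GLM oracle, including one row per cluster", {
  pan <- stratum_panel()
  f <- fit_stratum(pan, corstr = "independence")
  g <- glm(deaths ~ X1 + X2 + X3 + exposure + offset(log(population)),
           poisson, data = pan)
  expect_equal(unname(f$beta), unname(coef(g)), tolerance = 1e-6)

  one_per <- dplyr::filter(pan, year == 2005)
  f1 <- fit_stratum(one_per, corstr = "independence")
  g1 <- glm(deaths ~ X1 + X2 + X3 + exposure + offset(log(population)),
            poisson, data = one_per)
  expect_equal(unname(f1$beta), unname(coef(g1)), tolerance = 1e-6)
})

test_that("the exchangeable solver matches an independently coded estimating-equation oracle", {
  pan <- stratum_panel(seed = 103, n_counties = 25, n_plants = 3)
  f <- fit_stratum(pan)
  X <- cbind(1, as.matrix(pan[, c("X1", "X2", "X3", "exposure")]))
  o <- gee_oracle(pan$deaths, X, log(pan$population), pan$fips)
  expect_equal(unname(f$beta), unname(o$beta), tolerance = 1e-7)
  expect_equal(f$alpha, o$alpha, tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(f$vcov_robust))),
               unname(sqrt(diag(o$vcov_robust))), tolerance = 1e-6)
})

test_that("multiplying populations by k shifts only the intercept, by -log(k)", {
  pan <- stratum_panel()
  f0 <- fit_stratum(pan)
  pan2 <- dplyr::mutate(pan, population = population * 7)
  f2 <- fit_stratum(pan2)
  expect_equal(f2$beta[["(Intercept)"]], f0$beta[["(Intercept)"]] - log(7),
               tolerance = 1e-8)
  keep <- setdiff(names(f0$beta), "(Intercept)")
  expect_equal(f2$beta[keep], f0$beta[keep], tolerance = 1e-8)
})

test_that("an all-zero exposure column is dropped with a flag; the rest matches the reduced model", {
  pan <- dplyr::mutate(stratum_panel(), exposure = 0)
  f <- fit_stratum(pan, corstr = "independence")
  expect_equal(f$dropped, "exposure")
  expect_false("exposure" %in% names(f$beta))
  g <- glm(deaths ~ X1 + X2 + X3 + offset(log(population)), poisson, data = pan)
  expect_equal(unname(f$beta), unname(coef(g)), tolerance = 1e-6)
  expect_error(wald_ci(f, "exposure"), "unknown coefficient")
})

test_that("rank deficiency is an error naming the collinear column", {
  pan <- dplyr::mutate(stratum_panel(), X4 = X1)
  expect_error(fit_stratum(pan, covariates = c("X1", "X2", "X3", "X4")),
               "collinear.*X4")
})

test_that("Wald intervals use the robust SE and standard-normal quantiles", {
  f <- fake_fit(beta_e = 0, se_e = 1)
  ci <- wald_ci(f, "exposure", level = 0.95)
  expect_equal(unname(ci[c("low", "high")]),
               c(-1, 1) * qnorm(0.975), tolerance = 1e-10)
  f0 <- fake_fit(beta_e = 2, se_e = 0)
  ci0 <- wald_ci(f0, "exposure")
  expect_equal(unname(ci0[["low"]]), 2)
  expect_equal(unname(ci0[["high"]]), 2)
  expect_error(wald_ci(f, "nope"), "unknown coefficient")
})

test_that("fits are invariant to row order and cluster relabeling", {
  pan <- stratum_panel()
  f0 <- fit_stratum(pan)
  set.seed(81)
  perm <- pan[sample.int(nrow(pan)), ]
  f1 <- fit_stratum(perm)
  expect_equal(f0$beta, f1$beta, tolerance = 1e-9)
  expect_equal(f0$vcov_robust, f1$vcov_robust, tolerance = 1e-9)
  relab <- dplyr::mutate(pan, fips = paste0("Z", fips))
  f2 <- fit_stratum(relab)
  expect_equal(f0$beta, f2$beta, tolerance = 1e-9)
})

test_that("non-convergence is flagged, not silent; tiny cluster counts error", {
  pan <- stratum_panel()
  expect_warning(f <- fit_stratum(pan, maxit = 1), "did not converge")
  expect_false(f$converged)
  one_cluster <- dplyr::filter(pan, fips == pan$fips[1])
  expect_error(fit_stratum(one_cluster), "2 clusters")
})

test_that("fit_all_strata fits each stratum separately; tidy/glance expose the results", {
  st <- small_study(seed = 107)
  fits <- fit_all_strata(st$panel)
  expect_equal(nrow(fits), 12)
  td <- tidy(fits)
  expect_true(all(c("age_group", "sex", "term", "estimate", "std.error",
                    "conf.low", "conf.high") %in% names(td)))
  expect_equal(nrow(dplyr::filter(td, term == "exposure")), 12)
  one <- dplyr::filter(st$panel, age_group == "55-64", sex == "M")
  f_direct <- fit_stratum(one)
  f_from_all <- fits$fit[[which(fits$age_group == "55-64" & fits$sex == "M")]]
  expect_equal(f_direct$beta, f_from_all$beta, tolerance = 1e-10)
  gl <- glance(f_direct)
  expect_equal(gl$n_clusters, dplyr::n_distinct(one$fips))
  expect_true(gl$converged)
  sm <- fits_summary(fits)
  expect_true(all(c("age_group", "sex", "term", "estimate", "robust_se",
                    "ci_low", "ci_high", "n_rows", "n_clusters",
                    "converged") %in% names(sm)))
})

test_that("robust covariance is symmetric PSD and CI bounds are ordered", {
  pan <- stratum_panel()
  f <- fit_stratum(pan)
  expect_equal(f$vcov_robust, t(f$vcov_robust))
  expect_true(all(eigen(f$vcov_robust, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))
  ci <- wald_ci(f)
  expect_lt(ci[["low"]], ci[["high"]])
})
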