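# Poisson generalized estimating equations with log link, log-population
# offset, exchangeable within-cluster working correlation and robust sandwich
# covariance. The solver is written against the estimating equations directly;
# the exchangeable working correlation is inverted in closed form
# (Sherman-Morrison), so each iteration is a handful of cross-products.

#' Poisson GEE solver
#'
#' Solves the generalized estimating equations for a log-link Poisson marginal
#' model with an offset and a working correlation that is either exchangeable
#' within clusters or independence. Iterates Fisher-scoring-type updates with
#' the correlation parameter re-estimated each step from Pearson residuals by
#' the standard moment estimator; starting values come from the independence
#' GLM fit. Convergence is declared when the relative coefficient change drops
#' below `tol`.
#'
#' @param y Nonnegative integer response vector (death counts).
#' @param X Design matrix including the intercept column.
#' @param offset Numeric offset vector on the log scale (log population).
#' @param cluster Cluster identifier vector (county), same length as `y`.
#' @param corstr `"exchangeable"` or `"independence"`.
#' @param tol Convergence tolerance on the relative coefficient change.
#' @param maxit Maximum number of iterations.
#' @return List with `beta`, `vcov_robust` (sandwich), `vcov_naive`
#'   (model-based), `alpha` (working correlation), `phi` (dispersion),
#'   `n_iter`, `converged`, `n`, `n_clusters`.
#' @export
gee_poisson <- function(y, X, offset, cluster,
                        corstr = c("exchangeable", "independence"),
                        tol = 1e-8, maxit = 100L) {
  corstr <- match.arg(corstr)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  cl <- factor(cluster)
  K <- nlevels(cl)
  if (K < 2) abort("at least 2 clusters are required")
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  n_i <- as.numeric(table(cl))
  # independence GLM starting values
  beta <- as.numeric(coef(stats::glm.fit(X, y, offset = offset,
                                         family = poisson())))
  alpha <- 0
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta) + offset
    mu <- exp(eta)
    sqmu <- sqrt(mu)
    r <- (y - mu) / sqmu
    phi <- sum(r^2) / (n - p)
    if (corstr == "exchangeable") {
      sum_r <- as.numeric(rowsum(r, cl))
      sum_r2 <- as.numeric(rowsum(r^2, cl))
      n_pairs <- sum(n_i * (n_i - 1)) / 2
      alpha <- sum(sum_r^2 - sum_r2) / 2 / (phi * (n_pairs - p))
      # keep the working correlation invertible
      alpha <- min(max(alpha, -1 / (max(n_i) - 1) + 1e-6), 1 - 1e-6)
    }
    U <- X * sqmu
    z <- r
    S <- rowsum(U, cl)                    # per-cluster column sums of U
    t_i <- as.numeric(rowsum(z, cl))      # per-cluster residual sums
    c2 <- alpha / (1 - alpha + n_i * alpha)
    B <- (crossprod(U) - t(S) %*% (c2 * S)) / ((1 - alpha) * phi)
    g <- (crossprod(U, z) - t(S) %*% (c2 * t_i)) / ((1 - alpha) * phi)
    delta <- solve(B, g)
    beta <- beta + as.numeric(delta)
    if (max(abs(delta) / pmax(abs(beta), 1)) < tol) {
      converged <- TRUE
      break
    }
  }
  # final quantities at the converged coefficients
  eta <- as.numeric(X %*% beta) + offset
  mu <- exp(eta)
  sqmu <- sqrt(mu)
  z <- (y - mu) / sqmu
  phi <- sum(z^2) / (n - p)
  U <- X * sqmu
  S <- rowsum(U, cl)
  t_i <- as.numeric(rowsum(z, cl))
  c2 <- alpha / (1 - alpha + n_i * alpha)
  B <- (crossprod(U) - t(S) %*% (c2 * S)) / ((1 - alpha) * phi)
  # per-cluster score contributions -> sandwich meat
  G <- (rowsum(U * z, cl) - (c2 * t_i) * S) / ((1 - alpha) * phi)
  Binv <- solve(B)
  vcov_robust <- Binv %*% crossprod(G) %*% Binv
  vcov_robust <- (vcov_robust + t(vcov_robust)) / 2
  dimnames(vcov_robust) <- list(colnames(X), colnames(X))
  vcov_naive <- Binv
  dimnames(vcov_naive) <- dimnames(vcov_robust)
  list(beta = setNames(beta, colnames(X)), vcov_robust = vcov_robust,
       vcov_naive = vcov_naive, alpha = if (corstr == "exchangeable") alpha else 0,
       phi = phi, n_iter = iter, converged = converged, n = n, n_clusters = K)
}

#' Fit the stratum-level Poisson GEE model
#'
#' Fits, for the rows of one age-sex stratum, a log-link Poisson marginal
#' model of death counts on exposure and covariates with a log-population
#' offset, clustered by county with exchangeable working correlation, and
#' robust (sandwich) standard errors. A constant-zero exposure column is
#' dropped from the design with a flag rather than producing a singular fit.
#'
#' @param data Stratum panel rows (one age-sex stratum) with columns `fips`,
#'   `deaths`, `population`, `exposure` and the covariates.
#' @param covariates Character vector of covariate column names; by default
#'   every column not among the standard panel keys is used.
#' @param corstr Working correlation, `"exchangeable"` (default) or
#'   `"independence"`.
#' @param tol,maxit Convergence controls passed to [gee_poisson()].
#' @return Object of class `gee_fit`: coefficient vector, robust and naive
#'   covariance, working-correlation and dispersion estimates, stratum label,
#'   convergence flag, and the names of any dropped terms.
#' @export
fit_stratum <- function(data, covariates = NULL,
                        corstr = c("exchangeable", "independence"),
                        tol = 1e-8, maxit = 100L) {
  corstr <- match.arg(corstr)
  if (dplyr::n_distinct(data$age_group) > 1 || dplyr::n_distinct(data$sex) > 1) {
    abort("fit_stratum expects rows from a single age-sex stratum; see fit_all_strata()")
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(data), c("fips", "year", "age_group", "sex",
                                         "deaths", "population", "exposure"))
  }
  terms <- c(covariates, "exposure")
  X <- cbind("(Intercept)" = 1, as.matrix(data[, terms, drop = FALSE]))
  dropped <- character()
  const0 <- apply(X[, -1, drop = FALSE], 2, function(col) all(col == 0))
  if (any(const0)) {
    dropped <- names(const0)[const0]
    X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
  }
  fit <- gee_poisson(data$deaths, X, offset = log(data$population),
                     cluster = data$fips, corstr = corstr,
                     tol = tol, maxit = maxit)
  if (!fit$converged) {
    warn(sprintf("GEE did not converge in %d iterations", fit$n_iter))
  }
  structure(c(fit, list(
    stratum = c(age_group = as.character(data$age_group[1]),
                sex = as.character(data$sex[1])),
    corstr = corstr, dropped = dropped, covariates = covariates
  )), class = "gee_fit")
}

#' Fit one GEE model per age-sex stratum
#'
#' Runs [fit_stratum()] separately for every age-sex combination in the panel
#' (separate models, never a pooled model with interactions).
#'
#' @param panel Stratum panel tibble.
#' @inheritParams fit_stratum
#' @return Tibble of class `gee_fits` with columns `age_group`, `sex` and a
#'   `fit` list-column of `gee_fit` objects.
#' @export
fit_all_strata <- function(panel, covariates = NULL,
                           corstr = c("exchangeable", "independence"),
                           tol = 1e-8, maxit = 100L) {
  corstr <- match.arg(corstr)
  out <- panel |>
    dplyr::group_by(.data$age_group, .data$sex) |>
    dplyr::group_modify(function(rows, key) {
      rows$age_group <- key$age_group
      rows$sex <- key$sex
      tibble::tibble(fit = list(fit_stratum(rows, covariates = covariates,
                                            corstr = corstr, tol = tol,
                                            maxit = maxit)))
    }) |>
    dplyr::ungroup()
  class(out) <- c("gee_fits", class(out))
  out
}

#' Wald confidence interval for a fitted coefficient
#'
#' Two-sided interval `estimate +/- z * SE` using the robust (sandwich)
#' standard error and a standard-normal quantile.
#'
#' @param fit A `gee_fit`.
#' @param coefficient Coefficient name (default `"exposure"`).
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(estimate, low, high)`.
#' @export
wald_ci <- function(fit, coefficient = "exposure", level = 0.95) {
  if (!coefficient %in% names(fit$beta)) {
    abort(sprintf("unknown coefficient '%s'; available: %s", coefficient,
                  paste(names(fit$beta), collapse = ", ")))
  }
  est <- fit$beta[[coefficient]]
  se <- sqrt(fit$vcov_robust[coefficient, coefficient])
  zq <- qnorm(1 - (1 - level) / 2)
  c(estimate = est, low = est - zq * se, high = est + zq * se)
}

#' Tidy a stratum GEE fit
#'
#' @param x A `gee_fit`.
#' @param conf.int Add robust Wald confidence bounds (default `TRUE`).
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error` (robust), `statistic`,
#'   `p.value` and optionally `conf.low`/`conf.high`.
#' @export
tidy.gee_fit <- function(x, conf.int = TRUE, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$vcov_robust))
  out <- tibble::tibble(
    term = names(x$beta), estimate = as.numeric(x$beta),
    std.error = as.numeric(se),
    statistic = .data$estimate / .data$std.error,
    p.value = 2 * stats::pnorm(-abs(.data$statistic))
  )
  if (conf.int) {
    zq <- qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - zq * out$std.error
    out$conf.high <- out$estimate + zq * out$std.error
  }
  out
}

#' One-row summary of a stratum GEE fit
#'
#' @param x A `gee_fit`.
#' @param ... Unused.
#' @return Tibble with stratum labels, sizes, working-correlation and
#'   dispersion estimates, iteration count and convergence flag.
#' @export
glance.gee_fit <- function(x, ...) {
  tibble::tibble(
    age_group = x$stratum[["age_group"]], sex = x$stratum[["sex"]],
    n_rows = x$n, n_clusters = x$n_clusters, alpha = x$alpha, phi = x$phi,
    n_iter = x$n_iter, converged = x$converged
  )
}

#' Tidy every stratum fit in a `gee_fits` table
#'
#' @param x A `gee_fits` tibble from [fit_all_strata()].
#' @param ... Passed to [tidy.gee_fit()].
#' @return Tibble of per-stratum coefficient rows with `age_group` and `sex`.
#' @export
tidy.gee_fits <- function(x, ...) {
  purrr::map2_dfr(seq_len(nrow(x)), x$fit, function(i, fit) {
    dplyr::bind_cols(x[i, c("age_group", "sex")], tidy(fit, ...))
  })
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("Poisson GEE fit (%s working correlation), stratum %s/%s\n",
              x$corstr, x$stratum[["age_group"]], x$stratum[["sex"]]))
  cat(sprintf("  %d rows in %d county clusters; alpha = %.4f, phi = %.3f; %s\n",
              x$n, x$n_clusters, x$alpha, x$phi,
              if (x$converged) sprintf("converged in %d iterations", x$n_iter)
              else "DID NOT CONVERGE"))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Coefficient table for a set of stratum fits
#'
#' Flattens a `gee_fits` table into the on-disk summary schema
#' (`age_group,sex,term,estimate,robust_se,ci_low,ci_high,n_rows,n_clusters,converged`).
#'
#' @param fits A `gee_fits` tibble.
#' @param conf.level Confidence level for the Wald bounds.
#' @return Tibble in the fits-summary schema.
#' @export
fits_summary <- function(fits, conf.level = 0.95) {
  purrr::map2_dfr(seq_len(nrow(fits)), fits$fit, function(i, fit) {
    td <- tidy(fit, conf.int = TRUE, conf.level = conf.level)
    tibble::tibble(
      age_group = fits$age_group[i], sex = fits$sex[i], term = td$term,
      estimate = td$estimate, robust_se = td$std.error,
      ci_low = td$conf.low, ci_high = td$conf.high,
      n_rows = fit$n, n_clusters = fit$n_clusters, converged = fit$converged
    )
  })
}
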