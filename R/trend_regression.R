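## Trend by regression on design-based annual status estimates: simple
## (SLRDB) and inverse-variance weighted (WLRDB) least squares of the annual
## Horvitz-Thompson means on year.

check_series <- function(series, need_var = FALSE) {
  stopifnot(is.data.frame(series),
            all(c("year", "mu_hat") %in% names(series)))
  if (is.unsorted(series$year, strictly = TRUE)) {
    stop("status series years must be strictly increasing")
  }
  if (nrow(series) < 3) stop("at least 3 annual estimates required (no residual df otherwise)")
  if (need_var) {
    if (!"v_nbh" %in% names(series)) stop("series lacks v_nbh variances")
    if (any(series$v_nbh <= 0)) stop("all neighborhood variances must be positive for WLRDB")
  }
  invisible(series)
}

regress_status <- function(series, weights, method, conf_level, ar1) {
  n <- nrow(series)
  dat <- data.frame(mu = series$mu_hat, xj = series$year)
  fit <- if (is.null(weights)) stats::lm(mu ~ xj, data = dat)
         else stats::lm(mu ~ xj, data = dat, weights = weights)
  if (ar1) {
    # Experimental Cochrane-Orcutt style AR(1) hook; off by default and not
    # part of the estimator comparison.
    r <- stats::residuals(fit)
    rho <- sum(r[-1] * r[-n]) / sum(r^2)
    mu2 <- dat$mu[-1] - rho * dat$mu[-n]
    x2 <- dat$xj[-1] - rho * dat$xj[-n]
    fit <- stats::lm(mu2 ~ x2)
    co <- stats::coef(summary(fit))[2, ]
    return(new_trend_fit(co[["Estimate"]], co[["Std. Error"]], n - 3,
                         conf_level, method = paste0(method, "-AR1"),
                         n_years = n, notes = "AR(1) pre-transformed"))
  }
  co <- stats::coef(summary(fit))["xj", ]
  new_trend_fit(co[["Estimate"]], co[["Std. Error"]], n - 2, conf_level,
                method = method, model = fit, n_years = n)
}

#' Simple linear regression of design-based status estimates (SLRDB)
#'
#' Ordinary least squares of the annual status estimates \eqn{\hat\mu_j} on
#' year; the slope's Wald t statistic is referred to a t distribution with
#' `n - 2` degrees of freedom (n = number of annual estimates).
#'
#' @param series A [status_series()] result (or data.frame with `year`,
#'   `mu_hat`).
#' @param conf_level Confidence level for the slope interval (default 0.90).
#' @param ar1 Apply an experimental AR(1) pre-transformation (default
#'   `FALSE`; annual estimates are treated as independent).
#' @return A `trend_fit` with method `"SLRDB"`.
#' @export
fit_slrdb <- function(series, conf_level = 0.90, ar1 = FALSE) {
  check_series(series)
  regress_status(series, NULL, "SLRDB", conf_level, ar1)
}

#' Weighted linear regression of design-based status estimates (WLRDB)
#'
#' Weighted least squares of \eqn{\hat\mu_j} on year with weights
#' \eqn{1/\hat V_{NBH}(\hat\mu_j)}. Weights are treated as known up to a
#' constant: the residual scale is re-estimated on `n - 2` degrees of
#' freedom, matching the SLRDB reference distribution.
#'
#' @inheritParams fit_slrdb
#' @return A `trend_fit` with method `"WLRDB"`.
#' @export
fit_wlrdb <- function(series, conf_level = 0.90, ar1 = FALSE) {
  check_series(series, need_var = TRUE)
  regress_status(series, 1 / series$v_nbh, "WLRDB", conf_level, ar1)
}
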