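## Synthetic finite populations of lake-like monitoring sites and log-scale
## responses from the random-coefficients trend model.

#' Specify the generating trend model
#'
#' Defines the linear mixed trend model used to simulate log-scale responses
#' over a finite population of sites:
#' \deqn{y_{ij} = \gamma_0 + x_j(\gamma_1 + \Delta_i) + b_j + a_i + x_j t_i + e_{ij}}
#' where \eqn{b_j} is a shared random year effect, \eqn{(a_i, t_i)} are
#' correlated random site intercepts and slopes, \eqn{e_{ij}} is residual
#' noise, and \eqn{\Delta_i} is an extra slope applied to a named
#' subpopulation (by default the high-elevation stratum).
#'
#' On the natural-log scale an annual trend of \eqn{r}\% corresponds to a
#' slope of \eqn{\log(1 + r/100)}. The default year-to-year variance 0.0157
#' reflects a high year-variance water-chemistry indicator (log acid
#' neutralizing capacity); the remaining component defaults (`sigma2_a` =
#' 0.5, `sigma2_t` = 5e-4, `sigma_at` = 0, `sigma2_e` = 0.1) are documented
#' stand-ins at realistic orders of magnitude for log-scale lake chemistry,
#' not estimates from any particular survey.
#'
#' @param gamma0 Fixed intercept (log units).
#' @param gamma1 Fixed slope (log units per year); use `log(1 + r/100)` for an
#'   `r`% annual trend.
#' @param sigma2_b Year-to-year variance of the shared year effect.
#' @param sigma2_a Site-to-site variance of the random intercept.
#' @param sigma2_t Variance of the random site slope.
#' @param sigma_at Covariance of random site intercept and slope.
#' @param sigma2_e Residual variance.
#' @param subpop_trend_delta Additional log-scale slope applied to sites in
#'   `subpop`.
#' @param subpop Either the name of a stratum (default `"high"`) or a
#'   predicate `function(frame)` returning a logical vector of member sites.
#' @param years Ordered numeric vector of location-shifted year values
#'   \eqn{x_j} (0-based by convention).
#' @return An object of class `population_model`.
#' @export
population_model <- function(gamma0 = 4, gamma1 = 0,
                             sigma2_b = 0.0157, sigma2_a = 0.5,
                             sigma2_t = 5e-4, sigma_at = 0,
                             sigma2_e = 0.1,
                             subpop_trend_delta = 0, subpop = "high",
                             years = 0:11) {
  vars <- c(sigma2_b = sigma2_b, sigma2_a = sigma2_a,
            sigma2_t = sigma2_t, sigma2_e = sigma2_e)
  if (any(vars < 0)) stop("variance components must be nonnegative")
  S <- matrix(c(sigma2_a, sigma_at, sigma_at, sigma2_t), 2, 2)
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-12) {
    stop("site random-effect covariance matrix is not positive semidefinite")
  }
  stopifnot(length(years) >= 1, !is.unsorted(years, strictly = TRUE))
  structure(list(gamma0 = gamma0, gamma1 = gamma1,
                 sigma2_b = sigma2_b, sigma2_a = sigma2_a,
                 sigma2_t = sigma2_t, sigma_at = sigma_at,
                 sigma2_e = sigma2_e,
                 subpop_trend_delta = subpop_trend_delta, subpop = subpop,
                 years = years),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Generating trend model (log scale)\n")
  cat(sprintf("  gamma0 = %.4g, gamma1 = %.6g (%.2f%%/yr)\n",
              x$gamma0, x$gamma1, 100 * (exp(x$gamma1) - 1)))
  cat(sprintf("  var components: b %.4g | a %.4g | t %.4g | at %.4g | e %.4g\n",
              x$sigma2_b, x$sigma2_a, x$sigma2_t, x$sigma_at, x$sigma2_e))
  cat(sprintf("  years x_j: %s ... %s (%d)\n",
              x$years[1], x$years[length(x$years)], length(x$years)))
  if (x$subpop_trend_delta != 0) {
    cat(sprintf("  subpopulation extra slope: %.6g\n", x$subpop_trend_delta))
  }
  invisible(x)
}

#' Shift year-to-year variance into site-to-site variance
#'
#' Returns a modified generating model whose year variance is reduced to
#' `new_sigma2_b`, with the reduction added to the site-intercept variance so
#' that the total variance \eqn{\sigma_b^2+\sigma_a^2+\sigma_t^2+\sigma_e^2}
#' is preserved exactly. This emulates constructing a "low year-variance"
#' counterpart of an indicator (e.g., reducing 0.0157 to 0.0001 moves 0.0156
#' into the site component).
#'
#' @param model A [population_model()].
#' @param new_sigma2_b New year variance; must not exceed the current one.
#' @return A `population_model` with the modified composition.
#' @export
modify_variance_composition <- function(model, new_sigma2_b) {
  stopifnot(inherits(model, "population_model"))
  if (new_sigma2_b > model$sigma2_b) {
    stop("new year variance exceeds the current one; total variance would change")
  }
  if (new_sigma2_b < 0) stop("variance must be nonnegative")
  transfer <- model$sigma2_b - new_sigma2_b
  out <- model
  out$sigma2_b <- new_sigma2_b
  out$sigma2_a <- model$sigma2_a + transfer
  out
}

#' Build a synthetic sampling frame of discrete sites
#'
#' Constructs a finite population emulating a mountain-lake frame: planar
#' coordinates uniform on the unit square, elevations split into high/low
#' strata at a cutoff (default 3100 m), six travel-cost classes whose
#' population shares follow `cost_spec`, and — when a generating model is
#' supplied — latent bivariate-normal site intercept/slope deviations. The
#' travel-time proxy used to form cost classes is a monotone function of
#' elevation plus noise tuned to a Pearson correlation of about 0.72, so the
#' unequal-probability design undersamples high-elevation sites.
#'
#' @param n_sites Number of sites in the frame (default 684).
#' @param strata_spec Named vector (`high`, `low`) of stratum counts or
#'   proportions; default 598 high / 86 low.
#' @param cost_spec Six cost-class population shares, low- to high-cost;
#'   default 6/13/29/25/18/8 (percent; normalized internally).
#' @param model Optional [population_model()]; when given, latent `a_i`,
#'   `t_i` are drawn from its site covariance, otherwise they are zero.
#' @param elev_cutoff Elevation (m) separating the high stratum.
#' @param seed Optional integer seed; `NULL` continues the current RNG stream.
#' @return A `data.frame` of class `population_frame` with columns
#'   `site_id`, `x`, `y`, `elevation`, `stratum`, `cost_class`, `travel`
#'   (standardized travel-time proxy), `a_i`, `t_i`.
#' @export
build_frame <- function(n_sites = 684,
                        strata_spec = c(high = 598, low = 86),
                        cost_spec = c(6, 13, 29, 25, 18, 8),
                        model = NULL, elev_cutoff = 3100, seed = NULL) {
  stopifnot(n_sites >= 1)
  if (!is.null(seed)) set.seed(seed)

  ## stratum counts: accept counts or proportions
  if (is.null(names(strata_spec))) names(strata_spec) <- c("high", "low")[seq_along(strata_spec)]
  if (all(strata_spec <= 1)) {
    p <- normalize_props(strata_spec, "stratum proportions")
    counts <- largest_remainder(n_sites, p)
  } else {
    counts <- as.integer(round(strata_spec))
    if (sum(counts) != n_sites) {
      stop(sprintf("stratum counts sum to %d but n_sites = %d", sum(counts), n_sites))
    }
  }
  names(counts) <- names(strata_spec)
  if (any(counts < 0)) stop("negative stratum count")

  cost_p <- normalize_props(cost_spec, "cost-class proportions")
  if (length(cost_p) < 1) stop("cost_spec must be non-empty")
  class_counts <- largest_remainder(n_sites, cost_p)

  x <- stats::runif(n_sites)
  y <- stats::runif(n_sites)

  ## elevation as a two-component mixture reproducing the stratum split
  stratum <- rep(names(counts), counts)
  stratum <- sample(stratum)           # random spatial interleaving
  elevation <- numeric(n_sites)
  hi <- stratum == "high"
  elevation[hi] <- elev_cutoff + stats::runif(sum(hi), 0, 800)
  elevation[!hi] <- elev_cutoff - stats::runif(sum(!hi), 1, 1400)
  if (length(counts) == 1) {
    # degenerate single-stratum frames: label only, all on one side
    if (names(counts) == "low") elevation <- elev_cutoff - stats::runif(n_sites, 1, 1400)
  }

  ## travel-time proxy: monotone in elevation + noise, target r ~ 0.72
  ez <- as.vector(scale(elevation))
  if (any(!is.finite(ez))) ez <- rep(0, n_sites)
  r_target <- 0.72
  travel <- r_target * ez + sqrt(1 - r_target^2) * stats::rnorm(n_sites)
  cost_class <- integer(n_sites)
  ord <- order(travel, seq_len(n_sites))
  cost_class[ord] <- rep(seq_along(class_counts), class_counts)

  a_i <- t_i <- numeric(n_sites)
  if (!is.null(model)) {
    stopifnot(inherits(model, "population_model"))
    S <- matrix(c(model$sigma2_a, model$sigma_at,
                  model$sigma_at, model$sigma2_t), 2, 2)
    ev <- eigen(S, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) # PSD-safe root
    at <- matrix(stats::rnorm(2 * n_sites), n_sites, 2) %*% t(L)
    a_i <- at[, 1]
    t_i <- at[, 2]
  }

  out <- data.frame(site_id = seq_len(n_sites), x = x, y = y,
                    elevation = elevation, stratum = stratum,
                    cost_class = cost_class, travel = travel,
                    a_i = a_i, t_i = t_i,
                    stringsAsFactors = FALSE)
  attr(out, "elev_cutoff") <- elev_cutoff
  class(out) <- c("population_frame", "data.frame")
  out
}

#' Population sizes by stratum
#'
#' @param frame A [build_frame()] result.
#' @return Named integer vector of stratum sizes (sorted by label).
#' @export
stratum_sizes <- function(frame) {
  tab <- table(frame$stratum)
  stats::setNames(as.integer(tab), names(tab))
}

# Logical membership vector for the model's subpopulation.
subpop_members <- function(frame, model) {
  if (is.function(model$subpop)) {
    m <- model$subpop(frame)
    stopifnot(is.logical(m), length(m) == nrow(frame))
    m
  } else {
    frame$stratum == model$subpop
  }
}

#' Simulate log-scale responses for every site and year
#'
#' Generates the full population response surface
#' \eqn{y_{ij} = \gamma_0 + x_j(\gamma_1+\Delta_i) + b_j + a_i + x_j t_i + e_{ij}}
#' with the year effect \eqn{b_j} shared by all sites within a year and site
#' effects \eqn{(a_i, t_i)} taken from the frame.
#'
#' @param frame A [build_frame()] result (its `a_i`, `t_i` columns are used).
#' @param model A [population_model()].
#' @param seed Optional integer seed; `NULL` continues the current stream.
#' @param keep_effects If `TRUE`, attach the realized `b_j` and residual
#'   draws as attributes `"b_j"` and `"e_ij"` (useful for diagnostics).
#' @return Numeric matrix (sites in rows, years in columns, log scale) with
#'   `dimnames` `site_id` x `x_j`.
#' @export
simulate_response <- function(frame, model, seed = NULL, keep_effects = FALSE) {
  stopifnot(inherits(frame, "population_frame"), inherits(model, "population_model"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(frame)
  xj <- model$years
  J <- length(xj)
  b <- stats::rnorm(J, 0, sqrt(model$sigma2_b))
  e <- matrix(stats::rnorm(n * J, 0, sqrt(model$sigma2_e)), n, J)
  delta <- ifelse(subpop_members(frame, model), model$subpop_trend_delta, 0)
  slope_i <- model$gamma1 + delta + frame$t_i
  ymat <- model$gamma0 + frame$a_i + outer(slope_i, xj) +
    matrix(b, n, J, byrow = TRUE) + e
  dimnames(ymat) <- list(site_id = frame$site_id, x_j = xj)
  if (keep_effects) {
    attr(ymat, "b_j") <- b
    attr(ymat, "e_ij") <- e
  }
  ymat
}
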