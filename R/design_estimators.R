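## Design-based annual status estimation: Horvitz-Thompson means and the
## local-neighborhood variance estimator for spatially balanced samples.

#' Horvitz-Thompson estimator of a mean
#'
#' \deqn{\hat\mu = \sum_i (y_i/\pi_i) / \sum_i (1/\pi_i)}
#'
#' @param y Observed responses.
#' @param pi Inclusion probabilities, one per observation, all positive.
#' @return The estimated mean.
#' @export
ht_mean <- function(y, pi) {
  if (!length(y)) stop("empty input")
  if (length(pi) != length(y)) stop("y and pi lengths differ")
  if (any(pi <= 0)) stop("inclusion probabilities must be positive")
  sum(y / pi) / sum(1 / pi)
}

# Doubly stochastic neighborhood weight matrix: each site's neighborhood is
# itself plus its (nbh_size - 1) nearest sampled neighbors (Euclidean, ties
# by position), uniform initial weights, then iterative proportional scaling
# until row and column sums are both 1.
neighborhood_weights <- function(coords, nbh_size = 4) {
  n <- nrow(coords)
  m <- min(nbh_size, n)
  d <- as.matrix(stats::dist(coords))
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ], seq_len(n))[seq_len(m)]
    A[i, nb] <- TRUE
  }
  A <- A | t(A)              # symmetric pattern so the scaling has a limit
  W <- A / rowSums(A)
  for (it in seq_len(1000)) {
    W <- sweep(W, 2, colSums(W), "/")
    W <- W / rowSums(W)      # end on rows: row sums are exactly 1
    if (max(abs(colSums(W) - 1)) < 1e-12) break
  }
  W
}

#' Local-neighborhood variance of a Horvitz-Thompson mean
#'
#' Variance estimator for spatially balanced samples built from weighted
#' contrasts of \eqn{y_i/\pi_i} within small spatial neighborhoods. Each
#' neighborhood is the site plus its three nearest sampled neighbors;
#' neighborhood weights start uniform and are proportionally scaled until
#' both row and column sums equal 1. The variance of the weighted total,
#' \deqn{\sum_i \sum_{j \in D_i} v_{ij}\,(y_j/\pi_j - \textstyle\sum_{k \in D_i} v_{ik} y_k/\pi_k)^2,}
#' is divided by \eqn{(\sum_i 1/\pi_i)^2} to give the variance of the mean.
#' Returns exactly 0 when all \eqn{y_i/\pi_i} are equal.
#'
#' @param y Observed responses (at least 2).
#' @param pi Positive inclusion probabilities.
#' @param coords Two-column matrix (or data.frame) of planar coordinates.
#' @param nbh_size Neighborhood size including the site itself (default 4).
#' @return Estimated variance of the mean (nonnegative).
#' @export
neighborhood_variance <- function(y, pi, coords, nbh_size = 4) {
  n <- length(y)
  if (n < 2) stop("variance undefined for fewer than 2 observations")
  if (any(pi <= 0)) stop("inclusion probabilities must be positive")
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == n, ncol(coords) == 2)
  z <- y / pi
  W <- neighborhood_weights(coords, nbh_size)
  zhat <- as.vector(W %*% z)
  dev2 <- (matrix(z, n, n, byrow = TRUE) - zhat)^2
  vtot <- sum(W * dev2)
  max(vtot, 0) / sum(1 / pi)^2
}

#' Design-based status estimate for one year
#'
#' Applies the Horvitz-Thompson mean and the neighborhood variance to the
#' records of one monitoring year. By default the first-stage design weight
#' \eqn{\pi_i} alone is used (within a year a panel is a complete spatially
#' balanced subsample, so the constant panel factor cancels from the mean);
#' set `include_panel_pi = TRUE` to use \eqn{\pi_i \pi_{j|i}}. Under a
#' stratified design, stratum-level means and variances are computed
#' independently and combined with stratum-size weights:
#' \eqn{\hat\mu = \sum_h (N_h/N)\hat\mu_h},
#' \eqn{\hat V = \sum_h (N_h/N)^2 \hat V_h}.
#'
#' @param survey A [assemble_survey()] result.
#' @param year Location-shifted year value to estimate.
#' @param Nh Named stratum population sizes; when supplied (and the year's
#'   records span several strata) the estimate is combined across strata,
#'   otherwise the records are treated as one spatially balanced sample.
#' @param include_panel_pi Include the panel inclusion probability in the
#'   weights (default `FALSE`).
#' @return A one-row `data.frame`: `year`, `mu_hat`, `v_nbh`, `n`.
#' @export
annual_status <- function(survey, year, Nh = NULL, include_panel_pi = FALSE) {
  stopifnot(inherits(survey, "survey_data"))
  rec <- survey[survey$year == year, , drop = FALSE]
  if (!nrow(rec)) stop("no records for year ", year)
  pival <- if (include_panel_pi) rec$pi_site * rec$pi_panel else rec$pi_site
  strata <- sort(unique(rec$stratum))
  if (!is.null(Nh) && length(strata) > 1) {
    if (!all(strata %in% names(Nh))) stop("Nh missing strata: ",
                                          paste(setdiff(strata, names(Nh)), collapse = ", "))
    share <- Nh[strata] / sum(Nh[strata])
    mu_h <- v_h <- numeric(length(strata))
    for (k in seq_along(strata)) {
      i <- rec$stratum == strata[k]
      mu_h[k] <- ht_mean(rec$y[i], pival[i])
      v_h[k] <- neighborhood_variance(rec$y[i], pival[i],
                                      cbind(rec$coord_x[i], rec$coord_y[i]))
    }
    mu <- sum(share * mu_h)
    v <- sum(share^2 * v_h)
  } else {
    mu <- ht_mean(rec$y, pival)
    v <- neighborhood_variance(rec$y, pival, cbind(rec$coord_x, rec$coord_y))
  }
  data.frame(year = year, mu_hat = mu, v_nbh = v, n = nrow(rec))
}

#' Annual status series over the monitoring period
#'
#' @inheritParams annual_status
#' @return A `data.frame` of class `status_series`, one row per surveyed
#'   year: `year`, `mu_hat`, `v_nbh`, `n`.
#' @export
status_series <- function(survey, Nh = NULL, include_panel_pi = FALSE) {
  stopifnot(inherits(survey, "survey_data"))
  yrs <- sort(unique(survey$year))
  out <- do.call(rbind, lapply(yrs, annual_status, survey = survey, Nh = Nh,
                               include_panel_pi = include_panel_pi))
  rownames(out) <- NULL
  class(out) <- c("status_series", "data.frame")
  out
}
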