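## Probability-weighted iterative generalized least squares for the
## two-stage trend model.  Sites are stage-1 units with random intercepts
## and slopes u_i ~ N(0, Omega); within-site year measurements are stage-2
## units with scalar noise v_ij ~ N(0, sigma2).  Design weights enter by the
## "Step A" transformation, replacing z_ij with w_i^{-1/2} z_ij and z_0ij
## with w_ij^{-1/2} z_0ij, after which the standard IGLS algorithm runs on
## the transformed model.  Equivalently, the working marginal covariance of
## cluster i is
##   V_i = w_i^{-1} [ Z_i Omega Z_i' + sigma2 diag(1/w_{j|i}) ].
## Fixed-effect standard errors come from the cluster-level linearization
## (sandwich) estimator; degrees of freedom for trend testing are taken from
## the unweighted mixed-model fit on the same records, whose own df are not
## inflated by the weighted variance components.

#' Step-A design transformation of random-effect covariates
#'
#' Replaces the stage-1 random design rows by \eqn{w_i^{-1/2} z_{ij}} and the
#' stage-2 rows by \eqn{w_{ij}^{-1/2} z_{0ij}}; with unit weights the
#' transformation is the identity.
#'
#' @param z Stage-1 random design matrix (rows are observations).
#' @param z0 Stage-2 random design matrix.
#' @param w_i Stage-1 (site) weight per observation.
#' @param w_ij Total weight per observation (`w_i * w_j_given_i`).
#' @return List with transformed `z` and `z0`.
#' @export
pwigls_transform <- function(z, z0, w_i, w_ij) {
  z <- as.matrix(z); z0 <- as.matrix(z0)
  if (any(w_i <= 0) || any(w_ij <= 0)) stop("weights must be positive")
  list(z = z * (w_i^(-0.5)), z0 = z0 * (w_ij^(-0.5)))
}

#' Scale design weights before the PWIGLS transformation
#'
#' Optional weight scalings from the Pfeffermann / Asparouhov families:
#' `"none"` uses raw inverse-probability weights; `"s2mean"` divides each
#' site's stage-2 weights by their within-site mean; `"effn"` rescales
#' stage-2 weights to the within-site effective sample size
#' (multiplying by \eqn{\sum_j w_{j|i} / \sum_j w_{j|i}^2}); `"s1mean"`
#' divides the stage-1 weights by their mean. All scalings leave unit
#' weights unchanged.
#'
#' @param w_i Stage-1 weight per observation.
#' @param w_j_given_i Stage-2 weight per observation.
#' @param site Site identifier per observation (stage-2 scalings operate
#'   within site).
#' @param scaling One of `"none"`, `"s1mean"`, `"s2mean"`, `"effn"`.
#' @return List with scaled `w_i` and `w_j_given_i`.
#' @export
pwigls_scale_weights <- function(w_i, w_j_given_i, site,
                                 scaling = c("none", "s1mean", "s2mean", "effn")) {
  scaling <- match.arg(scaling)
  if (scaling == "s1mean") {
    site_w <- tapply(w_i, site, `[`, 1)
    w_i <- w_i / mean(site_w)
  } else if (scaling == "s2mean") {
    m <- stats::ave(w_j_given_i, site, FUN = mean)
    w_j_given_i <- w_j_given_i / m
  } else if (scaling == "effn") {
    s1 <- stats::ave(w_j_given_i, site, FUN = sum)
    s2 <- stats::ave(w_j_given_i^2, site, FUN = sum)
    w_j_given_i <- w_j_given_i * s1 / s2
  }
  list(w_i = w_i, w_j_given_i = w_j_given_i)
}

# Project a symmetric matrix onto the PSD cone (eigenvalue truncation).
psd_project <- function(S, floor = 0) {
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE)
  ev$vectors %*% diag(pmax(ev$values, floor), nrow(S)) %*% t(ev$vectors)
}

# Core iterated-GLS engine.  clusters: list of lists with X, Z, y, w_i (scalar),
# w_ji (vector).  Returns beta, Omega, sigma2, per-cluster pieces.
pwigls_igls <- function(clusters, max_iter = 200, tol = 1e-7) {
  p <- ncol(clusters[[1]]$X)
  ## initial values from OLS
  Xall <- do.call(rbind, lapply(clusters, `[[`, "X"))
  yall <- unlist(lapply(clusters, `[[`, "y"))
  beta <- stats::lm.fit(Xall, yall)$coefficients
  s2 <- stats::var(yall - Xall %*% beta)[1]
  Omega <- diag(c(s2 / 2, 1e-4))
  sigma2 <- s2 / 2
  theta <- c(Omega[1, 1], Omega[1, 2], Omega[2, 2], sigma2)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ## GLS step for beta
    A <- matrix(0, p, p); bvec <- numeric(p)
    Vinv <- vector("list", length(clusters))
    for (k in seq_along(clusters)) {
      cl <- clusters[[k]]
      Vk <- (cl$Z %*% Omega %*% t(cl$Z) + sigma2 * diag(1 / cl$w_ji,
                                                        length(cl$w_ji))) / cl$w_i
      Vinv[[k]] <- solve(Vk)
      A <- A + t(cl$X) %*% Vinv[[k]] %*% cl$X
      bvec <- bvec + t(cl$X) %*% Vinv[[k]] %*% cl$y
    }
    beta_new <- solve(A, bvec)
    ## IGLS normal equations for the variance parameters
    q <- 4L
    M <- matrix(0, q, q); cth <- numeric(q)
    for (k in seq_along(clusters)) {
      cl <- clusters[[k]]
      r <- cl$y - cl$X %*% beta_new
      z1 <- cl$Z[, 1]; z2 <- cl$Z[, 2]
      G <- list((z1 %o% z1) / cl$w_i,
                (z1 %o% z2 + z2 %o% z1) / cl$w_i,
                (z2 %o% z2) / cl$w_i,
                diag(1 / cl$w_ji, length(cl$w_ji)) / cl$w_i)
      Vi <- Vinv[[k]]
      VG <- lapply(G, function(g) Vi %*% g)
      rv <- Vi %*% r
      for (a in 1:q) {
        cth[a] <- cth[a] + drop(t(rv) %*% G[[a]] %*% rv)
        for (b in a:q) {
          M[a, b] <- M[a, b] + sum(VG[[a]] * t(VG[[b]]))
        }
      }
    }
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    theta_new <- tryCatch(solve(M, cth), error = function(e) theta)
    ## constrain to the parameter space
    Om <- matrix(c(theta_new[1], theta_new[2], theta_new[2], theta_new[3]), 2, 2)
    Om <- psd_project(Om)
    s2_new <- max(theta_new[4], 1e-10)
    theta_new <- c(Om[1, 1], Om[1, 2], Om[2, 2], s2_new)
    delta <- max(abs(c(beta_new - beta, theta_new - theta)) /
                   pmax(abs(c(beta, theta)), 1e-4))
    beta <- drop(beta_new); Omega <- Om; sigma2 <- s2_new; theta <- theta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  ## final per-cluster pieces at the solution
  bread <- matrix(0, p, p)
  scores <- matrix(0, length(clusters), p)
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    Vk <- (cl$Z %*% Omega %*% t(cl$Z) + sigma2 * diag(1 / cl$w_ji,
                                                      length(cl$w_ji))) / cl$w_i
    Vi <- solve(Vk)
    bread <- bread + t(cl$X) %*% Vi %*% cl$X
    scores[k, ] <- t(cl$X) %*% Vi %*% (cl$y - cl$X %*% beta)
  }
  list(beta = beta, Omega = Omega, sigma2 = sigma2, iterations = iter,
       converged = converged, bread = bread, scores = scores,
       coef_names = colnames(clusters[[1]]$X))
}

#' Linearization (sandwich) covariance of the PWIGLS fixed effects
#'
#' Cluster-level sandwich estimator built from the weighted GLS estimating
#' equations: \eqn{B^{-1} (\frac{m}{m-1}\sum_i s_i s_i^\top) B^{-1}} with
#' bread \eqn{B = \sum_i X_i^\top V_i^{-1} X_i} and site-level scores
#' \eqn{s_i = X_i^\top V_i^{-1} r_i}. Symmetric and positive semidefinite.
#'
#' @param fit A `trend_fit` from [fit_pwigls()] (its stored cluster pieces
#'   are used).
#' @return Covariance matrix of the estimated fixed effects.
#' @export
linearization_variance <- function(fit) {
  parts <- if (inherits(fit, "trend_fit")) fit$model else fit
  if (is.null(parts$bread)) stop("no PWIGLS internals available")
  m <- nrow(parts$scores)
  p <- ncol(parts$bread)
  if (m <= p) warning("fewer clusters than fixed effects; sandwich is rank deficient")
  meat <- crossprod(parts$scores) * m / max(m - 1, 1)
  Binv <- solve(parts$bread)
  Vb <- Binv %*% meat %*% Binv
  dimnames(Vb) <- list(parts$coef_names, parts$coef_names)
  (Vb + t(Vb)) / 2
}

#' Probability-weighted IGLS trend fit
#'
#' Fits the two-stage trend model with design weights by the Step-A-only
#' PWIGLS recipe: scale the weights (optional), absorb them into the
#' random-effect design, and iterate GLS to convergence. Fixed-effect
#' standard errors use the cluster linearization (sandwich) estimator. By
#' default the trend test's degrees of freedom are taken from the unweighted
#' mixed-model fit on the same records, because the weighted variance
#' components (reported in `$varcomp`, year variance unavailable) are known
#' to be inflated. With all weights equal the fixed effects coincide with
#' the unweighted mixed-model fit.
#'
#' When the survey carries more than one stratum and `Nh` is supplied, a
#' separate-slopes model is fitted and the population-level slope
#' \eqn{\gamma_1^*} is returned, with the stratum structure carried through
#' the linearization variance.
#'
#' @inheritParams fit_po
#' @param scaling Weight scaling method (see [pwigls_scale_weights()]).
#' @param Nh Stratum population sizes; triggers the separate-slopes
#'   population-level fit when the survey is stratified.
#' @param df Optional externally supplied degrees of freedom (e.g., from an
#'   existing PO fit); if `NULL` a companion unweighted fit provides them.
#' @param max_iter,tol IGLS iteration controls.
#' @return A `trend_fit` with method `"PWIGLS"`.
#' @export
fit_pwigls <- function(survey, scaling = c("none", "s1mean", "s2mean", "effn"),
                       Nh = NULL, conf_level = 0.90, df = NULL,
                       max_iter = 200, tol = 1e-7) {
  scaling <- match.arg(scaling)
  stopifnot(is.data.frame(survey))
  req <- c("site_id", "year", "y", "pi_site", "pi_panel")
  miss <- setdiff(req, names(survey))
  if (length(miss)) stop("survey data missing columns: ", paste(miss, collapse = ", "))
  if (any(survey$pi_site <= 0) || any(survey$pi_panel <= 0)) {
    stop("missing or invalid inclusion probabilities")
  }
  sites <- unique(survey$site_id)
  if (length(sites) < 2) stop("stage-1 structure undefined with a single site")
  dat <- survey_model_frame(survey)
  stratified <- nlevels(dat$stratum) > 1 && !is.null(Nh)
  X <- if (stratified) stats::model.matrix(~ xj * stratum, dat)
       else stats::model.matrix(~ xj, dat)
  w <- pwigls_scale_weights(1 / survey$pi_site, 1 / survey$pi_panel,
                            survey$site_id, scaling)
  clusters <- lapply(sites, function(s) {
    i <- which(survey$site_id == s)
    list(X = X[i, , drop = FALSE],
         Z = cbind(1, survey$year[i]),
         y = survey$y[i],
         w_i = w$w_i[i][1],
         w_ji = w$w_j_given_i[i])
  })
  res <- pwigls_igls(clusters, max_iter = max_iter, tol = tol)
  if (!res$converged) {
    stop(sprintf("PWIGLS did not converge within %d iterations", res$iterations))
  }
  Vb <- linearization_variance(res)
  beta <- stats::setNames(res$beta, colnames(X))
  strata_df <- NULL
  if (stratified) {
    strata <- levels(dat$stratum)
    Nh <- Nh[strata]
    share <- as.numeric(Nh) / sum(Nh)
    cvec <- stats::setNames(numeric(length(beta)), names(beta))
    cvec["xj"] <- 1
    for (h in seq_along(strata)[-1]) {
      term <- paste0("xj:stratum", strata[h])
      cvec[term] <- share[h]
    }
    est <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% Vb %*% cvec))
  } else {
    est <- beta[["xj"]]
    se <- sqrt(Vb["xj", "xj"])
  }
  if (is.null(df)) {
    po <- if (stratified) fit_po_stratified(survey, Nh, conf_level)
          else fit_po(survey, conf_level)
    df <- po$df
  }
  vc <- c(sigma2_b = NA_real_, sigma2_a = res$Omega[1, 1],
          sigma2_t = res$Omega[2, 2], sigma_at = res$Omega[1, 2],
          sigma2_e = res$sigma2)
  new_trend_fit(est, se, df, conf_level, varcomp = vc, method = "PWIGLS",
                strata = strata_df, model = res,
                n_years = length(unique(survey$year)),
                n_sites = length(sites),
                converged = res$converged,
                notes = c(paste0("scaling=", scaling),
                          "variance components from weighted fits are typically inflated; df taken from the unweighted fit"))
}
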