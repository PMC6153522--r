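## Unweighted linear mixed trend model: REML fit with random year effects and
## correlated random site intercepts/slopes, Wald t tests on Satterthwaite
## (Giesbrecht-Burns) degrees of freedom, and the stratified separate-slopes
## model with the population-level slope combination.

new_trend_fit <- function(gamma1_hat, se, df, conf_level, varcomp = NULL,
                          method, strata = NULL, model = NULL,
                          n_years = NA_integer_, n_sites = NA_integer_,
                          converged = TRUE, notes = character()) {
  if (!is.finite(se) || se <= 0) stop("invalid standard error")
  if (!is.finite(df) || df <= 0) stop("invalid degrees of freedom")
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  tstat <- gamma1_hat / se
  structure(list(gamma1_hat = gamma1_hat, se = se, df = df,
                 ci = c(lower = gamma1_hat - tcrit * se,
                        upper = gamma1_hat + tcrit * se),
                 conf_level = conf_level,
                 statistic = tstat,
                 p_value = 2 * stats::pt(-abs(tstat), df),
                 varcomp = varcomp, method = method, strata = strata,
                 model = model, n_years = n_years, n_sites = n_sites,
                 converged = converged, notes = notes),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("%s trend fit: slope = %.6g (se %.4g, df %.2f)\n",
              x$method, x$gamma1_hat, x$se, x$df))
  cat(sprintf("  %.0f%% CI [%.6g, %.6g], two-sided p = %.4g\n",
              100 * x$conf_level, x$ci[1], x$ci[2], x$p_value))
  if (!is.null(x$varcomp)) {
    vc <- x$varcomp
    cat("  variance components:",
        paste(sprintf("%s=%.4g", names(vc), vc), collapse = ", "), "\n")
  }
  if (!x$converged) cat("  (fit did not fully converge)\n")
  invisible(x)
}

# Fit an lmer model quietly, retrying across optimizers; returns list(fit,
# converged).  Singular (boundary) fits count as converged.
fit_lmer_robust <- function(formula, data) {
  optimizers <- c("nloptwrap", "bobyqa", "Nelder_Mead")
  best <- NULL
  for (opt in optimizers) {
    ok <- TRUE
    fit <- tryCatch(
      withCallingHandlers(
        suppressMessages(
        lmerTest::lmer(formula, data = data, REML = TRUE,
                       control = lme4::lmerControl(optimizer = opt,
                                                   calc.derivs = TRUE))),
        warning = function(w) {
          if (!grepl("singular|Hessian|unable to evaluate scaled gradient",
                     conditionMessage(w)) &&
              grepl("converge", conditionMessage(w))) ok <<- FALSE
          invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (!is.null(fit)) {
      if (is.null(best)) best <- list(fit = fit, converged = ok)
      if (ok) return(list(fit = fit, converged = TRUE))
    }
  }
  if (is.null(best)) stop("mixed-model fit failed for all optimizer restarts")
  best
}

# Extract the (sigma2_b, sigma2_a, sigma2_t, sigma_at, sigma2_e) vector.
lmer_varcomp <- function(fit) {
  vc <- lme4::VarCorr(fit)
  site <- vc$site_f
  c(sigma2_b = as.numeric(vc$year_f[1, 1]),
    sigma2_a = as.numeric(site[1, 1]),
    sigma2_t = as.numeric(site[2, 2]),
    sigma_at = as.numeric(site[1, 2]),
    sigma2_e = stats::sigma(fit)^2)
}

survey_model_frame <- function(survey) {
  stopifnot(inherits(survey, "survey_data") || is.data.frame(survey))
  req <- c("site_id", "year", "y")
  miss <- setdiff(req, names(survey))
  if (length(miss)) stop("survey data missing columns: ", paste(miss, collapse = ", "))
  data.frame(y = survey$y, xj = survey$year,
             site_f = factor(survey$site_id),
             year_f = factor(survey$year),
             stratum = if ("stratum" %in% names(survey))
               factor(survey$stratum, levels = sort(unique(survey$stratum)))
             else factor(rep("all", nrow(survey))))
}

#' Fit the unweighted mixed trend model
#'
#' REML fit of
#' \deqn{y_{ij} = \gamma_0 + x_j\gamma_1 + b_j + a_i + x_j t_i + e_{ij}}
#' with a random year effect and correlated random site intercept and slope.
#' Trend inference is a Wald t test of \eqn{\hat\gamma_1/se(\hat\gamma_1)}
#' with Satterthwaite (Giesbrecht-Burns) degrees of freedom. Responses are
#' expected on the analysis (log) scale.
#'
#' @param survey A [assemble_survey()] result or a data.frame with columns
#'   `site_id`, `year`, `y`.
#' @param conf_level Confidence level for the slope interval (default 0.90).
#' @param het_stratum_resid Allow the residual variance to differ by stratum
#'   (fitted via `glmmTMB` with a stratum dispersion model; degrees of
#'   freedom are taken from the homoscedastic fit).
#' @return A `trend_fit` (method `"PO"`) carrying the slope, its standard
#'   error, Satterthwaite df, confidence interval, p-value, and the REML
#'   variance components.
#' @export
fit_po <- function(survey, conf_level = 0.90, het_stratum_resid = FALSE) {
  dat <- survey_model_frame(survey)
  if (nlevels(dat$year_f) < 2) stop("at least 2 distinct years required")
  if (nlevels(dat$site_f) < 2) stop("at least 2 sites required")
  res <- fit_lmer_robust(y ~ xj + (1 | year_f) + (xj | site_f), dat)
  fit <- res$fit
  co <- suppressWarnings(stats::coef(summary(fit)))
  est <- co["xj", "Estimate"]
  se <- co["xj", "Std. Error"]
  df <- co["xj", "df"]
  notes <- character()
  if (!is.finite(df) || df <= 0) {
    df <- nlevels(dat$year_f) - 2
    notes <- "singular Satterthwaite information; df fell back to n_years - 2"
    warning(notes)
  }
  vc <- lmer_varcomp(fit)
  if (het_stratum_resid && nlevels(dat$stratum) > 1) {
    if (!requireNamespace("glmmTMB", quietly = TRUE)) {
      stop("het_stratum_resid requires the glmmTMB package")
    }
    tmb <- suppressWarnings(
      glmmTMB::glmmTMB(y ~ xj + (1 | year_f) + (xj | site_f),
                       dispformula = ~ stratum, data = dat, REML = TRUE))
    est <- glmmTMB::fixef(tmb)$cond[["xj"]]
    se_het <- sqrt(diag(stats::vcov(tmb)$cond))[["xj"]]
    if (is.finite(se_het) && se_het > 0) se <- se_het
    notes <- c(notes, "stratum-heteroscedastic residuals; df from homoscedastic fit")
  }
  new_trend_fit(est, se, df, conf_level, varcomp = vc, method = "PO",
                model = fit, n_years = nlevels(dat$year_f),
                n_sites = nlevels(dat$site_f),
                converged = res$converged, notes = notes)
}

#' Satterthwaite degrees of freedom for a slope contrast
#'
#' Giesbrecht-Burns Satterthwaite df for a linear combination of the fixed
#' effects of a converged REML fit,
#' \eqn{\nu = 2[se^2]^2 / (g^\top A g)} with \eqn{g} the gradient of the
#' contrast variance in the variance parameters and \eqn{A} their asymptotic
#' covariance.
#'
#' @param fit A `trend_fit` from [fit_po()]/[fit_po_stratified()] (its
#'   underlying mixed model is used) or an `lmerModLmerTest` object.
#' @param contrast Optional numeric contrast over the fixed effects; default
#'   is the year-slope coefficient.
#' @return Degrees of freedom (positive scalar).
#' @export
satterthwaite_df <- function(fit, contrast = NULL) {
  mod <- if (inherits(fit, "trend_fit")) fit$model else fit
  if (!inherits(mod, "lmerModLmerTest")) {
    stop("no underlying Satterthwaite-capable mixed model available")
  }
  if (is.null(contrast)) {
    contrast <- as.numeric(names(lme4::fixef(mod)) == "xj")
  }
  ct <- lmerTest::contest1D(mod, contrast, confint = FALSE)
  as.numeric(ct[["df"]])
}

# Population-level slope from stratum-specific coefficients:
# gamma1* = gamma1 + sum_{h>=2} N_h * delta_h1 / N.
combine_stratum_slopes <- function(gamma1, delta_h1, Nh) {
  stopifnot(length(delta_h1) == length(Nh) - 1)
  gamma1 + sum(Nh[-1] * delta_h1) / sum(Nh)
}

#' Fit the stratified separate-slopes mixed trend model
#'
#' Adds fixed stratum intercept and slope deviations to the trend model,
#' \deqn{y_{hij} = \gamma_0 + x_j\gamma_1 + \delta_{h0} + x_j\delta_{h1} + b_j + a_i + x_j t_i + e_{ij},}
#' and reports the population-level trend
#' \eqn{\gamma_1^* = \gamma_1 + \sum_{h\ge2} N_h\delta_{h1}/N}, whose
#' standard error comes from the stratum-share contrast applied to the
#' fixed-effect covariance, and whose reference t distribution has degrees
#' of freedom equal to the sum of the stratum-level Satterthwaite df.
#'
#' @inheritParams fit_po
#' @param Nh Named vector of stratum population sizes matching the survey's
#'   stratum labels.
#' @return A `trend_fit` (method `"PO"`) for \eqn{\gamma_1^*}; per-stratum
#'   slopes, their df, and the stratum coefficients are in `$strata`.
#' @export
fit_po_stratified <- function(survey, Nh, conf_level = 0.90,
                              het_stratum_resid = FALSE) {
  dat <- survey_model_frame(survey)
  strata <- levels(dat$stratum)
  if (length(strata) < 2) return(fit_po(survey, conf_level, het_stratum_resid))
  if (!all(strata %in% names(Nh))) {
    stop("Nh missing strata: ", paste(setdiff(strata, names(Nh)), collapse = ", "))
  }
  cnt <- table(dat$stratum[!duplicated(dat$site_f)])
  if (any(cnt < 2)) stop("each stratum needs at least 2 sites")
  Nh <- Nh[strata]
  res <- fit_lmer_robust(y ~ xj * stratum + (1 | year_f) + (xj | site_f), dat)
  fit <- res$fit
  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  nb <- names(beta)
  share <- as.numeric(Nh) / sum(Nh)
  # contrast for gamma1*: full weight on xj, stratum shares on interactions
  cvec <- stats::setNames(numeric(length(beta)), nb)
  cvec["xj"] <- 1
  per_str <- data.frame(stratum = strata, slope = NA_real_, df = NA_real_,
                        delta_h1 = 0, stringsAsFactors = FALSE)
  for (h in seq_along(strata)) {
    lh <- stats::setNames(numeric(length(beta)), nb)
    lh["xj"] <- 1
    if (h > 1) {
      term <- paste0("xj:stratum", strata[h])
      if (!term %in% nb) stop("missing interaction coefficient for stratum ", strata[h])
      lh[term] <- 1
      cvec[term] <- share[h]
      per_str$delta_h1[h] <- beta[[term]]
    }
    per_str$slope[h] <- sum(lh * beta)
    per_str$df[h] <- as.numeric(lmerTest::contest1D(fit, lh, confint = FALSE)[["df"]])
  }
  if (any(!is.finite(per_str$df) | per_str$df <= 0)) {
    per_str$df[!is.finite(per_str$df) | per_str$df <= 0] <- nlevels(dat$year_f) - 2
    warning("singular Satterthwaite information in a stratum; df fell back to n_years - 2")
  }
  est <- sum(cvec * beta)
  se <- sqrt(drop(t(cvec) %*% V %*% cvec))
  df <- sum(per_str$df)
  vcomp <- lmer_varcomp(fit)
  if (het_stratum_resid) {
    if (!requireNamespace("glmmTMB", quietly = TRUE)) {
      stop("het_stratum_resid requires the glmmTMB package")
    }
    tmb <- suppressWarnings(
      glmmTMB::glmmTMB(y ~ xj * stratum + (1 | year_f) + (xj | site_f),
                       dispformula = ~ stratum, data = dat, REML = TRUE))
    bt <- glmmTMB::fixef(tmb)$cond
    Vt <- as.matrix(stats::vcov(tmb)$cond)
    est <- sum(cvec[names(bt)] * bt)
    se_het <- sqrt(drop(t(cvec[names(bt)]) %*% Vt %*% cvec[names(bt)]))
    if (is.finite(se_het) && se_het > 0) se <- se_het
  }
  new_trend_fit(est, se, df, conf_level, varcomp = vcomp, method = "PO",
                strata = per_str, model = fit,
                n_years = nlevels(dat$year_f), n_sites = nlevels(dat$site_f),
                converged = res$converged)
}

#' Wald t test for trend
#'
#' Two-sided test of zero trend from a fitted slope: the statistic
#' \eqn{\hat\gamma_1/se} is referred to a t distribution with the fit's
#' degrees of freedom.
#'
#' @param fit A `trend_fit`.
#' @param alpha Significance level (default 0.10).
#' @return A list: `statistic`, `df`, `p_value`, `reject`, and the
#'   `1 - alpha` confidence interval.
#' @export
wald_trend_test <- function(fit, alpha = 0.10) {
  stopifnot(inherits(fit, "trend_fit"))
  tcrit <- stats::qt(1 - alpha / 2, fit$df)
  list(statistic = fit$statistic, df = fit$df, p_value = fit$p_value,
       reject = fit$p_value < alpha,
       ci = c(lower = fit$gamma1_hat - tcrit * fit$se,
              upper = fit$gamma1_hat + tcrit * fit$se))
}
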