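## Monte Carlo engine: simulate populations, draw samples, allocate panels,
## apply every trend estimator, and summarize relative bias, coverage, test
## size, and power per scenario cell.

#' Net percent change from a constant annual rate
#'
#' \eqn{100((1 + r/100)^{years} - 1)}: e.g., 1% per year over 24 years and
#' 2% per year over 12 years both compound to a 27% net increase.
#'
#' @param annual_rate_percent Annual rate in percent.
#' @param years Number of years (>= 0).
#' @return Net change in percent.
#' @export
net_change <- function(annual_rate_percent, years) {
  stopifnot(years >= 0)
  100 * ((1 + annual_rate_percent / 100)^years - 1)
}

#' Mean relative bias of trend estimates
#'
#' Mean of \eqn{(\hat\gamma_1 - \gamma_1)/\gamma_1} over replicates, with
#' the conventional 5% threshold for calling an estimator biased.
#'
#' @param estimates Vector of slope estimates.
#' @param true_gamma1 True generating slope (nonzero).
#' @return List: `rel_bias`, `mc_se`, `biased` (`TRUE` when |rel bias| >=
#'   0.05), `n`.
#' @export
relative_bias <- function(estimates, true_gamma1) {
  if (true_gamma1 == 0) {
    stop("relative bias undefined for a zero true slope; report absolute bias instead")
  }
  estimates <- estimates[is.finite(estimates)]
  rb <- (estimates - true_gamma1) / true_gamma1
  list(rel_bias = mean(rb),
       mc_se = stats::sd(rb) / sqrt(length(rb)),
       biased = abs(mean(rb)) >= 0.05,
       n = length(rb))
}

#' Coverage, test size, and power from replicate fits
#'
#' Computes the share of confidence intervals containing the true slope and
#' the rejection rate of the two-sided trend test at level `alpha`. The
#' rejection rate is reported as test size when the true slope is zero and
#' as power otherwise; power is only assessed when the matched null cell's
#' test size is roughly nominal (at most `size_allowance`), mirroring the
#' convention that inflated size makes power optimistic.
#'
#' @param fits Data frame with columns `ci_lower`, `ci_upper`, `p_value`.
#' @param true_gamma1 True generating slope.
#' @param alpha Significance level (default 0.10).
#' @param null_size Test size observed in the matched null scenario
#'   (required to assess power when `true_gamma1 != 0`; `NULL` skips the
#'   gate with `power_assessed = NA`).
#' @param size_allowance Largest null size still treated as nominal
#'   (default 0.13).
#' @return List: `coverage`, `coverage_mc_se`, `reject_rate`,
#'   `reject_mc_se`, `metric` ("size" or "power"), `power_assessed`.
#' @export
coverage_size_power <- function(fits, true_gamma1, alpha = 0.10,
                                null_size = NULL, size_allowance = 0.13) {
  stopifnot(all(c("ci_lower", "ci_upper", "p_value") %in% names(fits)))
  ok <- stats::complete.cases(fits[, c("ci_lower", "ci_upper", "p_value")])
  fits <- fits[ok, , drop = FALSE]
  n <- nrow(fits)
  cover <- mean(fits$ci_lower <= true_gamma1 & true_gamma1 <= fits$ci_upper)
  rej <- mean(fits$p_value < alpha)
  bin_se <- function(p) sqrt(p * (1 - p) / n)
  if (true_gamma1 == 0) {
    metric <- "size"; assessed <- TRUE
  } else {
    metric <- "power"
    if (is.null(null_size)) {
      assessed <- NA
    } else {
      assessed <- null_size <= size_allowance
      if (!assessed) rej <- NA_real_
    }
  }
  list(coverage = cover, coverage_mc_se = bin_se(cover),
       reject_rate = rej,
       reject_mc_se = if (is.na(rej)) NA_real_ else bin_se(rej),
       metric = metric, power_assessed = assessed, n = n)
}

#' Relative bias of estimated variance components
#'
#' @param varcomps Matrix (replicates in rows) of estimated components with
#'   columns named like the generating model components.
#' @param model The generating [population_model()].
#' @param method Method tag; only variance-component methods (`"PO"`,
#'   `"PWIGLS"`) are accepted.
#' @return Named vector of mean relative biases; `NA` for components whose
#'   generating value is 0 (relative bias undefined).
#' @export
varcomp_bias <- function(varcomps, model, method = "PO") {
  if (!method %in% c("PO", "PWIGLS")) {
    stop("variance components are not estimated by method ", method)
  }
  truth <- c(sigma2_b = model$sigma2_b, sigma2_a = model$sigma2_a,
             sigma2_t = model$sigma2_t, sigma_at = model$sigma_at,
             sigma2_e = model$sigma2_e)
  comps <- intersect(colnames(varcomps), names(truth))
  out <- vapply(comps, function(k) {
    if (truth[[k]] == 0) return(NA_real_)
    mean((varcomps[, k] - truth[[k]]) / truth[[k]], na.rm = TRUE)
  }, numeric(1))
  stats::setNames(out, comps)
}

#' Specify a simulation scenario cell
#'
#' One cell of the scenario grid: sampling design, annual sample size,
#' revisit design, monitoring period, annual trend, optional subpopulation
#' trend, and variance structure (`"anc"`: high year-to-year variance
#' 0.0157; `"modified_anc"`: the same total variance with the year component
#' reduced to 0.0001 and the difference moved into the site component).
#' Nonzero annual trends follow the compounding pairing of the study grid:
#' 1% with 24-year periods, 2% with 12-year periods.
#'
#' @param design `"equiprobable"`, `"stratified"`, or `"unequal"`.
#' @param annual_n Sites visited per year (20, 35, or 50 in the study grid).
#' @param revisit Revisit notation: `"[1-0]"`, `"[1-0,1-3]"`, `"[1-3]"`.
#' @param period Monitoring period in years (12 or 24).
#' @param trend_pct Annual population trend in percent (0, 1, or 2).
#' @param subpop_trend_pct Additional annual trend (percent) in the
#'   high-elevation subpopulation (0 or 4).
#' @param variance `"anc"` or `"modified_anc"`.
#' @param n_reps Number of Monte Carlo replicates (default 500).
#' @param seed Scenario seed.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(design = c("equiprobable", "stratified", "unequal"),
                          annual_n = 20, revisit = "[1-0]", period = 12,
                          trend_pct = 0, subpop_trend_pct = 0,
                          variance = c("anc", "modified_anc"),
                          n_reps = 500, seed = 1) {
  design <- match.arg(design)
  variance <- match.arg(variance)
  stopifnot(n_reps >= 1, period >= 2)
  if (trend_pct == 1 && period != 24) stop("a 1% annual trend pairs with a 24-year period")
  if (trend_pct == 2 && period != 12) stop("a 2% annual trend pairs with a 12-year period")
  structure(list(design = design, annual_n = as.integer(annual_n),
                 revisit = revisit, period = as.integer(period),
                 trend_pct = trend_pct, subpop_trend_pct = subpop_trend_pct,
                 variance = variance, n_reps = as.integer(n_reps),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

# Generating model for a scenario cell.
scenario_model <- function(spec, gamma0 = 4) {
  m <- population_model(gamma0 = gamma0,
                        gamma1 = log(1 + spec$trend_pct / 100),
                        subpop_trend_delta = log(1 + spec$subpop_trend_pct / 100),
                        years = 0:(spec$period - 1))
  if (spec$variance == "modified_anc") m <- modify_variance_composition(m, 1e-4)
  m
}

# Population-level generating slope implied by a scenario (base slope plus
# the stratum-share-weighted subpopulation deviation).
scenario_true_slope <- function(spec, model, frame) {
  share <- mean(subpop_members(frame, model))
  model$gamma1 + share * model$subpop_trend_delta
}

run_one_replicate <- function(spec, model, design, rd, methods, conf_level) {
  frame <- build_frame(model = model)
  resp <- simulate_response(frame, model)
  pis <- inclusion_probabilities(frame, design)
  draw <- grts_draw(frame, pis, stratify = spec$design == "stratified")
  assign <- allocate_panels(draw, rd)
  survey <- assemble_survey(resp, assign, rd)
  Nh <- stratum_sizes(frame)
  truth <- scenario_true_slope(spec, model, frame)
  one <- function(expr) {
    f <- tryCatch(suppressWarnings(expr), error = function(e) NULL)
    if (is.null(f)) {
      return(data.frame(est = NA_real_, se = NA_real_, df = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_,
                        p_value = NA_real_, converged = FALSE))
    }
    data.frame(est = f$gamma1_hat, se = f$se, df = f$df,
               ci_lower = f$ci[1], ci_upper = f$ci[2],
               p_value = f$p_value, converged = f$converged)
  }
  out <- list(truth = truth)
  po_fit <- NULL
  if (any(c("po", "pwigls") %in% methods)) {
    po_fit <- tryCatch(suppressWarnings(
      if (spec$design == "stratified") fit_po_stratified(survey, Nh, conf_level)
      else fit_po(survey, conf_level)), error = function(e) NULL)
  }
  if ("po" %in% methods) {
    out$po <- one(if (is.null(po_fit)) stop("no fit") else po_fit)
    out$po_varcomp <- if (!is.null(po_fit)) po_fit$varcomp else
      stats::setNames(rep(NA_real_, 5),
                      c("sigma2_b", "sigma2_a", "sigma2_t", "sigma_at", "sigma2_e"))
  }
  if (any(c("slrdb", "wlrdb") %in% methods)) {
    ss <- tryCatch(status_series(survey,
                                 Nh = if (spec$design == "stratified") Nh else NULL),
                   error = function(e) NULL)
    if ("slrdb" %in% methods) {
      out$slrdb <- one(if (is.null(ss)) stop("no series") else fit_slrdb(ss, conf_level))
    }
    if ("wlrdb" %in% methods) {
      out$wlrdb <- one(if (is.null(ss)) stop("no series") else fit_wlrdb(ss, conf_level))
    }
  }
  if ("pwigls" %in% methods) {
    pwf <- tryCatch(suppressWarnings(
      fit_pwigls(survey, Nh = if (spec$design == "stratified") Nh else NULL,
                 conf_level = conf_level,
                 df = if (!is.null(po_fit)) po_fit$df else NULL)),
      error = function(e) NULL)
    out$pwigls <- one(if (is.null(pwf)) stop("no fit") else pwf)
    out$pwigls_varcomp <- if (!is.null(pwf)) pwf$varcomp else
      stats::setNames(rep(NA_real_, 5),
                      c("sigma2_b", "sigma2_a", "sigma2_t", "sigma_at", "sigma2_e"))
  }
  out
}

#' Run one Monte Carlo scenario cell
#'
#' For each replicate: build a fresh population, simulate responses under
#' the generating model, draw a spatially balanced sample for the design,
#' allocate panels, assemble the survey, and apply the requested trend
#' estimators. Replicates are seeded independently and deterministically
#' from the scenario seed, so results are reproducible and independent of
#' execution order. Fits that fail are excluded from the summaries with the
#' exclusion rate reported.
#'
#' @param spec A [scenario_spec()].
#' @param methods Estimators to apply: subset of `"po"`, `"slrdb"`,
#'   `"wlrdb"`, `"pwigls"`.
#' @param alpha Significance level for the trend test (default 0.10).
#' @param null_sizes Optional named vector of matched null-cell test sizes
#'   per method, used to gate power reporting.
#' @param verbose Print a progress line every 100 replicates.
#' @return An object of class `scenario_result`: `$metrics` (tidy
#'   data.frame: method, metric, value, mc_se), `$reps` (per-replicate
#'   estimates per method), `$varcomp` (per-method relative bias of
#'   variance components), `$true_gamma1`, and `$spec`.
#' @export
run_scenario <- function(spec, methods = c("po", "slrdb", "wlrdb", "pwigls"),
                         alpha = 0.10, null_sizes = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  methods <- match.arg(methods, c("po", "slrdb", "wlrdb", "pwigls"),
                       several.ok = TRUE)
  conf_level <- 1 - alpha
  model <- scenario_model(spec)
  design <- sample_design(kind = spec$design,
                          n = total_unique_sites(
                            parse_revisit_design(spec$revisit, spec$annual_n,
                                                 spec$period)))
  rd <- parse_revisit_design(spec$revisit, spec$annual_n, spec$period)
  reps <- vector("list", spec$n_reps)
  for (r in seq_len(spec$n_reps)) {
    set.seed(replicate_seed(spec$seed, r))
    reps[[r]] <- run_one_replicate(spec, model, design, rd, methods, conf_level)
    if (verbose && r %% 100 == 0) message("replicate ", r, "/", spec$n_reps)
  }
  truth <- reps[[1]]$truth
  collect <- function(meth) {
    do.call(rbind, lapply(reps, `[[`, meth))
  }
  metrics <- list()
  rep_tables <- list()
  vc_out <- list()
  for (meth in methods) {
    tab <- collect(meth)
    rep_tables[[meth]] <- tab
    okrate <- mean(tab$converged & is.finite(tab$est))
    ok <- tab[tab$converged & is.finite(tab$est), , drop = FALSE]
    mrow <- function(metric, value, mc_se = NA_real_) {
      data.frame(method = toupper(meth), metric = metric, value = value,
                 mc_se = mc_se, stringsAsFactors = FALSE)
    }
    rows <- mrow("convergence_rate", okrate)
    if (truth != 0) {
      rb <- relative_bias(ok$est, truth)
      rows <- rbind(rows, mrow("rel_bias", rb$rel_bias, rb$mc_se))
    } else {
      rows <- rbind(rows, mrow("abs_bias", mean(ok$est),
                               stats::sd(ok$est) / sqrt(nrow(ok))))
    }
    csp <- coverage_size_power(ok, truth, alpha,
                               null_size = null_sizes[[meth]])
    rows <- rbind(rows,
                  mrow("coverage90", csp$coverage, csp$coverage_mc_se),
                  mrow(csp$metric, csp$reject_rate, csp$reject_mc_se))
    metrics[[meth]] <- rows
    if (meth %in% c("po", "pwigls")) {
      vcs <- do.call(rbind, lapply(reps, `[[`, paste0(meth, "_varcomp")))
      vc_out[[meth]] <- varcomp_bias(vcs[tab$converged & is.finite(tab$est), ,
                                         drop = FALSE],
                                     model, toupper(meth))
      attr(vc_out[[meth]], "estimates") <- vcs
    }
  }
  structure(list(metrics = do.call(rbind, metrics), reps = rep_tables,
                 varcomp = vc_out, true_gamma1 = truth, spec = spec,
                 alpha = alpha),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Scenario: %s design, annual n=%d, %s, %d years, trend %.3g%% (+%.3g%% subpop), %s variance, %d reps\n",
              s$design, s$annual_n, s$revisit, s$period, s$trend_pct,
              s$subpop_trend_pct, s$variance, s$n_reps))
  cat(sprintf("True slope (log scale): %.6g\n", x$true_gamma1))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}
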