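# Probability-weighted IGLS: transformation, estimation, and the
# linearization variance.

test_that("the Step-A transformation scales by inverse square-root weights", {
  z <- cbind(1, 0:3)
  z0 <- matrix(1, 4, 1)
  id <- pwigls_transform(z, z0, w_i = rep(1, 4), w_ij = rep(1, 4))
  expect_equal(id$z, z)
  expect_equal(id$z0, z0)
  tr <- pwigls_transform(z, z0, w_i = rep(4, 4), w_ij = rep(4, 4))
  expect_equal(tr$z, z / 2)
  expect_equal(tr$z0, z0 / 2)
  expect_error(pwigls_transform(z, z0, rep(-1, 4), rep(1, 4)), "positive")
})

test_that("weight scalings behave as documented and fix unit weights", {
  site <- rep(1:2, each = 4)
  w2 <- rep(4, 8)
  s <- pwigls_scale_weights(rep(2, 8), w2, site, "s2mean")
  expect_equal(s$w_j_given_i, rep(1, 8))       # constant weights -> all 1
  s2 <- pwigls_scale_weights(rep(2, 8), w2, site, "effn")
  expect_equal(s2$w_j_given_i, rep(1, 8))
  s3 <- pwigls_scale_weights(c(rep(2, 4), rep(6, 4)), w2, site, "s1mean")
  expect_equal(unique(s3$w_i), c(0.5, 1.5))
  for (m in c("none", "s1mean", "s2mean", "effn")) {
    u <- pwigls_scale_weights(rep(1, 8), rep(1, 8), site, m)
    expect_equal(u$w_i, rep(1, 8))
    expect_equal(u$w_j_given_i, rep(1, 8))
  }
})

test_that("unit-weight PWIGLS reproduces the unweighted mixed-model slope", {
  sv <- make_balanced_survey(n_sites = 20, n_years = 10, gamma1 = 0.05,
                             seed = 91)
  fp <- quiet_fit(fit_po(sv))
  fw <- quiet_fit(fit_pwigls(sv))
  expect_equal(fw$gamma1_hat, fp$gamma1_hat, tolerance = 1e-4)
  expect_equal(fw$df, fp$df)        # df borrowed from the unweighted fit
  # scaling methods leave the unit-weight case unchanged
  for (m in c("s1mean", "s2mean", "effn")) {
    fm <- quiet_fit(fit_pwigls(sv, scaling = m))
    expect_equal(fm$gamma1_hat, fw$gamma1_hat, tolerance = 1e-8)
  }
})

test_that("estimates are invariant to rescaling stage-1 weights", {
  sv <- make_balanced_survey(n_sites = 15, n_years = 8, pi_site = 0.25,
                             pi_panel = 1, seed = 92)
  f1 <- quiet_fit(fit_pwigls(sv, df = 10))
  sv2 <- sv; sv2$pi_site <- sv2$pi_site / 3   # all weights tripled
  f2 <- quiet_fit(fit_pwigls(sv2, df = 10))
  expect_equal(f2$gamma1_hat, f1$gamma1_hat, tolerance = 1e-6)
  expect_equal(f2$se, f1$se, tolerance = 1e-5)
})

test_that("the linearization covariance is symmetric PSD and weight-scale stable", {
  sv <- make_balanced_survey(n_sites = 15, n_years = 8, pi_site = 0.2,
                             pi_panel = 0.5, seed = 93)
  f <- quiet_fit(fit_pwigls(sv, df = 10))
  V <- linearization_variance(f)
  expect_equal(V, t(V))
  expect_true(all(diag(V) >= 0))
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
  sv2 <- sv
  sv2$pi_site <- sv2$pi_site / 2              # doubles every total weight
  f2 <- quiet_fit(fit_pwigls(sv2, df = 10))
  V2 <- linearization_variance(f2)
  expect_equal(V2, V, tolerance = 1e-5)
})

test_that("linearization SEs track model-based SEs under equal weights", {
  set.seed(94)
  nrep <- 150
  ratio <- numeric(nrep)
  for (r in seq_len(nrep)) {
    sv <- make_balanced_survey(n_sites = 40, n_years = 8, gamma1 = 0.02,
                               sigma_b = 0, sigma_a = 0.5, sigma_t = 0.02,
                               sigma_e = 0.3, seed = 9000 + r)
    f <- quiet_fit(fit_pwigls(sv, df = 10))
    # model-based GLS SE from the bread alone
    se_model <- sqrt(solve(f$model$bread)["xj", "xj"])
    ratio[r] <- f$se / se_model
  }
  expect_lt(abs(mean(ratio) - 1), 0.15)
})

test_that("an informative site-selection design biases the unweighted fit more", {
  # Sites with stronger latent slopes are oversampled: inclusion probability
  # follows the travel-cost class, which is correlated with the
  # high-elevation subpopulation carrying an extra trend.
  m <- modify_variance_composition(
    population_model(gamma1 = log(1.02), subpop_trend_delta = log(1.04),
                     years = 0:11), 1e-4)
  nrep <- 120
  est_po <- est_pw <- rep(NA_real_, nrep)
  truth <- NA_real_
  for (r in seq_len(nrep)) {
    set.seed(9500 + r)
    frame <- build_frame(model = m)
    resp <- simulate_response(frame, m)
    des <- sample_design("unequal", 35)
    p <- inclusion_probabilities(frame, des)
    rd <- parse_revisit_design("[1-0]", 35, 12)
    sv <- assemble_survey(resp, allocate_panels(grts_draw(frame, p), rd), rd)
    truth <- m$gamma1 + mean(frame$stratum == "high") * m$subpop_trend_delta
    fpo <- tryCatch(quiet_fit(fit_po(sv)), error = function(e) NULL)
    fpw <- tryCatch(quiet_fit(fit_pwigls(sv, df = 10)), error = function(e) NULL)
    if (!is.null(fpo)) est_po[r] <- fpo$gamma1_hat
    if (!is.null(fpw)) est_pw[r] <- fpw$gamma1_hat
  }
  rb_po <- (mean(est_po, na.rm = TRUE) - truth) / truth
  rb_pw <- (mean(est_pw, na.rm = TRUE) - truth) / truth
  expect_lt(abs(rb_pw), abs(rb_po))   # weighting reduces the selection bias
  expect_lt(rb_po, 0)                 # undersampled subpopulation pulls it down
})

test_that("degenerate inputs are rejected", {
  sv <- make_balanced_survey(n_sites = 1, n_years = 8, seed = 95)
  expect_error(fit_pwigls(sv), "single site")
  sv2 <- make_balanced_survey(n_sites = 5, n_years = 8, seed = 96)
  sv2$pi_site <- NULL
  expect_error(fit_pwigls(sv2), "missing columns")
})
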