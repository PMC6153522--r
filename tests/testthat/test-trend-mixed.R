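# The unweighted mixed trend model and its Wald/Satterthwaite inference.

test_that("a noiseless plane is interpolated exactly", {
  d <- expand.grid(site_id = 1:8, year = 0:9)
  d$y <- 1 + 0.05 * d$year
  f <- quiet_fit(fit_po(d))
  expect_equal(f$gamma1_hat, 0.05, tolerance = 1e-8)
})

test_that("with random effects projected out the fit reduces to OLS", {
  set.seed(71)
  d <- expand.grid(site_id = 1:30, year = 0:9)
  e <- rnorm(nrow(d))
  e <- resid(lm(e ~ factor(d$site_id) * d$year + factor(d$year)))
  d$y <- 1 + 0.05 * d$year + e
  f <- quiet_fit(fit_po(d))
  ols <- coef(summary(lm(y ~ year, d)))
  expect_equal(f$gamma1_hat, ols["year", "Estimate"], tolerance = 1e-6)
  expect_equal(f$df, nrow(d) - 2, tolerance = 1)
})

test_that("under dominant year variance df collapses to n_years - 2", {
  set.seed(72)
  d <- expand.grid(site_id = 1:30, year = 0:11)
  d$y <- 1 + 0.02 * d$year + rnorm(12, 0, 0.5)[d$year + 1] +
    rnorm(nrow(d), 0, 0.02)
  f <- quiet_fit(fit_po(d))
  expect_equal(f$df, 10, tolerance = 2)
  # year-mean collapse oracle: slope agrees with OLS on annual means
  ym <- tapply(d$y, d$year, mean)
  oracle <- coef(lm(ym ~ I(0:11)))[2]
  expect_equal(f$gamma1_hat, unname(oracle), tolerance = 1e-3)
})

test_that("REML slope is shift-invariant and df is positive", {
  sv <- make_balanced_survey(n_sites = 15, n_years = 8, seed = 73)
  f1 <- quiet_fit(fit_po(sv))
  sv2 <- sv; sv2$y <- sv2$y + 100
  f2 <- quiet_fit(fit_po(sv2))
  expect_equal(f1$gamma1_hat, f2$gamma1_hat, tolerance = 1e-6)
  expect_gt(f1$df, 0)
  expect_true(all(f1$varcomp[c("sigma2_b", "sigma2_a", "sigma2_t", "sigma2_e")] >= 0))
  expect_true(f1$ci[1] <= f1$gamma1_hat && f1$gamma1_hat <= f1$ci[2])
  # satterthwaite_df accessor agrees with the stored df
  expect_equal(satterthwaite_df(f1), f1$df, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected", {
  d <- data.frame(site_id = 1:5, year = 0, y = rnorm(5))
  expect_error(fit_po(d), "2 distinct years")
  d2 <- data.frame(site_id = 1, year = 0:5, y = rnorm(6))
  expect_error(fit_po(d2), "2 sites")
})

test_that("population slope combination weights stratum deviations by size", {
  expect_equal(paneltrend:::combine_stratum_slopes(0.01, 0.02, c(60, 40)),
               0.018)
  expect_equal(paneltrend:::combine_stratum_slopes(0.01, c(0, 0), c(50, 30, 20)),
               0.01)
})

test_that("stratified fit reduces to fit_po with one stratum and equal slopes", {
  sv <- make_balanced_survey(n_sites = 16, n_years = 10, seed = 74)
  f0 <- quiet_fit(fit_po(sv))
  f1 <- quiet_fit(fit_po_stratified(sv, Nh = c(all = 100)))
  expect_equal(f1$gamma1_hat, f0$gamma1_hat)
  # two strata with a common generating slope: gamma1* close to the pooled slope
  sv$stratum <- rep(c("a", "b"), each = 8)[sv$site_id]
  f2 <- quiet_fit(fit_po_stratified(sv, Nh = c(a = 60, b = 40)))
  expect_equal(f2$gamma1_hat, f0$gamma1_hat, tolerance = 0.02)
  expect_equal(nrow(f2$strata), 2)
  expect_equal(f2$df, sum(f2$strata$df))
  # the linear-combination identity holds for the reported estimate
  expect_equal(f2$gamma1_hat,
               paneltrend:::combine_stratum_slopes(
                 f2$strata$slope[1], f2$strata$delta_h1[-1], c(60, 40)),
               tolerance = 1e-10)
})

test_that("the population-level slope is invariant to the reference stratum", {
  sv <- make_balanced_survey(n_sites = 16, n_years = 10, seed = 75)
  sv$stratum <- rep(c("a", "b"), each = 8)[sv$site_id]
  sv$y <- sv$y + ifelse(sv$stratum == "b", 0.03, 0) * sv$year
  f_ab <- quiet_fit(fit_po_stratified(sv, Nh = c(a = 70, b = 30)))
  sv2 <- sv
  sv2$stratum <- ifelse(sv$stratum == "a", "zb", "aa")  # flips sorted order
  f_ba <- quiet_fit(fit_po_stratified(sv2, Nh = c(aa = 30, zb = 70)))
  expect_equal(f_ab$gamma1_hat, f_ba$gamma1_hat, tolerance = 1e-5)
  expect_equal(f_ab$se, f_ba$se, tolerance = 1e-4)
})

test_that("stratum-heteroscedastic residuals barely move a homoscedastic fit", {
  sv <- make_balanced_survey(n_sites = 16, n_years = 10, seed = 76)
  sv$stratum <- rep(c("a", "b"), each = 8)[sv$site_id]
  f_hom <- quiet_fit(fit_po_stratified(sv, Nh = c(a = 60, b = 40)))
  f_het <- quiet_fit(fit_po_stratified(sv, Nh = c(a = 60, b = 40),
                                       het_stratum_resid = TRUE))
  expect_lt(abs(f_het$gamma1_hat - f_hom$gamma1_hat), 1e-4)
})

test_that("wald_trend_test matches the stored p-value and rejects correctly", {
  sv <- make_balanced_survey(n_sites = 15, n_years = 8, gamma1 = 0.3,
                             sigma_b = 0.01, sigma_e = 0.05, seed = 77)
  f <- quiet_fit(fit_po(sv))
  w <- wald_trend_test(f, alpha = 0.10)
  expect_equal(w$p_value, f$p_value)
  expect_true(w$reject)            # strong trend, little noise
  expect_equal(unname(w$ci), unname(f$ci))  # alpha = 1 - conf_level here
  # a zero slope gives t = 0, p = 1
  f0 <- f; f0$gamma1_hat <- 0; f0$statistic <- 0; f0$p_value <- 1
  w0 <- wald_trend_test(f0)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)
  expect_false(w0$reject)
})
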