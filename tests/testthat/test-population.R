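# Synthetic frame construction and response simulation.

test_that("default frame reproduces the configured stratum and class structure", {
  fr <- build_frame(seed = 11)
  expect_s3_class(fr, "population_frame")
  expect_equal(nrow(fr), 684)
  expect_false(anyDuplicated(fr$site_id) > 0)
  expect_equal(sum(fr$stratum == "high"), 598)
  expect_equal(sum(fr$stratum == "low"), 86)
  # stratum label consistent with the elevation cutoff
  expect_true(all((fr$elevation >= 3100) == (fr$stratum == "high")))
  # class counts follow largest-remainder apportionment of normalized shares
  oracle <- function(n, p) {
    p <- p / sum(p); raw <- n * p; cnt <- floor(raw)
    rem <- n - sum(cnt)
    if (rem > 0) {
      frac <- raw - cnt
      cnt[order(-frac, seq_along(frac))[seq_len(rem)]] <-
        cnt[order(-frac, seq_along(frac))[seq_len(rem)]] + 1
    }
    cnt
  }
  expect_equal(as.integer(table(factor(fr$cost_class, levels = 1:6))),
               as.integer(oracle(684, c(6, 13, 29, 25, 18, 8))))
  expect_true(all(fr$x >= 0 & fr$x <= 1 & fr$y >= 0 & fr$y <= 1))
})

test_that("cost classes apportion by largest remainder at other sizes", {
  oracle <- function(n, p) {
    p <- p / sum(p); raw <- n * p; cnt <- floor(raw)
    rem <- n - sum(cnt)
    if (rem > 0) {
      idx <- order(-(raw - cnt), seq_along(p))[seq_len(rem)]
      cnt[idx] <- cnt[idx] + 1
    }
    as.integer(cnt)
  }
  for (n in c(100, 237, 684)) {
    expect_equal(largest_remainder(n, c(6, 13, 29, 25, 18, 8) / 99),
                 oracle(n, c(6, 13, 29, 25, 18, 8)))
    expect_equal(sum(largest_remainder(n, c(6, 13, 29, 25, 18, 8))), n)
  }
  # exact proportions need no remainder distribution
  expect_equal(largest_remainder(100, c(0.2, 0.3, 0.5)), c(20L, 30L, 50L))
})

test_that("degenerate single-stratum single-class frames are supported", {
  fr <- build_frame(n_sites = 100, strata_spec = c(high = 1), cost_spec = 1,
                    seed = 3)
  expect_equal(unname(table(fr$stratum)[["high"]]), 100)
  expect_true(all(fr$cost_class == 1))
})

test_that("misconfigured frames are rejected", {
  expect_error(build_frame(strata_spec = c(high = 500, low = 100)),
               "sum to 600")
  expect_error(build_frame(cost_spec = c(0.5, 0.1)), "sum")
})

test_that("travel-cost proxy is correlated with elevation near r = 0.72", {
  set.seed(21)
  rs <- replicate(5, {
    fr <- build_frame()
    cor(fr$travel, fr$elevation)
  })
  expect_true(all(abs(rs - 0.72) < 0.1))
  # cost classes are a monotone coarsening of the proxy
  fr <- build_frame(seed = 22)
  expect_gt(cor(fr$cost_class, fr$travel, method = "spearman"), 0.9)
})

test_that("variance-composition modification conserves total variance", {
  m <- population_model()
  m2 <- modify_variance_composition(m, 1e-4)
  expect_equal(m2$sigma2_b, 1e-4)
  expect_equal(m2$sigma2_a - m$sigma2_a, 0.0156, tolerance = 1e-12)
  tot <- function(x) x$sigma2_b + x$sigma2_a + x$sigma2_t + x$sigma2_e
  expect_equal(tot(m), tot(m2), tolerance = 1e-12)
  expect_identical(modify_variance_composition(m, m$sigma2_b)$sigma2_a, m$sigma2_a)
  expect_error(modify_variance_composition(m, 1), "exceeds")
})

test_that("noise-free model yields an exact plane with shared year effects", {
  m <- population_model(gamma0 = 2, gamma1 = 0.03,
                        sigma2_b = 0, sigma2_a = 0, sigma2_t = 0, sigma2_e = 0,
                        years = 0:5)
  fr <- build_frame(n_sites = 50, strata_spec = c(high = 1), cost_spec = 1,
                    model = m, seed = 4)
  yy <- simulate_response(fr, m, seed = 5)
  expect_equal(dim(yy), c(50, 6))
  for (j in 1:6) expect_equal(unname(yy[, j]), rep(2 + 0.03 * (j - 1), 50))
})

test_that("year effects are shared within year and the mean surface is the trend line", {
  m <- population_model(gamma1 = log(1.01), years = 0:11)
  fr <- build_frame(n_sites = 2000, strata_spec = c(high = 1), cost_spec = 1,
                    model = m, seed = 6)
  yy <- simulate_response(fr, m, seed = 7, keep_effects = TRUE)
  b <- attr(yy, "b_j")
  # subtracting everything but b_j leaves a constant within each year
  det <- yy - (m$gamma0 + fr$a_i + outer(m$gamma1 + fr$t_i, m$years) +
                 attr(yy, "e_ij"))
  expect_equal(unname(apply(det, 2, stats::sd)), rep(0, 12), tolerance = 1e-12)
  expect_equal(unname(det[1, ]), b, tolerance = 1e-12)
  # population mean per year tracks gamma0 + x_j gamma1 within Monte Carlo error
  mu <- colMeans(yy)
  resid <- mu - (m$gamma0 + m$years * m$gamma1) - b
  expect_lt(max(abs(resid)), 4 * sqrt((m$sigma2_a + m$sigma2_e) / 2000 +
                                        m$sigma2_t * max(m$years)^2 / 2000))
})

test_that("method-of-moments recovery matches the realized variance components", {
  m <- population_model(gamma1 = 0.01, years = 0:11)
  fr <- build_frame(n_sites = 2000, strata_spec = c(high = 1), cost_spec = 1,
                    model = m, seed = 8)
  yy <- simulate_response(fr, m, seed = 9, keep_effects = TRUE)
  x <- m$years; S <- nrow(fr); J <- length(x)
  Sxx <- sum((x - mean(x))^2)
  # independent moment-matching oracle
  bhat <- colMeans(yy) - (m$gamma0 + x * m$gamma1)   # year-effect track
  det <- sweep(yy, 2, colMeans(yy))                  # remove year means
  a_hat <- t_hat <- e_ms <- numeric(S)
  for (i in seq_len(S)) {
    fit <- stats::lm.fit(cbind(1, x), det[i, ])
    a_hat[i] <- fit$coefficients[1] + mean(x) * fit$coefficients[2]
    t_hat[i] <- fit$coefficients[2]
    e_ms[i] <- sum(fit$residuals^2) / (J - 2)
  }
  sig_e <- mean(e_ms)
  sig_t <- stats::var(t_hat) - sig_e / Sxx
  sig_a_ctr <- stats::var(a_hat) - sig_e / J          # intercept at mean(x)
  a_real <- fr$a_i + mean(x) * fr$t_i
  expect_equal(sig_e, stats::var(as.vector(attr(yy, "e_ij"))), tolerance = 0.1)
  expect_equal(sig_t, stats::var(fr$t_i), tolerance = 0.1)
  expect_equal(sig_a_ctr, stats::var(a_real), tolerance = 0.1)
  expect_equal(stats::var(bhat), stats::var(attr(yy, "b_j")), tolerance = 0.1)
})

test_that("invalid site covariance is rejected", {
  expect_error(population_model(sigma2_a = 0.01, sigma2_t = 0.01, sigma_at = 0.5),
               "positive semidefinite")
  expect_error(population_model(sigma2_e = -1), "nonnegative")
})
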