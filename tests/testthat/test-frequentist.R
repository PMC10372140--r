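shasta_complete <- function() {
  x <- shasta_capacity()
  pcs2_sample(x, censoring_scheme(20, 20, rep(0, 20)))
}

test_that("censored log-likelihood matches a term-by-term hand sum", {
  smp <- toy_sample()
  a <- 1.7; b <- 0.9
  x <- smp$x; R <- smp$scheme$removals; m <- 3
  hand <- m * log(a) + m * log(b) + (a - 1) * sum(log(x)) +
    sum((b * (R + 1) - 1) * log(1 - x^a))
  expect_equal(loglik_pcs2(a, b, smp), hand, tolerance = 1e-12)
  # ordering constant: C = n(n-R1-1)(n-R1-R2-2) = 6*3*1
  expect_equal(loglik_pcs2(a, b, smp, include_constant = TRUE) -
                 loglik_pcs2(a, b, smp), log(6 * 3 * 1))
})

test_that("uniform parameters give zero log-likelihood on uncensored data", {
  smp <- pcs2_sample(c(0.1, 0.4, 0.8), censoring_scheme(3, 3, c(0, 0, 0)))
  expect_equal(loglik_pcs2(1, 1, smp), 0)
})

test_that("complete-sample fit reproduces the reservoir-data likelihood value", {
  f <- mle_fit(shasta_complete())
  expect_true(f$converged)
  expect_equal(f$loglik, 13.4747, tolerance = 1e-3)
  # beta always satisfies its closed form at the returned alpha
  x <- shasta_capacity()
  expect_equal(f$beta, -20 / sum(log1p(-x^f$alpha)), tolerance = 1e-10)
})

test_that("score vanishes at the MLE and the alpha=1 submodel closes", {
  s <- rpcs2(censoring_scheme(40, 25, "15,0*24"), 1.3, 2.1, seed = 12)
  f <- mle_fit(s)
  expect_lt(max(abs(score_pcs2(f$alpha, f$beta, s))), 1e-6)
  # fixing alpha = 1 on complete data: beta-hat = -n / sum log(1 - x)
  x <- rkum(30, 1, 2, seed = 4)
  smp <- pcs2_sample(x, censoring_scheme(30, 30, rep(0, 30)))
  bhat <- -30 / sum(log1p(-x))
  expect_equal(score_pcs2(1, bhat, smp)[["beta"]], 0, tolerance = 1e-10)
})

test_that("MLE agrees with an adaptive grid-search oracle on many instances", {
  set.seed(91)
  for (k in 1:20) {
    a0 <- runif(1, 0.4, 3); b0 <- runif(1, 0.4, 3)
    n <- sample(8:14, 1); m <- sample(5:n, 1)
    R <- rep(0, m); R[sample(m, 1)] <- n - m
    s <- rpcs2(censoring_scheme(n, m, R), a0, b0)
    f <- mle_fit(s)
    g <- grid_maximize(function(a, b) loglik_pcs2(a, b, s))
    expect_lt(abs(f$alpha - g$alpha), 2 * g$res_alpha + 1e-6)
    expect_lt(abs(f$beta - g$beta), 2 * g$res_beta + 1e-6)
    expect_gte(f$loglik, g$value - 1e-8)
  }
})

test_that("observed information matches finite differences and inverts exactly", {
  smp <- toy_sample()
  a <- 1.4; b <- 2.2
  oi <- observed_information(a, b, smp)
  H <- num_hessian(function(aa, bb) loglik_pcs2(aa, bb, smp), a, b)
  expect_equal(oi$info, -H, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(oi$info %*% oi$vcov, diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  # closed form l_bb = -m/beta^2
  expect_equal(oi$info[2, 2], 3 / b^2)
  smp20 <- shasta_complete()
  expect_equal(observed_information(2, 1, smp20)$info[2, 2], 20)
})

test_that("Wald intervals follow the normal quantile arithmetic", {
  f <- structure(list(alpha = 1, beta = 2,
                      vcov = matrix(c(0.04, 0, 0, 0), 2, 2),
                      method = "MLE", converged = TRUE,
                      sample = toy_sample(), loglik = 0),
                 class = "kum_fit")
  ci <- asymptotic_ci(f, 0.95)
  expect_equal(ci["alpha", "lower"], 1 - 1.959964 * 0.2, tolerance = 1e-6)
  expect_equal(ci["alpha", "upper"], 1 + 1.959964 * 0.2, tolerance = 1e-6)
  # zero variance: degenerate interval at the estimate
  expect_equal(ci["beta", "lower"], 2)
  expect_equal(ci["beta", "upper"], 2)
  expect_false(any(ci$truncated))
  # negative lower bounds truncate to zero and are flagged
  f$vcov <- matrix(c(9, 0, 0, 0.01), 2, 2)
  ci2 <- asymptotic_ci(f, 0.95)
  expect_equal(ci2["alpha", "lower"], 0)
  expect_true(ci2["alpha", "truncated"])
  expect_error(asymptotic_ci(f, 1.2), "level")
})
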