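diffuse <- gamma_priors(1, 0.01, 1, 0.01)

make_fit <- function(n = 40, a = 2, b = 3, seed = 11) {
  s <- rpcs2(censoring_scheme(n, n, rep(0, n)), a, b, seed = seed)
  list(sample = s, mle = mle_fit(s))
}

test_that("derivative ledger matches closed forms and finite differences", {
  fx <- make_fit(30, 1.5, 1)
  ws <- lindley_workspace(fx$sample, fx$mle, diffuse)
  # exact identities of the model
  expect_identical(ws$l_abb, 0)
  expect_equal(ws$l_bbb, 2 * 30 / fx$mle$beta^3)
  # third derivatives against finite differences of the log-likelihood
  a <- fx$mle$alpha; b <- fx$mle$beta
  h <- 1e-3
  num_aaa <- (loglik_pcs2(a + 2 * h, b, fx$sample) -
                2 * loglik_pcs2(a + h, b, fx$sample) +
                2 * loglik_pcs2(a - h, b, fx$sample) -
                loglik_pcs2(a - 2 * h, b, fx$sample)) / (2 * h^3)
  expect_equal(ws$l_aaa, num_aaa, tolerance = 1e-3)
  # l_aba = d/da of l_ab via finite difference on the analytic mixed second
  lab_of <- function(aa)
    -observed_information(aa, b, fx$sample)$info[1, 2] * -1  # info = -l_ab
  num_aba <- (-observed_information(a + h, b, fx$sample)$info[1, 2] -
                -observed_information(a - h, b, fx$sample)$info[1, 2]) / (2 * h)
  expect_equal(ws$l_aba, num_aba, tolerance = 1e-4)
  # sigma is the inverse negative Hessian = observed-information inverse
  expect_equal(ws$sigma, observed_information(a, b, fx$sample)$vcov,
               tolerance = 1e-12)
})

test_that("with flat prior and zero curvature the expansion returns the MLE", {
  fx <- make_fit()
  ws <- lindley_workspace(fx$sample, fx$mle, diffuse)
  ws$rho_a <- ws$rho_b <- 0
  ws$l_aaa <- ws$l_aba <- ws$l_bbb <- 0
  expand <- getFromNamespace("lindley_expand", "kumacens")
  expect_equal(expand(ws, fx$mle$alpha, 1, 0, 0, 0, 0), fx$mle$alpha)
  expect_equal(expand(ws, fx$mle$beta, 0, 1, 0, 0, 0), fx$mle$beta)
})

test_that("asymmetric losses reduce to squared error in their limits", {
  fx <- make_fit(50, 0.8, 1.6, seed = 21)
  se <- lindley_estimate(fx$sample, fx$mle, diffuse, loss_spec("SE"))
  for (cc in c(1e-6, -1e-6)) {
    lx <- lindley_estimate(fx$sample, fx$mle, diffuse,
                           loss_spec("LINEX", c = cc))
    expect_equal(unname(lx), unname(se), tolerance = 1e-4)
  }
  # GE with q = -1 targets E[theta]: identical to squared error algebraically
  ge <- lindley_estimate(fx$sample, fx$mle, diffuse, loss_spec("GE", q = -1))
  expect_equal(unname(ge), unname(se), tolerance = 1e-10)
})

test_that("squared-error expansion tracks quadrature posterior means", {
  fx <- make_fit(40, 2, 3, seed = 11)
  est <- lindley_estimate(fx$sample, fx$mle, diffuse, loss_spec("SE"))
  lpost <- function(a, b)
    loglik_pcs2(a, b, fx$sample) +
      (diffuse$a1 - 1) * log(a) - diffuse$b1 * a +
      (diffuse$a2 - 1) * log(b) - diffuse$b2 * b
  as <- seq(fx$mle$alpha * 0.4, fx$mle$alpha * 2.2, length.out = 400)
  bs <- seq(fx$mle$beta * 0.3, fx$mle$beta * 2.8, length.out = 400)
  W <- exp(outer(as, bs, Vectorize(lpost)) - lpost(fx$mle$alpha, fx$mle$beta))
  pm_a <- sum(W * as) / sum(W)
  pm_b <- sum(t(W) * bs) / sum(W)
  expect_lt(abs(est[["alpha"]] - pm_a) / pm_a, 0.10)
  expect_lt(abs(est[["beta"]] - pm_b) / pm_b, 0.10)
})

test_that("informative priors pull the expansion toward the prior mean", {
  fx <- make_fit(40, 0.5, 0.5, seed = 31)
  tight <- gamma_priors(25, 50, 25, 50)    # mean 0.5, sd 0.1
  est <- lindley_estimate(fx$sample, fx$mle, tight, loss_spec("SE"))
  expect_lt(abs(est[["alpha"]] - 0.5), abs(fx$mle$alpha - 0.5) + 1e-9)
})

test_that("expansion overshoot raises a named error instead of clamping", {
  # tiny censored sample with a hostile prior makes the inner LINEX
  # expectation go nonpositive
  s <- rpcs2(censoring_scheme(5, 4, c(1, 0, 0, 0)), 0.5, 0.5, seed = 140)
  f <- mle_fit(s)
  hostile <- gamma_priors(0.1, 40, 0.1, 40)
  err <- tryCatch(
    lindley_estimate(s, f, hostile, loss_spec("LINEX", c = 10)),
    error = function(e) conditionMessage(e))
  expect_match(err, "overshoot")
})
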