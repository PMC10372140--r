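test_that("log conditional of alpha matches a symbolic hand evaluation", {
  s <- pcs2_sample(c(0.3, 0.6), censoring_scheme(5, 2, c(2, 1)))
  pr <- gamma_priors(1.5, 2, 2.5, 3)
  a <- 1.2; b <- 0.7
  x <- s$x; R <- c(2, 1); m <- 2
  hand <- (m + 1.5 - 1) * log(a) + (a - 1) * sum(log(x)) -
    sum(log(1 - x^a)) + b * sum((R + 1) * log(1 - x^a)) - 2 * a
  expect_equal(log_conditional_alpha(a, b, s, pr), hand, tolerance = 1e-12)
  expect_identical(log_conditional_alpha(-1, b, s, pr), -Inf)
})

test_that("conditional differences equal joint posterior differences in alpha", {
  s <- rpcs2(censoring_scheme(12, 8, "4,0*7"), 1.5, 2, seed = 3)
  pr <- gamma_priors(2, 2, 2, 2)
  ljoint <- function(a, b)
    loglik_pcs2(a, b, s) + (pr$a1 - 1) * log(a) - pr$b1 * a +
      (pr$a2 - 1) * log(b) - pr$b2 * b
  b <- 1.7
  d_cond <- log_conditional_alpha(2.1, b, s, pr) -
    log_conditional_alpha(0.9, b, s, pr)
  d_joint <- ljoint(2.1, b) - ljoint(0.9, b)
  expect_equal(d_cond, d_joint, tolerance = 1e-10)
})

test_that("gamma conditional moments match analytic values when alpha is frozen", {
  s <- rpcs2(censoring_scheme(20, 15, "5,0*14"), 1, 1, seed = 9)
  pr <- gamma_priors(2, 3, 2, 3)
  f <- mle_fit(s)
  d <- sample_posterior(s, pr, mcmc_config(1e5, 100, proposal_sd = 0, seed = 13),
                        mle = f)
  expect_true(all(d$alpha == f$alpha))    # frozen chain
  rate <- pr$b2 - sum((s$scheme$removals + 1) * log1p(-s$x^f$alpha))
  shp <- s$scheme$m + pr$a2
  N <- length(d$beta)
  expect_lt(abs(mean(d$beta) - shp / rate),
            3 * sqrt(shp / rate^2 / N))
  expect_lt(abs(var(d$beta) - shp / rate^2),
            4 * shp / rate^2 * sqrt(2 / N))
})

test_that("chains are bit-reproducible under a fixed seed", {
  s <- rpcs2(censoring_scheme(20, 15, "5,0*14"), 0.8, 1.2, seed = 1)
  pr <- gamma_priors(2, 2, 2, 2)
  cfg <- mcmc_config(500, 100, seed = 77)
  d1 <- sample_posterior(s, pr, cfg)
  d2 <- sample_posterior(s, pr, cfg)
  expect_identical(d1$alpha, d2$alpha)
  expect_identical(d1$beta, d2$beta)
  expect_true(all(d1$alpha > 0) && all(d1$beta > 0))
})

test_that("posterior sampler agrees with quadrature on a small instance", {
  s <- rpcs2(censoring_scheme(8, 5, "3,0*4"), 1.5, 2, seed = 21)
  pr <- gamma_priors(2, 2, 2, 2)
  d <- sample_posterior(s, pr, mcmc_config(40000, 2000, seed = 5))
  lpost <- function(a, b)
    loglik_pcs2(a, b, s) + (pr$a1 - 1) * log(a) - pr$b1 * a +
      (pr$a2 - 1) * log(b) - pr$b2 * b
  as <- seq(0.05, 8, length.out = 500)
  bs <- seq(0.05, 12, length.out = 500)
  W <- exp(outer(as, bs, Vectorize(lpost)) - lpost(1.5, 2))
  pm_a <- sum(W * as) / sum(W)
  pm_b <- sum(t(W) * bs) / sum(W)
  est <- point_estimates(d)
  # generous MC band: heavy right tails at m = 5
  expect_lt(abs(est[["alpha"]] - pm_a) / pm_a, 0.05)
  expect_lt(abs(est[["beta"]] - pm_b) / pm_b, 0.05)
})

test_that("loss-based point estimates follow their defining formulas", {
  fake <- structure(list(alpha = rep(2, 300), beta = rep(2, 300),
                         acceptance_rate = 1,
                         config = mcmc_config(300, 0, seed = 1)),
                    class = "kum_draws")
  for (l in list(loss_spec("SE"), loss_spec("LINEX", c = 2),
                 loss_spec("GE", q = 3)))
    expect_equal(unname(point_estimates(fake, l)), c(2, 2), tolerance = 1e-12)
  # two-point chain, LINEX c = 1: direct evaluation of the estimator
  two <- fake
  two$alpha <- two$beta <- rep(c(1, 3), 150)
  expect_equal(point_estimates(two, loss_spec("LINEX", c = 1))[["alpha"]],
               -log((exp(-1) + exp(-3)) / 2), tolerance = 1e-12)
  # LINEX tends to the posterior mean as c -> 0
  skewed <- fake
  set.seed(2); skewed$alpha <- skewed$beta <- rgamma(300, 2, 3)
  expect_equal(point_estimates(skewed, loss_spec("LINEX", c = 1e-8))[["alpha"]],
               mean(skewed$alpha), tolerance = 1e-6)
  # extreme c must not overflow thanks to log-sum-exp
  expect_true(is.finite(
    point_estimates(skewed, loss_spec("LINEX", c = -800))[["alpha"]]))
})

test_that("highest posterior density intervals are shortest credible windows", {
  grid_chain <- seq(0, 1, by = 0.01)       # N = 101
  h <- hpd_interval(grid_chain, 0.95)
  expect_equal(unname(h["upper"] - h["lower"]), 0.95, tolerance = 1e-12)
  # exact tie among all windows: the leftmost is returned
  h_int <- hpd_interval(0:100, 0.95)
  expect_equal(unname(h_int), c(0, 95), ignore_attr = TRUE)
  nrm <- rnorm(1e5)
  set.seed(4); nrm <- rnorm(1e5)
  hn <- hpd_interval(nrm, 0.95)
  expect_equal(unname(hn["lower"]), -1.96, tolerance = 0.05)
  expect_equal(unname(hn["upper"]), 1.96, tolerance = 0.05)
  # never wider than the equal-tailed interval on skewed chains
  for (sd in 1:5) {
    set.seed(sd)
    ch <- rgamma(5000, shape = runif(1, 0.5, 3), rate = 1)
    hp <- hpd_interval(ch, 0.9)
    eq <- quantile(ch, c(0.05, 0.95), names = FALSE)
    expect_lte(hp["upper"] - hp["lower"], eq[2] - eq[1] + 1e-12)
  }
  expect_error(hpd_interval(grid_chain, 1.5), "level")
})

test_that("moment matching recovers gamma hyperparameters exactly", {
  # mean 2, k-1 variance 0.5  ->  a = 8, b = 4
  pr <- elicit_hyperparameters(c(1.5, 2.5), c(1.5, 2.5))
  expect_equal(pr$a1, 8)
  expect_equal(pr$b1, 4)
  set.seed(6)
  ah <- rgamma(50, 3, 2); bh <- rgamma(50, 4, 1)
  pr2 <- elicit_hyperparameters(ah, bh)
  expect_equal(pr2$a1 / pr2$b1, mean(ah))
  expect_equal(pr2$a1 / pr2$b1^2, var(ah))
  expect_equal(pr2$a2 / pr2$b2, mean(bh))
  expect_equal(pr2$a2 / pr2$b2^2, var(bh))
  expect_error(elicit_hyperparameters(c(1, 1), c(1, 2)), "variance")
})
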