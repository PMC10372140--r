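#' MCMC sampler configuration
#'
#' @param draws total number of draws `M` (default 10000).
#' @param burnin number of initial draws discarded (default 2000).
#' @param proposal_sd standard deviation of the normal random-walk proposal
#'   for `alpha`, or `"auto"` (default) to use the asymptotic standard error
#'   \eqn{\sqrt{\widehat{var}(\hat\alpha)}} from the MLE fit.
#' @param thin keep every `thin`-th post-burn-in draw (default 1).
#' @param seed optional integer for reproducibility.
#' @return object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(draws = 10000, burnin = 2000, proposal_sd = "auto",
                        thin = 1, seed = NULL) {
  if (burnin >= draws) stop("'burnin' must be smaller than 'draws'", call. = FALSE)
  if (thin < 1) stop("'thin' must be >= 1", call. = FALSE)
  if (!identical(proposal_sd, "auto") &&
      (!is.numeric(proposal_sd) || proposal_sd < 0))
    stop("'proposal_sd' must be \"auto\" or a nonnegative number", call. = FALSE)
  structure(list(draws = as.integer(draws), burnin = as.integer(burnin),
                 proposal_sd = proposal_sd, thin = as.integer(thin),
                 seed = seed),
            class = "mcmc_config")
}

#' Log full conditional density of alpha
#'
#' Up to an additive constant, the conditional posterior of \eqn{\alpha}
#' given \eqn{\beta} derived from the joint posterior under independent
#' gamma priors:
#' \deqn{(m + a_1 - 1)\log\alpha + (\alpha-1)\sum_i \log x_{(i)}
#'   - \sum_i \log(1-x_{(i)}^\alpha)
#'   + \beta\sum_i (R_i+1)\log(1-x_{(i)}^\alpha) - b_1\alpha.}
#'
#' @param alpha evaluation point (returns `-Inf` for `alpha <= 0`).
#' @param beta current value of the second shape parameter.
#' @param sample a [pcs2_sample()].
#' @param priors a [gamma_priors()].
#' @return scalar log density (unnormalized).
#' @export
log_conditional_alpha <- function(alpha, beta, sample, priors) {
  stopifnot(inherits(sample, "pcs2_sample"), inherits(priors, "gamma_priors"))
  if (!is.finite(alpha) || alpha <= 0) return(-Inf)
  x <- sample$x
  R <- sample$scheme$removals
  m <- sample$scheme$m
  z <- log1p(-x^alpha)
  (m + priors$a1 - 1) * log(alpha) + (alpha - 1) * sum(log(x)) -
    sum(z) + beta * sum((R + 1) * z) - priors$b1 * alpha
}

#' Metropolis-Hastings-within-Gibbs posterior sampling
#'
#' Alternates (i) an exact Gibbs draw of \eqn{\beta} from its gamma full
#' conditional, Gamma(shape \eqn{m+a_2}, rate
#' \eqn{b_2 - \sum_i (R_i+1)\log(1-x_{(i)}^\alpha)}) -- the rate is positive
#' because the log terms are negative -- and (ii) a random-walk
#' Metropolis-Hastings update of \eqn{\alpha} with a normal proposal,
#' accepting with probability \eqn{\min(1, \pi_1(\alpha^*)/\pi_1(\alpha))}.
#' Nonpositive proposals are rejected (zero prior mass), which preserves
#' detailed balance.  The chain starts at the MLE.
#'
#' @param sample a [pcs2_sample()].
#' @param priors a [gamma_priors()].
#' @param config an [mcmc_config()].
#' @param mle optional precomputed [mle_fit()] (computed if missing).
#' @return object of class `"kum_draws"`: list with numeric chains `alpha`
#'   and `beta` of length `draws`, `acceptance_rate`, `config`, and the
#'   initializing `mle`.
#' @examples
#' s <- rpcs2(censoring_scheme(40, 30, "10,0*29"), 0.5, 0.5, seed = 5)
#' d <- sample_posterior(s, gamma_priors(2, 4, 2, 4),
#'                       mcmc_config(2000, 500, seed = 1))
#' point_estimates(d, loss_spec("SE"))
#' @export
sample_posterior <- function(sample, priors, config = mcmc_config(),
                             mle = NULL) {
  stopifnot(inherits(sample, "pcs2_sample"), inherits(priors, "gamma_priors"),
            inherits(config, "mcmc_config"))
  if (is.null(mle)) mle <- mle_fit(sample)
  if (!isTRUE(mle$converged))
    stop("MLE initialization did not converge", call. = FALSE)
  S <- if (identical(config$proposal_sd, "auto")) {
    if (is.null(mle$vcov)) stop("no vcov available for \"auto\" proposal sd",
                                call. = FALSE)
    sqrt(mle$vcov[1, 1])
  } else config$proposal_sd
  if (!is.null(config$seed)) set.seed(config$seed)

  x <- sample$x
  R <- sample$scheme$removals
  m <- sample$scheme$m
  a1 <- priors$a1; b1 <- priors$b1; a2 <- priors$a2; b2 <- priors$b2
  sum_lx <- sum(log(x))
  # per-alpha sufficient pieces: T = sum (R+1) z, U = sum z, z = log(1-x^alpha)
  pieces <- function(a) {
    z <- log1p(-x^a)
    c(sum((R + 1) * z), sum(z))
  }
  lc <- function(a, pc, beta)
    (m + a1 - 1) * log(a) + (a - 1) * sum_lx - pc[2] + beta * pc[1] - b1 * a

  M <- config$draws
  alpha_chain <- beta_chain <- numeric(M)
  cur_a <- mle$alpha
  cur_p <- pieces(cur_a)
  accepted <- 0L
  for (i in seq_len(M)) {
    rate <- b2 - cur_p[1]
    stopifnot(rate > 0)                    # log terms are negative for valid data
    beta_i <- rgamma(1, shape = m + a2, rate = rate)
    prop_a <- rnorm(1, cur_a, S)
    if (prop_a > 0 && S > 0) {
      prop_p <- pieces(prop_a)
      if (log(runif(1)) <
          lc(prop_a, prop_p, beta_i) - lc(cur_a, cur_p, beta_i)) {
        cur_a <- prop_a
        cur_p <- prop_p
        accepted <- accepted + 1L
      }
    }
    alpha_chain[i] <- cur_a
    beta_chain[i] <- beta_i
  }
  structure(list(alpha = alpha_chain, beta = beta_chain,
                 acceptance_rate = accepted / M,
                 config = config, mle = mle),
            class = "kum_draws")
}

#' @export
print.kum_draws <- function(x, ...) {
  kept <- retained(x)
  cat(sprintf("Posterior draws: %d total, %d after burn-in/thinning\n",
              x$config$draws, length(kept$alpha)))
  cat(sprintf("  acceptance rate (alpha updates): %.3f\n", x$acceptance_rate))
  cat(sprintf("  posterior means: alpha %.4f, beta %.4f\n",
              mean(kept$alpha), mean(kept$beta)))
  invisible(x)
}

retained <- function(draws) {
  idx <- seq(draws$config$burnin + 1L, draws$config$draws,
             by = draws$config$thin)
  list(alpha = draws$alpha[idx], beta = draws$beta[idx])
}

log_sum_exp <- function(v) {
  mx <- max(v)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(v - mx)))
}

#' Bayes point estimates from posterior draws
#'
#' Post-burn-in estimators for each loss: squared error is the posterior
#' mean; LINEX is \eqn{-(1/c)\log \overline{e^{-c\theta}}}; general entropy
#' is \eqn{(\overline{\theta^{-q}})^{-1/q}}.  The exponential averages are
#' computed in log-sum-exp form so extreme `c` or `q` cannot overflow.
#'
#' @param draws a [sample_posterior()] result (at least 100 retained draws).
#' @param loss a [loss_spec()].
#' @return named numeric vector `c(alpha, beta)`.
#' @export
point_estimates <- function(draws, loss = loss_spec("SE")) {
  stopifnot(inherits(draws, "kum_draws"), inherits(loss, "loss_spec"))
  kept <- retained(draws)
  if (length(kept$alpha) < 100)
    stop("fewer than 100 retained draws", call. = FALSE)
  est_one <- function(th) {
    n <- length(th)
    switch(loss$kind,
      SE = mean(th),
      LINEX = -(log_sum_exp(-loss$c * th) - log(n)) / loss$c,
      GE = exp(-(log_sum_exp(-loss$q * log(th)) - log(n)) / loss$q))
  }
  c(alpha = est_one(kept$alpha), beta = est_one(kept$beta))
}

#' Highest posterior density interval (Chen-Shao)
#'
#' Sorts the draws and, among all windows
#' \eqn{[\theta_{(j)}, \theta_{(j + \lfloor N(1-\gamma)\rfloor)}]} containing
#' the target mass, returns the shortest; ties are broken by the smallest
#' `j`.
#'
#' @param chain numeric vector of posterior draws (length >= 100), or a
#'   `"kum_draws"` object together with `parameter`.
#' @param level credible level in (0, 1), default 0.95.
#' @param parameter which chain to use when `chain` is a `"kum_draws"`
#'   object.
#' @return numeric vector `c(lower, upper)` with attribute `level`.
#' @export
hpd_interval <- function(chain, level = 0.95, parameter = c("alpha", "beta")) {
  if (inherits(chain, "kum_draws")) {
    parameter <- match.arg(parameter)
    chain <- retained(chain)[[parameter]]
  }
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("'level' must lie in (0, 1)", call. = FALSE)
  N <- length(chain)
  if (N < 100) stop("at least 100 draws are required", call. = FALSE)
  s <- sort(chain)
  offset <- floor(N * level)
  widths <- s[(offset + 1):N] - s[1:(N - offset)]
  j <- which.min(widths)                  # which.min returns the first minimum
  structure(c(lower = s[j], upper = s[j + offset]), level = level)
}

#' Moment-matched gamma prior elicitation from past estimates
#'
#' Given maximum likelihood estimates \eqn{(\hat\alpha^j, \hat\beta^j)} from
#' `k` past samples, equates the gamma prior mean \eqn{a/b} and variance
#' \eqn{a/b^2} to the sample mean and (k-1 denominator) sample variance of
#' the estimates, giving \eqn{b = \bar\theta / s^2} and
#' \eqn{a = \bar\theta^2 / s^2} for each parameter.
#'
#' @param past_alpha_mles,past_beta_mles numeric vectors (length >= 2) of
#'   past maximum likelihood estimates.
#' @return a [gamma_priors()] whose mean and variance reproduce the sample
#'   moments exactly.
#' @export
elicit_hyperparameters <- function(past_alpha_mles, past_beta_mles) {
  for (v in list(past_alpha_mles, past_beta_mles)) {
    if (length(v) < 2) stop("at least two past estimates are required",
                            call. = FALSE)
    if (var(v) == 0) stop("past estimates have zero variance", call. = FALSE)
  }
  ma <- mean(past_alpha_mles); va <- var(past_alpha_mles)
  mb <- mean(past_beta_mles);  vb <- var(past_beta_mles)
  gamma_priors(a1 = ma^2 / va, b1 = ma / va,
               a2 = mb^2 / vb, b2 = mb / vb)
}

#' Elicit priors from simulated complete samples
#'
#' Convenience wrapper reproducing the simulation-study elicitation design:
#' draw `k` complete samples of size `n` from the stated population, fit the
#' MLE to each, and moment-match the gamma priors to the resulting estimate
#' clouds.
#'
#' @param alpha,beta generating shape parameters.
#' @param k number of past samples (default 500).
#' @param n size of each complete sample (default 60).
#' @param seed optional integer.
#' @return a [gamma_priors()].
#' @export
elicit_priors_simulated <- function(alpha, beta, k = 500, n = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sc <- censoring_scheme(n, n, rep(0, n))
  hats <- vapply(seq_len(k), function(j) {
    f <- mle_fit(pcs2_sample(qkum(runif(n), alpha, beta), sc))
    c(f$alpha, f$beta)
  }, numeric(2))
  elicit_hyperparameters(hats[1, ], hats[2, ])
}
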