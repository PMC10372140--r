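#' Maximum likelihood estimation by profile likelihood
#'
#' The score equation in \eqn{\beta} has the closed-form solution
#' \deqn{\hat\beta(\alpha) = \frac{-m}{\sum_i (R_i+1)\log(1-x_{(i)}^\alpha)},}
#' which, substituted into the \eqn{\alpha} score equation, leaves a single
#' monotone profile equation in \eqn{\alpha}.  The root is bracketed by
#' geometric expansion from `init_alpha` and solved with [stats::uniroot()];
#' this makes existence and uniqueness of the maximum cheap to verify.
#'
#' @param sample a [pcs2_sample()] with at least two observations.
#' @param init_alpha starting point for the bracket search (default 1, the
#'   scale-free uniform special case).
#' @param tol convergence tolerance on the profile score root.
#' @param maxit cap on bracket expansions.
#' @return An object of class `"kum_fit"`: list with `alpha`, `beta`,
#'   `vcov` (2x2 asymptotic variance-covariance), `loglik` (at the maximum,
#'   ordering constant excluded), `method = "MLE"`, `converged`,
#'   `iterations`, and the `sample`.
#' @examples
#' s <- rpcs2(censoring_scheme(40, 30, "10,0*29"), 0.5, 0.5, seed = 1)
#' mle_fit(s)
#' @export
mle_fit <- function(sample, init_alpha = 1, tol = 1e-10, maxit = 200) {
  stopifnot(inherits(sample, "pcs2_sample"))
  if (sample$scheme$m < 2)
    stop("at least two observed failures are required", call. = FALSE)
  x <- sample$x
  R <- sample$scheme$removals
  m <- sample$scheme$m
  sum_lx <- sum(log(x))

  beta_of <- function(a) -m / sum((R + 1) * log1p(-x^a))
  profile_score <- function(a) {
    xa <- x^a
    b <- -m / sum((R + 1) * log1p(-xa))
    m / a + sum_lx - sum((b * (R + 1) - 1) * xa * log(x) / (1 - xa))
  }

  # geometric bracket expansion: the profile score decreases in alpha
  lo <- hi <- init_alpha
  it <- 0
  while (profile_score(lo) < 0 && it < maxit) { lo <- lo / 2; it <- it + 1 }
  while (profile_score(hi) > 0 && it < maxit) { hi <- hi * 2; it <- it + 1 }
  if (it >= maxit || profile_score(lo) < 0 || profile_score(hi) > 0) {
    warning("profile score could not be bracketed; fit flagged as non-converged")
    a_hat <- init_alpha
    converged <- FALSE
  } else {
    root <- uniroot(profile_score, c(lo, hi), tol = tol)
    a_hat <- root$root
    it <- it + root$iter
    converged <- abs(profile_score(a_hat)) < 1e-6
  }
  b_hat <- beta_of(a_hat)

  oi <- tryCatch(observed_information(a_hat, b_hat, sample),
                 error = function(e) NULL)
  structure(list(alpha = a_hat, beta = b_hat,
                 vcov = if (is.null(oi)) NULL else oi$vcov,
                 loglik = loglik_pcs2(a_hat, b_hat, sample),
                 method = "MLE", converged = converged, iterations = it,
                 sample = sample),
            class = "kum_fit")
}

#' @export
print.kum_fit <- function(x, ...) {
  cat(sprintf("Kumaraswamy %s fit (m = %d of n = %d)\n",
              x$method, x$sample$scheme$m, x$sample$scheme$n))
  est <- c(alpha = x$alpha, beta = x$beta)
  se <- if (!is.null(x$vcov)) sqrt(pmax(diag(x$vcov), 0)) else rep(NA_real_, 2)
  print(cbind(estimate = est, `std.error` = se))
  cat(sprintf("log-likelihood: %.4f   converged: %s\n",
              x$loglik, x$converged))
  invisible(x)
}

#' Asymptotic (Wald) confidence intervals
#'
#' \eqn{\hat\theta \pm z_{\gamma/2}\sqrt{\widehat{var}(\hat\theta)}} for both
#' shape parameters, using the observed-information variance-covariance
#' matrix of the fit.  Lower bounds falling below zero are truncated to zero
#' (the parameter space is positive) and flagged in the `truncated` column.
#'
#' @param fit a converged [mle_fit()] (or [mps_fit()]) result with a valid
#'   `vcov`.
#' @param level confidence level in (0, 1), default 0.95.
#' @return data.frame with rows `alpha` and `beta` and columns `estimate`,
#'   `lower`, `upper`, `level`, `truncated`.
#' @export
asymptotic_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "kum_fit"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("'level' must lie in (0, 1)", call. = FALSE)
  if (is.null(fit$vcov))
    stop("fit has no variance-covariance matrix", call. = FALSE)
  z <- qnorm(1 - (1 - level) / 2)
  est <- c(alpha = fit$alpha, beta = fit$beta)
  se <- sqrt(pmax(diag(fit$vcov), 0))
  lower_raw <- est - z * se
  data.frame(estimate = est,
             lower = pmax(lower_raw, 0),
             upper = est + z * se,
             level = level,
             truncated = lower_raw < 0,
             row.names = names(est))
}
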