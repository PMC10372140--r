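#' Log-likelihood of a progressively Type-II censored Kumaraswamy sample
#'
#' For observed failures \eqn{x_{(1)} < \dots < x_{(m)}} with removal plan
#' \eqn{(R_1,\dots,R_m)},
#' \deqn{\ell(\alpha,\beta) = m\log\alpha + m\log\beta
#'   + (\alpha-1)\sum_i \log x_{(i)}
#'   + \sum_i \{\beta(R_i+1)-1\}\log(1-x_{(i)}^\alpha),}
#' optionally plus the ordering constant
#' \eqn{\log C = \sum_{i=1}^m \log(n - R_1 - \dots - R_{i-1} - i + 1)},
#' which does not depend on the parameters.  The constant is excluded by
#' default so that complete-sample values coincide with the i.i.d.
#' log-likelihood used by information criteria.
#'
#' @param alpha,beta positive shape parameters.
#' @param sample a [pcs2_sample()].
#' @param include_constant include the ordering constant \eqn{\log C}?
#' @return scalar log-likelihood.
#' @export
loglik_pcs2 <- function(alpha, beta, sample, include_constant = FALSE) {
  stopifnot(inherits(sample, "pcs2_sample"))
  check_shapes(alpha, beta)
  x <- sample$x
  R <- sample$scheme$removals
  m <- sample$scheme$m
  z <- log1p(-x^alpha)
  ll <- m * log(alpha) + m * log(beta) +
    (alpha - 1) * sum(log(x)) + sum((beta * (R + 1) - 1) * z)
  if (include_constant) ll <- ll + log_ordering_constant(sample$scheme)
  ll
}

log_ordering_constant <- function(scheme) {
  n <- scheme$n
  R <- scheme$removals
  m <- scheme$m
  sum(log(n - c(0, cumsum(R[-m])) - (seq_len(m) - 1)))
}

#' Score (gradient) of the censored log-likelihood
#'
#' @inheritParams loglik_pcs2
#' @return numeric vector `c(alpha, beta)` of partial derivatives.
#' @export
score_pcs2 <- function(alpha, beta, sample) {
  stopifnot(inherits(sample, "pcs2_sample"))
  check_shapes(alpha, beta)
  x <- sample$x
  R <- sample$scheme$removals
  m <- sample$scheme$m
  xa <- x^alpha
  w <- xa * log(x) / (1 - xa)
  c(alpha = m / alpha + sum(log(x)) - sum((beta * (R + 1) - 1) * w),
    beta  = m / beta + sum((R + 1) * log1p(-xa)))
}

#' Observed Fisher information and asymptotic variance-covariance matrix
#'
#' Builds the 2x2 observed information \eqn{I = -\nabla^2 \ell} from the
#' closed-form second derivatives
#' \deqn{\ell_{\alpha\alpha} = -m/\alpha^2 - \sum_i \{\beta(R_i+1)-1\}
#'        \frac{x_{(i)}^\alpha (\log x_{(i)})^2}{(1-x_{(i)}^\alpha)^2},\quad
#'       \ell_{\beta\beta} = -m/\beta^2,\quad
#'       \ell_{\alpha\beta} = -\sum_i (R_i+1)
#'        \frac{x_{(i)}^\alpha \log x_{(i)}}{1-x_{(i)}^\alpha},}
#' and inverts it by the 2x2 closed form.  The inverse evaluated at the MLE
#' is the asymptotic variance-covariance matrix of the estimates.
#'
#' @inheritParams loglik_pcs2
#' @return list with `info` (observed information) and `vcov` (its inverse),
#'   both 2x2 matrices with dimnames `alpha`, `beta`.
#' @export
observed_information <- function(alpha, beta, sample) {
  stopifnot(inherits(sample, "pcs2_sample"))
  check_shapes(alpha, beta)
  x <- sample$x
  R <- sample$scheme$removals
  m <- sample$scheme$m
  xa <- x^alpha
  lx <- log(x)
  laa <- -m / alpha^2 - sum((beta * (R + 1) - 1) * xa * lx^2 / (1 - xa)^2)
  lbb <- -m / beta^2
  lab <- -sum((R + 1) * xa * lx / (1 - xa))
  info <- matrix(c(-laa, -lab, -lab, -lbb), 2, 2,
                 dimnames = list(c("alpha", "beta"), c("alpha", "beta")))
  det_i <- info[1, 1] * info[2, 2] - info[1, 2]^2
  if (!is.finite(det_i) || abs(det_i) < 1e-300 * max(abs(info)))
    stop(sprintf(
      "observed information is singular (det = %.3e, condition number = %.3e)",
      det_i, kappa(info)), call. = FALSE)
  vcov <- matrix(c(info[2, 2], -info[1, 2], -info[1, 2], info[1, 1]), 2, 2,
                 dimnames = dimnames(info)) / det_i
  list(info = info, vcov = vcov)
}
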