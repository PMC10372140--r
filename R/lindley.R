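#' Gamma prior hyperparameters
#'
#' Independent Gamma(a1, b1) and Gamma(a2, b2) priors (shape/rate) for the
#' two shape parameters.
#'
#' @param a1,b1 shape and rate of the prior on `alpha`.
#' @param a2,b2 shape and rate of the prior on `beta`.
#' @return object of class `"gamma_priors"`.
#' @export
gamma_priors <- function(a1, b1, a2, b2) {
  v <- c(a1 = a1, b1 = b1, a2 = a2, b2 = b2)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all hyperparameters must be positive", call. = FALSE)
  structure(as.list(v), class = "gamma_priors")
}

#' @export
print.gamma_priors <- function(x, ...) {
  cat(sprintf("Gamma priors: alpha ~ Gamma(%.4g, %.4g), beta ~ Gamma(%.4g, %.4g)\n",
              x$a1, x$b1, x$a2, x$b2))
  cat(sprintf("  prior means %.4g and %.4g\n", x$a1 / x$b1, x$a2 / x$b2))
  invisible(x)
}

#' Loss-function specification for Bayes point estimation
#'
#' @param kind one of `"SE"` (squared error), `"LINEX"` (linear exponential,
#'   needs `c != 0`) or `"GE"` (general entropy, needs `q != 0`).
#' @param c LINEX asymmetry parameter.
#' @param q general-entropy asymmetry parameter.
#' @return object of class `"loss_spec"`.
#' @export
loss_spec <- function(kind = c("SE", "LINEX", "GE"), c = NULL, q = NULL) {
  kind <- match.arg(toupper(kind), c("SE", "LINEX", "GE"))
  if (kind == "LINEX" && (is.null(c) || c == 0))
    stop("LINEX loss requires a nonzero 'c'", call. = FALSE)
  if (kind == "GE" && (is.null(q) || q == 0))
    stop("GE loss requires a nonzero 'q'", call. = FALSE)
  structure(list(kind = kind, c = c, q = q), class = "loss_spec")
}

#' Derivative ledger for Lindley's approximation
#'
#' Evaluates, at the maximum likelihood estimates, every ingredient of the
#' two-parameter Lindley expansion: the log-likelihood second and third
#' derivatives
#' \deqn{\ell_{\alpha\alpha\alpha} = 2m/\alpha^3 - \sum_i \{\beta(R_i+1)-1\}
#'   \frac{x_i^\alpha (1+x_i^\alpha)(\log x_i)^3}{(1-x_i^\alpha)^3}, \quad
#'   \ell_{\alpha\beta\alpha} = -\sum_i (R_i+1)
#'   \frac{x_i^\alpha(\log x_i)^2}{(1-x_i^\alpha)^2},}
#' \eqn{\ell_{\beta\beta\beta} = 2m/\beta^3},
#' \eqn{\ell_{\alpha\beta\beta} = 0}; the log-prior gradient
#' \eqn{\rho_\alpha = (a_1-1)/\hat\alpha - b_1},
#' \eqn{\rho_\beta = (a_2-1)/\hat\beta - b_2}; and
#' \eqn{\sigma}, the inverse of the full negative Hessian (consistent with
#' the observed-information matrix, and making the flat-prior/zero-curvature
#' reduction to the MLE exact).
#'
#' @param sample a [pcs2_sample()].
#' @param mle a converged [mle_fit()] result.
#' @param priors a [gamma_priors()].
#' @return object of class `"lindley_workspace"`: list with `alpha`, `beta`,
#'   `sigma` (2x2), `l_aaa`, `l_aba`, `l_abb`, `l_bbb`, `rho_a`, `rho_b`.
#' @export
lindley_workspace <- function(sample, mle, priors) {
  stopifnot(inherits(sample, "pcs2_sample"), inherits(mle, "kum_fit"),
            inherits(priors, "gamma_priors"))
  if (!isTRUE(mle$converged))
    stop("Lindley expansion requires a converged MLE", call. = FALSE)
  a <- mle$alpha; b <- mle$beta
  x <- sample$x
  R <- sample$scheme$removals
  m <- sample$scheme$m
  xa <- x^a
  lx <- log(x)
  cc <- b * (R + 1) - 1
  sigma <- observed_information(a, b, sample)$vcov
  structure(list(
    alpha = a, beta = b, sigma = sigma,
    l_aaa = 2 * m / a^3 - sum(cc * xa * (1 + xa) * lx^3 / (1 - xa)^3),
    l_aba = -sum((R + 1) * xa * lx^2 / (1 - xa)^2),
    l_abb = 0,
    l_bbb = 2 * m / b^3,
    rho_a = (priors$a1 - 1) / a - priors$b1,
    rho_b = (priors$a2 - 1) / b - priors$b2
  ), class = "lindley_workspace")
}

# Full two-parameter Lindley expansion of the posterior expectation of g:
# E[g] ~ g + 1/2[(g_aa + 2 g_a rho_a) s_aa + (g_ba + 2 g_b rho_a) s_ba
#              + (g_ab + 2 g_a rho_b) s_ab + (g_bb + 2 g_b rho_b) s_bb]
#      + 1/2[(g_a s_aa + g_b s_ab)(l_aaa s_aa + l_aba s_ab + l_aba s_ba + 0)
#          + (g_a s_ba + g_b s_bb)(l_aba s_aa + 0 + 0 + l_bbb s_bb)]
# (terms involving l_abb = l_bba vanish identically for this model).
lindley_expand <- function(ws, g, g_a, g_b, g_aa, g_ab, g_bb) {
  s <- ws$sigma
  g +
    0.5 * ((g_aa + 2 * g_a * ws$rho_a) * s[1, 1] +
           (g_ab + 2 * g_b * ws$rho_a) * s[2, 1] +
           (g_ab + 2 * g_a * ws$rho_b) * s[1, 2] +
           (g_bb + 2 * g_b * ws$rho_b) * s[2, 2]) +
    0.5 * ((g_a * s[1, 1] + g_b * s[1, 2]) *
             (ws$l_aaa * s[1, 1] + 2 * ws$l_aba * s[1, 2]) +
           (g_a * s[2, 1] + g_b * s[2, 2]) *
             (ws$l_aba * s[1, 1] + ws$l_bbb * s[2, 2]))
}

#' Approximate Bayes estimates by Lindley's expansion
#'
#' Closed-form second-order approximations to the posterior expectations
#' defining the Bayes estimators under squared-error, LINEX and
#' general-entropy losses, expanded around the MLE.  For LINEX the expansion
#' approximates \eqn{E[e^{-c\theta}|x]} and the estimate is
#' \eqn{-(1/c)\log\{\cdot\}}; for GE it approximates
#' \eqn{E[\theta^{-q}|x]} and the estimate is \eqn{\{\cdot\}^{-1/q}}.
#'
#' The expansion can overshoot at small `m` and leave the inner expectation
#' nonpositive, in which case an error names the failing loss; callers may
#' fall back to MCMC.  Overshoot is surfaced, never clamped.
#'
#' @inheritParams lindley_workspace
#' @param loss a [loss_spec()].
#' @return named numeric vector `c(alpha, beta)` of approximate Bayes
#'   estimates.
#' @examples
#' s <- rpcs2(censoring_scheme(40, 40, rep(0, 40)), 1, 1, seed = 2)
#' f <- mle_fit(s)
#' lindley_estimate(s, f, gamma_priors(1, 0.01, 1, 0.01), loss_spec("SE"))
#' @export
lindley_estimate <- function(sample, mle, priors, loss = loss_spec("SE")) {
  stopifnot(inherits(loss, "loss_spec"))
  ws <- lindley_workspace(sample, mle, priors)
  est_one <- function(par) {                     # par: 1 = alpha, 2 = beta
    th <- if (par == 1) ws$alpha else ws$beta
    sel <- function(va, vb) if (par == 1) c(va, vb) else c(vb, va)
    switch(loss$kind,
      SE = {
        d1 <- sel(1, 0)
        lindley_expand(ws, th, d1[1], d1[2], 0, 0, 0)
      },
      LINEX = {
        cc <- loss$c
        g <- exp(-cc * th)
        d1 <- sel(-cc * g, 0)
        d2v <- cc^2 * g
        inner <- lindley_expand(ws, g, d1[1], d1[2],
                                if (par == 1) d2v else 0, 0,
                                if (par == 2) d2v else 0)
        if (!is.finite(inner) || inner <= 0)
          stop(sprintf(
            "Lindley expansion overshoot for %s under LINEX loss (inner = %.3g)",
            c("alpha", "beta")[par], inner), call. = FALSE)
        -log(inner) / cc
      },
      GE = {
        q <- loss$q
        g <- th^(-q)
        d1 <- sel(-q * th^(-q - 1), 0)
        d2v <- q * (q + 1) * th^(-q - 2)
        inner <- lindley_expand(ws, g, d1[1], d1[2],
                                if (par == 1) d2v else 0, 0,
                                if (par == 2) d2v else 0)
        if (!is.finite(inner) || inner <= 0)
          stop(sprintf(
            "Lindley expansion overshoot for %s under GE loss (inner = %.3g)",
            c("alpha", "beta")[par], inner), call. = FALSE)
        inner^(-1 / q)
      })
  }
  c(alpha = est_one(1), beta = est_one(2))
}
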