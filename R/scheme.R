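#' Progressive Type-II censoring schemes
#'
#' A censoring scheme records the number of units on test `n`, the number of
#' observed failures `m`, and the removal plan \eqn{(R_1,\dots,R_m)}: at the
#' i-th failure, \eqn{R_i} of the surviving units are withdrawn.  Validity
#' requires \eqn{\sum_i R_i = n - m} with all \eqn{R_i \ge 0}.
#'
#' `removals` may be given as an integer vector, or as a run-length shorthand
#' string such as `"20,0*19"` (meaning 20 followed by nineteen zeros), the
#' compact notation commonly used to tabulate schemes.
#'
#' @param n number of units placed on test.
#' @param m number of failures to be observed.
#' @param removals removal plan: integer vector of length `m`, or a
#'   shorthand string.
#'
#' @return An object of class `"censoring_scheme"`: a list with elements
#'   `n`, `m` and `removals`.
#'
#' @examples
#' censoring_scheme(40, 20, "20,0*19")
#' censoring_scheme(40, 40, rep(0, 40))   # complete sample
#' @export
censoring_scheme <- function(n, m, removals) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a positive integer", call. = FALSE)
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    stop("'m' must be a positive integer", call. = FALSE)
  if (m > n) stop("'m' cannot exceed 'n'", call. = FALSE)
  R <- expand_removals(removals)
  if (length(R) != m)
    stop(sprintf("removal plan has length %d but m = %d", length(R), m),
         call. = FALSE)
  if (any(R != round(R)) || any(!is.finite(R)))
    stop("removals must be finite integers", call. = FALSE)
  if (any(R < 0))
    stop("removals must be nonnegative", call. = FALSE)
  if (sum(R) != n - m)
    stop(sprintf("inconsistent scheme: sum(removals) = %d but n - m = %d",
                 sum(R), n - m), call. = FALSE)
  structure(list(n = as.integer(n), m = as.integer(m),
                 removals = as.integer(R)),
            class = "censoring_scheme")
}

#' Expand run-length shorthand for removal plans
#'
#' Turns `"20,0*19"` into `c(20, rep(0, 19))`.  Numeric input is passed
#' through unchanged.
#'
#' @param removals integer vector or shorthand string.
#' @return integer vector.
#' @export
expand_removals <- function(removals) {
  if (is.numeric(removals)) return(as.integer(removals))
  if (!is.character(removals) || length(removals) != 1L)
    stop("removals must be a numeric vector or a single shorthand string",
         call. = FALSE)
  parts <- strsplit(gsub("[[:space:]]", "", removals), ",", fixed = TRUE)[[1]]
  if (!length(parts)) stop("empty removal specification", call. = FALSE)
  out <- lapply(parts, function(p) {
    if (grepl("*", p, fixed = TRUE)) {
      vr <- strsplit(p, "*", fixed = TRUE)[[1]]
      if (length(vr) != 2L) stop("malformed shorthand token: ", p, call. = FALSE)
      rep(as.integer(vr[1]), as.integer(vr[2]))
    } else as.integer(p)
  })
  unlist(out)
}

#' @export
print.censoring_scheme <- function(x, ...) {
  cat(sprintf("Progressive Type-II censoring scheme: n = %d, m = %d\n",
              x$n, x$m))
  cat("  removals:", format_removals(x$removals), "\n")
  invisible(x)
}

format_removals <- function(R) {
  rl <- rle(R)
  paste(ifelse(rl$lengths > 1,
               sprintf("%d*%d", rl$values, rl$lengths),
               as.character(rl$values)),
        collapse = ",")
}

#' Bind ordered censored observations to a scheme
#'
#' Constructs a progressively Type-II censored sample object from `m`
#' observed failure values (on the unit interval) and their scheme.
#'
#' @param x numeric vector of the `m` observed failures, in (0, 1).  Sorted
#'   internally; strict increase is required (tied failures are rejected).
#' @param scheme a [censoring_scheme()].
#' @return An object of class `"pcs2_sample"`: list with `x` (sorted) and
#'   `scheme`.
#' @export
pcs2_sample <- function(x, scheme) {
  if (!inherits(scheme, "censoring_scheme"))
    stop("'scheme' must be a censoring_scheme", call. = FALSE)
  if (!is.numeric(x) || length(x) != scheme$m)
    stop(sprintf("expected %d observations, got %d", scheme$m, length(x)),
         call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1))
    stop("observations must lie strictly inside (0, 1)", call. = FALSE)
  xs <- sort(x)
  if (any(diff(xs) == 0))
    stop("tied observations: censored order statistics must be strictly increasing",
         call. = FALSE)
  structure(list(x = xs, scheme = scheme), class = "pcs2_sample")
}

#' @export
print.pcs2_sample <- function(x, ...) {
  cat(sprintf("Progressively Type-II censored sample: m = %d of n = %d\n",
              x$scheme$m, x$scheme$n))
  cat("  removals:", format_removals(x$scheme$removals), "\n")
  print(x$x)
  invisible(x)
}

#' Generate a progressively Type-II censored Kumaraswamy sample
#'
#' Draws the `m` censored order statistics in one pass by the
#' Balakrishnan-Sandhu construction: with \eqn{W_1,\dots,W_m} i.i.d.
#' Uniform(0,1), set
#' \deqn{V_i = W_i^{1/(i + R_m + R_{m-1} + \dots + R_{m-i+1})}, \qquad
#'       U_{(i)} = 1 - V_m V_{m-1} \cdots V_{m-i+1},}
#' so that \eqn{U_{(1)} < \dots < U_{(m)}} have the exact joint distribution
#' of progressively censored uniform order statistics; the observations are
#' their Kumaraswamy quantiles.
#'
#' @param scheme a [censoring_scheme()].
#' @param alpha,beta positive shape parameters of the sampled population.
#' @param seed optional integer for reproducibility.
#' @return A [pcs2_sample()].
#' @examples
#' s <- censoring_scheme(10, 5, "5,0*4")
#' rpcs2(s, 2, 5, seed = 1)
#' @export
rpcs2 <- function(scheme, alpha, beta, seed = NULL) {
  if (!inherits(scheme, "censoring_scheme"))
    stop("'scheme' must be a censoring_scheme", call. = FALSE)
  check_shapes(alpha, beta)
  if (!is.null(seed)) set.seed(seed)
  m <- scheme$m
  R <- scheme$removals
  W <- runif(m)
  # exponent of V_i: i plus the removals at the last i failure stages
  V <- W^(1 / (seq_len(m) + cumsum(rev(R))))
  U <- 1 - cumprod(rev(V))
  pcs2_sample(qkum(U, alpha, beta), scheme)
}

#' Apply a censoring scheme to an observed complete dataset
#'
#' Emulates running the life test on recorded data: the smallest remaining
#' value is the next observed failure, after which \eqn{R_i} of the remaining
#' units are withdrawn uniformly at random without replacement.
#'
#' @param data numeric vector of length `scheme$n`, all values in (0, 1).
#' @param scheme a [censoring_scheme()].
#' @param seed optional integer controlling which units are withdrawn.
#' @return A [pcs2_sample()].
#' @export
censor_complete_sample <- function(data, scheme, seed = NULL) {
  if (!inherits(scheme, "censoring_scheme"))
    stop("'scheme' must be a censoring_scheme", call. = FALSE)
  if (length(data) != scheme$n)
    stop(sprintf("data has %d values but the scheme requires n = %d",
                 length(data), scheme$n), call. = FALSE)
  if (any(!is.finite(data)) || any(data <= 0) || any(data >= 1))
    stop("data values must lie strictly inside (0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  remaining <- sort(data)
  obs <- numeric(scheme$m)
  for (i in seq_len(scheme$m)) {
    obs[i] <- remaining[1]
    remaining <- remaining[-1]
    Ri <- scheme$removals[i]
    if (Ri > 0) {
      drop <- sample.int(length(remaining), Ri)
      remaining <- remaining[-drop]
    }
  }
  pcs2_sample(obs, scheme)
}
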