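# Independent oracles used across the suite.

# Adaptive 2-D grid maximizer: log-spaced grid, refined around the argmax.
# Deliberately independent of the package's fitting code paths.
grid_maximize <- function(fn, lo = c(0.02, 0.02), hi = c(60, 60),
                          n_grid = 60, refinements = 4) {
  r <- 1
  while (r <= refinements) {
    as <- exp(seq(log(lo[1]), log(hi[1]), length.out = n_grid))
    bs <- exp(seq(log(lo[2]), log(hi[2]), length.out = n_grid))
    vals <- outer(as, bs, Vectorize(fn))
    idx <- arrayInd(which.max(vals), dim(vals))
    ia <- idx[1]; ib <- idx[2]
    if ((ia == n_grid || ib == n_grid) && r == 1) {
      # argmax on the outer boundary: widen the search box and restart
      hi <- hi * 4
      next
    }
    lo <- c(as[max(ia - 2, 1)], bs[max(ib - 2, 1)])
    hi <- c(as[min(ia + 2, n_grid)], bs[min(ib + 2, n_grid)])
    r <- r + 1
  }
  list(alpha = as[ia], beta = bs[ib], value = vals[ia, ib],
       res_alpha = diff(range(as)) / (n_grid - 1),
       res_beta = diff(range(bs)) / (n_grid - 1))
}

# Central finite-difference gradient and Hessian of a scalar function of
# (alpha, beta).
num_gradient <- function(fn, a, b, h = 1e-5) {
  c((fn(a + h, b) - fn(a - h, b)) / (2 * h),
    (fn(a, b + h) - fn(a, b - h)) / (2 * h))
}

num_hessian <- function(fn, a, b, h = 1e-4) {
  gaa <- (fn(a + h, b) - 2 * fn(a, b) + fn(a - h, b)) / h^2
  gbb <- (fn(a, b + h) - 2 * fn(a, b) + fn(a, b - h)) / h^2
  gab <- (fn(a + h, b + h) - fn(a + h, b - h) -
          fn(a - h, b + h) + fn(a - h, b - h)) / (4 * h^2)
  matrix(c(gaa, gab, gab, gbb), 2, 2)
}

# Fixed small fixture shared by hand-evaluation tests.
toy_sample <- function(m = 3, n = 6, removals = c(2, 1, 0),
                       x = c(0.2, 0.45, 0.7)) {
  pcs2_sample(x, censoring_scheme(n, m, removals))
}
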