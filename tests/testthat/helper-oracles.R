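# Independent oracles and small fixture builders used across the tests.
# These deliberately re-derive quantities by brute force or closed form,
# never by calling the solver code paths they are used to check.

# dense grid search for the binary calibration offset
grid_delta_oracle <- function(eta, target, lo = -15, hi = 15, by = 1e-3) {
  grid <- seq(lo, hi, by = by)
  pred <- vapply(grid, function(d) mean(plogis(eta + d)), 0)
  grid[which.min(abs(pred - target))]
}

# Brent root-finder (stats::uniroot) as a high-precision independent check
uniroot_delta_oracle <- function(eta, target) {
  stats::uniroot(function(d) mean(plogis(eta + d)) - target,
                 lower = -50, upper = 50, tol = 1e-13)$root
}

# nested interval bisection for a 3-level covariate (two offsets): the
# inner loop solves the level-3 equation for d3 given d2; the outer loop
# bisects d2 on its own equation evaluated at the inner solution.
nested_bisection_oracle <- function(eta, targets, iters = 80L) {
  stopifnot(ncol(eta) == 2L, length(targets) == 2L)
  margin <- function(d) {
    e <- exp(sweep(eta, 2L, d, "+"))
    colMeans(e / (1 + rowSums(e)))
  }
  inner <- function(d2) {
    lo <- -60; hi <- 60
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      if (margin(c(d2, mid))[2L] > targets[2L]) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  lo <- -60; hi <- 60
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (margin(c(mid, inner(mid)))[1L] > targets[1L]) hi <- mid else lo <- mid
  }
  d2 <- (lo + hi) / 2
  c(d2, inner(d2))
}

# build a dataset realising exact 2x2 complete-record counts
# (n00, n01, n10, n11) = (x=0,y=0), (x=0,y=1), (x=1,y=0), (x=1,y=1),
# plus optional nonrespondent y counts
counts_2x2_data <- function(n00, n01, n10, n11, mis_y0 = 0, mis_y1 = 0) {
  x <- c(rep("0", n00 + n01), rep("1", n10 + n11), rep(NA, mis_y0 + mis_y1))
  y <- c(rep(0L, n00), rep(1L, n01), rep(0L, n10), rep(1L, n11),
         rep(0L, mis_y0), rep(1L, mis_y1))
  data.frame(x = factor(x, levels = c("0", "1")), y = y)
}
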