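# Independent oracles, deliberately sharing no code with the package fitter.

# Profiled grid-search least squares: for every tau on a 0.01-decade
# lattice, solve the linear subproblem with lm.fit and keep the best SSE.
# For any tau on the lattice this profiled SSE lower-bounds the SSE of any
# (D0, Dinf) HU-lattice search at that tau, so beating this oracle implies
# beating the coarser lattice oracle as well.
oracle_profiled_sse <- function(times, y, lg = seq(-3, 2, by = 0.01)) {
  best <- sum((y - mean(y))^2)
  for (l in lg) {
    X <- cbind(1, exp(-times / 10^l))
    r <- stats::lm.fit(X, y)$residuals
    s <- sum(r^2)
    if (s < best) best <- s
  }
  best
}

# F-distribution upper tail by direct numerical integration of the density
# written from the gamma/beta definition (independent of stats::pf)
oracle_f_tail <- function(f, d1, d2) {
  dens <- function(x) {
    (d1 / d2)^(d1 / 2) * x^(d1 / 2 - 1) *
      (1 + d1 * x / d2)^(-(d1 + d2) / 2) / beta(d1 / 2, d2 / 2)
  }
  stats::integrate(dens, f, Inf, rel.tol = 1e-10)$value
}
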