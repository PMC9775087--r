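# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the integrator below steps the McConnell system
# with classical RK4 instead of a matrix exponential, and the quantile /
# decomposition oracles are brute-force.

# fixed-step RK4 integration of the homogeneous McConnell system; state
# layout matches the propagator: (x_i, y_i, z_i) per state plus a constant
mcconnell_rk4 <- function(delta, omega1, tsat, r1, r2, K, p0, dt = 1e-5,
                          z0 = p0) {
  n <- length(r2)
  A <- matrix(0, 3 * n + 1, 3 * n + 1)
  for (i in seq_len(n)) {
    x <- 3 * i - 2; y <- 3 * i - 1; z <- 3 * i
    A[x, x] <- A[x, x] - r2[i]; A[x, y] <- A[x, y] + delta
    A[y, x] <- A[y, x] - delta; A[y, y] <- A[y, y] - r2[i]
    A[y, z] <- A[y, z] + omega1
    A[z, y] <- A[z, y] - omega1; A[z, z] <- A[z, z] - r1
    A[z, 3 * n + 1] <- A[z, 3 * n + 1] + r1 * p0[i]
    for (j in seq_len(n)) {
      A[x, 3 * j - 2] <- A[x, 3 * j - 2] + K[i, j]
      A[y, 3 * j - 1] <- A[y, 3 * j - 1] + K[i, j]
      A[z, 3 * j]     <- A[z, 3 * j]     + K[i, j]
    }
  }
  m <- c(rbind(0, 0, z0), 1)
  nstep <- ceiling(tsat / dt)
  h <- tsat / nstep
  for (s in seq_len(nstep)) {
    k1 <- A %*% m
    k2 <- A %*% (m + h / 2 * k1)
    k3 <- A %*% (m + h / 2 * k2)
    k4 <- A %*% (m + h * k3)
    m <- m + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  m[3]  # free-state z
}

# brute-force 1.5*IQR rule with the type-7 quantile convention
iqr_oracle <- function(v, k = 1.5) {
  q1 <- quantile(v, 0.25, type = 7)
  q3 <- quantile(v, 0.75, type = 7)
  keep <- logical(length(v))
  for (i in seq_along(v))
    keep[i] <- v[i] >= q1 - k * (q3 - q1) && v[i] <= q3 + k * (q3 - q1)
  list(kept = v[keep], removed = v[!keep])
}

# grid-search solution of the simplex-constrained spectral decomposition
decompose_oracle <- function(spec, free, bound, step = 1e-5) {
  cb <- seq(0, 1, by = step)
  sse <- vapply(cb, function(c)
    sum((spec - ((1 - c) * free + c * bound))^2), 0)
  cb[which.min(sse)]
}

# numeric half-maximum positions of a log-normal band by root finding
halfmax_oracle <- function(fit) {
  f <- function(nu) lognormal_eval(fit, nu) - fit$Im / 2
  lo <- uniroot(f, c(fit$nu_m - 5 * fit$H, fit$nu_m), tol = 1e-9)$root
  hi <- uniroot(f, c(fit$nu_m, fit$a - 1e-9), tol = 1e-9)$root
  c(nu_minus = lo, nu_plus = hi)
}
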