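# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# closed-form triangular CDF, written out from the definition
tri_cdf_oracle <- function(x, a, c, b) {
  ifelse(x <= a, 0,
  ifelse(x >= b, 1,
  ifelse(x <= c,
         if (c > a) (x - a)^2 / ((b - a) * (c - a)) else 0,
         1 - (b - x)^2 / ((b - a) * (b - c)))))
}

ks_distance <- function(draws, cdf) {
  x <- sort(draws)
  n <- length(x)
  Fx <- cdf(x)
  max(abs(Fx - seq_len(n) / n), abs(Fx - (seq_len(n) - 1) / n))
}

# fixed-step RK4 integration of dC/dt = a - b*C from C(0) = 0
rk4_linear_ode <- function(a, b, t_end, n_steps = 2000) {
  h <- t_end / n_steps
  f <- function(C) a - b * C
  C <- 0
  for (i in seq_len(n_steps)) {
    k1 <- f(C)
    k2 <- f(C + h / 2 * k1)
    k3 <- f(C + h / 2 * k2)
    k4 <- f(C + h * k3)
    C <- C + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  C
}

# brute-force linear-interpolation percentile (quantile type 7 convention)
percentile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
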