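# Shared fixtures, all generated in code under fixed seeds.

# Autocorrelated source signal (AR(1)).
make_ar1 <- function(n, phi = 0.9, seed = 1) {
  set.seed(seed)
  as.numeric(arima.sim(list(ar = phi), n))
}

# Two-component Gaussian mixture density gridded on [-L, L].
mixture_grid <- function(w = 0.5, m1 = -2, m2 = 2, s1 = 1, s2 = 1,
                         n_points = 1024L, L = 10) {
  grid_from_function(function(x) w * dnorm(x, m1, s1) +
                       (1 - w) * dnorm(x, m2, s2),
                     -L, L, n_points)
}

# Exponential density gridded on [0, L] (strongly skewed fixture).
exponential_grid <- function(rate = 1, n_points = 2048L, L = 16) {
  grid_from_function(function(x) dexp(x, rate), 0, L, n_points)
}

# Random valid density: seeded random Gaussian mixture on a fixed grid.
random_mixture_grid <- function(seed, n_points = 512L, L = 8) {
  set.seed(seed)
  k <- sample(2:4, 1)
  w <- runif(k); w <- w / sum(w)
  m <- runif(k, -3, 3)
  s <- runif(k, 0.4, 1.5)
  grid_from_function(function(x) {
    y <- 0
    for (i in seq_len(k)) y <- y + w[i] * dnorm(x, m[i], s[i])
    y
  }, -L, L, n_points)
}

# Trapezoidal quadrature used by test oracles (independent of the package's
# internal helpers).
oracle_trapz <- function(y, dx) dx * (sum(y) - 0.5 * (y[1] + y[length(y)]))

# Hand-run Benjamini-Hochberg step-up: reject ranks 1..i* where i* is the
# largest i with p_(i) <= i * q / m.
oracle_bh_mask <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * q / m)
  mask <- logical(m)
  if (length(ok)) mask[o[seq_len(max(ok))]] <- TRUE
  mask
}
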