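# Trapezoidal integral on a uniform grid.
trapz_uniform <- function(y, dx) {
  n <- length(y)
  dx * (sum(y) - 0.5 * (y[1] + y[n]))
}

# Trapezoidal cell masses (length n-1), used for boundary-mass checks.
cell_masses <- function(q) {
  0.5 * (q$q[-1] + q$q[-length(q$q)]) * q$dx
}

# Row-wise log-sum-exp with max subtraction.
logsumexp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

# Renormalize exp(logq) on a uniform grid, working from log values.
normalize_log <- function(logq, x, dx) {
  logq <- logq - max(logq)
  q <- exp(logq)
  density_grid(x, q)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
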