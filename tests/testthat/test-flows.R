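test_that("entropy matches closed forms and a fine-quadrature oracle", {
  # uniform on [0, 1]: entropy log(1) = 0
  u <- density_grid(seq(0, 1, length.out = 512), rep(1, 512))
  expect_equal(entropy(u), 0, tolerance = 1e-10)

  # standard Gaussian truncated at +/- 8 sd: 0.5 * log(2*pi*e)
  g <- gaussian_grid(0, 1, 2048)
  expect_equal(entropy(g), 0.5 * log(2 * pi * exp(1)), tolerance = 1e-4)

  # bimodal mixture vs an independent quadrature oracle at 10x resolution
  f <- function(x) 0.5 * dnorm(x, -2, 1) + 0.5 * dnorm(x, 2, 1)
  m <- grid_from_function(f, -10, 10, 1024L)
  xf <- seq(-10, 10, length.out = 10240L)
  yf <- f(xf) / oracle_trapz(f(xf), diff(xf)[1])
  oracle <- -oracle_trapz(yf * log(yf), diff(xf)[1])
  expect_equal(entropy(m), oracle, tolerance = 1e-6)
})

test_that("expectation is exact for symmetric, shifted and gridded normals", {
  expect_equal(expectation(gaussian_grid(0, 1)), 0, tolerance = 1e-10)
  expect_equal(expectation(gaussian_grid(1.5, 1)), 1.5, tolerance = 1e-4)
  # translation equivariance
  g <- mixture_grid()
  gc <- density_grid(g$x + 3.25, g$q)
  expect_equal(expectation(gc), expectation(g) + 3.25, tolerance = 1e-8)
})

test_that("flow fields are the projected gradients with zero mean under q", {
  u <- density_grid(seq(0, 1, length.out = 512), rep(1, 512))
  expect_lt(max(abs(entropic_flow_field(u))), 1e-10)

  g <- gaussian_grid(0, 1, 2048)
  vs <- entropic_flow_field(g)
  expect_lt(max(abs(vs - (-g$x^2 / 2 + 0.5))[abs(g$x) < 6]), 1e-3)

  gc <- gaussian_grid(2.5, 1.3)
  expect_equal(expectation_flow_field(gc), gc$x - expectation(gc))

  # projection property over seeded random densities
  for (s in 1:8) {
    q <- random_mixture_grid(s)
    expect_lt(abs(oracle_trapz(entropic_flow_field(q) * q$q, q$dx)), 1e-8)
    expect_lt(abs(oracle_trapz(expectation_flow_field(q) * q$q, q$dx)), 1e-8)
  }
})

test_that("power-law transform reproduces Gaussian closed forms", {
  g <- gaussian_grid(0, 1, 2048)
  expect_lt(max(abs(power_law_transform(g, 1)$q - g$q)), 1e-12)
  for (lam in c(1.5, 2, 4)) {
    out <- power_law_transform(g, lam)
    expect_lt(max(abs(out$q - dnorm(out$x, 0, 1 / sqrt(lam)))), 1e-6)
  }
  # entropy decreases monotonically in lam, tracking the closed form
  ents <- sapply(c(1, 1.5, 2, 4), function(l)
    entropy(power_law_transform(g, l)))
  expect_true(all(diff(ents) < 0))
  expect_equal(ents, 0.5 * log(2 * pi * exp(1) / c(1, 1.5, 2, 4)),
               tolerance = 1e-4)
  expect_error(power_law_transform(g, 0), "positive")
  expect_error(power_law_transform(g, -1), "positive")
})

test_that("exponential tilt reproduces the Gaussian mean-shift closed form", {
  g <- gaussian_grid(0, 1, 2048)
  expect_lt(max(abs(exponential_tilt(g, 0)$q - g$q)), 1e-12)
  for (lam in c(-1, 0.5, 2)) {
    out <- exponential_tilt(g, lam)
    expect_lt(max(abs(out$q - dnorm(out$x, lam, 1))), 1e-6)
  }
  # expectation nondecreasing in lam, for a Gaussian and a skewed density
  for (q0 in list(g, exponential_grid())) {
    means <- sapply(c(-1, 0, 1), function(l)
      expectation(suppressWarnings(exponential_tilt(q0, l))))
    expect_true(all(diff(means) > 0))
  }
  # truncation by the grid boundary is flagged
  narrow <- gaussian_grid(0, 1, n_points = 64, span_sd = 3)
  expect_warning(exponential_tilt(narrow, 6), "boundary")
})

test_that("mixed-flow Euler integration converges to the exact transforms", {
  g <- gaussian_grid(0, 1, 1024)
  # alpha = beta = 0: identity
  same <- flow_endpoint(integrate_mixed_flow(g, c(0, 0), 1, 10))
  expect_lt(max(abs(same$q - g$q)), 1e-12)

  # beta = 0: q0 ^ exp(alpha * lam); first-order error halves with the step
  exact_s <- power_law_transform(g, exp(0.3))
  e1 <- max(abs(flow_endpoint(
    integrate_mixed_flow(g, c(0.3, 0), 1, 100))$q - exact_s$q))
  e2 <- max(abs(flow_endpoint(
    integrate_mixed_flow(g, c(0.3, 0), 1, 200))$q - exact_s$q))
  expect_lt(e1, 1e-3)
  expect_equal(e1 / e2, 2, tolerance = 0.2)

  # alpha = 0: exponential tilt by beta * lam
  exact_e <- exponential_tilt(g, 0.5)
  et <- max(abs(flow_endpoint(
    integrate_mixed_flow(g, c(0, 0.5), 1, 50))$q - exact_e$q))
  expect_lt(et, 1e-10)  # tilt exponent accumulates exactly under log-Euler

  traj <- integrate_mixed_flow(g, c(0.1, 0.2), 0.5, 25)
  expect_equal(traj$lambdas[1], 0)
  expect_equal(length(traj$densities), 26L)
  expect_identical(traj$densities[[1]], g)
  for (d in traj$densities)
    expect_equal(oracle_trapz(d$q, d$dx), 1, tolerance = 1e-8)
})

test_that("log-density/coordinate covariance vanishes iff symmetric", {
  expect_lt(abs(orthogonality_covariance(gaussian_grid(0, 1, 2048))), 1e-8)
  expect_lt(abs(orthogonality_covariance(gaussian_grid(3, 0.5, 2048))), 1e-8)
  expect_lt(abs(orthogonality_covariance(
    mixture_grid(w = 0.5, m1 = -2, m2 = 2))), 1e-8)

  # strongly skewed density: nonzero, matching a 10x-resolution oracle
  q <- grid_from_function(function(x) dgamma(x, 3, 1), 0, 24, 2048L)
  got <- orthogonality_covariance(q)
  xf <- seq(0, 24, length.out = 20480L)
  dxf <- diff(xf)[1]
  yf <- pmax(dgamma(xf, 3, 1), 1e-300); yf <- yf / oracle_trapz(yf, dxf)
  lm_ <- oracle_trapz(yf * log(yf), dxf)
  xm_ <- oracle_trapz(xf * yf, dxf)
  oracle <- oracle_trapz((log(yf) - lm_) * (xf - xm_) * yf, dxf)
  expect_gt(abs(got), 0.1)
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("power-law map agrees with its generator to second order", {
  for (q in list(gaussian_grid(0, 1, 1024), mixture_grid())) {
    d1 <- generator_consistency_check(q, 0.01)
    d2 <- generator_consistency_check(q, 0.005)
    expect_lt(d1, 1e-3)
    expect_equal(d1 / d2, 4, tolerance = 0.3 * 4)
  }
  expect_identical(generator_consistency_check(gaussian_grid(0, 1), 0), 0)
  expect_error(generator_consistency_check(gaussian_grid(0, 1), 0.5),
               "0.1")
})
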