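test_that("the predictor reduces to identity and simple algebra", {
  x <- make_ar1(300, seed = 2)
  q <- kde_model(x)
  expect_identical(predict_series(x, q, c(0, 0)), x)
  # alpha = 0, beta = 1: mean-reflected doubling
  expect_equal(predict_series(x, q, c(0, 1)), 2 * x - mean(x),
               tolerance = 1e-12)
  # correction terms are centered: training mean preserved
  p <- predict_series(x, q, c(0.4, -1.3))
  expect_equal(mean(p), mean(x), tolerance = 1e-10)
})

test_that("r_squared matches hand arithmetic and rejects degenerate input", {
  obs <- c(1, 2, 3, 4)
  expect_identical(r_squared(obs, obs), 1)
  expect_equal(r_squared(rep(mean(obs), 4), obs), 0)
  expect_equal(r_squared(c(1, 2, 3, 5), obs), 1 - 1 / 5)
  expect_error(r_squared(obs, rep(2, 4)), "constant")
})

test_that("noiseless pairs are recovered to high relative accuracy", {
  x <- make_ar1(600, seed = 5)
  q <- kde_model(x)
  fit <- flow_fit(x, predict_series(x, q, c(0.003, -0.8)))
  expect_equal(unname(coef(fit)), c(0.003, -0.8), tolerance = 1e-4)
  expect_gte(fit$r.squared, 1 - 1e-8)
  expect_true(fit$converged)

  # property: recovery across the coefficient box, 1e-3 relative
  for (ab in list(c(-0.1, -2), c(0.05, 1), c(0.02, 0.5), c(-0.04, 2))) {
    f <- flow_fit(x, predict_series(x, q, ab))
    expect_equal(unname(coef(f)), ab, tolerance = 1e-3)
  }

  # identity target: coefficients collapse to zero
  f0 <- flow_fit(x, x)
  expect_lt(max(abs(coef(f0))), 1e-6)
  expect_gte(f0$r.squared, 1 - 1e-8)
})

test_that("the optimizer agrees with the closed-form least-squares oracle", {
  # the training objective is quadratic in (alpha, beta); ordinary least
  # squares on the two basis columns is an independent solution route
  set.seed(9)
  x <- make_ar1(400, seed = 9)
  y <- x + 0.3 * sin(x) + rnorm(400, 0, 0.2)
  fit <- flow_fit(x, y)
  q <- fit$kde
  c1 <- kde_log_density(q, x) - mean(kde_log_density(q, q$centers))
  c2 <- x - mean(q$centers)
  ols <- qr.solve(cbind(c1, c2), y - x)
  expect_equal(unname(coef(fit)), unname(ols), tolerance = 1e-6)
})

test_that("noisy fits degrade gracefully and tighten with series length", {
  truth <- c(0.05, -0.6)
  err <- sapply(c(500, 5000), function(T) {
    x <- make_ar1(T, seed = 31)
    pair <- generate_pair_from_flow(x, truth, noise_sd = 0.1 * sd(x),
                                    seed = 32)
    f <- flow_fit(x, pair$target)
    c(max(abs(coef(f) - truth) / abs(truth)), f$r.squared)
  })
  expect_lt(err[1, 2], err[1, 1])       # relative error shrinks with T
  expect_lt(err[1, 2], 0.20)            # and is modest at T = 5000
  expect_gt(err[2, 2], 0.8)             # R^2 remains high under 10% noise
})

test_that("fit bookkeeping: monotone trace, labels, JSON serialization", {
  x <- make_ar1(200, seed = 3)
  y <- predict_series(x, kde_model(x), c(0.01, 0.4))
  fit <- flow_fit(x, y, labels = c("V1", "AM"))
  expect_true(all(diff(fit$trace) <= 0))
  expect_output(print(fit), "V1 -> AM")
  expect_output(print(summary(fit)), "objective evaluations")
  f <- tempfile(fileext = ".json")
  write_fit(fit, f)
  j <- jsonlite::read_json(f)
  expect_equal(j$alpha, unname(coef(fit)[1]), tolerance = 1e-12)
  expect_identical(j$source, "V1")

  expect_error(flow_fit(x, y[-1]), "lengths differ")
  expect_error(flow_fit(rep(1, 200), y), "constant")
  expect_error(flow_fit(x[1:15], y[1:15]), "at least 20")
})

test_that("standardized fits predict on the raw target scale", {
  x <- make_ar1(500, seed = 21)
  y <- 3 + 2 * predict_series(x, kde_model(x), c(0.02, -0.5))
  fit <- flow_fit(x, y, standardize = TRUE)
  expect_gte(fit$r.squared, 1 - 1e-6)
  expect_equal(predict(fit, x), unname(fit$fitted.values),
               tolerance = 1e-10)
  expect_equal(mean(fitted(fit)), mean(y), tolerance = 1e-6)
  expect_equal(unname(fitted(fit)), unname(y), tolerance = 1e-4)
})

test_that("simulate() adds residual-scale noise around the fit", {
  x <- make_ar1(300, seed = 8)
  y <- predict_series(x, kde_model(x), c(0, 0.5)) + rnorm(300, 0, 0.1)
  fit <- flow_fit(x, y)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(300L, 3L))
  expect_equal(sd(sims[[1]] - fitted(fit)), sqrt(fit$loss), tolerance = 0.2)
})
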