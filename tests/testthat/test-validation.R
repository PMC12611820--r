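test_that("hold-out validation generalizes perfectly on noiseless pairs", {
  x <- make_ar1(1000, seed = 4)
  # the generating density is the training-portion KDE, so the held-out
  # prediction is exactly self-consistent
  y <- predict_series(x, kde_model(x[1:800]), c(0.02, -0.7))
  rep_ <- holdout_validate(x, y, train_frac = 0.8)
  expect_s3_class(rep_, "validation_report")
  expect_gte(rep_$splits$test_r2, 1 - 1e-6)
  expect_output(print(rep_), "holdout")
})

test_that("hold-out test performance is null for independent noise", {
  set.seed(14)
  x <- rnorm(2000)
  y <- rnorm(2000)
  rep_ <- holdout_validate(x, y)
  expect_lte(rep_$splits$test_r2, 0.05)
  expect_error(holdout_validate(x[1:30], y[1:30], train_frac = 0.8),
               "at least 10")
})

test_that("randomized CV is reproducible and gap-free without noise", {
  x <- make_ar1(600, seed = 6)
  y <- predict_series(x, kde_model(x), c(0.01, 0.9))
  r1 <- random_cv(x, y, n_splits = 5, seed = 77)
  # each split re-estimates the source density from its own training block,
  # so the generating basis is recovered only up to KDE refit error
  expect_lte(abs(r1$mean_gap), 1e-4)
  r2 <- random_cv(x, y, n_splits = 5, seed = 77)
  expect_identical(r1$splits, r2$splits)
  # pointwise split mode also runs
  r3 <- random_cv(x, y, n_splits = 3, seed = 77, contiguous = FALSE)
  expect_equal(nrow(r3$splits), 3L)
})

test_that("moderate noise yields a small positive train-test gap", {
  x <- make_ar1(2000, seed = 16)
  pair <- generate_pair_from_flow(x, c(0.03, -0.8), noise_sd = 0.3 * sd(x),
                                  seed = 17)
  rep_ <- random_cv(x, pair$target, n_splits = 20, seed = 18)
  expect_gt(rep_$mean_gap, 0)
  expect_lt(rep_$mean_gap, 0.1)  # order 1e-2
})

test_that("surrogate refits equal from-scratch refits on shifted series", {
  x <- make_ar1(300, seed = 19)
  pair <- generate_pair_from_flow(x, c(0.05, -0.5), noise_sd = 0.2 * sd(x),
                                  seed = 20)
  y <- pair$target
  pt <- circular_permutation_test(x, y, n_perm = 5, seed = 99)
  T <- length(x)
  for (i in seq_len(5)) {
    off <- pt$offsets[i]
    xs <- x[((seq_len(T) - 1 + off) %% T) + 1]
    ref <- flow_fit(xs, y)
    expect_equal(pt$surrogate_r2[i], ref$r.squared, tolerance = 1e-6)
  }
  expect_true(all(pt$offsets >= 1 & pt$offsets <= T - 1))
})

test_that("strong coupling gives p = 0; surrogates never reach it", {
  x <- make_ar1(400, seed = 23)
  y <- predict_series(x, kde_model(x), c(0.01, -0.9))
  pt <- circular_permutation_test(x, y, n_perm = 200, seed = 1)
  expect_identical(pt$p_value, 0)
  expect_true(all(pt$surrogate_r2 < pt$empirical_r2))
  # conservative variant relates to the plain proportion exactly
  pt2 <- circular_permutation_test(x, y, n_perm = 200, seed = 1,
                                   p_method = "conservative")
  expect_equal(pt2$p_value,
               (pt$p_value * 200 + 1) / 201, tolerance = 1e-12)
})

test_that("independent series give non-small p and the test is deterministic", {
  set.seed(33)
  x <- as.numeric(arima.sim(list(ar = 0.8), 300))
  y <- as.numeric(arima.sim(list(ar = 0.8), 300))
  p1 <- circular_permutation_test(x, y, n_perm = 99, seed = 5)
  p2 <- circular_permutation_test(x, y, n_perm = 99, seed = 5)
  expect_identical(p1$surrogate_r2, p2$surrogate_r2)
  expect_identical(p1$p_value, p2$p_value)
  expect_gt(p1$p_value, 0.01)
  expect_error(circular_permutation_test(x[1:50], y[1:50]), "at least 100")
})

test_that("session-aware shifts never cross session boundaries", {
  x <- make_ar1(400, seed = 41)
  y <- predict_series(x, kde_model(x), c(0, -0.8))
  pt <- circular_permutation_test(x, y, n_perm = 20, seed = 2,
                                  sessions = c(1, 151))
  expect_equal(dim(pt$offsets), c(20L, 2L))
  expect_true(all(pt$offsets[, 1] >= 1 & pt$offsets[, 1] <= 149))
  expect_true(all(pt$offsets[, 2] >= 1 & pt$offsets[, 2] <= 249))
  expect_error(circular_permutation_test(x, y, n_perm = 2,
                                         sessions = c(10, 100)),
               "beginning at 1")
})
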