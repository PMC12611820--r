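make_three_region_recording <- function(T = 400, seed = 50) {
  a <- make_ar1(T, seed = seed)
  bc <- lapply(list(c(0.02, -0.8), c(-0.01, 0.6)), function(ab)
    generate_pair_from_flow(a, ab, noise_sd = 0.05 * sd(a),
                            seed = seed + 1)$target)
  set.seed(seed + 2)
  d <- as.numeric(arima.sim(list(ar = 0.8), T))
  regional_recording(list(A = a, B = bc[[1]], C = bc[[2]], D = d), dt = 0.1)
}

test_that("planted transforms dominate the directional matrix and survive FDR", {
  rec <- make_three_region_recording()
  res <- pairwise_analysis(rec, n_perm = 99, q = 0.01, seed = 7)
  expect_s3_class(res, "pairwise_result")
  expect_identical(dimnames(res$r2)[[1]], c("A", "B", "C", "D"))
  expect_true(all(is.na(diag(res$r2))))
  # A -> B and A -> C are the planted couplings
  expect_gt(res$r2["A", "B"], 0.9)
  expect_gt(res$r2["A", "C"], 0.9)
  expect_true(res$sig_bh["A", "B"])
  expect_true(res$sig_bh["A", "C"])
  # the independent region is not significantly predicted by A
  expect_false(res$sig_bh["A", "D"])
  expect_gt(res$p["A", "D"], 0.01)
  # Bonferroni is a subset of BH
  off <- !is.na(res$p)
  expect_true(all(res$sig_bh[off][res$sig_bonferroni[off]]))
  expect_output(print(res), "Directional R")
})

test_that("identical regions are perfectly predictable in both directions", {
  x <- make_ar1(300, seed = 55)
  rec <- regional_recording(list(R1 = x, R2 = x))
  res <- pairwise_analysis(rec, n_perm = 19, seed = 3)
  expect_gte(res$r2["R1", "R2"], 1 - 1e-8)
  expect_gte(res$r2["R2", "R1"], 1 - 1e-8)
})

test_that("constant regions are skipped with a record, not an error", {
  x <- make_ar1(300, seed = 56)
  rec <- regional_recording(list(A = x, K = rep(1, 300),
                                 B = x + rnorm(300, 0, 0.3)))
  res <- pairwise_analysis(rec, n_perm = 19, seed = 4)
  expect_true(any(grepl("constant", res$skipped)))
  expect_true(is.na(res$r2["A", "K"]))
  expect_false(is.na(res$r2["A", "B"]))
})

test_that("the full pairwise pipeline is bit-reproducible under a seed", {
  rec <- make_three_region_recording(T = 300, seed = 60)
  r1 <- pairwise_analysis(rec, n_perm = 29, seed = 11)
  r2 <- pairwise_analysis(rec, n_perm = 29, seed = 11)
  expect_identical(r1$r2, r2$r2)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$sig_bh, r2$sig_bh)
  expect_identical(r1$alpha, r2$alpha)
})

test_that("joint correction pools off-diagonal cells across recordings", {
  recs <- list(make_three_region_recording(T = 300, seed = 70),
               make_three_region_recording(T = 300, seed = 80))
  out <- pairwise_analysis(recs, n_perm = 19, seed = 5)
  expect_length(out, 2L)
  expect_identical(out[[1]]$config$family_size, 24L)  # 2 x (4*3) cells
  expect_s3_class(out[[2]], "pairwise_result")
})

test_that("run_report writes matrices plus a faithful, reproducible manifest", {
  rec <- make_three_region_recording(T = 300, seed = 90)
  res <- pairwise_analysis(rec, n_perm = 19, seed = 13)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  run_report(res, d1)
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$seed, 13)
  expect_equal(man$config$n_perm, 19)
  expect_true(file.exists(file.path(d1, "r2_matrix.csv")))
  # rerunning with the same seed reproduces identical CSV bytes
  res2 <- pairwise_analysis(rec, n_perm = 19, seed = 13)
  run_report(res2, d2)
  for (f in c("r2_matrix.csv", "p_raw.csv", "significance_bh.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  expect_error(run_report(list(), tempdir()), "unsupported")
})
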