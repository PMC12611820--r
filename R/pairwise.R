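#' Directional mixed-flow analysis over all ordered region pairs
#'
#' For every ordered pair of regions in a recording, fits the mixed-flow
#' predictor, runs the circular-shift permutation test, and corrects the
#' resulting p-values for multiple comparisons across all off-diagonal cells
#' jointly (Benjamini-Hochberg at level `q`, plus Bonferroni at the same
#' level). When a list of recordings is supplied, the correction family pools
#' the off-diagonal cells of all recordings, and a list of per-recording
#' results (sharing the pooled adjustment) is returned.
#'
#' Signals are z-scored (training statistics) before fitting by default,
#' matching the use of normalized first principal components as regional
#' signals. Regions with constant signal are skipped and recorded in
#' `$skipped` rather than raising an error.
#'
#' @param rec A [regional_recording()], or a list of them.
#' @param n_perm Number of circular-shift surrogates per pair (default 1000).
#' @param q FDR level for Benjamini-Hochberg (and the Bonferroni level;
#'   default 0.01).
#' @param seed Integer seed; the full analysis is bit-reproducible given it.
#' @param standardize Z-score each series before fitting (default `TRUE`).
#' @param ... Passed to [circular_permutation_test()] (e.g. `p_method`).
#' @return For a single recording, an object of class `"pairwise_result"`
#'   with matrices `r2`, `p`, `p_adjusted`, `sig_bh`, `sig_bonferroni`,
#'   `alpha`, `beta` (rows = source region, columns = target region,
#'   diagonal `NA`), plus `labels`, `skipped`, `seed` and `config`. For a
#'   list input, a list of such objects.
#' @export
pairwise_analysis <- function(rec, n_perm = 1000L, q = 0.01, seed = NULL,
                              standardize = TRUE, ...) {
  single <- inherits(rec, "regional_recording")
  recs <- if (single) list(rec) else rec
  if (!length(recs) || !all(vapply(recs, inherits, TRUE, "regional_recording")))
    stop("'rec' must be a regional_recording or a list of them")
  if (!is.null(seed)) set.seed(seed)

  results <- lapply(recs, pairwise_one, n_perm = n_perm,
                    standardize = standardize, ...)

  # Joint correction across all off-diagonal cells of all recordings.
  pooled <- unlist(lapply(results, function(r) r$p[!is.na(r$p)]))
  adj <- bh_fdr(pooled, q = q)
  bonf <- bonferroni(pooled, alpha = q)
  pos <- 0L
  for (i in seq_along(results)) {
    r <- results[[i]]
    cells <- which(!is.na(r$p))
    take <- pos + seq_along(cells)
    r$p_adjusted <- r$p
    r$p_adjusted[cells] <- adj$adjusted[take]
    r$sig_bh <- array(NA, dim(r$p), dimnames = dimnames(r$p))
    r$sig_bh[cells] <- adj$mask[take]
    r$sig_bonferroni <- array(NA, dim(r$p), dimnames = dimnames(r$p))
    r$sig_bonferroni[cells] <- bonf[take]
    r$seed <- seed
    r$config <- list(n_perm = n_perm, q = q, standardize = standardize,
                     family_size = length(pooled))
    results[[i]] <- structure(r, class = "pairwise_result")
    pos <- pos + length(cells)
  }
  if (single) results[[1L]] else results
}

pairwise_one <- function(rec, n_perm, standardize, ...) {
  labs <- rec$labels
  k <- length(labs)
  mk <- function() matrix(NA_real_, k, k, dimnames = list(source = labs,
                                                          target = labs))
  r2 <- p <- a <- b <- mk()
  skipped <- character(0)
  const <- vapply(rec$series, function(s) sd(s) == 0, TRUE)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      if (const[i] || const[j]) {
        skipped <- c(skipped, sprintf("%s->%s (constant signal)",
                                      labs[i], labs[j]))
        next
      }
      pt <- circular_permutation_test(rec$series[[i]], rec$series[[j]],
                                      n_perm = n_perm,
                                      sessions = rec$sessions,
                                      standardize = standardize, ...)
      r2[i, j] <- pt$empirical_r2
      p[i, j] <- pt$p_value
      a[i, j] <- pt$coefficients[1]
      b[i, j] <- pt$coefficients[2]
    }
  }
  list(labels = labs, r2 = r2, p = p, alpha = a, beta = b, skipped = skipped)
}

#' @export
print.pairwise_result <- function(x, ...) {
  k <- length(x$labels)
  cat(sprintf("<pairwise_result> %d regions, %d ordered pairs (%d surrogates each)\n",
              k, k * (k - 1L), x$config$n_perm))
  cat("Directional R^2 (rows = source, cols = target):\n")
  print(round(x$r2, 3))
  n_sig <- sum(x$sig_bh, na.rm = TRUE)
  cat(sprintf("BH-significant at q = %g: %d / %d pairs (family of %d tests)\n",
              x$config$q, n_sig, sum(!is.na(x$p)), x$config$family_size))
  if (length(x$skipped))
    cat("Skipped:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
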