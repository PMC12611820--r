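#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR control at level `q`: with ordered p-values \eqn{p_{(1)} \le
#' \dots \le p_{(m)}}, reject all hypotheses up to the largest \eqn{i} with
#' \eqn{p_{(i)} \le i q / m}. Adjusted p-values come from
#' [stats::p.adjust()] (method `"BH"`); the rejection mask is exactly
#' `adjusted <= q`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.01).
#' @return List with `mask` (logical rejections) and `adjusted`
#'   (BH-adjusted p-values, monotone nondecreasing in the raw p-values).
#'   Empty input yields empty output.
#' @export
bh_fdr <- function(p_values, q = 0.01) {
  check_pvalues(p_values)
  if (length(p_values) == 0L)
    return(list(mask = logical(0), adjusted = numeric(0)))
  adjusted <- p.adjust(p_values, method = "BH")
  list(mask = adjusted <= q, adjusted = adjusted)
}

#' Bonferroni familywise error control
#'
#' Rejects hypotheses with \eqn{p \le \alpha / m}. Always a subset of the
#' Benjamini-Hochberg rejections at the same level.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha Familywise error level.
#' @return Logical rejection mask.
#' @export
bonferroni <- function(p_values, alpha = 0.01) {
  check_pvalues(p_values)
  if (length(p_values) == 0L) return(logical(0))
  p_values <= alpha / length(p_values)
}

check_pvalues <- function(p) {
  if (length(p) == 0L) return(invisible(TRUE))
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numeric in [0, 1]")
  invisible(TRUE)
}
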