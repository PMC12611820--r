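#' Write analysis results and a run manifest to a directory
#'
#' Serializes a [pairwise_analysis()] result (matrices as CSV, manifest as
#' JSON) or a recovery report (flat JSON), recording the seed, configuration
#' and package version so a run can be reproduced byte-for-byte. Outputs are
#' written to a temporary directory first and moved into place only when all
#' files succeed, so validation failures never leave partial output.
#'
#' @param result A `"pairwise_result"` or `"recovery_report"`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
run_report <- function(result, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  stage <- tempfile("mixedflow_report_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)

  files <- character(0)
  put_csv <- function(m, name) {
    f <- file.path(stage, name)
    write.csv(as.data.frame(m), f, row.names = TRUE)
    files <<- c(files, name)
  }
  manifest <- list(tool = "mixedflow",
                   version = as.character(packageVersion("mixedflow")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  if (inherits(result, "pairwise_result")) {
    put_csv(result$r2, "r2_matrix.csv")
    put_csv(result$p, "p_raw.csv")
    put_csv(result$p_adjusted, "p_adjusted.csv")
    put_csv(result$sig_bh, "significance_bh.csv")
    put_csv(result$sig_bonferroni, "significance_bonferroni.csv")
    put_csv(result$alpha, "alpha_matrix.csv")
    put_csv(result$beta, "beta_matrix.csv")
    manifest$seed <- result$seed
    manifest$config <- result$config
    manifest$labels <- result$labels
    manifest$skipped <- result$skipped
  } else if (inherits(result, "recovery_report")) {
    manifest$seed <- result$seed
    manifest$spec <- result$spec
    manifest$true_params <- unclass(result$true_params)
    manifest$fitted_params <- unclass(result$fitted_params)
    manifest$rel_err_alpha_pct <- result$rel_err_alpha_pct
    manifest$rel_err_beta_pct <- result$rel_err_beta_pct
    manifest$metrics <- result$metrics
    manifest$converged <- result$converged
  } else {
    stop("run_report: unsupported result class: ",
         paste(class(result), collapse = "/"))
  }
  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  files <- c(files, "manifest.json")
  for (f in files)
    if (!file.copy(file.path(stage, f), file.path(out_dir, f),
                   overwrite = TRUE))
      stop("run_report: failed to write ", f)
  invisible(file.path(out_dir, files))
}
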