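#' Multi-region recording container
#'
#' Named, equal-length regional time series (e.g. the normalized first
#' principal component of each visual area's pixel activity), with the
#' sampling interval and optional session boundaries carried as metadata.
#'
#' @param series Named list of equal-length numeric vectors, or a numeric
#'   matrix/data frame with one column per region.
#' @param labels Region labels; defaults to the names of `series`.
#' @param dt Sampling interval in seconds (metadata only; default 1).
#' @param sessions Optional strictly increasing session start indices,
#'   beginning at 1.
#' @param note Free-text provenance note.
#' @return An object of class `"regional_recording"`.
#' @export
regional_recording <- function(series, labels = NULL, dt = 1,
                               sessions = NULL, note = "") {
  if (is.matrix(series) || is.data.frame(series)) {
    if (is.null(labels)) labels <- colnames(series)
    series <- lapply(seq_len(ncol(series)), function(j) as.numeric(series[, j]))
  }
  if (is.null(labels)) labels <- names(series)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("regional_recording: region labels are required")
  if (anyDuplicated(labels))
    stop("regional_recording: duplicate region labels")
  if (length(series) != length(labels))
    stop("regional_recording: labels and series count differ")
  lens <- vapply(series, length, 1L)
  if (length(unique(lens)) != 1L)
    stop(sprintf("regional_recording: ragged series lengths (%s)",
                 paste(lens, collapse = ", ")))
  bad <- vapply(series, function(s) anyNA(s) || any(!is.finite(s)), TRUE)
  if (any(bad))
    stop("regional_recording: non-numeric or non-finite values in region(s): ",
         paste(labels[bad], collapse = ", "))
  if (!is.null(sessions)) session_segments(sessions, lens[1])  # validates
  names(series) <- labels
  structure(list(labels = labels, series = series, dt = dt,
                 sessions = sessions, note = note, n_time = lens[1]),
            class = "regional_recording")
}

#' @export
print.regional_recording <- function(x, ...) {
  cat(sprintf("<regional_recording> %d regions x %d time points (dt = %g s)\n",
              length(x$labels), x$n_time, x$dt))
  cat("  regions:", paste(x$labels, collapse = ", "), "\n")
  if (!is.null(x$sessions))
    cat("  sessions start at:", paste(x$sessions, collapse = ", "), "\n")
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Read or write a regional recording as CSV
#'
#' The on-disk format is a headered CSV whose first column is time (seconds)
#' and remaining columns are one region each; the header row carries the
#' region labels. `write_recording()`/`load_recording()` round-trip labels,
#' values and sampling interval.
#'
#' @param path CSV file path.
#' @param sessions,note Optional metadata attached on load (session start
#'   indices; provenance note).
#' @return `load_recording()` returns a [regional_recording()];
#'   `write_recording()` returns `path` invisibly.
#' @export
load_recording <- function(path, sessions = NULL, note = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!grepl("[A-Za-z]", first))
    stop("recording CSV must start with a header row of region labels ",
         "(first column time/index, one column per region)")
  d <- read.csv(path, check.names = FALSE)
  if (ncol(d) < 3L)
    stop("recording CSV needs a time column plus at least 2 region columns")
  num <- vapply(d, is.numeric, TRUE)
  if (!all(num)) {
    bad <- which(!num)
    stop(sprintf("non-numeric cells in column(s) %s of %s",
                 paste(names(d)[bad], collapse = ", "), path))
  }
  tcol <- d[[1L]]
  dt <- if (length(tcol) > 1L) mean(diff(tcol)) else 1
  regional_recording(d[-1L], dt = dt, sessions = sessions,
                     note = if (nzchar(note)) note else path)
}

#' @rdname load_recording
#' @param rec A [regional_recording()].
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "regional_recording"))
    stop("expected a 'regional_recording'")
  d <- data.frame(time = (seq_len(rec$n_time) - 1) * rec$dt)
  for (lab in rec$labels) d[[lab]] <- rec$series[[lab]]
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Pixel-by-time fluorescence stack with a region mask
#'
#' Container for raw pixel traces before regional signal extraction. Pixels
#' (rows) carry a region label each; rows containing any `NA` are dropped at
#' construction (with a message reporting the count), since fluorescence
#' extractions commonly contain invalid pixels.
#'
#' @param values Numeric pixel-by-time matrix (fluorescence units).
#' @param mask Character/factor vector of length `nrow(values)` assigning
#'   each pixel to a region.
#' @return An object of class `"pixel_stack"`.
#' @export
pixel_stack <- function(values, mask) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("pixel_stack: 'values' must be a numeric matrix (pixels x time)")
  mask <- as.character(mask)
  if (length(mask) != nrow(values))
    stop("pixel_stack: 'mask' length must equal the number of pixel rows")
  keep <- complete.cases(values)
  if (!all(keep)) {
    message(sprintf("pixel_stack: dropped %d pixel row(s) containing NA",
                    sum(!keep)))
    values <- values[keep, , drop = FALSE]
    mask <- mask[keep]
  }
  if (any(!is.finite(values)))
    stop("pixel_stack: non-finite values remain after NA filtering")
  structure(list(values = values, mask = mask,
                 regions = unique(mask)), class = "pixel_stack")
}

#' First principal component of a region's pixel activity
#'
#' Extracts the dominant shared temporal signal of a region: the first
#' principal component score series of the region's pixel-by-time submatrix
#' (each pixel mean-centered over time), with the sign fixed so the component
#' correlates non-negatively with the region's mean pixel trace, then
#' z-scored. Permutation of pixel order leaves the result unchanged.
#'
#' @param stack A [pixel_stack()].
#' @param region Region label present in the stack's mask.
#' @return Numeric z-scored component series (length = number of time
#'   points).
#' @export
first_pc <- function(stack, region) {
  if (!inherits(stack, "pixel_stack")) stop("expected a 'pixel_stack'")
  rows <- which(stack$mask == region)
  if (length(rows) < 2L)
    stop(sprintf("region '%s' needs at least 2 pixels", region))
  sub <- stack$values[rows, , drop = FALSE]
  v <- apply(sub, 1L, var)
  sub <- sub[v > 0, , drop = FALSE]
  if (nrow(sub) < 2L)
    stop(sprintf("region '%s' has fewer than 2 pixels with variance > 0",
                 region))
  # observations = time points, variables = pixels; centering each pixel
  # trace over time
  pc <- prcomp(t(sub), center = TRUE, scale. = FALSE)
  score <- pc$x[, 1L]
  if (cor(score, colMeans(sub)) < 0) score <- -score
  as.numeric(scale(score))
}
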