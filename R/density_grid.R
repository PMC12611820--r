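#' Discretized probability density on a uniform grid
#'
#' A `density_grid` is the container every flow operation acts on: a strictly
#' positive density sampled on a uniform one-dimensional grid, normalized so
#' that its trapezoidal integral is exactly 1. Values are floored at a tiny
#' positive constant before construction so that `log(mass)` is always finite.
#'
#' @param support Numeric vector of strictly increasing, uniformly spaced
#'   grid coordinates (signal units); at least 16 points.
#' @param mass Non-negative density values at each grid point
#'   (1/signal-units). Renormalized to unit trapezoidal mass.
#' @param floor Positive lower bound applied to `mass` before normalization,
#'   so that logarithms of the density are finite. Default `1e-300`.
#'
#' @return An object of class `"density_grid"`: a list with elements
#'   `x` (support), `q` (density values) and `dx` (grid spacing).
#'
#' @examples
#' g <- gaussian_grid(mean = 0, sd = 1)
#' entropy(g)            # ~ 0.5 * log(2 * pi * exp(1))
#' expectation(g)        # ~ 0
#' @seealso [gaussian_grid()], [grid_from_function()], [kde_to_grid()]
#' @export
density_grid <- function(support, mass, floor = 1e-300) {
  if (!is.numeric(support) || !is.numeric(mass))
    stop("density_grid: 'support' and 'mass' must be numeric")
  if (length(support) != length(mass))
    stop("density_grid: 'support' and 'mass' lengths differ")
  if (length(support) < 16L)
    stop("density_grid: support must have at least 16 points")
  if (anyNA(support) || any(!is.finite(support)))
    stop("density_grid: non-finite support coordinates")
  if (anyNA(mass) || any(!is.finite(mass)))
    stop("density_grid: non-finite mass values")
  d <- diff(support)
  if (any(d <= 0))
    stop("density_grid: support must be strictly increasing")
  dx <- mean(d)
  if (max(abs(d - dx)) > 1e-12 * max(abs(support)) + 1e-12)
    stop("density_grid: support spacing is not uniform")
  if (any(mass < 0))
    stop("density_grid: negative mass values")
  q <- pmax(mass, floor)
  z <- trapz_uniform(q, dx)
  if (!is.finite(z) || z <= 0)
    stop("density_grid: mass does not integrate to a positive value")
  structure(list(x = as.numeric(support), q = as.numeric(q / z), dx = dx),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf(
    "<density_grid> %d points on [%.4g, %.4g], dx = %.4g\n",
    length(x$x), x$x[1], x$x[length(x$x)], x$dx))
  cat(sprintf("  mass = %.8f, mean = %.4g, entropy = %.4g nats\n",
              trapz_uniform(x$q, x$dx), expectation(x), entropy(x)))
  invisible(x)
}

#' @export
as.data.frame.density_grid <- function(x, ...) {
  data.frame(x = x$x, q = x$q)
}

#' @export
plot.density_grid <- function(x, ..., xlab = "x", ylab = "density",
                              type = "l") {
  plot(x$x, x$q, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' @rdname density_grid
#' @param x Object to test or validate.
#' @export
is_density_grid <- function(x) inherits(x, "density_grid")

# Fails loudly, naming the violated invariant; used by every flow operation.
validate_density_grid <- function(q, tol_mass = 1e-8) {
  if (!is_density_grid(q))
    stop("expected a 'density_grid' object (see density_grid())")
  if (length(q$x) < 16L)
    stop("density_grid invariant violated: fewer than 16 grid points")
  if (any(q$q <= 0))
    stop("density_grid invariant violated: non-positive mass values")
  m <- trapz_uniform(q$q, q$dx)
  if (abs(m - 1) > tol_mass)
    stop(sprintf(
      "density_grid invariant violated: trapezoidal mass %.3e != 1", m))
  invisible(q)
}

#' Gaussian density on a uniform grid
#'
#' Convenience constructor used throughout the examples and benchmarks: a
#' normal density truncated to `mean +/- span_sd * sd` and renormalized.
#'
#' @param mean,sd Mean and standard deviation of the Gaussian.
#' @param n_points Number of grid points (default 1024).
#' @param span_sd Half-width of the grid in standard deviations (default 8).
#' @return A [density_grid()].
#' @export
gaussian_grid <- function(mean = 0, sd = 1, n_points = 1024L, span_sd = 8) {
  stopifnot(sd > 0, span_sd > 0)
  x <- seq(mean - span_sd * sd, mean + span_sd * sd, length.out = n_points)
  density_grid(x, dnorm(x, mean, sd))
}

#' Grid a density function
#'
#' Evaluates a vectorized density function on a uniform grid and renormalizes.
#'
#' @param f Vectorized function of one argument returning density values.
#' @param lower,upper Grid endpoints.
#' @param n_points Number of grid points.
#' @return A [density_grid()].
#' @export
grid_from_function <- function(f, lower, upper, n_points = 1024L) {
  x <- seq(lower, upper, length.out = n_points)
  density_grid(x, f(x))
}

#' Read or write a density as two-column CSV
#'
#' Densities serialize to a two-column table (`x`, `q`).
#'
#' @param q A [density_grid()].
#' @param path File path.
#' @return `write_density` returns `path` invisibly; `read_density` returns a
#'   [density_grid()].
#' @export
write_density <- function(q, path) {
  validate_density_grid(q)
  write.csv(as.data.frame(q), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_density
#' @export
read_density <- function(path) {
  d <- read.csv(path)
  if (!all(c("x", "q") %in% names(d)))
    stop("density CSV must have columns 'x' and 'q'")
  density_grid(d$x, d$q)
}
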