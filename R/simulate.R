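#' Simulate a diffusing Gaussian at two observation times
#'
#' Draws samples from a Gaussian whose variance grows linearly under
#' noise-driven diffusion: at time \eqn{t} the law is
#' \eqn{N(\mu_0, \sigma_0^2 + 2 D t)}. Used as the source of realistic
#' unimodal densities for the density-space recovery benchmark.
#'
#' @param mean0,sd0 Initial mean and standard deviation (`sd0 > 0`).
#' @param D Diffusion coefficient (signal-units^2 per unit time, `>= 0`).
#' @param t1,t2 Observation times, `t1 < t2`.
#' @param n Samples per time point.
#' @param seed Integer seed; draws are bit-reproducible given it.
#' @return List with numeric samples `at_t1` and `at_t2` and the spec echoed
#'   back (`spec`).
#' @export
simulate_gaussian_diffusion <- function(mean0 = 0, sd0 = 1, D = 0.25,
                                        t1 = 0, t2 = 1, n = 20000L,
                                        seed = NULL) {
  if (sd0 <= 0) stop("'sd0' must be positive")
  if (D < 0) stop("'D' must be non-negative")
  if (t1 >= t2) stop("'t1' must be earlier than 't2'")
  if (!is.null(seed)) set.seed(seed)
  s1 <- sqrt(sd0^2 + 2 * D * t1)
  s2 <- sqrt(sd0^2 + 2 * D * t2)
  list(at_t1 = rnorm(n, mean0, s1),
       at_t2 = rnorm(n, mean0, s2),
       spec = list(mean0 = mean0, sd0 = sd0, D = D, t1 = t1, t2 = t2,
                   n = n, seed = seed))
}

#' Simulate a Langevin process with oscillatory drift
#'
#' Euler-Maruyama integration of
#' \deqn{x_{k+1} = x_k + (a \sin(\omega t_k) - \gamma x_k)\,dt
#'   + \sigma \sqrt{dt}\, \xi_k,}
#' an Ornstein-Uhlenbeck process driven by a sinusoidal force. With
#' \eqn{a = 0} the stationary variance is \eqn{\sigma^2 / (2\gamma)}; with
#' \eqn{\sigma = 0} the trajectory relaxes onto a sinusoid of frequency
#' \eqn{\omega}.
#'
#' @param gamma Relaxation rate (1/time, `>= 0`); stability requires
#'   `gamma * dt < 1`.
#' @param a Drift amplitude.
#' @param omega Angular drift frequency (rad/time).
#' @param sigma Noise standard deviation.
#' @param dt Time step (`> 0`).
#' @param duration Total simulated time.
#' @param x0 Initial state.
#' @param seed Integer seed.
#' @return Numeric series of length `floor(duration / dt) + 1`.
#' @export
simulate_langevin <- function(gamma = 1, a = 1, omega = 2 * pi * 0.5,
                              sigma = 0.3, dt = 0.01, duration = 50,
                              x0 = 0, seed = NULL) {
  if (dt <= 0) stop("'dt' must be positive")
  if (gamma < 0) stop("'gamma' must be non-negative")
  if (gamma * dt >= 1)
    stop(sprintf("unstable discretization: gamma * dt = %.3g >= 1",
                 gamma * dt))
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration / dt)
  x <- numeric(n + 1L)
  x[1L] <- x0
  t <- (0:(n - 1L)) * dt
  noise <- if (sigma > 0) sigma * sqrt(dt) * rnorm(n) else numeric(n)
  drift <- a * sin(omega * t)
  for (k in seq_len(n))
    x[k + 1L] <- x[k] + (drift[k] - gamma * x[k]) * dt + noise[k]
  x
}

#' Generate a coupled target series from a source via the mixed flow
#'
#' Applies the mixed-flow predictor ([predict_series()]) with known
#' \eqn{(\alpha, \beta)} to a source series (using the source's own kernel
#' density) and adds Gaussian observation noise — the ground-truth generator
#' used to validate [flow_fit()] recovery.
#'
#' @param x_source Non-constant numeric source series.
#' @param params A [flow_params()] or numeric `c(alpha, beta)`.
#' @param noise_sd Observation noise standard deviation (default 0).
#' @param seed Integer seed for the noise draws.
#' @param ... Passed to [kde_model()] (e.g. `rule`).
#' @return List with `target` (numeric series), `clean` (the noiseless
#'   target), `kde` (the source density model) and `params`.
#' @export
generate_pair_from_flow <- function(x_source, params, noise_sd = 0,
                                    seed = NULL, ...) {
  check_sample(x_source)
  params <- as_flow_params(params)
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  kde <- kde_model(x_source, ...)
  clean <- predict_series(x_source, kde, params)
  if (!is.null(seed)) set.seed(seed)
  noise <- if (noise_sd > 0) rnorm(length(clean), 0, noise_sd)
           else numeric(length(clean))
  list(target = clean + noise, clean = clean, kde = kde, params = params)
}

# Inverse-CDF sampling from a gridded density.
sample_from_grid <- function(q, n) {
  validate_density_grid(q)
  grid_quantile(q, runif(n))
}
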