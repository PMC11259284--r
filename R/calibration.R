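#' Long-time firing rate of a single noise-driven neuron
#'
#' Simulates one uncoupled neuron driven only by the Poisson background input
#' and returns its empirical rate. This is the tabulation step of the
#' leak-conductance calibration.
#'
#' @param g_leak leak conductance (mS/cm^2)
#' @param duration_s simulated time (s)
#' @param params a \code{neuron_params}
#' @param dt integration step (ms)
#' @param rng_seed optional integer seed
#' @return rate (Hz); warns when fewer than 100 spikes were observed
#' @export
single_neuron_rate <- function(g_leak, duration_s = 500,
                               params = neuron_params(), dt = 0.1,
                               rng_seed = NULL) {
  stopifnot(g_leak > 0, duration_s > 0)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  conn <- empty_connectivity(1L)
  st <- initial_state(g_leak, params)
  st$V <- params$V_reset  # deterministic start; irrelevant for long runs
  n_spikes <- 0
  chunk <- 60000
  remaining <- duration_s * 1000
  while (remaining > 0) {
    d <- min(chunk, remaining)
    out <- integrate_interval(st, conn, params, duration = d, dt = dt)
    st <- out$state
    n_spikes <- n_spikes + nrow(out$raster)
    remaining <- remaining - d
  }
  if (n_spikes < 100)
    warning("fewer than 100 spikes; rate estimate is unstable")
  n_spikes / duration_s
}

#' Fit the linear rate-versus-leak-conductance calibration
#'
#' Tabulates the single-neuron rate over a grid of leak conductances and fits
#' f(g_leak) = alpha1 g_leak + alpha2 by ordinary least squares. The fitted
#' line is used to map requested natural firing rates to leak conductances.
#'
#' @param grid leak conductance grid (mS/cm^2); at least 2 distinct values
#' @param duration_s simulated seconds per grid point
#' @param params a \code{neuron_params}
#' @param dt integration step (ms)
#' @param rng_seed optional integer seed
#' @return an object of class \code{calibration}: \code{alpha1} (Hz per
#'   mS/cm^2), \code{alpha2} (Hz), \code{grid}, \code{rates},
#'   \code{r_squared}, and the noise settings of the fit
#' @export
fit_rate_curve <- function(grid = seq(0.005, 0.05, length.out = 10),
                           duration_s = 500, params = neuron_params(),
                           dt = 0.1, rng_seed = NULL) {
  if (length(unique(grid)) < 2) stop("degenerate grid")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  rates <- vapply(grid, single_neuron_rate, numeric(1),
                  duration_s = duration_s, params = params, dt = dt)
  fit <- lm(rates ~ grid)
  cal <- list(alpha1 = unname(coef(fit)[2]), alpha2 = unname(coef(fit)[1]),
              grid = grid, rates = rates,
              r_squared = summary(fit)$r.squared,
              kappa_noise = params$kappa_noise, f_noise = params$f_noise)
  class(cal) <- "calibration"
  cal
}

#' Sample per-neuron leak conductances for a target rate distribution
#'
#' Natural firing rates Gaussian with mean f0 and SD sigma_f map through the
#' inverted calibration line to Gaussian leak conductances with mean
#' (f0 - alpha2)/alpha1 and SD sigma_f/alpha1. Draws falling outside the
#' calibrated grid range are clipped with a warning.
#'
#' @param f0 target mean natural rate (Hz)
#' @param sigma_f target rate SD (Hz)
#' @param calib a \code{calibration}
#' @param N number of neurons
#' @param rng_seed optional integer seed
#' @return numeric vector of leak conductances (mS/cm^2)
#' @export
sample_gleak <- function(f0, sigma_f, calib, N, rng_seed = NULL) {
  stopifnot(inherits(calib, "calibration"), sigma_f >= 0, N >= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  g_tilde <- (f0 - calib$alpha2) / calib$alpha1
  rng <- range(calib$grid)
  if (g_tilde < rng[1] || g_tilde > rng[2])
    stop("requested mean rate maps outside the calibrated grid range")
  g <- if (sigma_f == 0) rep(g_tilde, N)
       else rnorm(N, g_tilde, sigma_f / calib$alpha1)
  if (any(g < rng[1] | g > rng[2])) {
    warning("some leak conductances clipped to the calibrated range")
    g <- pmin(rng[2], pmax(rng[1], g))
  }
  g
}

#' Natural rates implied by leak conductances under the calibration line
#'
#' @param g_leak leak conductances (mS/cm^2)
#' @param calib a \code{calibration}
#' @return rates (Hz)
#' @export
natural_rates <- function(g_leak, calib) {
  stopifnot(inherits(calib, "calibration"))
  calib$alpha1 * g_leak + calib$alpha2
}

#' Write / read a calibration cache
#'
#' JSON round trip of the tabulated grid, rates, fitted coefficients and
#' noise settings, so network builds can skip re-simulation.
#'
#' @param calib a \code{calibration}
#' @param path file path
#' @return \code{read_calibration} returns a \code{calibration}
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "calibration"))
  jsonlite::write_json(unclass(calib), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  cal <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(cal) <- "calibration"
  cal
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("Rate calibration: f = %.2f * g_leak + %.2f (R^2 = %.4f, %d grid points)\n",
              x$alpha1, x$alpha2, x$r_squared, length(x$grid)))
  invisible(x)
}
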