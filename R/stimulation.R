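#' Spatial spread of the stimulus from the target stimulated fraction
#'
#' The Gaussian footprint \eqn{D(l) = e^{-l^2/2\sigma_s^2}} is considered
#' effective out to 3 sigma (where D drops to about 0.01); equating the
#' covered area \eqn{\pi(3\sigma_s)^2} with a fraction gamma of the network
#' area gives \eqn{\sigma_s = (1/3)\sqrt{\gamma/\pi}\,L}.
#'
#' @param gamma fraction of the network each electrode should reach (0, 1]
#' @param L network side length
#' @return sigma_s in the units of L
#' @export
sigma_from_gamma <- function(gamma, L = 1) {
  if (!is.numeric(gamma) || gamma <= 0 || gamma > 1)
    stop("'gamma' must lie in (0, 1]")
  sqrt(gamma / pi) * L / 3
}

#' UMRS stimulation parameters
#'
#' Uncorrelated multichannel random stimulation: N_s electrodes at the
#' quadrant centers of the network plane independently deliver
#' charge-balanced stimulus events (positive pulse of width tau_sp and
#' amplitude 1, gap tau_sg, negative pulse of width tau_sn and amplitude
#' -tau_sp/tau_sn). Event onsets on one electrode are a renewal process with
#' intervals tau_Lambda + Exp(tau_UMRS), so the mean event rate is
#' F_s = 1/(tau_UMRS + tau_Lambda) with hard minimum interval
#' tau_Lambda = 1000/130 ms. The maximal current is
#' I0 = (V_th_spike - V_reset) C / tau_sp, scaled by a_s in [0, 1], and falls
#' off from each electrode as a Gaussian of SD sigma_s.
#'
#' @param a_s amplitude scale in [0, 1]
#' @param F_s mean stimulation frequency per electrode (Hz), at most 130
#' @param N_s electrode count
#' @param gamma target stimulated fraction per electrode
#' @param L network side length (mm)
#' @param tau_sp,tau_sg,tau_sn pulse sub-durations (ms)
#' @param neuron a \code{neuron_params} supplying V_th_spike, V_reset, C
#' @return an object of class \code{stim_params} with derived \code{I0},
#'   \code{sigma_s}, \code{tau_Lambda}, \code{tau_UMRS} and
#'   \code{electrode_positions}
#' @export
stim_params <- function(a_s, F_s, N_s = 4, gamma = 0.2, L = 1,
                        tau_sp = 0.5, tau_sg = 0.2, tau_sn = 1.5,
                        neuron = neuron_params()) {
  stopifnot(a_s >= 0, a_s <= 1, N_s >= 1, tau_sp > 0, tau_sg >= 0, tau_sn > 0)
  tau_Lambda <- 1000 / 130
  if (F_s > 130) stop("'F_s' must not exceed 130 Hz (minimum event interval)")
  stopifnot(F_s > 0)
  if (N_s != 4)
    stop("only the 4-electrode quadrant-center layout is supported")
  qc <- c(0.25, 0.75)
  pos <- cbind(x = L * rep(qc, times = 2), y = L * rep(qc, each = 2))
  p <- list(a_s = a_s, F_s = F_s, N_s = as.integer(N_s), gamma = gamma, L = L,
            tau_sp = tau_sp, tau_sg = tau_sg, tau_sn = tau_sn,
            tau_Lambda = tau_Lambda, tau_UMRS = 1000 / F_s - tau_Lambda,
            I0 = (neuron$V_th_spike - neuron$V_reset) * neuron$C / tau_sp,
            sigma_s = sigma_from_gamma(gamma, L),
            electrode_positions = pos)
  class(p) <- "stim_params"
  p
}

#' Sample UMRS event onsets for each electrode
#'
#' Independent renewal processes per electrode: inter-onset intervals are
#' tau_Lambda plus an exponential of mean tau_UMRS (degenerate, strictly
#' periodic at tau_Lambda when F_s = 130 Hz).
#'
#' @param F_s mean event rate (Hz), at most 130
#' @param duration window length (ms)
#' @param n_electrodes number of independent trains
#' @param rng_seed optional integer seed
#' @param t0 offset added to all onsets (ms)
#' @return list of per-electrode onset-time vectors
#' @export
umrs_event_times <- function(F_s, duration, n_electrodes = 4,
                             rng_seed = NULL, t0 = 0) {
  tau_Lambda <- 1000 / 130
  if (F_s > 130) stop("'F_s' must not exceed 130 Hz")
  stopifnot(F_s > 0, duration > 0)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  tau_U <- 1000 / F_s - tau_Lambda
  lapply(seq_len(n_electrodes), function(r) {
    n_guess <- max(10, ceiling(duration * F_s / 1000 * 1.5 + 20))
    draw <- function(n) tau_Lambda + (if (tau_U > 0) rexp(n, 1 / tau_U) else 0)
    t <- cumsum(draw(n_guess))
    while (t[length(t)] < duration) t <- c(t, t[length(t)] + cumsum(draw(n_guess)))
    t0 + t[t <= duration]
  })
}

#' Build a stimulus field for an integration epoch
#'
#' Precomputes the per-electrode event schedules over [t0, t0 + duration] and
#' the per-neuron spatial gains \eqn{D(l_{ir}) = e^{-l_{ir}^2/2\sigma_s^2}}.
#'
#' @param params a \code{stim_params}
#' @param geometry a \code{plast_geometry}
#' @param duration epoch length (ms)
#' @param t0 epoch start time (ms)
#' @param rng_seed optional integer seed
#' @return list of class \code{stim_field} with \code{params}, \code{onsets}
#'   and \code{gain} (N x N_s)
#' @export
stimulus_field <- function(params, geometry, duration, t0 = 0,
                           rng_seed = NULL) {
  stopifnot(inherits(params, "stim_params"),
            inherits(geometry, "plast_geometry"))
  onsets <- umrs_event_times(params$F_s, duration, params$N_s, rng_seed, t0)
  pos <- geometry$positions
  ep <- params$electrode_positions
  gain <- sapply(seq_len(params$N_s), function(r) {
    l2 <- (pos[, 1] - ep[r, 1])^2 + (pos[, 2] - ep[r, 2])^2
    exp(-l2 / (2 * params$sigma_s^2))
  })
  gain <- matrix(gain, nrow = geometry$N)
  f <- list(params = params, onsets = onsets, gain = gain, t0 = t0,
            duration = duration)
  class(f) <- "stim_field"
  f
}

#' Per-electrode waveform value at given times
#'
#' X_r(t) is +1 during the positive pulse, 0 during the gap, -tau_sp/tau_sn
#' during the negative pulse, and 0 between events.
#'
#' @param onsets vector of event onset times for one electrode (ms)
#' @param t times at which to evaluate (ms); vectorized
#' @param params a \code{stim_params}
#' @return numeric vector of waveform values
#' @export
umrs_waveform <- function(onsets, t, params) {
  width <- params$tau_sp + params$tau_sg + params$tau_sn
  idx <- findInterval(t, onsets)
  tau <- ifelse(idx >= 1, t - onsets[pmax(idx, 1)], Inf)
  ifelse(tau < params$tau_sp, 1,
         ifelse(tau < params$tau_sp + params$tau_sg, 0,
                ifelse(tau < width, -params$tau_sp / params$tau_sn, 0)))
}

#' Total stimulation current per neuron at given times
#'
#' \eqn{I_{stim,i}(t) = a_s I_0 \sum_r X_r(t) D(l_{ir})} in uA/cm^2.
#'
#' @param field a \code{stim_field}
#' @param t a single time (ms)
#' @return numeric vector of per-neuron currents
#' @export
stim_current <- function(field, t) {
  stopifnot(length(t) == 1)
  X <- vapply(field$onsets, umrs_waveform, numeric(1),
              t = t, params = field$params)
  field$params$a_s * field$params$I0 * as.numeric(field$gain %*% X)
}
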