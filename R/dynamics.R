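#' Initialize the per-neuron dynamic state
#'
#' Membrane potentials start uniform between \code{V_reset} and \code{V_rest},
#' thresholds at \code{V_th_rest}, all conductances at zero, STDP traces and
#' the slow rate estimate at zero.
#'
#' @param g_leak per-neuron leak conductance vector (mS/cm^2)
#' @param params a \code{neuron_params}
#' @param rng_seed optional integer seed for the membrane draws
#' @param t0 absolute start time (ms)
#' @return an object of class \code{plast_state}
#' @export
initial_state <- function(g_leak, params = neuron_params(), rng_seed = NULL,
                          t0 = 0) {
  stopifnot(inherits(params, "neuron_params"), is.numeric(g_leak),
            all(g_leak > 0))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  N <- length(g_leak)
  st <- list(
    V = runif(N, params$V_reset, params$V_rest),
    V_th = rep(params$V_th_rest, N),
    g_syn = rep(0, N),
    g_noise = rep(0, N),
    refrac = integer(N),
    g_leak = as.numeric(g_leak),
    chi = rep(0, N), chi_t = rep(t0, N),
    psi = rep(0, N), psi_t = rep(t0, N),
    fhat = rep(0, N), fhat_t = rep(t0, N),
    pend_t = numeric(0), pend_j = integer(0),
    t = t0, N = N)
  class(st) <- "plast_state"
  st
}

check_dt <- function(dt, params, stimulus = NULL) {
  divides <- function(x) abs(x / dt - round(x / dt)) < 1e-9
  if (!divides(params$tau_spike) || !divides(params$t_d))
    stop("'dt' must divide tau_spike and t_d")
  if (!is.null(stimulus)) {
    if (!divides(stimulus$params$tau_sp) || !divides(stimulus$params$tau_sg) ||
        !divides(stimulus$params$tau_sn))
      stop("'dt' must divide the stimulus pulse sub-durations")
  }
  invisible(TRUE)
}

#' Integrate the network for one interval of frozen connectivity
#'
#' Forward-Euler integration of the membrane, threshold, and conductance
#' equations with spike generation, refractory clamping, delayed synaptic
#' transmission, Poisson background noise and (optionally) additive STDP and
#' external stimulation. Connectivity structure is frozen for the call;
#' synaptic weights evolve if an STDP rule is supplied. Spikes crossing the
#' interval boundary have their deliveries carried in the state and are
#' honoured in the next call.
#'
#' @param state a \code{plast_state}
#' @param conn a \code{plast_conn}
#' @param params a \code{neuron_params}
#' @param stdp a \code{stdp_params} or \code{NULL} for frozen weights
#' @param stimulus a stimulus field built by \code{\link{stimulus_field}}, or
#'   \code{NULL}
#' @param duration interval length (ms)
#' @param dt integration step (ms); must divide \code{tau_spike}, \code{t_d}
#'   and, when stimulating, the pulse sub-durations
#' @param rng_seed optional integer seed (noise stream)
#' @param tau_slow_ms time constant (ms) of the slow rate filter carried in
#'   the state; only read by structural updates
#' @return list with the advanced \code{state}, the updated \code{conn}
#'   (weights), and \code{raster}, a data.frame with columns \code{time} (ms)
#'   and \code{neuron} (1-based index)
#' @export
integrate_interval <- function(state, conn, params = neuron_params(),
                               stdp = NULL, stimulus = NULL,
                               duration, dt = 0.1, rng_seed = NULL,
                               tau_slow_ms = 30 * 60 * 1000) {
  stopifnot(inherits(state, "plast_state"), inherits(conn, "plast_conn"))
  if (!is.numeric(duration) || duration <= 0) stop("'duration' must be > 0")
  check_dt(dt, params, stimulus)
  if (state$N != conn$N) stop("state and connectivity sizes differ")
  if (!is.null(rng_seed)) set.seed(rng_seed)

  par <- unclass(params)
  par$tau_slow_ms <- tau_slow_ms
  stdp_on <- !is.null(stdp)
  if (stdp_on) {
    stopifnot(inherits(stdp, "stdp_params"))
    par[c("eta", "tau_plus", "tau_R", "b")] <-
      stdp[c("eta", "tau_plus", "tau_R", "b")]
  }
  stim_on <- !is.null(stimulus)
  if (stim_on) {
    par$tau_sp <- stimulus$params$tau_sp
    par$tau_sg <- stimulus$params$tau_sg
    par$tau_sn <- stimulus$params$tau_sn
    gain <- stimulus$gain
    onsets <- stimulus$onsets
    scale <- stimulus$params$a_s * stimulus$params$I0
  } else {
    gain <- matrix(0, state$N, 1)
    onsets <- list(numeric(0))
    scale <- 0
  }

  out <- net_integrate_cpp(state$V, state$V_th, state$g_syn, state$g_noise,
                           state$refrac, state$g_leak,
                           conn$A, conn$W, stdp_on,
                           state$chi, state$chi_t, state$psi, state$psi_t,
                           state$fhat, state$fhat_t,
                           state$pend_t, state$pend_j,
                           par, state$t, duration, dt,
                           stim_on, gain, onsets, scale)

  new_state <- state
  for (f in c("V", "V_th", "g_syn", "g_noise", "refrac", "chi", "chi_t",
              "psi", "psi_t", "fhat", "fhat_t", "pend_t", "pend_j"))
    new_state[[f]] <- out[[f]]
  new_state$t <- state$t + duration
  conn$W <- out$W
  raster <- data.frame(time = out$spike_time, neuron = out$spike_neuron)
  list(state = new_state, conn = conn, raster = raster)
}

#' Slow firing-rate estimates at a given time
#'
#' Decays the lazily-updated low-pass rate estimates carried in the state to
#' the requested time and returns them in Hz.
#'
#' @param state a \code{plast_state}
#' @param at time (ms) at which to read the estimate; defaults to the state's
#'   current time
#' @param tau_slow_ms filter time constant (ms)
#' @return numeric vector of per-neuron rates (Hz)
#' @export
slow_rate <- function(state, at = state$t, tau_slow_ms = 30 * 60 * 1000) {
  state$fhat * exp(-(at - state$fhat_t) / tau_slow_ms)
}

#' Sample a homogeneous Poisson spike train
#'
#' Event times with i.i.d. exponential inter-event intervals of mean
#' 1000/rate ms.
#'
#' @param rate event rate (Hz)
#' @param duration window length (ms)
#' @param rng_seed optional integer seed
#' @return ordered numeric vector of event times in (0, duration]
#' @export
poisson_event_times <- function(rate, duration, rng_seed = NULL) {
  stopifnot(rate >= 0, duration > 0)
  if (rate == 0) return(numeric(0))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  mean_iei <- 1000 / rate
  n_guess <- max(10, ceiling(duration / mean_iei + 4 * sqrt(duration / mean_iei)))
  t <- cumsum(rexp(n_guess, rate = 1 / mean_iei))
  while (t[length(t)] < duration)
    t <- c(t, t[length(t)] + cumsum(rexp(n_guess, rate = 1 / mean_iei)))
  t[t <= duration]
}
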