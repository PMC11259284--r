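#' Membrane and synapse parameters of the conductance-based LIF neuron
#'
#' Returns the full parameter set of the integrate-and-fire model: membrane
#' capacitance, resting/reset/spike potentials, dynamic-threshold constants,
#' synaptic reversal potential and time constant, transmission delay, maximal
#' coupling strength, and the Poisson background-noise settings. Defaults are
#' the reference parameter set used throughout the package.
#'
#' @param C membrane capacitance (uF/cm^2)
#' @param V_rest resting membrane potential (mV)
#' @param V_reset post-spike reset potential (mV)
#' @param V_th_rest resting threshold potential (mV)
#' @param V_syn synaptic reversal potential (mV)
#' @param V_spike potential the membrane is pinned to during a spike (mV)
#' @param V_th_spike threshold value during a spike (mV)
#' @param t_d synaptic transmission delay (ms)
#' @param tau_th threshold relaxation time constant (ms)
#' @param tau_syn synaptic conductance time constant (ms)
#' @param tau_spike spike (clamp) duration (ms)
#' @param kappa maximal coupling strength (mS/cm^2); each delivered spike of
#'   weight w increments the postsynaptic conductance by kappa*w/N
#' @param f_noise rate of the background Poisson input (Hz)
#' @param kappa_noise conductance jump per noise event (mS/cm^2)
#' @return an object of class \code{neuron_params} (named list)
#' @export
neuron_params <- function(C = 3, V_rest = -38, V_reset = -67, V_th_rest = -40,
                          V_syn = 0, V_spike = 20, V_th_spike = 0,
                          t_d = 3, tau_th = 5, tau_syn = 1, tau_spike = 1,
                          kappa = 8, f_noise = 20, kappa_noise = 0.06) {
  stopifnot(C > 0, tau_th > 0, tau_syn > 0, tau_spike > 0, t_d > 0,
            f_noise >= 0, kappa_noise >= 0)
  p <- list(C = C, V_rest = V_rest, V_reset = V_reset, V_th_rest = V_th_rest,
            V_syn = V_syn, V_spike = V_spike, V_th_spike = V_th_spike,
            t_d = t_d, tau_th = tau_th, tau_syn = tau_syn,
            tau_spike = tau_spike, kappa = kappa, f_noise = f_noise,
            kappa_noise = kappa_noise)
  class(p) <- "neuron_params"
  p
}

#' Additive STDP parameters
#'
#' The weight update for a pre/post spike pair with lag
#' \eqn{q = t_{post} - t_{pre} - t_d} is
#' \deqn{\delta w(q) = \eta e^{-|q|/\tau_+}} for \eqn{q > 0} (potentiation) and
#' \deqn{\delta w(q) = -\eta (b/\tau_R) e^{-|q|/(\tau_R \tau_+)}} for
#' \eqn{q \le 0} (depression), so the net area over all lags is
#' \eqn{\eta\tau_+(1-b)}: \code{b} > 1 makes the rule depression-dominant.
#' \code{tau_R} is dimensionless; it scales the depression time constant
#' relative to \code{tau_plus} and divides the depression amplitude.
#'
#' @param eta learning rate (maximal weight change per pairing)
#' @param tau_plus potentiation time constant (ms)
#' @param tau_R depression scaling factor (dimensionless)
#' @param b asymmetry parameter
#' @return an object of class \code{stdp_params}
#' @export
stdp_params <- function(eta = 0.02, tau_plus = 10, tau_R = 4, b = 1.4) {
  stopifnot(eta > 0, tau_plus > 0, tau_R > 0, b >= 0)
  p <- list(eta = eta, tau_plus = tau_plus, tau_R = tau_R, b = b)
  class(p) <- "stdp_params"
  p
}

#' Stochastic structural-plasticity parameters
#'
#' Contact addition and pruning are Bernoulli events at each structural
#' update. The addition probability for an absent contact j -> i is
#' \deqn{P_{add} = P_h G(\hat f_i, f_-, -\nu) e^{-l_{ij}/l_0}}
#' and the pruning probability for a live contact is
#' \deqn{P_{prn} = P_w e^{-w_{ij}/w_{min}} + P_h G(\hat f_i, f_+, \nu)}
#' with the logistic \eqn{G(\Omega,\Omega_0,\nu) = 1/(1+e^{-(\Omega-\Omega_0)/\nu})}.
#' The midpoints and slope are derived from the target rate, the steepness
#' parameter and the floor probability:
#' \eqn{f_\pm = f_T \pm \Delta f/2} and
#' \eqn{\nu = \Delta f / (2\ln[(1-\tilde p_T)/\tilde p_T])}, which places the
#' addition and pruning factors at \eqn{\tilde p_T} when a neuron sits exactly
#' at its target rate.
#'
#' @param P_h maximal homeostatic probability (addition and pruning)
#' @param P_w maximal weight-dependent pruning probability
#' @param l0 distance decay constant (same units as the lattice, mm)
#' @param f_T homeostatic target firing rate (Hz)
#' @param delta_f steepness parameter of the logistic factors (Hz)
#' @param p_tilde_T floor probability at the target rate
#' @param w_min weight scale of weight-dependent pruning
#' @param tau_slow_min time constant of the slow firing-rate filter (minutes)
#' @return an object of class \code{sp_params} including the derived
#'   \code{f_plus}, \code{f_minus} and \code{nu}
#' @export
sp_params <- function(P_h = 0.01, P_w = 0, l0 = 0.5, f_T = 4.5, delta_f = 1,
                      p_tilde_T = 0.01, w_min = 0.001, tau_slow_min = 30) {
  stopifnot(P_h >= 0, P_h <= 1, P_w >= 0, P_w <= 1, l0 > 0, f_T > 0,
            delta_f > 0, p_tilde_T > 0, p_tilde_T < 0.5, w_min > 0,
            tau_slow_min > 0)
  p <- list(P_h = P_h, P_w = P_w, l0 = l0, f_T = f_T, delta_f = delta_f,
            p_tilde_T = p_tilde_T, w_min = w_min,
            tau_slow_min = tau_slow_min,
            tau_slow_ms = tau_slow_min * 60 * 1000,
            f_plus = f_T + delta_f / 2,
            f_minus = f_T - delta_f / 2,
            nu = delta_f / (2 * log((1 - p_tilde_T) / p_tilde_T)))
  class(p) <- "sp_params"
  p
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("Conductance-based LIF parameters:\n")
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}
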