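#' Logistic rate-dependence factor
#'
#' \eqn{G(\Omega, \Omega_0, \nu) = 1/(1 + e^{-(\Omega-\Omega_0)/\nu})}:
#' monotone increasing in omega for nu > 0, decreasing for nu < 0.
#'
#' @param omega rate argument (Hz); vectorized
#' @param omega0 midpoint (Hz)
#' @param nu slope (Hz); must be non-zero
#' @return value(s) in (0, 1)
#' @export
sp_logistic <- function(omega, omega0, nu) {
  stopifnot(nu != 0)
  1 / (1 + exp(-(omega - omega0) / nu))
}

#' Probability of adding an absent contact
#'
#' \eqn{P_{add}(f_i, l_{ij}) = P_h G(f_i, f_-, -\nu) e^{-l_{ij}/l_0}}:
#' addition is purely homeostatic, favoured for postsynaptic neurons firing
#' below target and for nearby pairs.
#'
#' @param f_i postsynaptic slow firing-rate estimate (Hz); vectorized
#' @param l_ij pair distance (mm); vectorized
#' @param params an \code{sp_params}
#' @return probability in [0, P_h]
#' @export
p_add <- function(f_i, l_ij, params = sp_params()) {
  stopifnot(all(f_i >= 0), all(l_ij >= 0))
  params$P_h * sp_logistic(f_i, params$f_minus, -params$nu) *
    exp(-l_ij / params$l0)
}

#' Probability of pruning a live contact
#'
#' \eqn{P_{prn}(f_i, w_{ij}) = P_w e^{-w_{ij}/w_{min}} + P_h G(f_i, f_+, \nu)},
#' capped at 1: weak contacts and contacts into neurons firing above target
#' are preferentially removed.
#'
#' @param f_i postsynaptic slow firing-rate estimate (Hz); vectorized
#' @param w_ij contact weight in [0, 1]; vectorized
#' @param params an \code{sp_params}
#' @return probability in [0, min(1, P_w + P_h)]
#' @export
p_prune <- function(f_i, w_ij, params = sp_params()) {
  stopifnot(all(f_i >= 0), all(w_ij >= -1e-12), all(w_ij <= 1 + 1e-12))
  pmin(1, params$P_w * exp(-w_ij / params$w_min) +
         params$P_h * sp_logistic(f_i, params$f_plus, params$nu))
}

#' Exact update of the slow low-pass firing-rate estimate
#'
#' Piecewise-exact solution of the first-order filter: exponential decay with
#' time constant tau_slow between spikes and a jump of 1000/tau_slow (Hz, with
#' tau_slow in ms) at each spike. For a stationary train of rate r the
#' long-run mean converges to r.
#'
#' @param f0 estimate (Hz) at time \code{t0}
#' @param spike_times spike times in (t0, t1] (ms)
#' @param t0 start time (ms)
#' @param t1 end time (ms)
#' @param tau_slow_ms filter time constant (ms)
#' @return the estimate (Hz) at \code{t1}
#' @export
update_rate_estimate <- function(f0, spike_times, t0, t1,
                                 tau_slow_ms = 30 * 60 * 1000) {
  stopifnot(t1 >= t0)
  f <- f0
  t <- t0
  for (ts in sort(spike_times)) {
    f <- f * exp(-(ts - t) / tau_slow_ms) + 1000 / tau_slow_ms
    t <- ts
  }
  f * exp(-(t1 - t) / tau_slow_ms)
}

#' One synchronous structural (birth-death) update
#'
#' Every absent ordered pair (i, j), i != j, becomes a contact with
#' probability \code{\link{p_add}}; every live contact is removed with
#' probability \code{\link{p_prune}}. Additions and removals are decided from
#' the pre-update snapshot, so no contact is both added and pruned within one
#' update and a contact added at iteration n is first exposed to pruning at
#' iteration n + 1. New contacts receive i.i.d. uniform weights on
#' \code{new_weight_range} and their birth iteration is recorded; removals are
#' reported with their lifetime in iterations.
#'
#' @param conn a \code{plast_conn}
#' @param geometry a \code{plast_geometry}
#' @param rates per-neuron slow firing-rate estimates (Hz)
#' @param params an \code{sp_params}; set \code{P_w = 0} for purely
#'   homeostatic structural plasticity
#' @param iteration current structural iteration index
#' @param new_weight_range support of new-contact weights; c(0, 0.2) when
#'   STDP shapes the weights afterwards, c(0, 1) for homeostatic-only runs
#' @param rng_seed optional integer seed
#' @return list with the updated \code{conn} and \code{events}, a data.frame
#'   (iteration, event, pre, post, weight_at_event, lifetime_iterations)
#' @export
sp_update <- function(conn, geometry, rates, params = sp_params(), iteration,
                      new_weight_range = c(0, 0.2), rng_seed = NULL) {
  stopifnot(inherits(conn, "plast_conn"), inherits(geometry, "plast_geometry"))
  if (length(rates) != conn$N)
    stop("rate vector length does not match the network size")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  N <- conn$N
  off <- !diag(TRUE, N)
  live <- conn$A == 1L
  absent <- off & !live

  # addition: postsynaptic rate by row, distance kernel by pair
  add_factor <- params$P_h * sp_logistic(rates, params$f_minus, -params$nu)
  Padd <- outer(add_factor, rep(1, N)) * exp(-geometry$distance / params$l0)
  draw <- matrix(runif(N * N), N, N)
  added <- absent & (draw < Padd)

  # pruning from the pre-update snapshot
  Pprn <- pmin(1, params$P_w * exp(-conn$W / params$w_min) +
                 outer(params$P_h * sp_logistic(rates, params$f_plus, params$nu),
                       rep(1, N)))
  draw2 <- matrix(runif(N * N), N, N)
  pruned <- live & (draw2 < Pprn)

  ev_add <- which(added, arr.ind = TRUE)
  ev_prn <- which(pruned, arr.ind = TRUE)
  w_new <- runif(nrow(ev_add), new_weight_range[1], new_weight_range[2])

  events <- rbind(
    if (nrow(ev_add)) data.frame(iteration = iteration, event = "add",
                                 pre = ev_add[, 2], post = ev_add[, 1],
                                 weight_at_event = w_new,
                                 lifetime_iterations = NA_integer_),
    if (nrow(ev_prn)) data.frame(iteration = iteration, event = "prune",
                                 pre = ev_prn[, 2], post = ev_prn[, 1],
                                 weight_at_event = conn$W[ev_prn],
                                 lifetime_iterations =
                                   iteration - conn$birth[ev_prn]))
  if (is.null(events))
    events <- data.frame(iteration = integer(0), event = character(0),
                         pre = integer(0), post = integer(0),
                         weight_at_event = numeric(0),
                         lifetime_iterations = integer(0))

  conn$A[pruned] <- 0L
  conn$W[pruned] <- 0
  conn$birth[pruned] <- NA_integer_
  conn$A[added] <- 1L
  conn$W[added] <- w_new
  conn$birth[added] <- as.integer(iteration)
  list(conn = conn, events = events)
}
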