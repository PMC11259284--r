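#' Weight change for a single pre/post spike pairing
#'
#' Evaluates the additive STDP window at lag
#' \eqn{q = t_{post} - t_{pre} - t_d}: potentiation
#' \eqn{\eta e^{-|q|/\tau_+}} for q > 0, depression
#' \eqn{-\eta (b/\tau_R) e^{-|q|/(\tau_R\tau_+)}} for q <= 0. The integral of
#' the window over all lags is \eqn{\eta\tau_+(1-b)}.
#'
#' @param q lag (ms); vectorized
#' @param params a \code{stdp_params}
#' @return weight change(s)
#' @export
stdp_delta <- function(q, params = stdp_params()) {
  stopifnot(inherits(params, "stdp_params"))
  ifelse(q > 0,
         params$eta * exp(-abs(q) / params$tau_plus),
         -params$eta * params$b / params$tau_R *
           exp(-abs(q) / (params$tau_R * params$tau_plus)))
}

#' Create a trace-based STDP engine
#'
#' The engine keeps one presynaptic trace chi per neuron (decay tau_plus,
#' incremented when a spike is delivered, i.e. at spike time + t_d) and one
#' postsynaptic trace psi per neuron (decay tau_R*tau_plus, incremented at
#' the spike itself). This all-to-all trace formulation is equivalent to
#' summing the pair rule \code{\link{stdp_delta}} over all pre/post spike
#' pairs. It mirrors exactly what the compiled integrator does internally and
#' exists as an independently exercisable surface.
#'
#' @param N number of neurons
#' @param params a \code{stdp_params}
#' @param t0 start time (ms)
#' @return an environment of class \code{stdp_engine}
#' @export
stdp_engine <- function(N, params = stdp_params(), t0 = 0) {
  e <- new.env(parent = emptyenv())
  e$params <- params
  e$chi <- rep(0, N)
  e$chi_t <- rep(t0, N)
  e$psi <- rep(0, N)
  e$psi_t <- rep(t0, N)
  class(e) <- "stdp_engine"
  e
}

chi_at <- function(engine, j, t)
  engine$chi[j] * exp(-(t - engine$chi_t[j]) / engine$params$tau_plus)

psi_at <- function(engine, i, t)
  engine$psi[i] * exp(-(t - engine$psi_t[i]) /
                        (engine$params$tau_R * engine$params$tau_plus))

#' Apply the depression step at a presynaptic delivery
#'
#' Called at the arrival time t = t_spike + t_d of a spike of neuron j. Every
#' live contact j -> i is depressed by \eqn{\eta (b/\tau_R) \psi_i(t)} (using
#' psi before any same-instant increment), then chi_j is incremented by 1.
#'
#' @param engine an \code{stdp_engine}
#' @param conn a \code{plast_conn}
#' @param j presynaptic neuron index
#' @param t delivery time (ms)
#' @return the updated \code{plast_conn} (weights clipped to [0, 1])
#' @export
on_presynaptic_delivery <- function(engine, conn, j, t) {
  p <- engine$params
  post <- which(conn$A[, j] == 1L)
  if (length(post)) {
    dw <- p$eta * p$b / p$tau_R * psi_at(engine, post, t)
    conn$W[post, j] <- pmin(1, pmax(0, conn$W[post, j] - dw))
  }
  engine$chi[j] <- chi_at(engine, j, t) + 1
  engine$chi_t[j] <- t
  conn
}

#' Apply the potentiation step at a postsynaptic spike
#'
#' Called at each spike time of neuron i. Every live contact j -> i is
#' potentiated by \eqn{\eta \chi_j(t)} (using chi before any same-instant
#' increment), then psi_i is incremented by 1.
#'
#' @param engine an \code{stdp_engine}
#' @param conn a \code{plast_conn}
#' @param i postsynaptic neuron index
#' @param t spike time (ms)
#' @return the updated \code{plast_conn} (weights clipped to [0, 1])
#' @export
on_postsynaptic_spike <- function(engine, conn, i, t) {
  p <- engine$params
  pre <- which(conn$A[i, ] == 1L)
  if (length(pre)) {
    dw <- p$eta * chi_at(engine, pre, t)
    conn$W[i, pre] <- pmin(1, pmax(0, conn$W[i, pre] + dw))
  }
  engine$psi[i] <- psi_at(engine, i, t) + 1
  engine$psi_t[i] <- t
  conn
}

#' Replay a spike sequence through the trace engine
#'
#' Convenience driver: takes per-neuron spike times, forms the merged event
#' sequence (deliveries at spike + t_d, potentiation at the spike itself) and
#' applies the engine hooks in order. On exact time ties the spike is
#' processed before the delivery, so a coincident pre/post pair (q = 0) falls
#' into the depression branch.
#'
#' @param spikes list of per-neuron spike-time vectors (ms)
#' @param conn a \code{plast_conn}
#' @param params a \code{stdp_params}
#' @param t_d synaptic delay (ms)
#' @return the final \code{plast_conn}
#' @export
stdp_replay <- function(spikes, conn, params = stdp_params(), t_d = 3) {
  ev <- do.call(rbind, lapply(seq_along(spikes), function(n) {
    ts <- spikes[[n]]
    if (!length(ts)) return(NULL)
    rbind(data.frame(t = ts, neuron = n, kind = 0),        # spike
          data.frame(t = ts + t_d, neuron = n, kind = 1))  # delivery
  }))
  if (is.null(ev)) return(conn)
  ev <- ev[order(ev$t, ev$kind), ]
  engine <- stdp_engine(conn$N, params, t0 = min(ev$t) - 1)
  for (k in seq_len(nrow(ev))) {
    if (ev$kind[k] == 1)
      conn <- on_presynaptic_delivery(engine, conn, ev$neuron[k], ev$t[k])
    else
      conn <- on_postsynaptic_spike(engine, conn, ev$neuron[k], ev$t[k])
  }
  conn
}
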