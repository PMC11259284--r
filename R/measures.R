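#' Piecewise-linear spike phases at given times
#'
#' Between consecutive spikes t_mu and t_mu+1 of a neuron the phase advances
#' linearly by 2 pi: phi(t) = 2 pi ((t - t_mu)/(t_mu+1 - t_mu) + mu). The
#' phase is undefined before a neuron's first spike and after its last; such
#' samples are returned as NA and excluded from population averages.
#'
#' @param spike_times ordered spike times of one neuron (ms)
#' @param t times at which to evaluate (ms)
#' @return numeric vector of phases (radians), NA where undefined
#' @export
spike_phase <- function(spike_times, t) {
  n <- length(spike_times)
  if (n < 2) return(rep(NA_real_, length(t)))
  mu <- findInterval(t, spike_times)
  ok <- mu >= 1 & mu < n
  phi <- rep(NA_real_, length(t))
  i <- mu[ok]
  phi[ok] <- 2 * pi * ((t[ok] - spike_times[i]) /
                         (spike_times[i + 1] - spike_times[i]) + i)
  phi
}

#' Kuramoto order parameter of a spike raster
#'
#' Time average over [t - T, t] of the modulus of the population-mean phase
#' factor \eqn{|N^{-1}\sum_i e^{\iota\phi_i(t')}|}, with phases interpolated
#' linearly between consecutive spikes. Neurons without a defined phase at a
#' sample instant are excluded from the mean at that instant; R ranges from 0
#' (incoherence) to 1 (perfect synchrony).
#'
#' @param raster data.frame with columns \code{time} (ms), \code{neuron}
#' @param N number of neurons
#' @param t right edge of the averaging window (ms); defaults to the last
#'   spike time
#' @param window averaging window T (ms)
#' @param dt_phase phase sampling step (ms)
#' @return list with \code{R} and \code{n_undefined}, the mean number of
#'   neurons per sample whose phase was undefined
#' @export
order_parameter <- function(raster, N, t = max(raster$time), window = 2000,
                            dt_phase = 1) {
  if (!nrow(raster)) return(list(R = NA_real_, n_undefined = N))
  tt <- seq(t - window, t, by = dt_phase)
  spk <- split(raster$time, factor(raster$neuron, levels = seq_len(N)))
  z_re <- matrix(0, length(tt), N)
  z_im <- matrix(0, length(tt), N)
  defined <- matrix(FALSE, length(tt), N)
  for (i in seq_len(N)) {
    phi <- spike_phase(spk[[i]], tt)
    ok <- !is.na(phi)
    defined[, i] <- ok
    z_re[ok, i] <- cos(phi[ok])
    z_im[ok, i] <- sin(phi[ok])
  }
  nn <- rowSums(defined)
  keep <- nn > 0
  mod <- sqrt(rowSums(z_re)[keep]^2 + rowSums(z_im)[keep]^2) / nn[keep]
  list(R = if (any(keep)) mean(mod) else NA_real_,
       n_undefined = mean(N - nn))
}

#' Population firing-rate statistics over an interval
#'
#' Per-neuron empirical rates (spike count / interval), their mean and the
#' coefficient of variation CV = population SD / population mean. CV = 0
#' together with a high order parameter indicates a frequency-locked state.
#'
#' @param raster data.frame with columns \code{time}, \code{neuron}
#' @param N number of neurons
#' @param interval interval length (ms)
#' @return list with \code{mean_rate} (Hz), \code{cv} (NA when the mean rate
#'   is 0) and \code{rates} (per-neuron, Hz)
#' @export
rate_and_cv <- function(raster, N, interval) {
  stopifnot(interval > 0)
  counts <- tabulate(raster$neuron, nbins = N)
  rates <- counts / (interval / 1000)
  m <- mean(rates)
  s <- sqrt(mean((rates - m)^2))
  list(mean_rate = m, cv = if (m > 0) s / m else NA_real_, rates = rates)
}

#' Mean incoming synaptic weight per neuron and network-wide
#'
#' W_i is the mean weight over the live incoming contacts of neuron i
#' (undefined, NA, when it has none); the network average is the mean over
#' defined W_i.
#'
#' @param conn a \code{plast_conn}
#' @return list with \code{mean_weight} and per-neuron \code{W_i}
#' @export
mean_weights <- function(conn) {
  live <- conn$A == 1L
  indeg <- rowSums(live)
  Wi <- ifelse(indeg > 0, rowSums(conn$W * live) / indeg, NA_real_)
  list(mean_weight = if (any(indeg > 0)) mean(Wi[indeg > 0]) else NA_real_,
       W_i = Wi)
}

#' Node degree densities
#'
#' in-NDD of neuron i is its in-degree / N, out-NDD its out-degree / N; the
#' network-averaged density beta is the common mean of the two vectors.
#'
#' @param conn a \code{plast_conn}
#' @return list with \code{beta_in}, \code{beta_out}, \code{beta}
#' @export
node_degree_densities <- function(conn) {
  N <- conn$N
  list(beta_in = rowSums(conn$A) / N,
       beta_out = colSums(conn$A) / N,
       beta = sum(conn$A) / N^2)
}

#' Directed degree assortativity (four edge-wise Pearson coefficients)
#'
#' For each directed edge e, U_e is a degree of its presynaptic endpoint and
#' V_e a degree of its postsynaptic endpoint; the coefficient for degree
#' types (epsilon, upsilon) in \{in, out\}^2 is the Pearson correlation of
#' (U, V) across edges. A coefficient is NA when a degree sequence is
#' constant across edges.
#'
#' @param conn a \code{plast_conn}
#' @return list with \code{rho}, a named numeric vector
#'   (\code{in_in}, \code{out_out}, \code{in_out}, \code{out_in}, first type
#'   = presynaptic endpoint), and \code{E}, the edge count
#' @export
degree_assortativity <- function(conn) {
  edges <- which(conn$A == 1L, arr.ind = TRUE)  # col 1 = post i, col 2 = pre j
  E <- nrow(edges)
  if (E < 2) stop("assortativity needs at least 2 edges")
  indeg <- rowSums(conn$A)
  outdeg <- colSums(conn$A)
  pre <- edges[, 2]
  post <- edges[, 1]
  edge_cor <- function(u, v) {
    if (sd(u) == 0 || sd(v) == 0) return(NA_real_)
    cor(u, v)
  }
  rho <- c(in_in = edge_cor(indeg[pre], indeg[post]),
           out_out = edge_cor(outdeg[pre], outdeg[post]),
           in_out = edge_cor(indeg[pre], outdeg[post]),
           out_in = edge_cor(outdeg[pre], indeg[post]))
  list(rho = rho, E = E)
}

#' Correlation between node degree densities and natural firing rates
#'
#' Pearson correlations, across neurons, of the in- and out-NDD with the
#' natural (uncoupled) firing rates. In reorganized synchronized networks
#' with weight-dependent pruning the expected sign pattern is (negative,
#' positive): slower neurons collect incoming contacts, faster neurons keep
#' outgoing ones.
#'
#' @param conn a \code{plast_conn}
#' @param natural_rates per-neuron natural firing rates (Hz)
#' @return named numeric vector c(in = ..., out = ...); NA on degenerate
#'   variance
#' @export
degree_frequency_correlation <- function(conn, natural_rates) {
  stopifnot(length(natural_rates) == conn$N)
  ndd <- node_degree_densities(conn)
  safe_cor <- function(a, b)
    if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
  setNames(c(safe_cor(ndd$beta_in, natural_rates),
             safe_cor(ndd$beta_out, natural_rates)), c("in", "out"))
}

#' Steady-state convergence test on interval series
#'
#' The series converge at the first n >= n_min for which the symmetric
#' relative differences \eqn{2|x_n - x_{n+1}|/(x_n + x_{n+1})} of both the
#' mean weight and the mean rate series fall below \code{upsilon}. Two
#' consecutive zeros count as converged in that observable.
#'
#' @param series_W per-interval mean weights
#' @param series_f per-interval mean rates (Hz)
#' @param upsilon relative accuracy
#' @param n_min minimum interval count before convergence may be declared
#' @param n_max maximum interval count
#' @return list with \code{converged} and \code{n}, the first pair index at
#'   which the test passed (NA if it never did within n_max)
#' @export
convergence_test <- function(series_W, series_f, upsilon = 1e-3,
                             n_min = 2, n_max = 31) {
  stopifnot(length(series_W) == length(series_f))
  reldiff <- function(a, b) {
    if (a == 0 && b == 0) return(0)
    2 * abs(a - b) / (a + b)
  }
  n_upper <- min(length(series_W) - 1, n_max)
  if (n_upper >= n_min) {
    for (n in seq(n_min, n_upper)) {
      if (reldiff(series_W[n], series_W[n + 1]) < upsilon &&
          reldiff(series_f[n], series_f[n + 1]) < upsilon)
        return(list(converged = TRUE, n = n))
    }
  }
  list(converged = FALSE, n = NA_integer_)
}

#' Per-interval network summary
#'
#' Bundles the standard observables of one convergence interval: order
#' parameter over the trailing window, rate statistics over the full
#' interval, mean weight and density of the (frozen) connectivity.
#'
#' @param raster interval spike raster
#' @param conn a \code{plast_conn}
#' @param interval interval length (ms)
#' @param t_end absolute end time of the interval (ms)
#' @param window order-parameter window (ms)
#' @return one-row data.frame
#' @export
network_summary <- function(raster, conn, interval, t_end,
                            window = 2000) {
  op <- order_parameter(raster, conn$N, t = t_end, window = window)
  rc <- rate_and_cv(raster, conn$N, interval)
  mw <- mean_weights(conn)
  ndd <- node_degree_densities(conn)
  data.frame(R = op$R, mean_rate = rc$mean_rate, cv = rc$cv,
             mean_weight = mw$mean_weight, beta = ndd$beta)
}
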