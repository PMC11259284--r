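#' Derive named independent seed streams from a master seed
#'
#' The master seed deterministically expands into one sub-seed per named
#' stream (wiring, initial weights, membrane initialization, background
#' noise, structural updates, stimulus, calibration), so e.g. the same wiring
#' can be reused across initial-weight conditions.
#'
#' @param master_seed integer master seed
#' @return named integer vector of sub-seeds (all below 2^31)
#' @export
derive_seeds <- function(master_seed) {
  streams <- c("wiring", "weights", "membrane", "noise", "sp", "stimulus",
               "calibration")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(master_seed))
  setNames(sample.int(.Machine$integer.max, length(streams)), streams)
}

#' Experiment configuration
#'
#' Collects everything a run needs: plasticity regime, geometry, initial
#' density and weights, rate heterogeneity, the structural and stimulation
#' parameter blocks and the convergence settings. The regime determines
#' which engines run: \code{stdp_only} freezes the structure,
#' \code{hsp_only} runs structural updates without STDP (P_w forced to 0),
#' \code{stdp_hsp} combines them without weight-dependent pruning (P_w = 0),
#' \code{stdp_sp} adds weight-dependent pruning.
#'
#' @param regime one of "stdp_only", "hsp_only", "stdp_hsp", "stdp_sp"
#' @param m lattice side count
#' @param L lattice side length (mm)
#' @param beta0 initial mean node degree density
#' @param mean_weight0 initial mean synaptic weight
#' @param f0 mean natural firing rate (Hz)
#' @param sigma_f natural-rate SD (Hz)
#' @param neuron a \code{neuron_params}
#' @param stdp an \code{stdp_params}
#' @param sp an \code{sp_params} (P_w forced to 0 under the hSP regimes)
#' @param interval_s convergence interval T (s)
#' @param upsilon convergence relative accuracy
#' @param n_min,n_max convergence interval bounds for steady-state runs
#' @param sp_n_min,sp_n_max convergence bounds inside each structural
#'   iteration
#' @param max_sp_iterations cap on structural iterations
#' @param dt integration step (ms)
#' @param op_window order-parameter averaging window (ms)
#' @return an object of class \code{experiment_config}
#' @export
experiment_config <- function(regime = c("stdp_only", "hsp_only", "stdp_hsp",
                                         "stdp_sp"),
                              m = 20, L = 1, beta0 = 0.075, mean_weight0 = 0.8,
                              f0 = 3, sigma_f = 0.5,
                              neuron = neuron_params(), stdp = stdp_params(),
                              sp = sp_params(l0 = 0.5 * L),
                              interval_s = 60, upsilon = 1e-3,
                              n_min = 60, n_max = 200,
                              sp_n_min = 2, sp_n_max = 31,
                              max_sp_iterations = 100, dt = 0.1,
                              op_window = 2000) {
  regime <- match.arg(regime)
  if (regime %in% c("hsp_only", "stdp_hsp")) sp$P_w <- 0
  cfg <- list(regime = regime, m = m, L = L, beta0 = beta0,
              mean_weight0 = mean_weight0, f0 = f0, sigma_f = sigma_f,
              neuron = neuron, stdp = stdp, sp = sp,
              interval_s = interval_s, upsilon = upsilon,
              n_min = n_min, n_max = n_max,
              sp_n_min = sp_n_min, sp_n_max = sp_n_max,
              max_sp_iterations = max_sp_iterations, dt = dt,
              op_window = op_window)
  class(cfg) <- "experiment_config"
  cfg
}

#' Build a network realization from a configuration
#'
#' Places the lattice, wires the initial random connectivity at the requested
#' density (empty when \code{beta0 = 0}), assigns initial weights, samples
#' the per-neuron leak conductances through the calibration line and
#' initializes the dynamic state. Each stochastic ingredient uses its own
#' stream derived from the master seed.
#'
#' @param config an \code{experiment_config}
#' @param calib a \code{calibration}
#' @param master_seed integer master seed
#' @return list with \code{geometry}, \code{conn}, \code{state},
#'   \code{g_leak}, \code{natural_rates} and the derived \code{seeds}
#' @export
build_network <- function(config, calib, master_seed) {
  seeds <- derive_seeds(master_seed)
  geometry <- place_neurons(config$m, config$L, rng_seed = seeds[["wiring"]])
  conn <- random_connectivity(geometry, config$beta0, config$sp$l0)
  conn <- init_weights(conn, config$mean_weight0, rng_seed = seeds[["weights"]])
  g_leak <- sample_gleak(config$f0, config$sigma_f, calib, geometry$N,
                         rng_seed = seeds[["membrane"]])
  state <- initial_state(g_leak, config$neuron, rng_seed = seeds[["membrane"]])
  list(geometry = geometry, conn = conn, state = state, g_leak = g_leak,
       natural_rates = natural_rates(g_leak, calib), seeds = seeds)
}

relax_to_steady_state <- function(state, conn, config, n_min, n_max,
                                  stimulus = NULL, collect_raster = TRUE) {
  interval_ms <- config$interval_s * 1000
  stdp <- if (config$regime == "hsp_only") NULL else config$stdp
  summaries <- NULL
  raster <- NULL
  converged <- FALSE
  n_used <- n_max
  for (n in seq_len(n_max)) {
    out <- integrate_interval(state, conn, config$neuron, stdp, stimulus,
                              duration = interval_ms, dt = config$dt,
                              tau_slow_ms = config$sp$tau_slow_ms)
    state <- out$state
    conn <- out$conn
    raster <- out$raster
    s <- network_summary(raster, conn, interval_ms, state$t, config$op_window)
    s$interval <- n
    summaries <- rbind(summaries, s)
    sw <- ifelse(is.na(summaries$mean_weight), 0, summaries$mean_weight)
    cv <- convergence_test(sw, summaries$mean_rate,
                           config$upsilon, n_min, n_max)
    if (cv$converged) { converged <- TRUE; n_used <- n; break }
  }
  list(state = state, conn = conn, summaries = summaries,
       raster = if (collect_raster) raster else NULL,
       converged = converged, n_intervals = n_used)
}

#' Relax a network with frozen structure to its steady state
#'
#' Iterates convergence intervals of length T with spiking dynamics (plus
#' STDP unless the regime is \code{hsp_only}) until both the mean weight and
#' the mean rate series pass the convergence test, or \code{n_max} intervals
#' elapse. Structure never changes during the call.
#'
#' @param network a list from \code{\link{build_network}} (or compatible)
#' @param config an \code{experiment_config}
#' @param noise_seed optional integer seed for the noise stream; defaults to
#'   the network's derived seed
#' @return an \code{experiment_record}: per-interval summaries, final state,
#'   connectivity, last-interval raster, convergence flag
#' @export
run_steady_state <- function(network, config, noise_seed = NULL) {
  seed <- if (!is.null(noise_seed)) noise_seed
          else unname(network$seeds[["noise"]])
  set.seed(seed)
  res <- relax_to_steady_state(network$state, network$conn, config,
                               config$n_min, config$n_max)
  rec <- list(summaries = res$summaries, state = res$state, conn = res$conn,
              raster = res$raster, converged = res$converged,
              n_intervals = res$n_intervals, config = config)
  class(rec) <- "experiment_record"
  rec
}

#' Adiabatic structural-plasticity loop
#'
#' Alternates (a) relaxation of the fast dynamics (spiking + STDP unless
#' hSP-only) until the convergence test passes with the within-iteration
#' bounds, (b) measurement, and (c) one synchronous structural update driven
#' by the slow firing-rate estimates. The slow estimator is warm-started
#' from the empirical rates of the first relaxation's final interval. New
#' contacts receive uniform weights on [0, 0.2] when STDP is active and on
#' [0, 1] under hSP-only. The loop stops after \code{max_sp_iterations} or
#' earlier if \code{beta_tol} is given and the density series converges to
#' that relative accuracy.
#'
#' @param network a list from \code{\link{build_network}}
#' @param config an \code{experiment_config} with an SP-capable regime
#' @param beta_tol optional relative accuracy on the density series for early
#'   stopping
#' @return an \code{experiment_record} with per-iteration summaries (one row
#'   per structural iteration), the structural event log, final state and
#'   connectivity
#' @export
run_adiabatic_sp <- function(network, config, beta_tol = NULL) {
  if (config$regime == "stdp_only")
    stop("regime 'stdp_only' has no structural updates; use run_steady_state")
  set.seed(unname(network$seeds[["noise"]]))
  sp_seed_base <- unname(network$seeds[["sp"]])
  state <- network$state
  conn <- network$conn
  new_w <- if (config$regime == "hsp_only") c(0, 1) else c(0, 0.2)
  summaries <- NULL
  events <- NULL
  warm <- FALSE
  interval_ms <- config$interval_s * 1000
  for (it in seq_len(config$max_sp_iterations)) {
    res <- relax_to_steady_state(state, conn, config,
                                 config$sp_n_min, config$sp_n_max)
    state <- res$state
    conn <- res$conn
    if (!warm) {
      # warm-start the slow filter from the final interval's empirical rates
      emp <- rate_and_cv(res$raster, conn$N, interval_ms)$rates
      state$fhat <- emp
      state$fhat_t <- rep(state$t, conn$N)
      warm <- TRUE
    }
    s <- tail(res$summaries, 1)
    s$iteration <- it
    s$n_intervals <- res$n_intervals
    s$relax_converged <- res$converged
    summaries <- rbind(summaries, s)
    rates <- slow_rate(state, tau_slow_ms = config$sp$tau_slow_ms)
    set.seed((sp_seed_base + it) %% .Machine$integer.max)
    up <- sp_update(conn, network$geometry, rates, config$sp, iteration = it,
                    new_weight_range = new_w)
    conn <- up$conn
    if (nrow(up$events)) events <- rbind(events, up$events)
    # restore the noise stream so relaxations stay reproducible
    set.seed((unname(network$seeds[["noise"]]) + it) %% .Machine$integer.max)
    if (!is.null(beta_tol) && nrow(summaries) >= 3) {
      b <- tail(summaries$beta, 3)
      if (all(abs(diff(b)) / pmax(b[-1], 1e-12) < beta_tol)) break
    }
  }
  rec <- list(summaries = summaries, events = events, state = state,
              conn = conn, raster = res$raster, config = config,
              n_iterations = nrow(summaries))
  class(rec) <- "experiment_record"
  rec
}

#' Stimulation protocol: pre / stimulation / post epochs
#'
#' Takes a prepared (typically synchronized) network, runs a short
#' pre-stimulation epoch, a stimulation epoch under UMRS, and a
#' post-stimulation observation epoch, with STDP active throughout and
#' structural updates halted. The outcome is classified as desynchronized
#' when the time-averaged order parameter of the final post-stimulation
#' interval falls below \code{r_threshold}.
#'
#' @param network list with \code{geometry}, \code{conn}, \code{state} (a
#'   prepared steady state)
#' @param config an \code{experiment_config}
#' @param a_s stimulus amplitude scale in [0, 1]
#' @param F_s mean stimulation frequency (Hz)
#' @param stim_duration_s stimulation epoch (s)
#' @param post_duration_s post-stimulation observation epoch (s)
#' @param pre_duration_s pre-stimulation epoch (s)
#' @param r_threshold classification threshold on the post-epoch order
#'   parameter
#' @param stim_seed optional integer seed for the stimulus stream
#' @return list with per-epoch summaries, the post-epoch order parameter
#'   \code{R_post}, the classification \code{desynchronized}, final state and
#'   connectivity
#' @export
run_stimulation_protocol <- function(network, config, a_s, F_s,
                                     stim_duration_s = 120,
                                     post_duration_s = 600,
                                     pre_duration_s = 60,
                                     r_threshold = 0.3,
                                     stim_seed = NULL) {
  stopifnot(pre_duration_s > 0, stim_duration_s >= 0, post_duration_s > 0)
  state <- network$state
  conn <- network$conn
  stdp <- if (config$regime == "hsp_only") NULL else config$stdp
  seed <- if (!is.null(stim_seed)) stim_seed
          else unname(network$seeds[["stimulus"]])
  epoch <- function(state, conn, dur_s, stim) {
    out <- integrate_interval(state, conn, config$neuron, stdp, stim,
                              duration = dur_s * 1000, dt = config$dt,
                              tau_slow_ms = config$sp$tau_slow_ms)
    s <- network_summary(out$raster, out$conn, dur_s * 1000, out$state$t,
                         config$op_window)
    list(state = out$state, conn = out$conn, summary = s, raster = out$raster)
  }
  pre <- epoch(state, conn, pre_duration_s, NULL)
  stim <- if (a_s > 0 && stim_duration_s > 0) {
    sp_ <- stim_params(a_s = a_s, F_s = F_s, L = config$L,
                       neuron = config$neuron)
    field <- stimulus_field(sp_, network$geometry, stim_duration_s * 1000,
                            t0 = pre$state$t, rng_seed = seed)
    epoch(pre$state, pre$conn, stim_duration_s, field)
  } else pre
  post <- stim
  post_summaries <- NULL
  n_post <- max(1, ceiling(post_duration_s / config$interval_s))
  for (k in seq_len(n_post)) {
    dur <- min(config$interval_s, post_duration_s - (k - 1) * config$interval_s)
    post <- epoch(post$state, post$conn, dur, NULL)
    post_summaries <- rbind(post_summaries, post$summary)
  }
  R_post <- tail(post_summaries$R, 1)
  list(pre = pre$summary, stim = stim$summary, post = post_summaries,
       R_post = R_post, desynchronized = is.finite(R_post) && R_post < r_threshold,
       state = post$state, conn = post$conn, raster = post$raster)
}

#' Deterministic miniature networks for tests and examples
#'
#' Presets: \code{two_neuron} (one directed contact), \code{ring_16}
#' (16 neurons on a 4 x 4 lattice wired in a directed ring),
#' \code{lattice_36} (6 x 6 lattice with random distance-dependent wiring)
#' and \code{reference_400} (20 x 20 lattice at the reference defaults).
#'
#' @param preset preset name
#' @param rng_seed integer seed
#' @return list with \code{geometry}, \code{conn}, \code{state},
#'   \code{g_leak}, \code{seeds}
#' @export
fixture_network <- function(preset = c("two_neuron", "ring_16", "lattice_36",
                                       "reference_400"), rng_seed = 1) {
  preset <- match.arg(preset)
  seeds <- derive_seeds(rng_seed)
  np <- neuron_params()
  g3 <- 0.0166  # leak conductance giving roughly the 3 Hz reference rate
  if (preset == "two_neuron") {
    geometry <- place_neurons(2, 1, jitter_scale = 0, rng_seed = seeds[["wiring"]])
    conn <- empty_connectivity(4L)
    conn$A[1, 2] <- 1L; conn$W[1, 2] <- 0.5; conn$birth[1, 2] <- 0L
    g_leak <- rep(g3, 4)
  } else if (preset == "ring_16") {
    geometry <- place_neurons(4, 1, jitter_scale = 0, rng_seed = seeds[["wiring"]])
    conn <- empty_connectivity(16L)
    for (i in seq_len(16)) {
      j <- i %% 16 + 1
      conn$A[j, i] <- 1L; conn$W[j, i] <- 0.5; conn$birth[j, i] <- 0L
    }
    g_leak <- rep(g3, 16)
  } else if (preset == "lattice_36") {
    geometry <- place_neurons(6, 1, rng_seed = seeds[["wiring"]])
    conn <- random_connectivity(geometry, 0.1, 0.5, rng_seed = seeds[["wiring"]])
    conn <- init_weights(conn, 0.8, rng_seed = seeds[["weights"]])
    g_leak <- rep(g3, 36)
  } else {
    geometry <- place_neurons(20, 1, rng_seed = seeds[["wiring"]])
    conn <- random_connectivity(geometry, 0.075, 0.5, rng_seed = seeds[["wiring"]])
    conn <- init_weights(conn, 0.8, rng_seed = seeds[["weights"]])
    g_leak <- rep(g3, 400)
  }
  state <- initial_state(g_leak, np, rng_seed = seeds[["membrane"]])
  list(geometry = geometry, conn = conn, state = state, g_leak = g_leak,
       seeds = seeds)
}
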