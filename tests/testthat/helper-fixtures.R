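# Shared miniature builders for the test suite. Everything is generated in
# code; no stored fixtures.

# a 2-neuron connectivity with a single directed contact pre -> post
two_neuron_conn <- function(pre = 2, post = 1, w = 1) {
  conn <- empty_connectivity(2L)
  conn$A[post, pre] <- 1L
  conn$W[post, pre] <- w
  conn$birth[post, pre] <- 0L
  conn
}

# a quiet state: leak so small that neurons never fire on their own within
# short windows, no noise unless asked for
quiet_params <- function(...) neuron_params(kappa_noise = 0, f_noise = 0, ...)

quiet_state <- function(N, params = quiet_params(), g_leak = rep(0.005, N)) {
  st <- initial_state(g_leak, params, rng_seed = 1)
  st$V <- rep(params$V_reset, N)
  st
}

# hand-built calibration object (exact line), for algebra-only tests
line_calibration <- function(alpha1 = 125.67, alpha2 = 0.92) {
  cal <- list(alpha1 = alpha1, alpha2 = alpha2,
              grid = seq(0.005, 0.05, length.out = 10), rates = NULL,
              r_squared = 1, kappa_noise = 0.06, f_noise = 20)
  class(cal) <- "calibration"
  cal
}

# random small digraph as plast_conn
random_digraph <- function(N, p, seed) {
  set.seed(seed)
  conn <- empty_connectivity(as.integer(N))
  A <- matrix(runif(N * N) < p, N, N)
  diag(A) <- FALSE
  conn$A[] <- as.integer(A)
  conn$W[A] <- runif(sum(A))
  conn$birth[A] <- 0L
  conn
}

# brute-force edge-enumeration of the four directed degree-degree Pearson
# coefficients: explicit loops, no reuse of the package's linear algebra
brute_assortativity <- function(conn) {
  N <- conn$N
  indeg <- integer(N); outdeg <- integer(N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (conn$A[i, j] == 1L) { indeg[i] <- indeg[i] + 1L; outdeg[j] <- outdeg[j] + 1L }
  }
  U <- list(); V <- list()
  for (eps in c("in", "out")) for (ups in c("in", "out")) {
    u <- c(); v <- c()
    for (i in seq_len(N)) for (j in seq_len(N)) {
      if (conn$A[i, j] == 1L) {  # edge j -> i
        u <- c(u, if (eps == "in") indeg[j] else outdeg[j])
        v <- c(v, if (ups == "in") indeg[i] else outdeg[i])
      }
    }
    E <- length(u)
    ub <- sum(u) / E; vb <- sum(v) / E
    se <- sqrt(sum((u - ub)^2) / E); sv <- sqrt(sum((v - vb)^2) / E)
    key <- paste(eps, ups, sep = "_")
    U[[key]] <- if (se == 0 || sv == 0) NA_real_
                else sum((u - ub) * (v - vb)) / (E * se * sv)
  }
  unlist(U)
}
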