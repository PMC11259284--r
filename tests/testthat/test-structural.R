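test_that("derived logistic constants match their definitions", {
  p <- sp_params()
  expect_equal(p$f_minus, 4.0)
  expect_equal(p$f_plus, 5.0)
  expect_equal(p$nu, 1 / (2 * log(99)))
  # at the target rate both factors sit at the floor probability
  expect_equal(sp_logistic(p$f_T, p$f_minus, -p$nu), p$p_tilde_T,
               tolerance = 1e-12)
  expect_equal(sp_logistic(p$f_T, p$f_plus, p$nu), p$p_tilde_T,
               tolerance = 1e-12)
  # one steepness width below target the addition factor saturates
  expect_equal(sp_logistic(p$f_T - p$delta_f, p$f_minus, -p$nu),
               1 - p$p_tilde_T, tolerance = 1e-12)
  expect_equal(sp_logistic(5, 5, 0.3), 0.5)
})

test_that("addition probability follows its closed form", {
  p <- sp_params()
  expect_equal(p_add(0, 0, p), p$P_h, tolerance = 1e-12)
  expect_equal(p_add(p$f_T, 0, p), p$P_h * p$p_tilde_T, tolerance = 1e-12)
  expect_equal(p_add(p$f_T, 0, p), 1e-4, tolerance = 1e-12)
  # reference curve construction at P_h = 1, f = 4 Hz, l = 0.1, l0 = 0.5
  p1 <- sp_params(P_h = 1)
  expect_equal(p_add(4, 0.1, p1), 0.5 * exp(-0.2), tolerance = 1e-12)
  expect_equal(p_add(4, 0.1, p1), 0.4094, tolerance = 1e-4)
  # monotone decreasing in rate and distance
  f <- seq(0, 10, 0.25)
  expect_true(all(diff(p_add(f, 0.1, p)) < 0))
  l <- seq(0, 1, 0.05)
  expect_true(all(diff(p_add(3, l, p)) < 0))
})

test_that("pruning probability combines weight and homeostatic hazards", {
  p9 <- sp_params(P_w = 0.9)
  expect_equal(p_prune(p9$f_T, 0, p9), p9$P_w + p9$P_h * p9$p_tilde_T,
               tolerance = 1e-12)
  # probabilities are capped at 1 when the two hazards add past it
  p <- sp_params(P_w = 1)
  expect_equal(p_prune(1e3, 0, p), 1)
  # strong contacts lose the weight hazard entirely
  expect_equal(p_prune(p$f_T, 1, p), p$P_h * p$p_tilde_T, tolerance = 1e-12)
  # pure homeostatic pruning saturates at P_h
  p0 <- sp_params(P_w = 0)
  expect_equal(p_prune(1e6, 0.5, p0), p0$P_h, tolerance = 1e-12)
  # monotonicity: non-increasing in w, non-decreasing in f
  w <- seq(0, 0.02, 0.001)
  expect_true(all(diff(p_prune(4.5, w, p)) < 0))
  f <- seq(0, 10, 0.5)
  expect_true(all(diff(p_prune(f, 0.5, p)) >= 0))
  expect_true(all(p_prune(f, 0, p) <= 1))
})

test_that("slow rate filter has exact decay, jump and steady state", {
  tau <- 1.8e6  # 30 min in ms
  expect_equal(update_rate_estimate(2, numeric(0), 0, 5000, tau),
               2 * exp(-5000 / tau))
  expect_equal(update_rate_estimate(0, 100, 0, 100, tau), 1000 / tau)
  # stationary 4.5 Hz train over several filter constants settles at 4.5 Hz
  spikes <- seq(0, 3 * tau, by = 1000 / 4.5)
  f_end <- update_rate_estimate(0, spikes, 0, 3 * tau, tau)
  expect_lt(abs(f_end - 4.5) / 4.5, 0.1)
})

test_that("structural update matches its binomial expectations", {
  g <- place_neurons(3, 1, jitter_scale = 0)
  p <- sp_params(P_h = 0.2, P_w = 0)
  # near-equilibrium trickle: all rates at target
  conn0 <- random_digraph(9, 0.5, seed = 1)
  rates <- rep(p$f_T, 9)
  live0 <- sum(conn0$A)
  off <- !diag(TRUE, 9)
  absent0 <- sum(off) - live0
  nrep <- 400
  set.seed(99)
  adds <- pruns <- numeric(nrep)
  for (r in seq_len(nrep)) {
    up <- sp_update(conn0, g, rates, p, iteration = 1)
    adds[r] <- sum(up$events$event == "add")
    pruns[r] <- sum(up$events$event == "prune")
  }
  exp_add <- sum(p$P_h * p$p_tilde_T * exp(-g$distance / p$l0)[off & conn0$A == 0L])
  exp_prn <- live0 * p$P_h * p$p_tilde_T
  expect_lt(abs(mean(adds) - exp_add), 3 * sd(adds) / sqrt(nrep) + 1e-9)
  expect_lt(abs(mean(pruns) - exp_prn), 3 * sd(pruns) / sqrt(nrep) + 1e-9)
  # saturated homeostatic pruning at very high rates, no additions
  up_hi <- sp_update(conn0, g, rates = rep(100, 9), p, iteration = 1,
                     rng_seed = 7)
  expect_equal(sum(up_hi$events$event == "add"), 0)
  set.seed(98)
  prn_hi <- replicate(nrep, {
    u <- sp_update(conn0, g, rates = rep(100, 9), p, iteration = 1)
    sum(u$events$event == "prune")
  })
  expect_lt(abs(mean(prn_hi) - live0 * p$P_h),
            3 * sd(prn_hi) / sqrt(nrep) + 1e-9)
  # pure growth from an empty network at very low rates
  empty <- empty_connectivity(9L)
  set.seed(97)
  grow <- replicate(nrep, {
    u <- sp_update(empty, g, rates = rep(0.01, 9), p, iteration = 1)
    sum(u$events$event == "add")
  })
  exp_grow <- sum((p$P_h * sp_logistic(0.01, p$f_minus, -p$nu) *
                     exp(-g$distance / p$l0))[off])
  expect_lt(abs(mean(grow) - exp_grow), 3 * sd(grow) / sqrt(nrep))
})

test_that("one update never both adds and prunes a pair; state stays valid", {
  g <- place_neurons(3, 1, jitter_scale = 0)
  p <- sp_params(P_h = 0.5, P_w = 0.5, w_min = 0.5)
  conn <- random_digraph(9, 0.4, seed = 3)
  up <- sp_update(conn, g, rates = rep(4.5, 9), p, iteration = 5, rng_seed = 4)
  dA <- up$conn$A - conn$A
  expect_true(all(abs(dA) <= 1))
  key <- function(e) paste(e$pre, e$post)
  expect_length(intersect(key(up$events[up$events$event == "add", ]),
                          key(up$events[up$events$event == "prune", ])), 0)
  expect_true(all(diag(up$conn$A) == 0L))
  expect_true(all(up$conn$W[up$conn$A == 1L] >= 0 &
                  up$conn$W[up$conn$A == 1L] <= 1))
  expect_true(all(up$conn$birth[up$conn$A == 1L] %in% c(0L, 5L)))
  expect_true(all(is.na(up$conn$birth[up$conn$A == 0L])))
  # lifetime bookkeeping: pruned contacts born at 0 report 5 iterations
  prn <- up$events[up$events$event == "prune", ]
  expect_true(all(prn$lifetime_iterations == 5L))
})

test_that("a single pair reaches the birth-death equilibrium occupancy", {
  # frozen rate and weight; occupancy should match p_add/(p_add + p_prune)
  g <- place_neurons(2, 1, jitter_scale = 0)
  p <- sp_params(P_h = 0.9, P_w = 0.3, w_min = 0.2, l0 = 20)
  rate <- 4.2
  conn <- empty_connectivity(4L)
  w_new <- c(0.25, 0.25)  # degenerate support: frozen weight on rebirth
  a <- p_add(rate, g$distance[1, 2], p)
  b <- p_prune(rate, 0.25, p)
  n_it <- 1e4
  set.seed(123)
  occ <- logical(n_it)
  for (k in seq_len(n_it)) {
    up <- sp_update(conn, g, rates = rep(rate, 4), p, iteration = k,
                    new_weight_range = w_new)
    conn <- up$conn
    occ[k] <- conn$A[1, 2] == 1L
  }
  pi_hat <- mean(occ)
  pi_exp <- a / (a + b)
  # two-state chain: stationary variance with autocorrelation correction
  rho <- 1 - a - b
  se <- sqrt(pi_exp * (1 - pi_exp) / n_it * (1 + rho) / (1 - rho))
  expect_lt(abs(pi_hat - pi_exp), 3 * se)
})

test_that("contact lifetimes under a frozen hazard are geometric", {
  g <- place_neurons(4, 1, jitter_scale = 0)
  p <- sp_params(P_h = 0.01, P_w = 0.3, w_min = 0.15, l0 = 0.5)
  conn <- empty_connectivity(16L)
  off <- !diag(TRUE, 16)
  conn$A[off] <- 1L
  conn$W[off] <- 0.3
  conn$birth[off] <- 0L
  rate <- 100  # homeostatic pruning saturated, additions off
  hazard <- p_prune(rate, 0.3, p)
  lifetimes <- c()
  set.seed(11)
  for (k in 1:60) {
    up <- sp_update(conn, g, rates = rep(rate, 16), p, iteration = k)
    conn <- up$conn
    prn <- up$events[up$events$event == "prune", ]
    lifetimes <- c(lifetimes, prn$lifetime_iterations)
    if (sum(conn$A) == 0) break
  }
  n <- length(lifetimes)
  expect_gt(n, 100)
  # censoring is negligible once (1-h)^60 << 1
  expect_lt(abs(mean(lifetimes) - 1 / hazard), 3 * (1 / hazard) / sqrt(n))
})

test_that("rate/connectivity size mismatches are rejected", {
  g <- place_neurons(3, 1, jitter_scale = 0)
  conn <- empty_connectivity(9L)
  expect_error(sp_update(conn, g, rates = rep(3, 4), sp_params(), 1),
               "does not match")
})
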