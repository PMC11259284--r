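test_that("fixture presets satisfy the basic invariants", {
  two <- fixture_network("two_neuron", rng_seed = 1)
  expect_equal(two$conn$N, 4L)
  expect_equal(sum(two$conn$A), 1)
  lat <- fixture_network("lattice_36", rng_seed = 1)
  expect_equal(lat$geometry$m, 6L)
  expect_equal(lat$geometry$N, 36L)
  expect_true(all(diag(lat$conn$A) == 0L))
  expect_true(all(lat$conn$W[lat$conn$A == 1L] >= 0 &
                  lat$conn$W[lat$conn$A == 1L] <= 1))
  ring <- fixture_network("ring_16", rng_seed = 2)
  nd <- node_degree_densities(ring$conn)
  expect_true(all(nd$beta_in == 1 / 16))
  expect_error(fixture_network("nope"), "arg")
})

test_that("seed streams are deterministic and independent by name", {
  s1 <- derive_seeds(7)
  s2 <- derive_seeds(7)
  s3 <- derive_seeds(8)
  expect_identical(s1, s2)
  expect_false(any(s1 == s3))
  expect_true(all(s1 <= .Machine$integer.max))
  expect_setequal(names(s1), c("wiring", "weights", "membrane", "noise",
                               "sp", "stimulus", "calibration"))
})

test_that("the same master seed reuses wiring across weight conditions", {
  cal <- line_calibration()
  cfg_a <- experiment_config("stdp_only", m = 6, beta0 = 0.1,
                             mean_weight0 = 0.8)
  cfg_b <- experiment_config("stdp_only", m = 6, beta0 = 0.1,
                             mean_weight0 = 0.05)
  na <- build_network(cfg_a, cal, master_seed = 3)
  nb <- build_network(cfg_b, cal, master_seed = 3)
  expect_identical(na$conn$A, nb$conn$A)
  expect_identical(na$g_leak, nb$g_leak)
  expect_false(isTRUE(all.equal(na$conn$W, nb$conn$W)))
})

test_that("regimes gate the plasticity engines", {
  expect_equal(experiment_config("hsp_only", sp = sp_params(P_w = 0.5))$sp$P_w, 0)
  expect_equal(experiment_config("stdp_hsp", sp = sp_params(P_w = 0.5))$sp$P_w, 0)
  expect_equal(experiment_config("stdp_sp", sp = sp_params(P_w = 0.5))$sp$P_w, 0.5)
  expect_error(experiment_config("bogus"), "arg")
})

test_that("identical config and master seed reproduce a run bit-exactly", {
  cal <- line_calibration()
  cfg <- experiment_config("stdp_only", m = 6, beta0 = 0.15, sigma_f = 0.5,
                           mean_weight0 = 0.8, interval_s = 2,
                           n_min = 2, n_max = 3)
  r1 <- run_steady_state(build_network(cfg, cal, 11), cfg)
  r2 <- run_steady_state(build_network(cfg, cal, 11), cfg)
  expect_identical(r1$summaries, r2$summaries)
  expect_identical(r1$raster, r2$raster)
  expect_identical(r1$conn$W, r2$conn$W)
  r3 <- run_steady_state(build_network(cfg, cal, 12), cfg)
  expect_false(identical(r1$raster, r3$raster))
})

test_that("adiabatic structural loop grows an empty network towards target", {
  cal <- line_calibration()
  cfg <- experiment_config("hsp_only", m = 6, beta0 = 0, f0 = 3,
                           sigma_f = 0.5, interval_s = 5,
                           sp_n_min = 1, sp_n_max = 2,
                           max_sp_iterations = 8,
                           sp = sp_params(P_h = 0.05, f_T = 4.5))
  net <- build_network(cfg, cal, master_seed = 5)
  expect_equal(sum(net$conn$A), 0)
  rec <- run_adiabatic_sp(net, cfg)
  expect_equal(nrow(rec$summaries), 8)
  # density and rate grow monotonically towards the target from scratch
  expect_true(all(diff(rec$summaries$beta) >= 0))
  expect_gt(tail(rec$summaries$beta, 1), 0)
  expect_gt(tail(rec$summaries$mean_rate, 1),
            head(rec$summaries$mean_rate, 1))
  expect_true(all(rec$events$event == "add"))
  # hSP-only rebirth weights span (0, 1)
  expect_gt(max(rec$events$weight_at_event), 0.5)
  # determinism of the full structural record
  rec2 <- run_adiabatic_sp(build_network(cfg, cal, 5), cfg)
  expect_identical(rec$summaries, rec2$summaries)
  expect_identical(rec$events, rec2$events)
})

test_that("structural updates under STDP use small rebirth weights", {
  cal <- line_calibration()
  cfg <- experiment_config("stdp_sp", m = 6, beta0 = 0.05, f0 = 3,
                           sigma_f = 0.5, mean_weight0 = 0.5, interval_s = 5,
                           sp_n_min = 1, sp_n_max = 2, max_sp_iterations = 4,
                           sp = sp_params(P_h = 0.05, P_w = 0.01, f_T = 4.5))
  rec <- run_adiabatic_sp(build_network(cfg, cal, 6), cfg)
  adds <- rec$events[rec$events$event == "add", ]
  expect_gt(nrow(adds), 0)
  expect_true(all(adds$weight_at_event <= 0.2))
})

test_that("UMRS suppresses synchrony during the stimulation epoch", {
  cal <- line_calibration(125.91, 0.9159)
  cfg <- experiment_config("stdp_only", m = 10, beta0 = 0.12,
                           mean_weight0 = 0.8, sigma_f = 0.5,
                           interval_s = 10, n_min = 4, n_max = 6)
  net <- suppressWarnings(build_network(cfg, cal, master_seed = 41))
  rec <- run_steady_state(net, cfg)
  prep <- net
  prep$conn <- rec$conn
  prep$state <- rec$state
  out <- run_stimulation_protocol(prep, cfg, a_s = 0.4, F_s = 50,
                                  stim_duration_s = 60, post_duration_s = 30,
                                  pre_duration_s = 10)
  expect_gt(out$pre$R, 0.5)
  expect_lt(out$stim$R, out$pre$R - 0.1)
  # the stimulated epoch raises the firing rate
  expect_gt(out$stim$mean_rate, out$pre$mean_rate)
})

test_that("zero-amplitude stimulation leaves a network in its attractor", {
  cal <- line_calibration()
  cfg <- experiment_config("stdp_only", m = 6, beta0 = 0.15, sigma_f = 0.5,
                           mean_weight0 = 0.8, interval_s = 5,
                           n_min = 2, n_max = 3, op_window = 2000)
  net <- build_network(cfg, cal, 21)
  rec <- run_steady_state(net, cfg)
  prepared <- list(geometry = net$geometry, conn = rec$conn,
                   state = rec$state, seeds = net$seeds)
  out <- run_stimulation_protocol(prepared, cfg, a_s = 0, F_s = 50,
                                  stim_duration_s = 0, post_duration_s = 10,
                                  pre_duration_s = 5)
  expect_false(out$desynchronized)
  expect_equal(out$stim$R, out$pre$R)  # zero stimulus epoch is skipped
  expect_true(is.finite(out$R_post))
})
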