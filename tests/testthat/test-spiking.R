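test_that("NMDA gating has the right limits, monotonicity, and pinned value", {
  expect_gt(nmda_gating(200, 1), 0.999)
  v <- seq(-90, 0, by = 1)
  expect_true(all(diff(nmda_gating(v, 1)) > 0))
  # direct evaluation at threshold, 1 mM magnesium (regression pin)
  expect_equal(nmda_gating(-48.6, 1),
               1 / (1 + (1 / 3.57) * exp(48.6 / 16.13)), tolerance = 1e-12)
  expect_equal(nmda_gating(-48.6, 1), 0.149255, tolerance = 1e-4)
})

test_that("LIF membrane follows the closed-form subthreshold response", {
  sp <- spiking_params(n_conductor = 1, n_student = 1, g_inh = 0)
  empty <- spike_train(list(numeric(0)), 0, 0.3)
  W <- matrix(0, 1, 1)

  # no input: V stays at rest
  res0 <- simulate_lif(empty, NULL, W, sp, t_end = 0.1, record_v = TRUE)
  expect_true(all(res0$v == sp$v_reset))
  expect_equal(length(res0$spikes$times[[1]]), 0L)

  # constant current below rheobase: V relaxes along exp(-t/tau_m)
  I <- 50 # pA; rheobase is ~67 pA
  res <- simulate_lif(empty, NULL, W, sp, t_end = 0.3, i_ext = I,
                      record_v = TRUE)
  tt <- seq_len(ncol(res$v)) * sp$dt
  vth <- sp$v_reset + sp$r_in * I * 1e-3 * (1 - exp(-tt / sp$tau_m))
  expect_lt(max(abs(res$v[1, ] - vth) / abs(vth)), 1e-3)
  expect_equal(length(res$spikes$times[[1]]), 0L)
})

test_that("suprathreshold firing matches the analytic ISI and obeys reset", {
  sp <- spiking_params(n_conductor = 1, n_student = 1, g_inh = 0)
  empty <- spike_train(list(numeric(0)), 0, 0.5)
  W <- matrix(0, 1, 1)
  I <- 120 # pA, suprathreshold
  res <- simulate_lif(empty, NULL, W, sp, t_end = 0.5, i_ext = I,
                      record_v = TRUE)
  spk <- res$spikes$times[[1]]
  expect_gt(length(spk), 10)
  vinf <- sp$r_in * I * 1e-3
  isi_theory <- sp$tau_ref +
    sp$tau_m * log(vinf / (vinf - (sp$v_thresh - sp$v_reset)))
  expect_lt(max(abs(diff(spk) - isi_theory)), sp$dt + 1e-12)

  # reset and refractory contracts on every emitted spike
  expect_true(all(diff(spk) >= sp$tau_ref))
  idx <- round(spk / sp$dt)
  expect_true(all(res$v[1, idx] == sp$v_reset))
})

test_that("conductor bursts have 5-6 spikes at the intra-burst rate", {
  g <- time_grid(0, 1, 1e-3)
  sp <- spiking_params(n_conductor = 20)
  st <- generate_conductor_spikes(g, sp, jitter = FALSE)
  counts <- lengths(st$times)
  expect_true(all(counts %in% c(5, 6)))
  expect_true(any(counts == 5) && any(counts == 6))
  # zero jitter: exactly periodic at 1/632 s within a burst
  isis <- unlist(lapply(st$times, diff))
  expect_equal(isis, rep(1 / 632, length(isis)), tolerance = 1e-12)

  # onset jitter statistics across renditions: sd of uniform(+/- 0.3 ms)
  set.seed(61)
  onsets <- replicate(300, generate_conductor_spikes(g, sp)$times[[3]][1])
  expect_equal(sd(onsets), 0.3e-3 / sqrt(3), tolerance = 0.2)
})

test_that("Poisson tutor spikes have the right count statistics", {
  set.seed(62)
  g <- time_grid(0, 10, 1e-3)
  f <- signal(matrix(100, 1, g$n), g, units = "Hz")
  counts <- replicate(200, length(generate_poisson_tutor(f)$times[[1]]))
  # mean count within 3 standard errors of rate * duration
  expect_lt(abs(mean(counts) - 1000), 3 * sd(counts) / sqrt(200))
  # Fano factor near 1
  expect_gt(var(counts) / mean(counts), 0.75)
  expect_lt(var(counts) / mean(counts), 1.3)

  none <- generate_poisson_tutor(signal(matrix(0, 1, g$n), g))
  expect_equal(lengths(none$times), 0L)
  expect_error(generate_poisson_tutor(signal(matrix(-1, 1, g$n), g)),
               "non-negative")
})

test_that("rate estimation matches impulse response and long-run average", {
  g <- time_grid(0, 1, 1e-3)
  none <- estimate_rates(spike_train(list(numeric(0)), 0, 1), 0.02, g)
  expect_true(all(none$values == 0))

  one <- estimate_rates(spike_train(list(0.2), 0, 1), 0.02, g)
  idx <- g$times >= 0.2
  expect_equal(one$values[1, idx],
               exp(-(g$times[idx] - 0.2) / 0.02) / 0.02, tolerance = 1e-9)

  set.seed(63)
  gl <- time_grid(0, 200, 1e-3)
  spk <- cumsum(rexp(20000, rate = 50))
  spk <- spk[spk < 200]
  est <- estimate_rates(spike_train(list(spk), 0, 200), 0.02, gl)
  expect_equal(mean(est$values[1, gl$times > 1]), 50, tolerance = 0.05)
})

test_that("initial spiking weights are sparse log-normal with Table values", {
  set.seed(64)
  sp <- spiking_params()
  W <- init_spiking_weights(sp)
  expect_equal(dim(W), c(300L, 80L))
  expect_true(all(colSums(W > 0) == 148))
  nz <- W[W > 0]
  expect_true(all(nz > 0))
  expect_equal(mean(nz), 32.6, tolerance = 0.05)
  expect_equal(sd(nz), 17.4, tolerance = 0.1)
})

test_that("untrained network fires irregularly under conductor drive", {
  set.seed(65)
  sp <- spiking_params(n_conductor = 150, n_student = 40,
                       synapses_per_student = 74,
                       w_mean = 32.6 * 2, w_sd = 17.4 * 2)
  g <- time_grid(0, 1, 1e-3)
  W <- init_spiking_weights(sp)
  cond <- generate_conductor_spikes(g, sp)
  f <- signal(matrix(80, 40, g$n), g, units = "Hz")
  tut <- generate_poisson_tutor(f)
  sim <- simulate_lif(cond, tut, W, sp)
  stats <- spike_statistics(sim$spikes)
  expect_gt(stats$mean_rate, 10)   # students are active, not silent
  expect_gt(stats$isi_cv, 0.5)     # juvenile-like irregular firing
  # hard refractory contract on every neuron
  isis <- unlist(lapply(sim$spikes$times, diff))
  expect_true(all(isis >= sp$tau_ref))
})
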