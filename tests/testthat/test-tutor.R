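test_that("matched tutor integrates the error with the stated closed form", {
  g <- time_grid(0, 0.5, 1e-3)
  p <- plasticity_params(2, 1, eta = 1)
  spec <- tutor_spec("matched", tau_tutor = 0.1, zeta = 3, theta = 80)

  # zero error -> g = theta everywhere
  z <- matched_tutor(signal(matrix(0, 2, g$n), g), spec, p)
  expect_true(all(z$values == 80))

  # constant error: step response of the normalized filter
  e0 <- 0.4
  gm <- matched_tutor(signal(rep(e0, g$n), g), spec, p)
  pred <- 80 - (3 / 1) * e0 * (1 - exp(-g$times / 0.1))
  expect_equal(gm$values[1, ], pred, tolerance = 1e-3)

  # random error against the quadrature oracle
  set.seed(51)
  ev <- rnorm(g$n)
  gm2 <- matched_tutor(signal(ev, g), spec, p)
  oracle <- 80 - 3 * oracle_exp_filter(ev, g$times, 0.1)
  expect_lt(max(abs(gm2$values[1, -1] - oracle[-1])), 1e-8)
})

test_that("saturating tutor is bounded and attains 160 Hz in the limit", {
  g <- time_grid(0, 1, 1e-3)
  p <- plasticity_params(1, 0, eta = 1)
  spec <- tutor_spec("saturating", tau_tutor = 0.08, zeta = 1,
                     rho = 80, theta = 80)

  z <- saturating_tutor(signal(matrix(0, 1, g$n), g), spec, p)
  expect_true(all(z$values == 80))

  # arbitrary errors stay within [theta - rho, theta + rho]
  set.seed(52)
  wild <- saturating_tutor(signal(matrix(rnorm(2 * g$n, sd = 1e3), 2), g),
                           spec, p)
  expect_gte(min(wild$values), 0)
  expect_lte(max(wild$values), 160)

  # large negative integrated error drives the rate to the 160 Hz ceiling
  big <- saturating_tutor(signal(rep(-1e9, g$n), g), spec, p)
  expect_equal(max(big$values), 160)

  # agreement with the matched tutor to first order when |error| << rho
  sm <- signal(rep(0.5, g$n), g)
  expect_equal(saturating_tutor(sm, spec, p)$values,
               matched_tutor(sm, spec, p)$values, tolerance = 1e-4)
})

test_that("reward trace is monotone in the mismatch and integrates to -2L", {
  g <- time_grid(0, 1, 1e-3)
  set.seed(53)
  y <- signal(matrix(rnorm(2 * g$n), 2), g)
  yt <- signal(matrix(rnorm(2 * g$n), 2), g)
  expect_true(all(reward_from_loss(yt, yt)$values == 0))

  r <- reward_from_loss(y, yt)
  expect_true(all(r$values <= 0))
  # worse match at a time -> lower reward there
  y2 <- y; y2$values[, 100] <- y$values[, 100] + 10
  r2 <- reward_from_loss(y2, yt)
  expect_lt(r2$values[1, 100], r$values[1, 100])

  expect_equal(integrate_signal(r), -2 * motor_loss(y, yt),
               tolerance = 1e-10)
})

test_that("reinforcement updates obey the trivial contracts", {
  g <- time_grid(0, 0.5, 1e-3)
  spec <- tutor_spec("reinforcement", tau_tutor = 0, eta_tutor = 0.1)
  f <- signal(matrix(80, 2, g$n), g)
  gbar <- signal(matrix(80, 2, g$n), g)

  # R identically at baseline -> no update
  st <- reinforcement_state(f, gbar, r_bar_init = -1)
  flat_r <- signal(matrix(-1, 1, g$n), g)
  up <- reinforcement_update(st, signal(matrix(85, 2, g$n), g), flat_r, spec)
  expect_equal(up$f$values, f$values, tolerance = 1e-9)

  # zero fluctuation -> no update even with varying reward
  set.seed(54)
  rw <- signal(matrix(-runif(g$n), 1), g)
  up2 <- reinforcement_update(st, gbar, rw, spec)
  expect_equal(up2$f$values, f$values, tolerance = 1e-9)

  # positive fluctuation at above-baseline reward raises the rate there
  gact <- gbar; gact$values[1, 200:260] <- 95
  rw3 <- signal(matrix(-0.5, 1, g$n), g)
  rw3$values[1, 200:260] <- 0 # above the running baseline
  up3 <- reinforcement_update(st, gact, rw3, spec)
  expect_gt(mean(up3$f$values[1, 200:260]), 80)
  expect_equal(up3$f$values[2, ], f$values[2, ], tolerance = 1e-9)

  # rates stay non-negative
  gact2 <- gbar; gact2$values[1, ] <- 300
  rwneg <- signal(matrix(-1e6, 1, g$n), g)
  st2 <- reinforcement_state(f, gbar, r_bar_init = 0)
  up4 <- reinforcement_update(st2, gact2, rwneg, spec)
  expect_gte(min(up4$f$values), 0)
})

test_that("memory-less reinforcement learning converges on the rate model", {
  ratios <- vapply(1:3, function(s) {
    cfg <- rate_config(seed = s, renditions = 3500,
                       plasticity = plasticity_params(0, -1, eta = 2),
                       tutor = tutor_spec("reinforcement", tau_tutor = 0,
                                          eta_tutor = 1e-3))
    tr <- run_reinforcement(cfg)
    tr$final_loss / tr$initial_loss
  }, numeric(1))
  expect_true(all(ratios < 0.1))
})

test_that("expected reinforcement update aligns with the matched correction", {
  # frozen network: average the stochastic tutor update over many renditions
  # and compare its direction with the error-opposing correction
  set.seed(55)
  cfg <- rate_config(seed = 55, renditions = 1,
                     plasticity = plasticity_params(0, -1, eta = 1))
  grid <- time_grid(0, cfg$t_end, cfg$dt)
  c_sig <- generate_conductor_rates(grid, cfg$n_conductor)
  target <- generate_target(cfg$target, grid)
  M <- output_map(cfg$n_student, 2)
  W <- matrix(runif(cfg$n_conductor * cfg$n_student, 0, 2),
              cfg$n_conductor, cfg$n_student)
  st <- network_state(W, M, w = cfg$w, x_inh = cfg$w * 80)
  spec <- tutor_spec("reinforcement", tau_tutor = 0, eta_tutor = 1,
                     explore_sd = 20, explore_tau = 0.02)

  theta_sig <- signal(matrix(80, cfg$n_student, grid$n), grid)
  # converged baselines: run with g_bar = theta (true mean of g) and R_bar
  # from the noise-free rendition
  s0 <- student_rates(st, c_sig, theta_sig)
  y0 <- motor_output(st, s0, cfg$tau_out)
  eps0 <- motor_error(st, y0, target)
  r0 <- reward_from_loss(y0, target)

  acc <- 0
  n_mc <- 150
  for (k in seq_len(n_mc)) {
    noise <- matrix(rnorm(cfg$n_student * grid$n), cfg$n_student, grid$n)
    noise <- exp_filter(noise, spec$explore_tau, dt = grid$dt) *
      sqrt(2 * spec$explore_tau / grid$dt) * spec$explore_sd
    gk <- signal(pmax(80 + noise, 0), grid)
    sk <- student_rates(st, c_sig, gk)
    yk <- motor_output(st, sk, cfg$tau_out)
    rk <- reward_from_loss(yk, target)
    stt <- reinforcement_state(theta_sig, theta_sig,
                               r_bar_init = r0$values[1, grid$n])
    up <- reinforcement_update(stt, gk, rk, spec)
    acc <- acc + (up$f$values - 80)
  }
  mean_df <- acc / n_mc
  expect_gt(sum(mean_df * (-eps0$values)), 0)
})
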