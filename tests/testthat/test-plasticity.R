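test_that("plasticity kernel is causal with the analytic moments", {
  p <- plasticity_params(1, 0, eta = 1)
  expect_equal(plasticity_kernel(-0.01, p), 0)

  # quadrature of the kernel and its first moment on a fine grid
  p2 <- plasticity_params(3, 2, eta = 1)
  tt <- seq(0, 2, by = 1e-4)
  k <- plasticity_kernel(tt, p2)
  expect_equal(oracle_trapz(k, 1e-4), p2$alpha - p2$beta, tolerance = 1e-6)
  expect_equal(oracle_trapz(tt * k, 1e-4),
               p2$alpha * p2$tau1 - p2$beta * p2$tau2, tolerance = 1e-6)

  expect_error(plasticity_params(2, 0.5, eta = 1), "alpha - beta")
  p3 <- plasticity_params(2, 0.5, eta = 1, enforce_normalization = FALSE)
  expect_equal(p3$alpha - p3$beta, 1.5)
})

test_that("filter_conductor reproduces impulse responses and the oracle", {
  g <- time_grid(0, 0.5, 1e-3)
  p <- plasticity_params(2, 1, eta = 1)
  zero <- filter_conductor(signal(rep(0, g$n), g), p)
  expect_true(all(zero$values == 0))

  # unit-area impulse at t0: filtered trace approximates K(t - t0)
  t0 <- 0.1
  imp <- rep(0, g$n); imp[which.min(abs(g$times - t0))] <- 1 / g$dt
  cf <- filter_conductor(signal(imp, g), p)
  idx <- g$times > t0 + 0.01
  expect_equal(cf$values[1, idx], plasticity_kernel(g$times[idx] - t0, p),
               tolerance = 0.02)

  set.seed(31)
  x <- rnorm(g$n)
  cf2 <- filter_conductor(signal(x, g), p)
  oracle <- p$alpha * oracle_exp_filter(x, g$times, p$tau1) -
    p$beta * oracle_exp_filter(x, g$times, p$tau2)
  expect_equal(cf2$values[1, ], oracle, tolerance = 1e-9)
})

test_that("weight update vanishes at threshold and is linear in g - theta", {
  g <- time_grid(0, 1, 1e-3)
  p <- plasticity_params(1, 0, eta = 0.5, theta = 80)
  cs <- generate_conductor_rates(g, 10)
  cf <- filter_conductor(cs, p)
  W0 <- matrix(1, 10, 3)

  g_th <- signal(matrix(80, 3, g$n), g)
  expect_equal(weight_update(W0, cf, g_th, p), W0, tolerance = 1e-12)

  set.seed(41)
  gv <- matrix(80 + rnorm(3 * g$n, sd = 10), 3)
  d1 <- weight_update(W0, cf, signal(gv, g), p) - W0
  d2 <- weight_update(W0, cf, signal(80 + 2 * (gv - 80), g), p) - W0
  expect_equal(2 * d1, d2, tolerance = 1e-9)

  # positivity clipping applies after the rendition's update
  gneg <- signal(matrix(0, 3, g$n), g) # g far below theta
  Wneg <- weight_update(matrix(0.01, 10, 3), cf, gneg, p, positivity = TRUE)
  expect_true(all(Wneg >= 0))
})

test_that("two-term kernel approximation holds for impulse and slow ramps", {
  # fine grid; narrow conductor pulse well inside the program
  g <- time_grid(0, 1.5, 1e-4)
  p <- plasticity_params(2, 1, eta = 1, theta = 0)
  ti <- 0.4
  pulse <- as.numeric(g$times >= ti & g$times < ti + 1e-3) / 1e-3
  cf <- filter_conductor(signal(pulse, g), p)

  # constant tutor signal: Delta W = eta (alpha - beta) (g0 - theta)
  g0 <- 30
  dW <- weight_update(matrix(0, 1, 1), cf,
                      signal(matrix(g0, 1, g$n), g), p)
  expect_equal(as.numeric(dW), (p$alpha - p$beta) * g0, tolerance = 1e-3)

  # slow linear ramp (variation over ~10 tau1): two-term form within 2%
  slope <- 30 / 0.8 # 30 Hz change over 0.8 s >> tau1
  gv <- 50 + slope * (g$times - ti)
  dW2 <- weight_update(matrix(0, 1, 1), cf, signal(matrix(gv, 1), g), p)
  pred <- (p$alpha - p$beta) * 50 +
    (p$alpha * p$tau1 - p$beta * p$tau2) * slope
  expect_equal(as.numeric(dW2), pred, tolerance = 0.02)
})

test_that("optimal timescale reproduces the printed parameter sets", {
  expect_equal(optimal_timescale(plasticity_params(0, -1, 0.08, 0.04)), 0.04)
  expect_equal(optimal_timescale(plasticity_params(24, 23, 0.08, 0.04)), 1)
  expect_equal(optimal_timescale(plasticity_params(1, 0, 0.08, 0.04)), 0.08)
  # beta = 0 collapses to tau1
  expect_equal(optimal_timescale(plasticity_params(1, 0, 0.123, 0.04)),
               0.123)
  expect_error(
    optimal_timescale(plasticity_params(2, 2, eta = 1,
                                        enforce_normalization = FALSE)),
    "alpha = beta")
})

test_that("matched tutor update is anti-parallel to the loss gradient", {
  # regime where the matching derivation's assumptions hold: bursts tile the
  # interior of a long program, kernel timescales well below tau_tutor, and
  # the error varying slowly relative to the kernel width
  set.seed(42)
  grid <- time_grid(0, 5, 1e-3)
  nc <- 30; ns <- 10
  c_sig <- interior_conductor(grid, nc, margin = 0.5)
  target <- generate_target(target_spec(2, tau_smooth = 1), grid)
  M <- output_map(ns, 2)
  W <- matrix(3, nc, ns)
  p <- plasticity_params(24, 23, tau1 = 0.02, tau2 = 0.01, eta = 1e-4,
                         theta = 0)
  taut <- optimal_timescale(p)
  expect_gt(taut / p$tau1, 10) # tau_tutor >> tau_1,2

  st <- network_state(W, M, w = 0, x_inh = 0)
  s <- student_rates(st, c_sig)
  y <- motor_output(st, s, tau_out = 0.01)
  eps <- motor_error(st, y, target)
  gsig <- matched_tutor(eps, tutor_spec("matched", tau_tutor = taut,
                                        zeta = 1, theta = 0), p)
  dW <- weight_update(W * 0, filter_conductor(c_sig, p), gsig, p)
  G <- oracle_loss_gradient(W, c_sig, M, target, tau_out = 0.01)
  expect_gt(cosine(dW, -G), 0.99)
})
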