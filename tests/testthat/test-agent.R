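test_that("LOS geometry is Euclidean, symmetric and translation invariant", {
  s <- engagement_state(c(0, 0, 0), c(0, 0, 1000), v_p = 100, v_e = 50)
  g <- los_geometry(s)
  expect_equal(g$lambda, 1000)
  expect_equal(g$d_t, g$lambda)
  expect_equal(g$v_c, 50)

  sw <- engagement_state(c(0, 0, 1000), c(0, 0, 0), v_p = 100, v_e = 50)
  expect_equal(los_geometry(sw)$lambda, g$lambda)

  sh <- engagement_state(c(7, -3, 11), c(7, -3, 1011), v_p = 100, v_e = 50)
  expect_equal(los_geometry(sh)$lambda, g$lambda)

  s0 <- engagement_state(c(1, 2, 3), c(1, 2, 3), 10, 10)
  g0 <- los_geometry(s0)
  expect_equal(g0$lambda, 0)
  expect_false(g0$defined)
  expect_true(is.na(g0$mu))
})

test_that("deviation angle is 180 deg for a pursuer dead ahead of the evader", {
  # x_p = x_e, psi_p = 0, pursuer farther forward (z_p > z_e): the
  # two-argument arctangent gives atan2(0, +) = 0, so mu = 180 + 0 - 0
  s <- engagement_state(c(0, 0, 100), c(0, 0, -50), v_p = 100, v_e = 50,
                        psi_p = 0, psi_e = 0)
  g <- los_geometry(s)
  mu_direct <- 180 + 0 - atan2(0 - 0, 100 - (-50)) * 180 / pi
  expect_equal(g$mu, mu_direct)
  expect_equal(g$mu, 180)
})

test_that("lambda_dot modes give the LOS-angle rate and the range rate", {
  p1 <- engagement_state(c(0, 0, 0), c(0, 0, 1000), 100, 0, time = 0)
  p2 <- engagement_state(c(0, 0, 0), c(100, 0, 1000), 100, 0, time = 1)
  ang <- los_geometry(p2, p1, lambda_dot_mode = "angle")$lambda_dot
  expect_equal(ang, atan2(100, 1000), tolerance = 1e-9)   # rad/s over 1 s
  rng <- los_geometry(p2, p1, lambda_dot_mode = "range")$lambda_dot
  expect_equal(rng, sqrt(100^2 + 1000^2) - 1000, tolerance = 1e-9)
})

test_that("the APN command follows N * Vc * lambda_dot + a_nt * N / 2", {
  cfg <- guidance_config(N = 3)
  g <- structure(list(lambda_dot = 0, v_c = 100), class = "los_geometry")
  expect_equal(apn_accel(g, cfg), 0)
  g$lambda_dot <- 0.01
  expect_equal(apn_accel(g, cfg), 3)
  cfg2 <- guidance_config(N = 3, a_nt = 2)
  expect_equal(apn_accel(g, cfg2), 6)   # adds N * a_nt / 2 = 3
})

test_that("radar observation honours latency and the 1.2 km coverage", {
  hist <- data.frame(time = seq(0, 1, by = 0.1),
                     xe = seq(0, 100, by = 10), ye = 0, ze = 500,
                     ve = 50, psi_e = 0, xp = 0, yp = 0, zp = 0)
  cfg <- guidance_config(radar_latency = 0.4)
  obs <- radar_observe(hist, 1.0, cfg)
  expect_equal(obs$time, 0.6)
  expect_equal(obs$xe, 60)

  cfg0 <- guidance_config(radar_latency = 0)
  expect_equal(radar_observe(hist, 1.0, cfg0)$time, 1.0)

  expect_null(radar_observe(hist, 0.2, cfg))          # history too short

  hist2 <- hist; hist2$ze <- 1500                     # beyond coverage
  expect_null(radar_observe(hist2, 1.0, cfg))
})

test_that("the reward evaluator applies strict advantage conditions", {
  thr <- reward_thresholds(d_min = 100, d_max = 500, mu_max = 60, eta_max = 45)
  g <- structure(list(d_t = 300, mu = 30, eta = 20), class = "los_geometry")
  r <- rl_reward(g, thr)
  expect_equal(r$reward, 3)
  expect_true(all(r$components))

  g$d_t <- 500                                         # boundary: strict
  expect_false(rl_reward(g, thr)$components[["distance"]])
  g$d_t <- 100
  expect_false(rl_reward(g, thr)$components[["distance"]])
  g$d_t <- 50
  expect_false(rl_reward(g, thr)$components[["distance"]])

  g2 <- structure(list(d_t = 300, mu = 75, eta = 50), class = "los_geometry")
  expect_equal(rl_reward(g2, thr)$reward, 1)
  expect_equal(rl_reward(g2, thr, weights = c(5, 1, 1))$reward, 5)
  expect_error(reward_thresholds(500, 100, 60, 45))
})

test_that("a collision-course pursuit closes with near-zero LOS rate and command", {
  cfg <- guidance_config(step = 0.01, agent1_alt_amp = 0)
  init <- engagement_state(c(0, 700, 0), c(0, 700, 800), v_p = 150, v_e = 0)
  run <- simulate_engagement(init, cfg, "agent1", duration = 8)
  expect_equal(nrow(run$trajectory), 8 / 0.01 + 1)
  expect_lt(run$summary$min_lambda, 1)
  pre <- run$trajectory$t < run$summary$t_min_lambda - 0.05
  expect_lt(max(abs(run$trajectory$a_n[pre])), 1e-6)
  expect_lt(max(abs(run$trajectory$lambda_dot[pre]), na.rm = TRUE), 1e-6)

  # independent fine-step kinematic oracle: closed-form straight-line chase
  tt <- seq(0, 8, by = 1e-4)
  lam_oracle <- abs(800 - 150 * tt)
  expect_equal(run$summary$min_lambda, min(lam_oracle), tolerance = 0.5)
  expect_equal(run$summary$t_min_lambda, tt[which.min(lam_oracle)],
               tolerance = 0.02)
})

test_that("halving the integration step barely changes the miss distance", {
  # degraded-latency chase with a maneuvering evader: a smooth, non-zero
  # miss distance, so relative convergence is well defined
  init <- engagement_state(c(0, 680, 0), c(200, 720, 600), v_p = 150, v_e = 70,
                           psi_p = atan2(200, 600) * 180 / pi, psi_e = 120)
  cfg1 <- guidance_config(step = 0.01, radar_latency = 0.8)
  cfg2 <- guidance_config(step = 0.005, radar_latency = 0.8)
  r1 <- simulate_engagement(init, cfg1, "agent1", 10)
  r2 <- simulate_engagement(init, cfg2, "agent1", 10)
  expect_gt(r1$summary$min_lambda, 10)
  expect_lt(abs(r1$summary$min_lambda - r2$summary$min_lambda) /
              r1$summary$min_lambda, 0.01)
})

test_that("APN beats an unguided pursuer and degrades with radar latency", {
  set.seed(25)
  wins <- 0; mono <- 0; nrep <- 15
  for (i in seq_len(nrep)) {
    rng <- runif(1, 300, 800); brg <- runif(1, -60, 60) * pi / 180
    ev <- c(rng * sin(brg), 700, rng * cos(brg))
    aim <- atan2(ev[1], ev[3]) * 180 / pi
    init <- engagement_state(c(0, 680, 0), ev, 150, 50, psi_p = aim,
                             psi_e = runif(1, -180, 180))
    c4 <- guidance_config(step = 0.01)
    c8 <- guidance_config(step = 0.01, radar_latency = 0.8)
    r4 <- simulate_engagement(init, c4, "agent1", 12)
    r0 <- simulate_engagement(init, c4, "agent1", 12, guidance = "none")
    r8 <- simulate_engagement(init, c8, "agent1", 12)
    wins <- wins + (r4$summary$min_lambda < r0$summary$min_lambda)
    mono <- mono + (r8$summary$min_lambda >= r4$summary$min_lambda - 1e-9)
  }
  expect_equal(mono, nrep)
  expect_gte(wins / nrep, 0.95)
})

test_that("the LOS-proportional evader outruns the pursuer", {
  init <- engagement_state(c(0, 700, 0), c(100, 700, 600), v_p = 120, v_e = 130)
  run <- simulate_engagement(init, guidance_config(step = 0.01),
                             "los_proportional", 10)
  n <- nrow(run$trajectory)
  expect_gt(run$trajectory$lambda[n], run$summary$min_lambda)
  expect_gt(run$trajectory$lambda[n], 400)   # evader opened the range
})

test_that("engagement runs are rejected for inconsistent step/duration", {
  init <- engagement_state(c(0, 0, 0), c(0, 0, 500), 100, 50)
  cfg <- guidance_config(step = 0.3)
  expect_error(simulate_engagement(init, cfg, "agent1", 1), "divide")
  expect_error(simulate_engagement(init, cfg, "agent1", -3), "positive")
})
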