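make_gaze <- function(t, pd, valid = rep(TRUE, length(t))) {
  data.frame(t = t, dir_x = 0, dir_y = 0, dir_z = 1,
             pd_left_mm = pd, pd_right_mm = pd, valid = valid)
}

test_that("pupil preprocessing fills gaps with a natural cubic spline", {
  t <- (0:99) / 120
  pd <- 3 + 0.4 * t * 120 / 99          # linear 3.0 -> 3.4
  g <- make_gaze(t, pd)
  expect_equal(preprocess_pupil(g, "left")$pd, pd)   # identity on clean data

  v <- rep(TRUE, 100); v[41:50] <- FALSE              # interior gap
  g2 <- make_gaze(t, pd, v)
  out <- preprocess_pupil(g2, "left")
  expect_equal(out$pd[41:50], pd[41:50], tolerance = 1e-9)  # collinear fill

  # irregular interior gap: match an independently solved spline system
  set.seed(4)
  pd3 <- 3.5 + 0.2 * sin(2 * pi * 0.8 * t) + rnorm(100, 0, 0.01)
  v3 <- rep(TRUE, 100); v3[60:72] <- FALSE
  g3 <- make_gaze(t, pd3, v3)
  out3 <- preprocess_pupil(g3, "left")
  oracle <- oracle_natural_spline(t[v3], pd3[v3], t[!v3])
  expect_equal(out3$pd[!v3], oracle, tolerance = 1e-8)

  # edge gap: nearest-valid-value extension
  v4 <- rep(TRUE, 100); v4[1:6] <- FALSE
  out4 <- preprocess_pupil(make_gaze(t, pd3, v4), "left")
  expect_equal(out4$pd[1:6], rep(pd3[7], 6))

  v5 <- rep(FALSE, 100); v5[1:3] <- TRUE
  expect_error(preprocess_pupil(make_gaze(t, pd3, v5), "left"), "4 valid")
})

test_that("pupil normalization uses the max of the first-5-second window", {
  t <- (0:1199) / 120
  out <- normalize_pupil(data.frame(t = t, pd = rep(4, 1200)))
  expect_equal(attr(out, "baseline"), 4)
  expect_true(all(out$pct_pd == 0))

  pd <- rep(4, 1200); pd[700] <- 4.2
  expect_equal(normalize_pupil(data.frame(t = t, pd = pd))$pct_pd[700], 5)

  # a larger later value must not enter the baseline
  pd2 <- rep(3.0, 1200); pd2[t <= 5] <- 3.5; pd2[900] <- 3.9
  expect_equal(attr(normalize_pupil(data.frame(t = t, pd = pd2)), "baseline"), 3.5)

  expect_error(normalize_pupil(data.frame(t = t, pd = rep(-1, 1200))),
               "nonpositive")
  expect_error(normalize_pupil(data.frame(t = t[1:120], pd = rep(4, 120))),
               "baseline window")
})

test_that("Haar MRA is orthonormal, exactly reconstructing, and matches the recursion", {
  expect_error(haar_mra(rnorm(100), 7), "lower")

  x <- rep(2.5, 256)
  m <- haar_mra(x, 7)
  expect_equal(m$approx, x, tolerance = 1e-12)
  for (d in m$details) expect_lt(max(abs(d)), 1e-12)

  x <- rep(c(1, -1), 64)                     # length 128: all energy level 1
  m <- haar_mra(x, 7)
  expect_lt(max(abs(m$approx)), 1e-12)
  expect_equal(sum(m$details[[1]]^2), sum(x^2), tolerance = 1e-10)

  set.seed(8)
  for (n in c(128, 512, 1024)) {
    x <- rnorm(n)
    m <- haar_mra(x, 7)
    o <- oracle_haar_coefs(x, 7)
    expect_equal(m$approx_coef, o$approx, tolerance = 1e-10)
    for (j in 1:7) expect_equal(m$detail_coefs[[j]], o$details[[j]],
                                tolerance = 1e-10)
    # energy conservation across coefficient domains
    e <- sum(m$approx_coef^2) + sum(vapply(m$detail_coefs,
                                           function(d) sum(d^2), numeric(1)))
    expect_equal(e, sum(x^2), tolerance = 1e-8)
    # level-7 approximation component equals the dyadic block mean
    expect_equal(m$approx, oracle_block_mean(x, 7), tolerance = 1e-10)
  }

  # non-dyadic length: components still sum back to the input exactly
  x <- rnorm(300)
  m <- haar_mra(x, 7)
  expect_equal(m$approx + Reduce(`+`, m$details), x, tolerance = 1e-8)
})

test_that("low-frequency pupil variability matches closed-form limits", {
  t <- (0:7199) / 120
  expect_equal(pd_lowfreq_std(data.frame(t = t, pct_pd = rep(3, 7200))), 0,
               tolerance = 1e-10)

  a <- 5
  np <- data.frame(t = t, pct_pd = a * sin(2 * pi * 0.1 * t))
  expect_equal(pd_lowfreq_std(np), a / sqrt(2), tolerance = 0.05 * a / sqrt(2))

  # |k|-homogeneous, and invariant to adding a constant
  set.seed(2)
  np2 <- data.frame(t = t, pct_pd = rnorm(7200))
  s0 <- pd_lowfreq_std(np2)
  np3 <- np2; np3$pct_pd <- -3 * np2$pct_pd
  expect_equal(pd_lowfreq_std(np3), 3 * s0, tolerance = 1e-10)
  np4 <- np2; np4$pct_pd <- np2$pct_pd + 17
  expect_equal(pd_lowfreq_std(np4), s0, tolerance = 1e-8)
})

test_that("angular velocity follows the spherical angle over the time step", {
  g <- data.frame(t = c(0, 1), dir_x = c(0, 0), dir_y = c(0, 0), dir_z = c(1, 1))
  expect_equal(angular_velocity(g)$velocity, 0)

  th <- 1 * pi / 180
  g2 <- data.frame(t = c(0, 1 / 120), dir_x = c(0, sin(th)), dir_y = 0,
                   dir_z = c(1, cos(th)))
  expect_equal(angular_velocity(g2)$velocity, 120, tolerance = 1e-9)

  g3 <- data.frame(t = c(0, 1), dir_x = c(0, 0), dir_y = 0, dir_z = c(1, -1))
  expect_equal(angular_velocity(g3)$velocity, 180, tolerance = 1e-9)

  g4 <- data.frame(t = c(0, 0), dir_x = 0, dir_y = 0, dir_z = 1)
  expect_error(angular_velocity(g4), "timestamps")
})

test_that("I-VT fixation detection merges sub-threshold runs", {
  t <- (0:1199) / 120
  g <- data.frame(t = t, dir_x = 0, dir_y = 0, dir_z = 1)
  f <- detect_fixations(g)
  expect_equal(nrow(f), 1)
  expect_equal(f$end - f$start, max(t), tolerance = 1e-9)

  # uniform motion at 60 deg/s -> no fixations
  th <- 60 * (pi / 180) * t
  g2 <- data.frame(t = t, dir_x = sin(th), dir_y = 0, dir_z = cos(th))
  expect_equal(nrow(detect_fixations(g2)), 0)

  # five planted plateaus separated by fast saccades
  plate <- function(x0, n) cbind(rep(x0, n))
  xs <- c(rep(0, 100), seq(0, 0.2, length.out = 4), rep(0.2, 100),
          seq(0.2, 0, length.out = 4), rep(0, 100),
          seq(0, -0.2, length.out = 4), rep(-0.2, 100),
          seq(-0.2, 0.1, length.out = 4), rep(0.1, 100))
  tt <- (seq_along(xs) - 1) / 120
  nrm <- sqrt(xs^2 + 1)
  g3 <- data.frame(t = tt, dir_x = xs / nrm, dir_y = 0, dir_z = 1 / nrm)
  f3 <- detect_fixations(g3)
  expect_equal(nrow(f3), 5)
  expect_equal(f3, oracle_fixations(tt, cbind(xs / nrm, 0, 1 / nrm)),
               ignore_attr = TRUE)
})

test_that("fixation statistics follow the defining ratios", {
  f <- structure(data.frame(start = 0, end = 10), class = c("fixation_list", "data.frame"))
  attr(f, "task_duration") <- 10
  s <- fixation_stats(f)
  expect_equal(s$fixation_rate, 0.1)
  expect_equal(s$mean_fixation_duration, 10)

  f2 <- structure(data.frame(start = c(0, 3, 6, 10, 15),
                             end = c(1, 5, 8, 12, 16)),
                  class = c("fixation_list", "data.frame"))
  s2 <- fixation_stats(f2, task_duration = 20)
  expect_equal(s2$fixation_rate, 0.25)
  expect_equal(s2$mean_fixation_duration, 1.6)

  f0 <- structure(data.frame(start = numeric(0), end = numeric(0)),
                  class = c("fixation_list", "data.frame"))
  s0 <- fixation_stats(f0, task_duration = 10)
  expect_equal(s0$fixation_rate, 0)
  expect_true(is.na(s0$mean_fixation_duration))
})

test_that("NNI matches its geometric reference values", {
  # perfect square grid of spacing s: NNI = 2
  gp <- expand.grid(x = (1:10) * 0.3, y = (1:10) * 0.3)
  expect_equal(nni(gp, area = 100 * 0.3^2), 2, tolerance = 1e-10)

  # coincident points with an explicit positive area: 0
  cp <- matrix(0.5, 20, 2)
  expect_equal(nni(cp, area = 1), 0)
  expect_error(nni(cp), "area")

  # uniform random points approach 1
  set.seed(12)
  up <- cbind(runif(2000), runif(2000))
  expect_lt(abs(nni(up, area = 1) - 1), 0.05)

  expect_error(nni(matrix(0, 1, 2)), "2 points")
})

test_that("NNI falls monotonically as planted clustering tightens", {
  set.seed(3)
  z <- matrix(rnorm(2 * 180), ncol = 2)      # cluster shape, reused
  bg <- cbind(runif(40), runif(40))          # fixed scatter sets the area
  vals <- vapply(c(0.2, 0.1, 0.05, 0.02, 0.01), function(s) {
    nni(rbind(bg, 0.5 + s * z), area = 1)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("ocular metrics are invariant to a uniform time shift", {
  d <- tiny_design()
  s <- generate_session(d, effect_profile(), 1, 2)
  m0 <- ocular_metrics(s)
  s2 <- s
  s2$gaze$t <- s2$gaze$t + 250
  m1 <- ocular_metrics(s2)
  expect_equal(m1, m0, tolerance = 1e-9)
})
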