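# Independent oracle implementations used to cross-check the package.
# Each is written as a direct, unoptimised transcription of the defining
# formula and shares no code with the implementation under test.

# --- brute-force per-sample I-VT classifier -------------------------------
oracle_fixations <- function(t, dirs, threshold = 30) {
  n <- length(t)
  lab <- logical(n - 1)
  for (i in seq_len(n - 1)) {
    d <- sum(dirs[i, ] * dirs[i + 1, ])
    d <- max(-1, min(1, d))
    ang <- acos(d) * 180 / pi
    lab[i] <- (ang / (t[i + 1] - t[i])) < threshold
  }
  starts <- c(); ends <- c()
  i <- 1L
  while (i <= n - 1) {
    if (lab[i]) {
      j <- i
      while (j + 1 <= n - 1 && lab[j + 1]) j <- j + 1L
      starts <- c(starts, t[i]); ends <- c(ends, t[j + 1])
      i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(start = as.numeric(starts), end = as.numeric(ends))
}

# random gaze series: plateaus + jumps, arbitrary velocities
random_gaze_series <- function(n = 120, fs = 120) {
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n); y <- numeric(n)
  i <- 1L
  cx <- stats::runif(1, -0.3, 0.3); cy <- stats::runif(1, -0.3, 0.3)
  while (i <= n) {
    k <- sample(1:12, 1)
    idx <- i:min(n, i + k - 1L)
    if (stats::runif(1) < 0.5) {          # plateau with small jitter
      x[idx] <- cx + stats::rnorm(length(idx), 0, 4e-4)
      y[idx] <- cy + stats::rnorm(length(idx), 0, 4e-4)
    } else {                               # drifting sweep
      nx <- stats::runif(1, -0.3, 0.3); ny <- stats::runif(1, -0.3, 0.3)
      w <- seq_along(idx) / length(idx)
      x[idx] <- cx + w * (nx - cx); y[idx] <- cy + w * (ny - cy)
      cx <- nx; cy <- ny
    }
    i <- max(idx) + 1L
  }
  nrm <- sqrt(x^2 + y^2 + 1)
  data.frame(t = t, dir_x = x / nrm, dir_y = y / nrm, dir_z = 1 / nrm)
}

# --- Haar analysis: direct pairwise average/difference recursion ----------
oracle_haar_coefs <- function(x, levels) {
  a <- x
  det <- vector("list", levels)
  for (j in seq_len(levels)) {
    m <- length(a) / 2
    aa <- numeric(m); dd <- numeric(m)
    for (i in seq_len(m)) {
      aa[i] <- (a[2 * i - 1] + a[2 * i]) / sqrt(2)
      dd[i] <- (a[2 * i - 1] - a[2 * i]) / sqrt(2)
    }
    det[[j]] <- dd
    a <- aa
  }
  list(approx = a, details = det)
}

# level-j approximation component on a dyadic grid is the block mean
oracle_block_mean <- function(x, j) {
  b <- 2^j
  m <- matrix(x, nrow = b)
  rep(colMeans(m), each = b)
}

# --- straight-line windowed DFT band power --------------------------------
oracle_band_power <- function(x, fs = 128, window = 256, hop = 16) {
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(window - 1)) / (window - 1))
  U <- sum(w^2)
  half <- window / 2
  kk <- 0:half
  E <- exp(-2i * pi * outer(kk, 0:(window - 1)) / window)  # DFT matrix
  freqs <- kk * fs / window
  bands <- list(theta = c(4, 8), alpha = c(8, 12),
                beta = c(16, 25), gamma = c(25, 45))
  nwin <- (length(x) - window) %/% hop + 1
  out <- matrix(NA_real_, nwin, length(bands),
                dimnames = list(NULL, names(bands)))
  for (m in seq_len(nwin)) {
    seg <- x[((m - 1) * hop + 1):((m - 1) * hop + window)] * w
    X <- as.vector(E %*% seg)
    P <- Mod(X)^2 * 2 / (fs * U)
    P[1] <- P[1] / 2; P[half + 1] <- P[half + 1] / 2
    for (b in names(bands)) {
      sel <- freqs > bands[[b]][1] & freqs <= bands[[b]][2]
      out[m, b] <- mean(P[sel])
    }
  }
  out
}

# --- direct stick-metric formula evaluation -------------------------------
oracle_duty_cycle <- function(t, delta, delta_max, thr = 0.005) {
  n <- length(t)
  num <- 0; den <- 0
  for (i in 2:n) {
    dt <- t[i] - t[i - 1]
    rate <- abs(delta[i] - delta[i - 1]) / dt
    x <- if (rate < thr * 2 * delta_max / dt && abs(delta[i]) < delta_max) 0 else 1
    num <- num + x * dt
    den <- den + dt
  }
  100 * num / den
}

oracle_aggressiveness <- function(t, delta) {
  n <- length(t)
  s <- 0
  for (i in 2:n) s <- s + ((delta[i] - delta[i - 1]) / (t[i] - t[i - 1]))^2
  sqrt(s / (n - 1))
}

# --- design-matrix ANCOVA least squares for rmcorr ------------------------
oracle_rmcorr <- function(subject, x, y) {
  subject <- factor(subject)
  k <- nlevels(subject)
  D <- matrix(0, length(x), k)
  for (j in seq_len(k)) D[subject == levels(subject)[j], j] <- 1
  Xf <- cbind(D, x)
  bf <- qr.solve(Xf, y)
  rss_f <- sum((y - Xf %*% bf)^2)
  br <- qr.solve(D, y)
  rss_r <- sum((y - D %*% br)^2)
  ss_x <- rss_r - rss_f
  df <- length(x) - k - 1
  r <- sign(bf[k + 1]) * sqrt(ss_x / (ss_x + rss_f))
  Fst <- ss_x / (rss_f / df)
  list(r_rm = unname(r), df = df,
       p = stats::pf(Fst, 1, df, lower.tail = FALSE))
}

# --- natural cubic spline via the tridiagonal second-derivative system ----
oracle_natural_spline <- function(xs, ys, xout) {
  n <- length(xs)
  h <- diff(xs)
  A <- matrix(0, n, n); rhs <- numeric(n)
  A[1, 1] <- 1; A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    rhs[i] <- 6 * ((ys[i + 1] - ys[i]) / h[i] - (ys[i] - ys[i - 1]) / h[i - 1])
  }
  M <- solve(A, rhs)
  vapply(xout, function(x0) {
    i <- max(1, min(n - 1, findInterval(x0, xs)))
    a <- (xs[i + 1] - x0) / h[i]; b <- (x0 - xs[i]) / h[i]
    a * ys[i] + b * ys[i + 1] +
      ((a^3 - a) * M[i] + (b^3 - b) * M[i + 1]) * h[i]^2 / 6
  }, numeric(1))
}

# small helper: a quick low-difficulty test design
tiny_design <- function(...) {
  study_design(n_participants = 2, condition_difficulties = c(0.2, 0.8),
               session_duration = 12, seed = 42, ...)
}
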