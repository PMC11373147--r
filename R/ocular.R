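#' @title Ocular cognitive-load metrics
#' @description Pupil preprocessing and normalization, Haar multiresolution
#'   analysis of the normalized pupil signal, I-VT fixation detection and
#'   statistics, and the nearest-neighbour index of gaze dispersion.
#' @name ocular-metrics
NULL

#' Clean a pupil-diameter series by cubic-spline interpolation
#'
#' Samples flagged invalid (blink or tracking loss) are replaced by a
#' natural cubic spline fitted through the valid samples and evaluated on
#' the original timestamp grid. Outside the valid support the nearest valid
#' value is carried (cubic extrapolation of pupil data is unstable).
#'
#' @param g Gaze data frame with columns `t`, `valid` and the pupil column.
#' @param eye `"left"` or `"right"` (columns `pd_left_mm` / `pd_right_mm`).
#' @return Data frame `t`, `pd` on the original grid, all finite.
#' @export
preprocess_pupil <- function(g, eye = c("left", "right")) {
  eye <- match.arg(eye)
  col <- paste0("pd_", eye, "_mm")
  if (!col %in% names(g)) stop("missing column ", col)
  v <- as.logical(g$valid)
  pd <- g[[col]]
  v <- v & is.finite(pd)
  if (sum(v) < 4)
    stop("pupil stream has fewer than 4 valid samples (", col, ")")
  if (all(v)) return(data.frame(t = g$t, pd = pd))
  f <- stats::splinefun(g$t[v], pd[v], method = "natural")
  out <- pd
  out[!v] <- f(g$t[!v])
  lo <- min(g$t[v]); hi <- max(g$t[v])
  out[g$t < lo] <- pd[v][1]
  out[g$t > hi] <- pd[v][sum(v)]
  data.frame(t = g$t, pd = out)
}

#' Normalize a pupil series against its resting baseline
#'
#' The baseline is the maximum pupil diameter over the first
#' `baseline_window` seconds (the participant's relaxed reference segment);
#' every sample is expressed as percent change from that baseline:
#' `pct = (pd - baseline) / baseline * 100`.
#'
#' @param pd Data frame `t`, `pd` (output of [preprocess_pupil()]).
#' @param baseline_window Reference window length in seconds (default 5).
#' @return Data frame `t`, `pct_pd`, with attributes `baseline` (mm) and
#'   `baseline_window`.
#' @export
normalize_pupil <- function(pd, baseline_window = 5) {
  t0 <- pd$t[1]
  if (max(pd$t) - t0 <= baseline_window)
    stop("series not longer than the baseline window")
  base <- max(pd$pd[pd$t <= t0 + baseline_window])
  if (!is.finite(base) || base <= 0)
    stop("nonpositive pupil baseline is physically impossible")
  out <- data.frame(t = pd$t, pct_pd = (pd$pd - base) / base * 100)
  attr(out, "baseline") <- base
  attr(out, "baseline_window") <- baseline_window
  out
}

#' Haar multiresolution analysis
#'
#' Orthonormal Haar discrete wavelet analysis to `levels` depth, with each
#' coefficient band reconstructed back onto the original sampling grid
#' (multiresolution components). Non-dyadic lengths are handled by
#' symmetric (reflection) extension at the tail up to the next multiple of
#' `2^levels`; components are truncated back to the input length, so the
#' approximation plus all detail components reproduce the input exactly.
#'
#' @param x Numeric series, length at least `2^levels`.
#' @param levels Decomposition depth (default 7).
#' @return An object of class `haar_mra`: `approx` and `details` (list,
#'   level 1 = finest) as full-length components, plus the raw
#'   `approx_coef` / `detail_coefs` in the downsampled coefficient domain.
#' @export
haar_mra <- function(x, levels = 7L) {
  n <- length(x)
  if (n < 2^levels)
    stop("series of length ", n, " is shorter than 2^levels = ", 2^levels,
         "; lower `levels`")
  block <- 2^levels
  N <- ceiling(n / block) * block
  xx <- if (N > n) c(x, rev(x)[seq_len(N - n)]) else x

  a <- xx
  dets <- vector("list", levels)
  for (j in seq_len(levels)) {
    odd <- a[seq(1, length(a), 2)]
    even <- a[seq(2, length(a), 2)]
    dets[[j]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }

  inv_step <- function(ap, de) {
    out <- numeric(2 * length(ap))
    out[seq(1, length(out), 2)] <- (ap + de) / sqrt(2)
    out[seq(2, length(out), 2)] <- (ap - de) / sqrt(2)
    out
  }
  # detail component at level j: invert with only d_j non-zero
  details <- lapply(seq_len(levels), function(j) {
    v <- inv_step(numeric(length(dets[[j]])), dets[[j]])
    for (k in seq_len(j - 1L)) v <- inv_step(v, numeric(length(v)))
    v[seq_len(n)]
  })
  v <- a
  for (k in seq_len(levels)) v <- inv_step(v, numeric(length(v)))
  approx <- v[seq_len(n)]

  structure(list(approx = approx, details = details,
                 approx_coef = a, detail_coefs = dets,
                 wavelet = "haar", levels = as.integer(levels),
                 n = n, padded_n = N),
            class = "haar_mra")
}

#' Low-frequency pupil-diameter variability
#'
#' Standard deviation (sample, N-1 denominator) of the level-`levels` Haar
#' approximation of the normalized pupil series. At 120 Hz with 7 levels
#' the approximation band is 0 to 120 / 2^8 = 0.469 Hz, isolating the slow
#' pupil drift that tracks cognitive load.
#'
#' @param np Normalized pupil data frame (`t`, `pct_pd`) from
#'   [normalize_pupil()], or any data frame with a `pct_pd` column.
#' @param levels Wavelet depth (default 7).
#' @param on `"reconstruction"` (default; the full-length approximation
#'   component) or `"coefficients"` (the downsampled level-7 coefficients).
#' @return Scalar standard deviation in percent-PD units.
#' @export
pd_lowfreq_std <- function(np, levels = 7L,
                           on = c("reconstruction", "coefficients")) {
  on <- match.arg(on)
  x <- np$pct_pd
  if (length(x) < max(2, 2^levels)) stop("series too short for pd_lowfreq_std")
  m <- haar_mra(x, levels)
  y <- if (on == "reconstruction") m$approx else m$approx_coef
  stats::sd(y)
}

#' Angular gaze velocity between consecutive samples
#'
#' The angle between consecutive gaze direction unit vectors divided by the
#' time increment, in degrees per second.
#'
#' @param g Gaze data frame with `t`, `dir_x`, `dir_y`, `dir_z`.
#' @return Data frame `t` (interval end time), `velocity` (deg/s), with
#'   `n - 1` rows.
#' @export
angular_velocity <- function(g) {
  n <- nrow(g)
  if (n < 2) stop("need at least 2 samples")
  dt <- diff(g$t)
  if (any(dt <= 0)) stop("duplicate or non-increasing timestamps")
  d1 <- cbind(g$dir_x, g$dir_y, g$dir_z)
  dot <- rowSums(d1[-n, , drop = FALSE] * d1[-1, , drop = FALSE])
  dot <- pmin(1, pmax(-1, dot))
  ang <- acos(dot) * 180 / pi
  data.frame(t = g$t[-1], velocity = ang / dt)
}

#' I-VT fixation detection
#'
#' Velocity-threshold identification: an inter-sample interval whose
#' angular velocity is below `threshold` belongs to a fixation; maximal
#' runs of sub-threshold intervals are merged into single fixation events
#' (successive fixations count as one). Only originally-valid samples enter
#' the velocity computation; invalid samples are dropped and the velocity
#' is evaluated across the resulting gap with its true time increment.
#'
#' @param g Gaze data frame (`t`, `dir_x`, `dir_y`, `dir_z`, optionally
#'   `valid`).
#' @param threshold Velocity threshold in deg/s (default 30).
#' @return An object of class `fixation_list`: data frame `start`, `end`
#'   (seconds), with attributes `threshold` and `task_duration`.
#' @export
detect_fixations <- function(g, threshold = 30) {
  if (!is.null(g$valid)) g <- g[as.logical(g$valid), , drop = FALSE]
  task_dur <- if (nrow(g) >= 2) max(g$t) - min(g$t) else 0
  empty <- function() {
    out <- data.frame(start = numeric(0), end = numeric(0))
    attr(out, "threshold") <- threshold
    attr(out, "task_duration") <- task_dur
    class(out) <- c("fixation_list", "data.frame")
    out
  }
  if (nrow(g) < 2) return(empty())
  v <- angular_velocity(g)
  fix <- v$velocity < threshold
  if (!any(fix)) return(empty())
  r <- rle(fix)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(start = g$t[starts[keep]],
                    end = g$t[ends[keep] + 1L])
  attr(out, "threshold") <- threshold
  attr(out, "task_duration") <- task_dur
  class(out) <- c("fixation_list", "data.frame")
  out
}

#' Fixation rate and mean fixation duration
#'
#' Fixation rate is the number of fixations divided by the task duration;
#' mean fixation duration is the summed fixation time divided by the number
#' of fixations. With zero fixations the rate is 0 and the mean duration is
#' flagged missing (`NA`), to be excluded from correlations.
#'
#' @param f A `fixation_list` from [detect_fixations()].
#' @param task_duration Override for the task duration in seconds
#'   (defaults to the attribute recorded at detection time).
#' @return List `fixation_rate` (1/s) and `mean_fixation_duration` (s).
#' @export
fixation_stats <- function(f, task_duration = attr(f, "task_duration")) {
  if (is.null(task_duration) || task_duration <= 0)
    stop("task_duration must be positive")
  n <- nrow(f)
  if (n == 0) return(list(fixation_rate = 0, mean_fixation_duration = NA_real_))
  list(fixation_rate = n / task_duration,
       mean_fixation_duration = sum(f$end - f$start) / n)
}

#' Project gaze directions onto the unit-forward plane
#'
#' Maps each gaze direction to planar coordinates (x/z, y/z); requires a
#' forward-pointing (z > 0) direction.
#'
#' @param g Gaze data frame with `dir_x`, `dir_y`, `dir_z` (and optionally
#'   `valid`, honoured).
#' @return Two-column matrix of planar gaze points.
#' @export
gaze_points <- function(g) {
  if (!is.null(g$valid)) g <- g[as.logical(g$valid), , drop = FALSE]
  if (any(g$dir_z <= 0)) stop("gaze projection requires forward (z > 0) directions")
  cbind(x = g$dir_x / g$dir_z, y = g$dir_y / g$dir_z)
}

#' Fixation centroids in the projected gaze plane
#'
#' @param g Gaze data frame.
#' @param f A `fixation_list`; defaults to running [detect_fixations()].
#' @return Two-column matrix, one centroid per fixation.
#' @export
fixation_centroids <- function(g, f = detect_fixations(g)) {
  if (!is.null(g$valid)) g <- g[as.logical(g$valid), , drop = FALSE]
  p <- gaze_points(g)
  t(vapply(seq_len(nrow(f)), function(i) {
    idx <- g$t >= f$start[i] & g$t <= f$end[i]
    colMeans(p[idx, , drop = FALSE])
  }, numeric(2)))
}

#' Nearest-neighbour index of a planar point pattern
#'
#' Ratio of the observed mean nearest-neighbour distance to the expected
#' mean under complete spatial randomness over the same area
#' (Clark-Evans expectation `0.5 * sqrt(area / n)`). Values near 1 indicate
#' random scanning; lower values indicate clustered scanning.
#'
#' @param points Two-column matrix or data frame of planar coordinates.
#' @param area Reference area; defaults to the bounding-box area of the
#'   points. A zero default area (all points coincident) is an error;
#'   supply a positive `area` explicitly in that case.
#' @return Scalar NNI.
#' @export
nni <- function(points, area = NULL) {
  p <- as.matrix(points)
  n <- nrow(p)
  if (n < 2) stop("NNI needs at least 2 points")
  if (is.null(area))
    area <- diff(range(p[, 1])) * diff(range(p[, 2]))
  if (!is.finite(area) || area <= 0)
    stop("reference area must be positive (coincident-only points?)")
  dm <- as.matrix(stats::dist(p))
  diag(dm) <- Inf
  mean_nnd <- mean(apply(dm, 1, min))
  mean_nnd / (0.5 * sqrt(area / n))
}

#' All ocular metrics for one session
#'
#' @param session A `session_data` list (or any list with a `gaze` data
#'   frame).
#' @param threshold I-VT velocity threshold, deg/s.
#' @param nni_points `"centroids"` (default; fixation centroids) or
#'   `"samples"` (raw projected samples).
#' @return Named list: `stddev_pd_left`, `stddev_pd_right`,
#'   `fixation_rate`, `mean_fixation_duration`, `nni`.
#' @export
ocular_metrics <- function(session, threshold = 30,
                           nni_points = c("centroids", "samples")) {
  nni_points <- match.arg(nni_points)
  g <- session$gaze
  std <- function(eye) {
    pd_lowfreq_std(normalize_pupil(preprocess_pupil(g, eye)))
  }
  f <- detect_fixations(g, threshold)
  fs <- fixation_stats(f)
  pts <- if (nni_points == "centroids") fixation_centroids(g, f) else gaze_points(g)
  nni_val <- if (nrow(pts) >= 2) nni(pts) else NA_real_
  list(stddev_pd_left = std("left"),
       stddev_pd_right = std("right"),
       fixation_rate = fs$fixation_rate,
       mean_fixation_duration = fs$mean_fixation_duration,
       nni = nni_val)
}
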