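#' @title EEG band power and workload indices
#' @description Sliding Hann-window FFT band powers per electrode, the
#'   frontal-theta / parietal-alpha task-load index (TLI) and the
#'   beta / (alpha + theta) task-engagement index (TEI).
#' @name eeg-metrics
NULL

#' Canonical EEG frequency bands
#'
#' theta 4--8 Hz, alpha 8--12 Hz, beta 16--25 Hz, gamma 25--45 Hz. The
#' 12--16 Hz gap between alpha and beta is deliberate and is not filled.
#' Band membership of a frequency bin uses half-open intervals (lo, hi] so
#' no bin is double-counted at a shared edge.
#'
#' @return Named list of `c(lo, hi)` pairs in Hz.
#' @export
eeg_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 12), beta = c(16, 25), gamma = c(25, 45))
}

#' Electrode montages for the workload indices
#'
#' The task-load index uses theta power over 11 anterior-frontal/frontal
#' electrodes against alpha power over 5 parietal electrodes. Five
#' task-engagement montages from the literature are provided; the frontal
#' F3/F4/F7/F8 set is the default.
#'
#' @return List with `tli_theta`, `tli_alpha` and `tei` (named list of the
#'   five montages).
#' @export
index_montage <- function() {
  list(
    tli_theta = .FRONTAL_THETA_SET,
    tli_alpha = .PARIETAL_ALPHA_SET,
    tei = list(
      frontal_f = c("F3", "F4", "F7", "F8"),
      parietal_cz = c("Pz", "P3", "P4", "Cz"),
      parietal_frontal_c3 = c("Pz", "P3", "Fz", "C3"),
      fp1 = "Fp1",
      parietal_frontal_c4 = c("Pz", "P4", "Fz", "C4")
    )
  )
}

#' Sliding-window band power from raw EEG
#'
#' For every window position: Hann taper, FFT, one-sided power spectral
#' density in signal-units^2/Hz (window-power compensated), then the mean
#' density over each band's frequency bins. Windows of 256 samples slide by
#' 16 samples, matching a 128 Hz acquisition.
#'
#' @param eeg Data frame: column `t` (seconds, 128 Hz) plus one numeric
#'   column per electrode (microvolts).
#' @param fs Sampling rate; must be 128 Hz (the band-bin mapping is fixed).
#' @param window,hop Window and hop sizes in samples.
#' @param channels Electrode subset (default: every non-`t` column).
#' @return Object of class `band_power_series`: `power` array of dimension
#'   windows x electrodes x bands (uV^2/Hz), `window_start` (s), plus the
#'   window parameters.
#' @export
band_power <- function(eeg, fs = 128, window = 256L, hop = 16L,
                       channels = NULL) {
  if (!"t" %in% names(eeg)) stop("EEG table needs a `t` column")
  chans <- channels %||% setdiff(names(eeg), "t")
  miss <- setdiff(chans, names(eeg))
  if (length(miss)) stop("missing EEG channel(s): ", paste(miss, collapse = ", "))
  dt <- stats::median(diff(eeg$t))
  if (abs(dt - 1 / fs) > 1e-6)
    stop("sampling rate is not ", fs, " Hz (median dt = ", signif(dt, 4), " s)")
  n <- nrow(eeg)
  if (n < window) stop("every channel needs at least ", window, " samples")
  k <- (n - window) %/% hop + 1L
  starts <- (seq_len(k) - 1L) * hop
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(window - 1)) / (window - 1))
  U <- sum(w^2)
  half <- window %/% 2L
  freqs <- (0:half) * fs / window
  bands <- eeg_bands()
  masks <- lapply(bands, function(b) freqs > b[1] & freqs <= b[2])
  idx <- outer(seq_len(window), starts, "+")
  pow <- array(NA_real_, dim = c(k, length(chans), length(bands)),
               dimnames = list(NULL, chans, names(bands)))
  for (ch in chans) {
    X <- matrix(eeg[[ch]][idx], nrow = window) * w
    Fm <- stats::mvfft(X)
    P <- Mod(Fm[1:(half + 1L), , drop = FALSE])^2 * (2 / (fs * U))
    P[1L, ] <- P[1L, ] / 2
    P[half + 1L, ] <- P[half + 1L, ] / 2
    for (b in names(bands))
      pow[, ch, b] <- colMeans(P[masks[[b]], , drop = FALSE])
  }
  structure(list(power = pow, window_start = eeg$t[starts + 1L],
                 window = window, hop = hop, fs = fs, bands = bands),
            class = "band_power_series")
}

# mean band power over an electrode set, per window
.montage_mean <- function(bp, electrodes, band) {
  miss <- setdiff(electrodes, dimnames(bp$power)[[2]])
  if (length(miss))
    stop("montage electrode(s) absent from band powers: ",
         paste(miss, collapse = ", "))
  m <- bp$power[, electrodes, band, drop = FALSE]
  rowMeans(matrix(m, nrow = dim(bp$power)[1]))
}

#' EEG task-load index
#'
#' Per window: mean theta power over the 11 frontal electrodes divided by
#' mean alpha power over the 5 parietal electrodes ("power of the
#' electrodes" is aggregated as the arithmetic mean across electrodes, so
#' the index is montage-size invariant). The session value is the mean of
#' the per-window ratios; windows with a zero denominator are dropped and
#' counted.
#'
#' @param bp A `band_power_series`.
#' @param montage Montage list from [index_montage()].
#' @param session_stat `"mean_of_ratios"` (default) or `"ratio_of_means"`.
#' @return List: `session` (scalar TLI), `series` (per-window TLI),
#'   `window_start`, `dropped` (zero-denominator window count).
#' @export
tli <- function(bp, montage = index_montage(),
                session_stat = c("mean_of_ratios", "ratio_of_means")) {
  session_stat <- match.arg(session_stat)
  th <- .montage_mean(bp, montage$tli_theta, "theta")
  al <- .montage_mean(bp, montage$tli_alpha, "alpha")
  ok <- is.finite(th) & is.finite(al) & al > 0
  series <- ifelse(ok, th / al, NA_real_)
  session <- if (session_stat == "mean_of_ratios") mean(series[ok])
  else sum(th[ok]) / sum(al[ok])
  list(session = session, series = series,
       window_start = bp$window_start, dropped = sum(!ok))
}

#' EEG task-engagement index
#'
#' Per window: montage-averaged beta power divided by the sum of
#' montage-averaged alpha and theta power. Session value is the mean of the
#' per-window ratios (zero-denominator windows dropped and counted).
#'
#' @param bp A `band_power_series`.
#' @param montage Electrode set, or the name of one of the five literature
#'   montages in `index_montage()$tei` (default the frontal F3/F4/F7/F8
#'   set).
#' @param session_stat `"mean_of_ratios"` (default) or `"ratio_of_means"`.
#' @return List: `session`, `series`, `window_start`, `dropped`, `montage`.
#' @export
tei <- function(bp, montage = "frontal_f",
                session_stat = c("mean_of_ratios", "ratio_of_means")) {
  session_stat <- match.arg(session_stat)
  if (is.character(montage) && length(montage) == 1 &&
      montage %in% names(index_montage()$tei))
    montage <- index_montage()$tei[[montage]]
  be <- .montage_mean(bp, montage, "beta")
  al <- .montage_mean(bp, montage, "alpha")
  th <- .montage_mean(bp, montage, "theta")
  den <- al + th
  ok <- is.finite(be) & is.finite(den) & den > 0
  series <- ifelse(ok, be / den, NA_real_)
  session <- if (session_stat == "mean_of_ratios") mean(series[ok])
  else sum(be[ok]) / sum(den[ok])
  list(session = session, series = series,
       window_start = bp$window_start, dropped = sum(!ok),
       montage = montage)
}

#' Optional zero-phase band-pass for non-preprocessed EEG
#'
#' Forward/backward FFT-mask filter keeping `c(lo, hi)` Hz; headset-side
#' filtering (0.2--45 Hz, notch) is normally assumed already applied, so
#' this is off the default path.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param band `c(lo, hi)` pass band in Hz.
#' @return Filtered signal, same length.
#' @export
eeg_bandpass <- function(x, fs, band = c(0.2, 45)) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  X[f < band[1] | f > band[2]] <- 0+0i
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' EEG metrics for one session
#'
#' @param session A `session_data` list (or any list with an `eeg` data
#'   frame).
#' @param tei_montage TEI montage name or electrode vector.
#' @return Named list `tli`, `tei`, `tei_montage`.
#' @export
eeg_metrics <- function(session, tei_montage = "frontal_f") {
  bp <- band_power(session$eeg)
  t_ <- tli(bp)
  e_ <- tei(bp, tei_montage)
  list(tli = t_$session, tei = e_$session,
       tei_montage = paste(e_$montage, collapse = "+"))
}
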