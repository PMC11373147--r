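#' @title Synthetic session and study generation
#' @description Seeded generators for the gaze/pupil, raw-EEG and inceptor
#'   streams of one simulated flight-task session, structured so that every
#'   downstream metric recovers the planted difficulty effects.
#' @name synthetic-data
NULL

# 32-electrode saline headset layout (10-20 names); contains every montage
# electrode required by the task-load and task-engagement indices.
.ELECTRODES <- c("Fp1", "Fp2", "Fz", "F3", "F4", "F7", "F8",
                 "FC1", "FC2", "FC5", "FC6",
                 "Cz", "C3", "C4", "T7", "T8",
                 "CP1", "CP2", "CP5", "CP6",
                 "Pz", "P3", "P4", "P7", "P8",
                 "PO3", "PO4", "PO7", "PO8",
                 "O1", "O2", "Oz")

.FRONTAL_THETA_SET <- c("Fz", "Fp1", "Fp2", "F3", "F4", "F7", "F8",
                        "FC1", "FC2", "FC5", "FC6")
.PARIETAL_ALPHA_SET <- c("P7", "P3", "Pz", "P4", "P8")
.TEI_DEFAULT_SET <- c("F3", "F4", "F7", "F8")

#' Electrode names of the synthetic EEG layout
#' @return Character vector of 32 electrode names.
#' @export
eeg_electrodes <- function() .ELECTRODES

# Deterministic per-(participant, condition) sub-seed below 2^31.
sub_seed <- function(seed, participant, condition) {
  as.integer((abs(as.numeric(seed)) %% 65536) * 20011 +
               participant * 1013 + condition * 131 + 17) %% 2147483647L
}

# Per-participant random effects, constant across that participant's
# conditions: standard-normal draws per channel, scaled by participant_sd
# at the point of use. Keyed only by (master seed, participant).
participant_effects <- function(design, participant) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(design$seed, participant, 0L))
  z <- stats::rnorm(6)
  list(pd = z[1], fixation = z[2], gaze = z[3],
       eeg_theta = z[4], eeg_alpha = z[5], stick = z[6])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Band-limited Gaussian noise with unit sample variance via FFT masking:
# white noise -> keep DFT bins inside [f_lo, f_hi] -> inverse -> rescale.
band_noise <- function(n, fs, f_lo, f_hi) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  X[f < f_lo | f > f_hi] <- 0+0i
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

#' Generate one synthetic session
#'
#' Produces the three per-session data streams on independent clocks sharing
#' t = 0: a gaze/pupil stream (fixation plateaus alternating with
#' supra-threshold saccades, slow difficulty-scaled pupil drift, blink
#' gaps), a 32-electrode raw EEG stream (band-limited noise per canonical
#' band with montage-specific difficulty gains), and an inceptor stream
#' (difficulty-scaled deflection bursts). The first 5 seconds of every
#' stream form a quiet resting baseline.
#'
#' @param design A [study_design()].
#' @param effects An [effect_profile()].
#' @param participant Participant index (1-based).
#' @param condition Condition index (1-based).
#' @param seed Optional integer overriding the seed derived from
#'   `design$seed`; the same arguments always yield identical output.
#' @return A list of class `session_data` with elements `gaze`, `eeg`,
#'   `stick` (data frames), identifiers, `difficulty`, `delta_max`, and a
#'   `planted` list of generator internals (plateau count, mean plateau
#'   duration, drift amplitude, burst rate/amplitude, band multipliers,
#'   focus probability) used by recovery tests.
#' @export
generate_session <- function(design, effects, participant, condition,
                             seed = NULL) {
  stopifnot(inherits(design, "study_design"), inherits(effects, "effect_profile"))
  if (participant < 1 || participant > design$n_participants)
    stop("participant index out of range")
  if (condition < 1 || condition > design$n_conditions)
    stop("condition index out of range")
  if (design$session_duration <= design$baseline_window)
    stop("session shorter than one baseline window")
  d <- design$condition_difficulties[condition]
  pe <- participant_effects(design, participant)
  if (is.null(seed)) seed <- sub_seed(design$seed, participant, condition)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  dur <- design$session_duration
  base_win <- design$baseline_window
  psd <- effects$participant_sd

  ## ---- gaze / pupil stream (eye_rate Hz) ----
  dt_eye <- 1 / design$eye_rate
  t_eye <- seq(0, dur - dt_eye, by = dt_eye)
  n_eye <- length(t_eye)

  mean_plateau <- max(0.12, effects$fixation_duration_base +
                        effects$fixation_duration_slope * d +
                        0.05 * psd * pe$fixation)
  focus_p <- min(0.95, max(0.05, effects$gaze_focus_base -
                             effects$gaze_dispersion_slope * d +
                             0.05 * psd * pe$gaze))
  focus_center <- c(0.02, -0.01)      # on-target cluster in the gaze plane
  sd_focus <- 0.02
  sd_scan <- 0.25

  draw_target <- function(cur) {
    repeat {
      p <- if (stats::runif(1) < focus_p)
        focus_center + stats::rnorm(2, 0, sd_focus)
      else stats::rnorm(2, 0, sd_scan)
      if (sqrt(sum((p - cur)^2)) >= 0.035) return(p)  # >= ~2 deg saccade
    }
  }

  sacc_samp <- 3L                      # 25 ms saccades at 120 Hz
  # plateau schedule: baseline plateau then alternating saccade/plateau
  seg_type <- character(0); seg_len <- integer(0)
  tgt_x <- numeric(0); tgt_y <- numeric(0)
  cur <- c(0, 0)
  i <- round(base_win / dt_eye)
  seg_type <- "plateau"; seg_len <- i; tgt_x <- cur[1]; tgt_y <- cur[2]
  while (i < n_eye) {
    nxt <- draw_target(cur)
    k <- min(sacc_samp, n_eye - i)
    seg_type <- c(seg_type, "saccade"); seg_len <- c(seg_len, k)
    tgt_x <- c(tgt_x, nxt[1]); tgt_y <- c(tgt_y, nxt[2])
    i <- i + k
    if (i >= n_eye) break
    pl <- max(0.08, stats::rnorm(1, mean_plateau, 0.08))
    k <- min(max(2L, round(pl / dt_eye)), n_eye - i)
    seg_type <- c(seg_type, "plateau"); seg_len <- c(seg_len, k)
    tgt_x <- c(tgt_x, nxt[1]); tgt_y <- c(tgt_y, nxt[2])
    i <- i + k
    cur <- nxt
  }
  n_seg <- length(seg_type)
  gx <- numeric(n_eye); gy <- numeric(n_eye)
  pos <- 1L
  prev <- c(tgt_x[1], tgt_y[1])
  for (s in seq_len(n_seg)) {
    k <- seg_len[s]
    idx <- pos:(pos + k - 1L)
    if (seg_type[s] == "plateau") {
      gx[idx] <- tgt_x[s]; gy[idx] <- tgt_y[s]
      prev <- c(tgt_x[s], tgt_y[s])
    } else {
      w <- seq_len(k) / (k + 1)        # linear sweep, endpoints excluded
      gx[idx] <- prev[1] + w * (tgt_x[s] - prev[1])
      gy[idx] <- prev[2] + w * (tgt_y[s] - prev[2])
      prev <- c(tgt_x[s], tgt_y[s])
    }
    pos <- pos + k
  }
  # fixational tremor, kept far below the 30 deg/s I-VT threshold
  gx <- gx + stats::rnorm(n_eye, 0, 3e-4)
  gy <- gy + stats::rnorm(n_eye, 0, 3e-4)
  nrm <- sqrt(gx^2 + gy^2 + 1)
  dir_x <- gx / nrm; dir_y <- gy / nrm; dir_z <- 1 / nrm

  plateau_starts <- cumsum(c(1L, seg_len))[seq_len(n_seg)][seg_type == "plateau"]
  plateau_lens <- seg_len[seg_type == "plateau"]

  ## pupil diameter: baseline + slow drift (after baseline) + hippus + noise
  pd_base <- effects$pd_baseline_mm * (1 + 0.08 * psd * pe$pd)
  drift_amp <- effects$pd_drift_gain * d * (1 + 0.3 * psd * pe$pd)
  ph <- stats::runif(2, 0, 2 * pi)
  drift <- drift_amp * (0.6 * sin(2 * pi * 0.05 * t_eye + ph[1]) +
                          0.4 * sin(2 * pi * 0.12 * t_eye + ph[2]))
  env <- pmin(1, pmax(0, (t_eye - base_win) / 2))   # 2 s ramp after baseline
  hip_l <- effects$pd_hippus_amp * band_noise(n_eye, design$eye_rate, 0.3, 1.0)
  hip_r <- effects$pd_hippus_amp * band_noise(n_eye, design$eye_rate, 0.3, 1.0)
  pd_left <- pd_base + env * drift + hip_l + stats::rnorm(n_eye, 0, effects$pd_noise_sd)
  pd_right <- pd_base * 0.98 + env * drift + hip_r +
    stats::rnorm(n_eye, 0, effects$pd_noise_sd)

  ## blinks: Poisson count over the task segment, each gap placed wholly
  ## inside one post-baseline fixation plateau (never across a saccade)
  valid <- rep(TRUE, n_eye)
  n_blinks <- stats::rpois(1, effects$blink_rate * (dur - base_win))
  task_plat <- which(plateau_starts > base_win / dt_eye)
  for (b in seq_len(n_blinks)) {
    gap <- round(stats::runif(1, 0.1, 0.4) / dt_eye)
    ok <- task_plat[plateau_lens[task_plat] > gap + 4L]
    if (!length(ok)) next
    s <- if (length(ok) == 1L) ok else sample(ok, 1)
    off <- sample.int(plateau_lens[s] - gap - 2L, 1)
    i0 <- plateau_starts[s] + off
    valid[i0:(i0 + gap - 1L)] <- FALSE
  }

  gaze <- data.frame(t = t_eye, dir_x = dir_x, dir_y = dir_y, dir_z = dir_z,
                     pd_left_mm = pd_left, pd_right_mm = pd_right,
                     valid = valid)

  ## ---- raw EEG stream (eeg_rate Hz, 32 electrodes) ----
  dt_eeg <- 1 / design$eeg_rate
  t_eeg <- seq(0, dur - dt_eeg, by = dt_eeg)
  n_eeg <- length(t_eeg)
  bands <- list(theta = c(4, 8), alpha = c(8, 12),
                beta = c(16, 25), gamma = c(25, 45))
  base_amp <- c(theta = 4, alpha = 5, beta = 2.5, gamma = 1)  # uV scale
  th_mult <- (1 + effects$frontal_theta_gain * d) *
    (1 + 0.3 * psd * pe$eeg_theta)
  al_mult <- (1 + effects$parietal_alpha_gain * d) *
    (1 + 0.3 * psd * pe$eeg_alpha)
  be_mult <- 1 + effects$beta_gain * d
  env_eeg <- pmin(1, pmax(0, (t_eeg - base_win) / 1))  # 1 s ramp
  eeg <- matrix(0, n_eeg, length(.ELECTRODES),
                dimnames = list(NULL, .ELECTRODES))
  for (el in .ELECTRODES) {
    sig <- numeric(n_eeg)
    for (b in names(bands)) {
      x <- band_noise(n_eeg, design$eeg_rate, bands[[b]][1], bands[[b]][2])
      mult <- 1
      if (b == "theta" && el %in% .FRONTAL_THETA_SET) mult <- th_mult
      if (b == "alpha" && el %in% .PARIETAL_ALPHA_SET) mult <- al_mult
      if (b == "beta" && el %in% .FRONTAL_THETA_SET) mult <- be_mult
      amp <- base_amp[[b]] * (1 + env_eeg * (sqrt(mult) - 1))
      sig <- sig + amp * x
    }
    eeg[, el] <- sig
  }
  eeg <- data.frame(t = t_eeg, eeg, check.names = FALSE)

  ## ---- inceptor stream (stick_rate Hz) ----
  dt_st <- 1 / design$stick_rate
  t_st <- seq(0, dur - dt_st, by = dt_st)
  n_st <- length(t_st)
  burst_rate <- effects$stick_burst_rate_base + effects$stick_burst_rate_gain * d
  burst_amp <- (effects$stick_amplitude_base + effects$stick_amplitude_gain * d) *
    (1 + 0.2 * psd * pe$stick)
  delta <- numeric(n_st)
  # jittered-regular burst arrivals: count is near-deterministic in the rate
  tt <- base_win + stats::runif(1, 0, 1 / burst_rate)
  n_bursts <- 0L
  while (tt < dur) {
    w <- stats::runif(1, 0.4, 1.0)                 # burst width, s
    a <- burst_amp * stats::runif(1, 0.6, 1.0) *
      sample(c(-1, 1), 1)
    idx <- which(t_st >= tt & t_st <= tt + w)
    if (length(idx) > 1) {
      ph2 <- (t_st[idx] - tt) / w
      delta[idx] <- delta[idx] + a * sin(pi * ph2)^2
      n_bursts <- n_bursts + 1L
    }
    tt <- tt + (1 / burst_rate) * stats::runif(1, 0.8, 1.2)
  }
  delta <- delta + stats::rnorm(n_st, 0, 0.01)     # sub-threshold sensor noise
  delta[t_st < base_win] <- stats::rnorm(sum(t_st < base_win), 0, 0.005)
  delta <- pmin(pmax(delta, -effects$delta_max), effects$delta_max)
  stick <- data.frame(t = t_st, delta_deg = delta)

  structure(list(
    gaze = gaze, eeg = eeg, stick = stick,
    participant = as.integer(participant), condition = as.integer(condition),
    difficulty = d, delta_max = effects$delta_max,
    planted = list(
      n_plateaus = sum(seg_type == "plateau"),
      mean_plateau_s = mean_plateau,
      pd_drift_amp_mm = drift_amp,
      focus_prob = focus_p,
      theta_mult = th_mult, alpha_mult = al_mult, beta_mult = be_mult,
      burst_rate_hz = burst_rate, burst_amp_deg = burst_amp,
      n_bursts = n_bursts,
      blink_rate_hz = effects$blink_rate
    )
  ), class = "session_data")
}

#' Generate a full synthetic study
#'
#' Runs [generate_session()] for every participant-by-condition cell.
#' Per-participant random effects are keyed only to (master seed,
#' participant) and are therefore identical across that participant's
#' conditions. A per-participant random presentation order is drawn (order
#' effect nullification) and recorded in each session's `presentation_order`
#' field; it does not alter the generated signals.
#'
#' @param design A [study_design()].
#' @param effects An [effect_profile()].
#' @return A list of class `study_data`: `sessions` (list of
#'   `session_data`, length participants x conditions), plus the design and
#'   effects used.
#' @export
generate_study <- function(design, effects = effect_profile()) {
  stopifnot(inherits(design, "study_design"))
  sessions <- vector("list", design$n_participants * design$n_conditions)
  k <- 0L
  for (p in seq_len(design$n_participants)) {
    old <- .Random.seed_save()
    set.seed(sub_seed(design$seed, p, 9999L))
    ord <- sample(design$n_conditions)
    .Random.seed_restore(old)
    for (cc in seq_len(design$n_conditions)) {
      k <- k + 1L
      s <- generate_session(design, effects, p, cc)
      s$presentation_order <- match(cc, ord)
      sessions[[k]] <- s
    }
  }
  structure(list(sessions = sessions, design = design, effects = effects),
            class = "study_data")
}

#' Write one session's streams as CSV files
#'
#' Writes `gaze_{p}_{c}.csv`, `eeg_{p}_{c}.csv` and `stick_{p}_{c}.csv` into
#' `dir`.
#'
#' @param session A `session_data` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_session_csv <- function(session, dir) {
  stopifnot(inherits(session, "session_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tag <- sprintf("%d_%d", session$participant, session$condition)
  paths <- file.path(dir, paste0(c("gaze_", "eeg_", "stick_"), tag, ".csv"))
  utils::write.csv(session$gaze, paths[1], row.names = FALSE)
  utils::write.csv(session$eeg, paths[2], row.names = FALSE)
  utils::write.csv(session$stick, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Write a study to disk (CSV streams + JSON manifest)
#'
#' @param study A `study_data` object.
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_study_csv <- function(study, dir) {
  stopifnot(inherits(study, "study_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- lapply(study$sessions, function(s) {
    write_session_csv(s, dir)
    list(participant = s$participant, condition = s$condition,
         difficulty = s$difficulty, delta_max = s$delta_max,
         presentation_order = s$presentation_order %||% NA_integer_)
  })
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(seed = study$design$seed, sessions = manifest),
                       mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mp)
}

#' Read a study back from a session directory
#'
#' Loads the `manifest.json` written by [write_study_csv()] and the per
#' session CSV streams.
#'
#' @param dir Directory holding the manifest and CSV files.
#' @return A `study_data`-like list with a `sessions` element.
#' @export
read_study_csv <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stop("no manifest.json in ", dir)
  man <- jsonlite::read_json(mp, simplifyVector = TRUE)
  sessions <- lapply(seq_len(nrow(man$sessions)), function(i) {
    p <- man$sessions$participant[i]; cc <- man$sessions$condition[i]
    tag <- sprintf("%d_%d", p, cc)
    g <- utils::read.csv(file.path(dir, paste0("gaze_", tag, ".csv")))
    g$valid <- as.logical(g$valid)
    structure(list(
      gaze = g,
      eeg = utils::read.csv(file.path(dir, paste0("eeg_", tag, ".csv")),
                            check.names = FALSE),
      stick = utils::read.csv(file.path(dir, paste0("stick_", tag, ".csv"))),
      participant = p, condition = cc,
      difficulty = man$sessions$difficulty[i],
      delta_max = man$sessions$delta_max[i]
    ), class = "session_data")
  })
  structure(list(sessions = sessions, seed = man$seed), class = "study_data")
}
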