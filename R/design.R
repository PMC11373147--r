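#' Study design for a synthetic cognitive-load experiment
#'
#' Describes a participants-by-conditions repeated-measures design in which
#' every participant flies every condition once. Conditions differ only by a
#' latent task-difficulty scalar in \[0, 1\]; all physiological and control
#' channels of the synthetic generator are driven by that scalar.
#'
#' @param n_participants Number of participants (default 12).
#' @param condition_difficulties Numeric vector of per-condition latent
#'   difficulties, each in \[0, 1\]. Default: five conditions spread over
#'   0.1--0.9.
#' @param session_duration Session length in seconds (must exceed the 5 s
#'   resting baseline window).
#' @param eye_rate Eye-tracker sampling rate in Hz (default 120).
#' @param eeg_rate EEG sampling rate in Hz (default 128).
#' @param stick_rate Inceptor sampling rate in Hz (default 60).
#' @param seed Integer master seed; every session derives its own stream
#'   from it deterministically.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_participants = 12,
                         condition_difficulties = c(0.1, 0.3, 0.5, 0.7, 0.9),
                         session_duration = 60,
                         eye_rate = 120,
                         eeg_rate = 128,
                         stick_rate = 60,
                         seed = 1L) {
  stopifnot(is.numeric(n_participants), length(n_participants) == 1,
            n_participants >= 2)
  if (!is.numeric(condition_difficulties) || length(condition_difficulties) < 1)
    stop("condition_difficulties must be a non-empty numeric vector")
  if (any(condition_difficulties < 0 | condition_difficulties > 1))
    stop("all condition difficulties must lie in [0, 1]")
  if (eye_rate <= 0 || eeg_rate <= 0 || stick_rate <= 0)
    stop("sampling rates must be positive")
  if (session_duration <= 5)
    stop("session_duration must exceed the 5 s baseline window")
  structure(list(
    n_participants = as.integer(n_participants),
    condition_difficulties = as.numeric(condition_difficulties),
    n_conditions = length(condition_difficulties),
    session_duration = as.numeric(session_duration),
    eye_rate = as.numeric(eye_rate),
    eeg_rate = as.numeric(eeg_rate),
    stick_rate = as.numeric(stick_rate),
    baseline_window = 5,
    seed = as.integer(seed)
  ), class = "study_design")
}

#' Effect profile linking latent difficulty to every generated channel
#'
#' Holds the generator gains that translate the latent task-difficulty
#' scalar into channel-level effects, with signs fixed so the generated data
#' reproduce the direction pattern expected of rising cognitive load: pupil
#' diameter variability up, fixation rate up, mean fixation duration down,
#' gaze-dispersion NNI down, task-load index up, task-engagement index down,
#' and pilot inceptor workload up.
#'
#' Difficulty-to-channel links are linear with additive Gaussian
#' between-participant effects scaled by `participant_sd`.
#'
#' @param pd_baseline_mm Resting pupil diameter in mm.
#' @param pd_drift_gain Peak amplitude (mm per unit difficulty) of the slow
#'   (< 0.2 Hz) pupil drift that carries the load signal.
#' @param pd_hippus_amp Amplitude (mm) of the 0.3--1 Hz hippus oscillation.
#' @param pd_noise_sd Per-sample measurement noise (mm).
#' @param blink_rate Blink arrivals per second; each blink opens a
#'   100--400 ms invalid gap.
#' @param fixation_duration_base,fixation_duration_slope Mean fixation
#'   plateau duration (s) at difficulty 0 and its change per unit
#'   difficulty (slope must be negative).
#' @param gaze_focus_base Probability, at difficulty 0, that a fixation
#'   lands in the tight on-target cluster rather than the wide scan field.
#' @param gaze_dispersion_slope Change in gaze dispersion per unit
#'   difficulty (negative: more difficulty, more clustered scanning; the
#'   magnitude is added to the focus probability).
#' @param frontal_theta_gain,parietal_alpha_gain,beta_gain Multiplicative
#'   band-power scale per unit difficulty for frontal theta (positive),
#'   parietal alpha (negative) and frontal beta (negative).
#' @param stick_burst_rate_base,stick_burst_rate_gain Stick-input bursts per
#'   second at difficulty 0 and added per unit difficulty.
#' @param stick_amplitude_base,stick_amplitude_gain Burst amplitude (deg) at
#'   difficulty 0 and added per unit difficulty.
#' @param delta_max Inceptor displacement limit (deg, one-sided).
#' @param participant_sd Scale of the Gaussian between-participant random
#'   effects applied multiplicatively per channel.
#' @return An object of class `effect_profile`.
#' @export
effect_profile <- function(pd_baseline_mm = 3.5,
                           pd_drift_gain = 0.35,
                           pd_hippus_amp = 0.03,
                           pd_noise_sd = 0.01,
                           blink_rate = 0.15,
                           fixation_duration_base = 0.45,
                           fixation_duration_slope = -0.22,
                           gaze_focus_base = 0.30,
                           gaze_dispersion_slope = -0.45,
                           frontal_theta_gain = 0.9,
                           parietal_alpha_gain = -0.5,
                           beta_gain = -0.35,
                           stick_burst_rate_base = 0.25,
                           stick_burst_rate_gain = 0.5,
                           stick_amplitude_base = 3,
                           stick_amplitude_gain = 9,
                           delta_max = 20,
                           participant_sd = 0.12) {
  if (fixation_duration_slope >= 0)
    stop("fixation_duration_slope must be negative (duration falls with difficulty)")
  if (gaze_dispersion_slope >= 0)
    stop("gaze_dispersion_slope must be negative (scanning clusters with difficulty)")
  if (frontal_theta_gain <= 0)
    stop("frontal_theta_gain must be positive (theta rises with difficulty)")
  if (parietal_alpha_gain >= 0 || parietal_alpha_gain <= -1)
    stop("parietal_alpha_gain must lie in (-1, 0) (alpha suppression)")
  if (beta_gain >= 0 || beta_gain <= -1)
    stop("beta_gain must lie in (-1, 0)")
  if (stick_burst_rate_gain <= 0 || stick_amplitude_gain <= 0)
    stop("stick gains must be positive (control activity rises with difficulty)")
  if (pd_drift_gain <= 0) stop("pd_drift_gain must be positive")
  if (participant_sd < 0) stop("participant_sd must be >= 0")
  if (delta_max <= 0) stop("delta_max must be positive")
  structure(as.list(environment()), class = "effect_profile")
}

#' Read a study configuration file
#'
#' Parses a YAML (or JSON, which is a YAML subset) key-value file holding a
#' `design:` block and an `effects:` block; unknown keys are rejected.
#'
#' @param path Path to a configuration file.
#' @return A list with elements `design` (`study_design`) and `effects`
#'   (`effect_profile`).
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  d <- cfg$design %||% list()
  e <- cfg$effects %||% list()
  bad <- setdiff(names(d), names(formals(study_design)))
  if (length(bad)) stop("unknown design keys: ", paste(bad, collapse = ", "))
  bad <- setdiff(names(e), names(formals(effect_profile)))
  if (length(bad)) stop("unknown effects keys: ", paste(bad, collapse = ", "))
  list(design = do.call(study_design, d),
       effects = do.call(effect_profile, e))
}

#' @export
print.study_design <- function(x, ...) {
  cat("Synthetic study design:", x$n_participants, "participants x",
      x$n_conditions, "conditions\n")
  cat("  difficulties:", paste(format(x$condition_difficulties), collapse = " "), "\n")
  cat("  session:", x$session_duration, "s  (eye", x$eye_rate, "Hz, EEG",
      x$eeg_rate, "Hz, stick", x$stick_rate, "Hz)  seed", x$seed, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
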