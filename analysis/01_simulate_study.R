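#!/usr/bin/env Rscript
# Stage 1: generate the synthetic 12-participant x 5-condition study.
#
# Emulates the data streams of a head-mounted-display flight-task study:
# 120 Hz gaze/pupil, 128 Hz 32-electrode EEG, 60 Hz inceptor deflections,
# each driven by a latent per-condition task difficulty. Writes a study
# configuration, the manifest, and one example session's CSV streams (the
# full study is regenerated deterministically by later stages from the
# seed, so the bulky streams are not persisted).

suppressPackageStartupMessages(library(vrcogload))

out_dir <- "results/study"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

design <- study_design(seed = 1)
effects <- effect_profile()
print(design)

yaml::write_yaml(list(
  design = design[c("n_participants", "condition_difficulties",
                    "session_duration", "eye_rate", "eeg_rate",
                    "stick_rate", "seed")],
  effects = unclass(effects)
), file.path(out_dir, "study_config.yaml"))

# one example session on disk, plus the manifest for the whole study
example <- generate_session(design, effects, participant = 1, condition = 5)
write_session_csv(example, out_dir)
cat(sprintf("example session (participant 1, condition 5, difficulty %.1f):\n",
            example$difficulty))
cat(sprintf("  gaze samples: %d (%.1f%% invalid), EEG samples: %d x %d ch, stick samples: %d\n",
            nrow(example$gaze), 100 * mean(!example$gaze$valid),
            nrow(example$eeg), ncol(example$eeg) - 1, nrow(example$stick)))
cat(sprintf("  planted: %d fixation plateaus, %d stick bursts, pupil drift %.2f mm\n",
            example$planted$n_plateaus, example$planted$n_bursts,
            example$planted$pd_drift_amp_mm))

st <- generate_study(design, effects)
man <- lapply(st$sessions, function(s)
  list(participant = s$participant, condition = s$condition,
       difficulty = s$difficulty, delta_max = s$delta_max,
       presentation_order = s$presentation_order))
jsonlite::write_json(list(seed = design$seed, sessions = man),
                     file.path(out_dir, "manifest.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat(sprintf("study manifest for %d sessions written to %s\n",
            length(st$sessions), out_dir))
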