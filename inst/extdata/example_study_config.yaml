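# Example study configuration for read_study_config(): a reduced
# 4-participant, 3-condition synthetic design with default effect gains.
design:
  n_participants: 4
  condition_difficulties: [0.2, 0.5, 0.8]
  session_duration: 30
  eye_rate: 120
  eeg_rate: 128
  stick_rate: 60
  seed: 11
effects:
  participant_sd: 0.12
  blink_rate: 0.15
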