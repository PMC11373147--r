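Package: vrcogload
Title: Cognitive Load Estimation from Ocular, EEG and Inceptor Signals in
    VR Flight Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a psychophysiological cognitive-load analysis for
    head-mounted-display flight-simulation studies: low-frequency pupil
    diameter variability via Haar multiresolution analysis, velocity
    threshold (I-VT) fixation detection, nearest-neighbour-index gaze
    dispersion, EEG band-power task-load and task-engagement indices,
    inceptor duty cycle and aggressiveness (pilot inceptor workload), and
    their association with workload via Pearson and repeated-measures
    correlation. Includes a seeded synthetic-data generator emulating a
    participants-by-conditions study design and a pursuit-evasion
    engagement simulator with augmented proportional navigation guidance
    and a reinforcement-learning reward evaluator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
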