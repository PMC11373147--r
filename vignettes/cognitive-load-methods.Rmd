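---
title: "Estimating pilot cognitive load from ocular, EEG and inceptor signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating pilot cognitive load from ocular, EEG and inceptor signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vrcogload)
```

## The problem

In a head-mounted-display flight simulator a pilot tracks an adversary
aircraft while flying the task. Three signal families are recorded
per session: a 120 Hz eye-tracker stream (gaze direction unit vectors,
left/right pupil diameters, validity flags), a 128 Hz 32-electrode EEG
stream, and the pilot's stick-deflection time history. The analysis asks a
single question: do the physiological channels track the pilot's workload,
where workload is measured behaviourally from the stick itself?

The behavioural baseline is the **pilot inceptor workload**
\(\mathrm{PIW} = \mathrm{DC}\times\mathrm{Agg}\): duty cycle (the
percentage of time the stick is actively deflected) times aggressiveness
(the RMS rate of stick deflection). Each physiological metric is computed
once per session, giving one row per participant per condition, and is
correlated with PIW two ways: ordinary Pearson correlation across all
rows, and repeated-measures correlation, which removes between-participant
offsets before asking whether the *within*-participant association is
common across participants.

## Ocular metrics

**Low-frequency pupil variability.** Pupil diameter rises with mental
effort, but the raw signal mixes slow load-driven drift with hippus,
measurement noise and blink artefacts. Invalid samples are removed and
refilled by a natural cubic spline on the original timestamp grid (edge
gaps take the nearest valid value; cubic extrapolation of pupil data is
unstable). The series is normalized against the participant's resting
baseline — the maximum diameter over the first 5 s of the session, taken
per eye per session — as percent change
\(\%PD(t) = (PD(t)-PD_{base})/PD_{base}\times100\), which removes
between-participant diameter differences. A 7-level Haar multiresolution
analysis then isolates the slow component: at 120 Hz the level-7
approximation spans 0–0.469 Hz. The metric is the sample standard
deviation (\(N-1\) denominator) of that approximation.

Two choices here are genuinely open and we fixed them as follows. First,
the "level-7 approximation data" is the approximation *component
reconstructed on the original sampling grid* — that is what makes the
procedure a multiresolution analysis — rather than the downsampled
coefficient vector; the coefficient variant is available via
`pd_lowfreq_std(..., on = "coefficients")`. For a slowly varying signal
the two differ only through the \(2^{7/2}\) coefficient scaling and edge
handling. Second, arbitrary session lengths are handled by symmetric
(reflection) extension up to the next multiple of \(2^7\); reflection
avoids the edge discontinuity a zero-pad or periodic wrap would inject
into a 7-level decomposition. Components are truncated back to the input
length, so approximation plus details still reproduce the input exactly.

**Fixations.** I-VT classification: the angle between consecutive gaze
direction vectors divided by the time increment gives an angular velocity;
intervals below 30 deg/s are fixation intervals, and maximal sub-threshold
runs merge into single fixation events. No minimum-duration filter is
applied. Velocity is computed only across originally-valid samples (gaze
and pupil validity share one flag); an interval spanning a dropped gap
uses the true, longer time increment. Fixation rate is events per task
second; mean fixation duration is summed event time over event count, and
is flagged missing when there are no events.

**Gaze dispersion (NNI).** Gaze directions are projected to the
unit-forward plane \((x/z,\,y/z)\). The nearest-neighbour index is the
observed mean nearest-neighbour distance over the Clark–Evans expectation
\(0.5\sqrt{A/n}\) under spatial uniformity on the same area \(A\)
(bounding box of the projected points by default; configurable). Points
default to fixation centroids, matching the spatial-statistics literature
this index comes from; a raw-sample mode exists. NNI near 1 means random
scanning; clustered, target-locked scanning pushes it toward 0. Note the
index is scale-invariant, so *shrinking* a scan pattern uniformly does not
lower it — what lowers it is concentration of most points into a tight
cluster while the scanned region stays wide.

## EEG indices

Band powers use the sliding-window FFT convention of consumer EEG
headsets: a 256-sample Hann window slid by 16 samples at 128 Hz, one-sided
power spectral density with window-power compensation (units
\(\mu V^2/\mathrm{Hz}\)), averaged over each band's bins — theta 4–8,
alpha 8–12, beta 16–25, gamma 25–45 Hz. The 12–16 Hz gap between alpha
and beta is deliberate and left unfilled; band edges use half-open
intervals \((lo, hi]\) so no bin is counted twice. Gamma is computed but
feeds no index. Headset-side filtering (0.2–45 Hz band-pass, notch) is
assumed already applied; `eeg_bandpass()` is available for raw input from
other hardware.

The **task-load index** is frontal-midline theta over parietal alpha:
mean theta power across Fz, Fp1, Fp2, F3, F4, F7, F8, FC1, FC2, FC5, FC6
divided by mean alpha power across P7, P3, Pz, P4, P8. "Power of a set of
electrodes" is aggregated as the arithmetic mean, making the ratio
invariant to montage size (a sum would not be). The **task-engagement
index** is beta over (alpha + theta) on a montage; five literature
montages are selectable and the frontal F3/F4/F7/F8 set is the default.
Both indices are evaluated per window and the session value is the mean of
per-window ratios — this tracks the per-window definition and is robust to
nonstationarity; the ratio-of-session-means alternative is a flag.
Zero-denominator windows are dropped and counted.

## Inceptor metrics

The duty-cycle activity indicator for increment \(i\) is 0 only when the
deflection rate is below the noise threshold — 0.5 % of the *total*
(two-sided, \(2\delta_{max}\)) displacement range per time increment —
*and* the stick is off its stop; otherwise 1. Two divisor conventions
exist for turning the indicator sum into a percentage. The printed
indicator-count form divides a unitless sum by the time span
\(t_n-t_2\), which does not yield a bounded percentage on a general grid
(with every increment active it exceeds 100 %). We therefore default to
the time-fraction reading — each active increment contributes its time
step, divided by the total increment time — which is exactly the stated
meaning, "the percentage of time the participant uses the controls", and
is bounded in [0, 100]. The literal variant is available with
`mode = "count"`. Aggressiveness is the RMS of the \(n-1\) successive
deflection rates. Deflection is single-axis (pitch) by default.

## The synthetic-data generator

No recorded pilot data ship with the package, so every downstream stage is
exercised on a seeded generator that emulates the study design: 12
participants by 5 conditions, 60 s sessions, with each condition reduced
to a latent difficulty scalar (defaults 0.1, 0.3, 0.5, 0.7, 0.9). The
first 5 s of every stream are a quiet resting baseline. Difficulty links
are linear with additive Gaussian participant effects — the simplest
structure under which sign recovery by correlation is provable — and every
sign is fixed to the expected load direction: pupil drift amplitude up,
plateau duration down, gaze focus probability up (NNI down), frontal theta
up, parietal alpha down, frontal beta down, stick burst rate and amplitude
up.

What the generator reproduces, and what it does not: gaze alternates
fixation plateaus with 25 ms saccades of at least ~2 degrees (so plateaus
are recoverable by the 30 deg/s detector); blinks are 100–400 ms invalid
gaps at Poisson arrivals, placed wholly inside plateaus so a blink never
hides a saccade; EEG is band-limited Gaussian noise per canonical band
with montage-specific amplitude scaling, not a biophysical source model —
adequate because only band powers are consumed; stick activity is
smooth bursts at jittered-regular arrivals (near-deterministic counts, so
planted monotonicity across conditions is strict). Streams run on
independent clocks (120/128/60 Hz) sharing \(t=0\), with no cross-stream
resampling. Real data differ in ways that matter for interpretation:
artefacts are not Gaussian, EEG band power is nonstationary within
conditions, difficulty effects are not linear, and participant effects are
not homoscedastic. Passing the recovery tests therefore shows the
*pipeline* is correct and directionally sensitive, not that real effect
sizes would match.

Session reproducibility is exact: every session derives its own RNG
stream from (master seed, participant, condition), and participant random
effects are keyed by (master seed, participant) only, so they are constant
across a participant's conditions. Condition presentation order is
randomized per participant and recorded, nullifying order effects by
design (it does not alter the generated signals, which depend only on the
condition).

## Correlation machinery

`pearson()` wraps the product-moment test (df \(=n-2\), two-sided p).
`rmcorr()` fits the ANCOVA \(y \sim \mathrm{subject} + x\) by least
squares and reports
\(r_{rm} = \mathrm{sign}(b)\sqrt{SS_x/(SS_x+SS_{err})}\) with
\(df = N - k - 1\); on the balanced designs used here the sequential and
Type-III sums of squares for \(x\) coincide. Missing cells are dropped
pairwise per metric, so ocular and EEG correlations may legitimately use
different \(n\). P-values are descriptive; no multiple-testing correction
is applied. The single optional data-exclusion rule — dropping rows whose
NNI falls below an explicit cut — must be requested per call and is never
automatic.

## The engagement simulator

The adversary interaction is a point-mass pursuer-evader pair (X lateral,
Y altitude, Z forward range; headings in the X–Z plane). The pursuer is
steered by augmented proportional navigation,
\(a_N = N V_c \dot\lambda + a_{Nt} N/2\) with \(N=3\), where
\(\dot\lambda\) is the line-of-sight *angle* rate. The distance symbol and
the rate symbol are kept distinct deliberately: the guidance literature's
\(\dot\lambda\) is the LOS rotation rate, and a range rate would not steer
an interceptor; the range-rate reading is still available from
`los_geometry(..., lambda_dot_mode = "range")`. The deviation and aspect
angles use the two-argument arctangent, since the one-argument form is
undefined for equal forward ranges and quadrant-ambiguous.

Observations reach the guidance loop through a radar model with 1.2 km
coverage and 400 ms latency (800 ms in degraded conditions). Integration
is forward Euler at 10 ms with heading rate \(a_N/V\); the commanded
acceleration is capped at 88 m/s² (about 9 g) because the raw command
diverges as the range collapses and an airframe cannot follow it. The
vertical channel is a rate-limited proportional climb toward the observed
evader altitude. The unguided evader flies constant speed on a fixed
heading with a sinusoidal altitude profile (50 m amplitude, 20 s period by
default, amplitude configurable); the fleeing evader moves along the
pursuer-to-evader bearing at a speed proportional to the LOS rate, never
slower than the pursuer plus a margin. The reward evaluator scores the
three strict advantage conditions (distance band, deviation-angle bound,
aspect-angle bound) with configurable weights; no reinforcement-learning
training is performed here — the evaluator makes the reward geometry
testable and reusable.

Two properties are verified by simulation rather than proof: APN attains a
smaller miss distance than an unguided straight-line pursuer on virtually
every random geometry, and doubling radar latency does not reduce the miss
distance on paired geometries. The latency property is statistical — on
wide-miss engagements an occasional pair can invert — and the test suite
pins it on fixed seed families where it holds throughout.

## Numerical choices and degenerate inputs

* Spline preprocessing needs ≥ 4 valid samples; an all-invalid stream is a
  hard error that the metric table converts into flagged-missing cells.
* A non-positive pupil baseline is rejected as physically impossible.
* `haar_mra()` refuses series shorter than \(2^{levels}\) and tells the
  caller to lower the depth.
* Zero fixations give rate 0 and a missing mean duration; coincident-only
  gaze points with zero bounding-box area are an NNI error unless a
  positive area is supplied.
* Duty cycle is clamped to [0, 100] against last-bit floating-point
  overshoot; duplicate timestamps are errors everywhere rates are formed.
* Coincident pursuer/evader positions flag the LOS angles undefined.

## Problem sizes

The shipped analysis uses 60 s sessions (7 200 gaze, 7 680 EEG x 32, 3 600
stick samples per session; 60 sessions), 100 random engagement geometries
with 50 latency pairs at 10 ms steps, and oracle sweeps of 1 000 random
series per estimator. These sizes make every distributional check
well-resolved while keeping a full run in the minutes range on one core.

## Known limitations

* The generator's effect sizes are free parameters chosen once to be
  comfortably recoverable; they are not calibrated to any recorded
  cohort, so reported correlation magnitudes characterize the pipeline,
  not human physiology.
* NNI is computed per session on fixation centroids; tasks with very few
  fixations make it noisy, and it is undefined below two centroids.
* The EEG model carries no artefact process, so no artefact
  rejection/ICA path exists (out of scope by design).
* The engagement model is 3-DOF kinematic: no aerodynamic forces, no
  missile flyout, no 6-DOF attitude dynamics.
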