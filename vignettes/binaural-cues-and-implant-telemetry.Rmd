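---
title: "Methods: binaural-cue measurement and cochlear-implant telemetry analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binaural-cue measurement and cochlear-implant telemetry analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(implantcues)
```

## Scope

`implantcues` implements the analysis chain used to validate a bilateral
cochlear-implant animal model in a small-headed mammal (the ferret):

1. **Acoustics** — impulse-response measurement with complementary Golay
   codes, and extraction of interaural time differences (ITD) and interaural
   level differences (ILD) as functions of speaker azimuth, including
   zero-crossing (F0) re-alignment of repeated recordings.
2. **ECAP electrophysiology** — recovery of electrically evoked compound
   action potentials by forward-masking artifact rejection, P1–N1
   amplitude-growth functions, threshold extrapolation with a noise-floor
   rule, and a longitudinal threshold-stability test.
3. **Impedance telemetry** — open/closed/functional classification,
   post-operative epoch summaries, across-array profiles, and the percentage
   of electrode positions that stay usable.
4. **Orienting behaviour** — head/jacket marker trajectories at video frame
   rate scored for movement latency and final bearing.

No animal recordings ship with the package. A seeded synthetic-data module
generates every input with the statistical structure the analyses assume, so
each stage can be verified end to end and the whole study can be re-run as a
simulation (`analysis/01`–`05`, `run_pipeline()`).

## Acoustic model and cue extraction

### Golay measurement

Transfer functions are measured with complementary Golay pairs built by the
append/negate recursion; a 512-point pair (order 9) is the default stimulus.
Writing $a_k, b_k$ for the codes, the defining property is that their
autocorrelations sum to $2L\,\delta(\tau)$, so per channel

$$\hat h = \frac{\mathrm{xcorr}(r_a, a) + \mathrm{xcorr}(r_b, b)}{2L}$$

recovers the impulse response exactly for a noiseless linear system. The
suite checks this to $10^{-9}$ relative error against direct convolution for
random sparse systems.

### ITD and ILD

ITDs are taken from the *unfiltered* impulse responses by cross-correlation,
because for this species they are essentially frequency independent. The
integer-lag peak is refined by 3-point parabolic interpolation, giving
sub-sample resolution (~1 µs at 80 kHz, where one sample is 12.5 µs); ties
are broken toward the smaller absolute lag. Sign convention: negative source
angles are to the animal's left, and a positive ITD/ILD means the right ear
leads / is louder, so cue curves increase over frontal angles.

ILDs vary strongly with frequency, so both channels are band-pass filtered
first — a 4th-order Butterworth applied forward–backward, hence zero phase
and incapable of shifting the delay — and the ILD is
$20\log_{10}(\mathrm{RMS}_R/\mathrm{RMS}_L)$. Default analysis bands are
0.75–1.5 kHz and 4–8 kHz. (Reported low-band edges vary between 1.25 and
1.5 kHz across summaries of the jacket data; both edges are arguments, with
0.75–1.5 kHz as the default.)

A reported cue range of "±X" is interpreted as the **half-range**
$(\max - \min)/2$ over the measured angle grid; whether such figures are
half-ranges or maxima of $|cue|$ is ambiguous in the source material, and the
half-range reading is used consistently. F0 alignment finds the angle at
which a cue crosses zero by linear interpolation between the bracketing grid
angles (nearest-to-zero crossing if several) and relabels the axis as
`angle − F0`, leaving cue values untouched.

### Synthetic heads

The generator is a spherical-head model: the Woodworth delay
$\mathrm{ITD}(\theta) = (a/c)(\sin\theta + \theta)$ for $|\theta| \le 90°$,
mirrored beyond so the function stays continuous and odd — chosen because it
is frequency independent, matching what is observed in this species. Head
shadow is a first-order per-band gain $\pm s(f)\sin\theta/2$ dB per ear,
with $s(f)$ flat below 2 kHz and above 3.5 kHz (log-linear between), so both
default analysis bands see exactly their configured ILD. Fractional-sample
delays are rendered by windowed-sinc (band-limited) interpolation and the
shadow gain is applied with zero phase.

Because the source gives no head radius or microphone spacing, the defaults
are **arbitrary calibrations, not species constants**: an effective radius of
25.3 mm puts the ITD maximum near 190 µs, and shadow strengths of 4.3/10.9 dB
put the band ILD half-ranges near the middle of the observed ranges. The
jacket-pocket site defaults to a slightly smaller radius (22.5 mm) and weaker
shadow (4.2/9.8 dB), since pocket microphones sit closer together than the
ear canals; the exact factors are configuration, not constants. Cohort
simulations draw per-animal radii and shadows uniformly over ranges whose
endpoints reproduce the spread of observed cue ranges (ITD half-range roughly
165–255 µs across ear-canal measurements).

What the generator does *not* emulate: pinna spectral (elevation) cues,
frequency-dependent ITDs, room reflections, or measurement noise in the
recordings. Passing tests therefore demonstrate the correctness of the
measurement chain, not robustness to acoustic artifacts of real chambers.

## ECAP analysis

### Artifact rejection

The forward-masking scheme records four frames per stimulus level:
probe alone ($A$), masker + probe ($B$), masker alone ($C$) and no stimulus
($D$). The canonical subtraction

$$\text{response} = A - (B - C) - D$$

is exact when artifacts are additive and identical across frames and the
masker completely suppresses the probe response in $B$ (the probe falls in
the nerve's refractory window). Commercial software implements a "modified"
variant whose details are not public; the canonical four-frame arithmetic is
used here and labelled as an assumption. Cancellation is algebraic, so the
tests require exactness to machine precision.

### Growth functions and thresholds

P1–N1 amplitude is `max` over a P1 window minus `min` over an N1 window
(defaults 0.4–1.0 ms and 0.1–0.5 ms post-probe; the morphology literature
for this preparation does not fix the latencies, so the windows are
arguments). Amplitudes below a 30 µV noise floor are excluded (strictly
below; a point at exactly 30 µV is retained), an ordinary least-squares line
is fitted to the remainder, and the threshold is the level at the line's zero
crossing, $-b_0/b_1$. Fewer than two retained points or a non-positive slope
are errors, not numbers. Stimulus levels are abstract device units
throughout; only differences matter to every computation.

Longitudinal stability fits threshold-versus-day OLS slopes per electrode
position and tests the slopes against zero with a two-sided one-sample
t-test (`stats::t.test`). Identical-slope degenerate inputs (exactly
collinear data) are reported with an undefined t statistic rather than a
spurious one; the detection threshold for "identical" is a $10^{-10}$
relative tolerance because `lm()` returns $O(10^{-16})$ coefficients on
exactly flat data.

### Noise model of the synthetic sessions

Each simulated frame is the average of `n_sweeps` stimulus repetitions
(default 500), with `noise_sd` (default 10 µV) the per-sweep noise; the
stored frame therefore carries residual noise of
$\sigma/\sqrt{n_\text{sweeps}} \approx 0.45$ µV. This matters because the
windowed max/min amplitude measure has an extreme-value bias of roughly
$3.7\sigma_\text{frame}$: un-averaged 10 µV frames would bias every
amplitude by ~74 µV and every threshold by ~37 level units, which no
downstream fitting could undo. Evoked-potential recording hardware always
averages sweeps, so the averaged-frame model is the physically faithful one;
with it, threshold recovery over 200 noisy sessions has a median absolute
error of about 0.6 level units (a small residual negative bias from the same
extreme-value effect remains visible in `analysis/02`).

## Impedance bookkeeping

Classification follows the desired-range rule: below 1 kΩ is a closed
circuit, above 20 kΩ an open circuit, and the boundaries themselves count as
functional because the failure rules are strict inequalities. Epoch summaries
("days 0–4", "days 16–20", both inclusive) report the arithmetic mean and
sample (n−1) SD of functional measurements only; open/closed readings are
failure codes, not tissue impedances, and are excluded from every mean with
the exclusion count reported. A *position* (animal × ear × electrode) counts
as functional only if **every** measurement stayed in range; because it is
ambiguous whether published percentages count positions or measurements,
both statistics are computed (position-level primary).

The generator's noiseless course is a logistic rise re-anchored so day 0
reads the baseline exactly: with $L(d)$ a logistic of midpoint 9 days and
scale 2.2 days, $s(d) = (L(d) - L(0))/(1 - L(0))$ and
$z(d) = \text{base} + (\text{plateau} + \text{offset}_e - \text{base})\,s(d)$.
Defaults (baseline 1.9 kΩ, plateau 8.5 kΩ) land the day 0–4 epoch near 2 kΩ
and the day 16–20 epoch near 8.5 kΩ. Per-electrode offsets make the profile
highest at the apical position (AE1) and lowest mid-array (AE5). Measurement
noise (SD 0.5 kΩ) is clamped so non-failed electrodes remain inside 1–20 kΩ:
out-of-range values are reserved for planted failures, which read >20 kΩ
(open) or <1 kΩ (closed) from their onset day onward.

## Orienting responses

The marker's per-frame displacement bearing (arena convention: 0° along the
start-spout axis, positive clockwise/rightward), taken relative to the
initial heading, is the angle series. The initial heading is estimated from
the five pre-onset frames; with the animal stationary at the start spout —
the designed case — it falls back to the arena axis, and it can be supplied
explicitly. Stationary frames carry the previous angle forward.

*Latency* is scored by the published video rule: the time of the third of
three consecutive frames that each moved ≥ a per-frame threshold in the same
direction, after stimulus onset. The source does not quantify "movement";
the default criterion is 1°/frame, configurable. Absence of a qualifying
triplet yields `NA`, not an error. *Final bearing* is the circular
(unit-vector) mean of the last three frames of the recorded second —
indistinguishable from the arithmetic mean at these bearings, but safe at
±180°.

The generator defines its `latency_ms` in the same scoring convention (time
of the third moving frame), so recovery is exact up to frame rounding; the
angular sweep is a raised-cosine ("sigmoid") profile over a 150 ms rise,
which makes the first moving frame's step exceed the 1° criterion for final
bearings above roughly 33°, the regime of the simulated task (≈ 42°
bearings). Latencies below three frame periods (50 ms at 60 frames/s) are
not representable under the scoring rule and are rejected at configuration.

## Reproducibility and problem sizes

Every generator draws from its own seeded stream (`withr::with_seed`), so
each stage is a pure function of (configuration, seed); `run_pipeline()`
writes a manifest with an MD5 checksum of every output, and rerunning with
the same seed reproduces every file byte for byte. WAV output uses 64-bit
IEEE float so sample data round-trips losslessly.

Simulated problem sizes are chosen to mirror the study design while keeping
any run to seconds: 16 ear-canal and 3 jacket heads measured at 31 azimuths
(±150° in 10° steps) with 512-point codes at 80 kHz; weekly ECAP sessions
(6 levels, threshold+10…+60) for 7 electrode positions × 2 ears over 12
weeks; 90 days of daily impedance telemetry for 4 animals × 2 ears × 8
positions with 6 open-circuit failures planted at day 43; 40 orienting
trials per marker condition at 60 frames/s. Statistical checks use 200
seeded sessions (threshold recovery) and 500 replicates (t-test type-I
rate).

## Known limitations

- The spherical-head generator is a geometric idealization; it validates the
  cue-extraction chain, not the acoustics of any real animal or jacket.
- The "modified" forward-masking variant of the commercial ECAP software is
  unknown; results assume the canonical four-frame arithmetic and complete
  masking.
- ECAP P1/N1 window defaults encode one plausible morphology; preparations
  with different latencies need the window arguments.
- The impedance model is phenomenological (logistic rise plus offsets); it
  contains no electrochemistry, and planted failures are step functions.
- Latency scoring inherits the video rule's granularity (one frame,
  ~16.7 ms) and its dependence on the per-frame movement criterion.
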