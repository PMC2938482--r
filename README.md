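# implantcues

Analysis toolkit for validating a bilateral cochlear-implant animal model in
a small, behaviourally testable mammal (the ferret). When both ears are
implanted and the sound processors are worn in a jacket, three questions
decide whether the model is usable for binaural hearing research, and this
package implements the measurement chain for each:

- **Are binaural cues preserved?** Impulse responses are measured with
  512-point complementary Golay code pairs; interaural time differences
  (ITD) come from cross-correlation of the unfiltered responses with
  parabolic sub-sample peak interpolation, and interaural level differences
  (ILD) from zero-phase band-passed RMS ratios
  (20·log10(RMS_R/RMS_L), bands 0.75–1.5 and 4–8 kHz). Cue curves versus
  azimuth are summarized by half-ranges and re-registered on their zero
  crossing (F0) to compare repeated recordings.
- **Does the implant drive the nerve stably?** Electrically evoked compound
  action potentials (ECAP) are recovered by forward-masking artifact
  rejection, `A − (B − C) − D` over the probe/masker/no-stimulus frames;
  the P1–N1 amplitude growth function is fitted by least squares after
  excluding points under a 30 µV noise floor, the threshold is the line's
  zero crossing, and per-electrode threshold-vs-day slopes are tested
  against zero.
- **Do the electrodes survive?** Longitudinal impedance telemetry is
  classified by the desired-range rule (<1 kΩ closed circuit, >20 kΩ open
  circuit), summarized by post-operative epoch and array position, and
  reduced to the percentage of electrode positions that stay functional.

A fourth stage scores head-orienting responses from 60 frames/s marker
coordinates: movement latency by the three-consecutive-frames rule and final
bearing as the circular mean of the last three frames — the behavioural
readout used to compare head- versus jacket-mounted microphones.

Because no animal recordings are distributed, a seeded synthetic module
generates every input the pipeline consumes (spherical-head Woodworth ITDs
with band-dependent head shadow, four-frame ECAP sessions with linear
supra-threshold growth, logistic impedance time courses with plantable
failures, sigmoid orienting trajectories), making every stage testable end
to end. See the methods vignette
(`vignettes/binaural-cues-and-implant-telemetry.Rmd`) for the models,
defaults and their rationale.

## Worked example

```r
library(implantcues)

# measure a synthetic head with Golay codes and extract its cues
pair  <- generate_golay_pair(9)            # 512-point complementary pair
model <- head_model()                      # ear-canal defaults
irs <- lapply(seq(-150, 150, by = 10), function(a) {
  rec <- record_golay(pair, simulate_head_ir(model, a))
  estimate_impulse_response(rec$resp_a, rec$resp_b, pair)
})
curve <- build_cue_curve(irs)
round(max(curve$itd_us), 1)
#> [1] 188.6          # Woodworth maximum at +90 deg: (a/c)(1 + pi/2) = 189.6 us

# ECAP threshold from a simulated forward-masking session
gf <- measure_growth(simulate_ecap_session(ecap_sim_config(
  threshold_level = 100, noise_sd = 0)))
fit_threshold(gf)[c("threshold", "slope")]
#> $threshold
#> [1] 100            # exact recovery of the configured threshold
#> $slope
#> [1] 2              # uV per stimulus-level unit
```

The numbered drivers under `analysis/` run each study stage at full size and
narrate what they find; with the default seed they print, among others:

```
ear-canal ITD half-ranges: 175-246 us (median 220, n = 16)
jacket ITD half-ranges:    164-167 us (median 166, n = 3)
threshold-vs-day slopes: mean -0.001 units/day (range -0.013 to 0.013)
one-sample t-test vs zero: t = -0.15, df = 6, p = 0.89
impedance, days 0-4:   2.1 kOhm (sd 0.5, n = 320)
impedance, days 16-20: 8.5 kOhm (sd 0.7, n = 320)
positions always in the 1-20 kOhm range: 90.62% of 64
mean latency:  head 200 ms, jacket 317 ms (difference -116 ms)
final bearing: head 42.47 deg, jacket 41.92 deg
```

i.e. the jacket compresses cue ranges slightly but preserves their shape,
ECAP thresholds show no drift, most electrode positions stay in range
despite six planted open circuits, and the jacket turns ~120 ms after the
head while settling on an almost identical final bearing. Tables land in
`results/`; bulky regenerable logs go to `scratch/`.

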