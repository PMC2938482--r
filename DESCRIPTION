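Package: implantcues
Title: Binaural Cue Preservation and Telemetry Analysis for Bilateral Cochlear Implant Animal Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis chain for assessing a bilateral cochlear-implant animal
    model: impulse-response measurement with complementary Golay codes and
    extraction of interaural time and level difference (ITD/ILD) cue curves
    versus source azimuth; electrically evoked compound action potential
    (ECAP) recovery by forward-masking artifact rejection, amplitude-growth
    threshold extrapolation with a noise-floor rule, and longitudinal
    threshold-stability testing; electrode-impedance bookkeeping with
    open/closed-circuit classification and epoch summaries; and head-orienting
    response quantification (movement latency, final bearing) from frame-rate
    marker coordinates. A seeded synthetic-data module generates every input
    the pipeline consumes, so all stages are testable without animal
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
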