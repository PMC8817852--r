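Package: facevigil
Title: Learning-State and Fatigue Assessment from Facial Landmark Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses attention and fatigue of a person in front of a camera
    from streams of 68-point 2D facial landmarks. Implements blink detection
    via the eye aspect ratio (EAR), yawn detection via the inner-lip mouth
    aspect ratio (MAR), head-pose estimation via a perspective-n-point camera
    model with Euler-angle extraction, per-frame state machines with
    consecutive-frame counters, and a fused per-minute alert rule combining
    eye-closing rate (PERCLOS), yawn counts, and out-of-range head angles.
    Includes a ground-truthed synthetic landmark-stream simulator so the whole
    pipeline is testable offline, plus JSON-lines stream readers and writers
    and command-line entry points.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
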