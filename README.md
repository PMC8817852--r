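# facevigil

Attention and fatigue monitoring of a person in front of a camera — an
online learner, a driver, a study participant — from streams of 68-point 2D
facial landmarks. The package takes the landmark stream a face-alignment
detector emits (one record per video frame), computes per-frame facial
features, runs per-frame state machines with consecutive-frame counters, and
fuses them into a per-minute alert decision. A ground-truthed synthetic
stream simulator makes the whole pipeline testable with no camera, images,
or detector in the loop.

## The method

Three facial signals are extracted per frame and fused per window:

**Blinking / eye closure.** From the six landmarks of each eye, the eye
aspect ratio

```
EAR = (‖P2−P6‖ + ‖P3−P5‖) / (2 ‖P1−P4‖)
```

sits near 0.3 while the eye is open and collapses toward 0 as the lids
close. A frame is *closed* (E = 0) when the two-eye average falls below
0.20. Blinks are completed open–close–open transitions; the eye-closing
rate (PERCLOS) is the closed-frame fraction of a window.

**Yawning.** The mouth aspect ratio is computed from *inner-lip* landmarks,

```
MAR = (‖A1−A2‖ + ‖B1−B2‖) / (2 ‖H1−H2‖)
```

so that lip thickness does not inflate the closed-mouth baseline across
faces. A frame is *open* (M = 1) at MAR ≥ 0.35; maximal open runs become
episodes graded by duration: ≤ 25 frames ordinary opening (Y = 0), 26–50
frames a yawn (Y = 1), > 50 frames a deep yawn (Y = 2).

**Head pose.** The 14 most rigid landmarks (brow and eye corners, nose
base, mouth corners, lower lip, chin) are matched to a 3D face model and
the head's rotation and translation relative to the camera are recovered by
solving the perspective-n-point problem: a DLT initialisation refined by
Levenberg-damped Gauss–Newton on the reprojection error, with the full
radial–tangential lens distortion model supported. The rotation is
decomposed into Euler angles (pitch = nod, yaw = turn, roll = sway); a
channel outside ±15° increments its consecutive-frame counter, and a
counter exceeding 60 frames signals fatigue (pitch/roll) or sight
deviation (yaw).

**Fused alert rule.** Within a one-minute window an alert is raised when
the eye-closing rate exceeds 0.2, or the window contains two yawns or one
deep yawn, or any Euler channel is out of range for more than 120 frames.

## Worked example

Simulate a one-minute session containing three blinks, one deep yawn and a
sustained 30° head turn, then assess it:

```r
library(facevigil)

script <- read_scenario(system.file("extdata", "example_scenario.yaml",
                                    package = "facevigil"))
res <- render_stream(script)
out <- run_pipeline(res$stream, assess_config(fps = 25))
out$windows[, c("eye_closing_rate", "blink_count", "deep_yawn_count",
                "yaw", "yaw_frames", "alert", "reasons")]
#>   eye_closing_rate blink_count deep_yawn_count      yaw yaw_frames alert   reasons
#> 1      0.009333333           3               1 29.99781         86  TRUE DEEP_YAWN
```

The pipeline recovered the three scripted blinks, classified the 60-frame
mouth opening as a deep yawn (which alone trips the alert), and measured
the head-turn peak at 30.0° of yaw with 86 out-of-range frames — below the
120-frame head clause, so `DEEP_YAWN` is the only reason.

Tabulated per-window records can be audited directly:

```r
rec <- example_session_records()[1, ]   # closing rate 0.23, head in range
evaluate_record(rec)
#> $alert
#> [1] TRUE
#> $reasons
#> [1] "CLOSING_RATE"
```

Command-line wrappers live in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/simulate.R", package="facevigil"))')" \
    --script scenario.yaml --out stream.jsonl --truth truth.json
Rscript "$(Rscript -e 'cat(system.file("cli/assess.R", package="facevigil"))')" \
    --landmarks stream.jsonl --fps 25 --out report.csv
```

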