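# Example scenario for the landmark-stream simulator: one 60-second window
# at 25 fps containing three blinks, one deep yawn (60 open-mouth frames),
# and a 130-frame head turn peaking at 30 degrees of yaw.
fps: 25
duration: 60
noise_sd: 0
seed: 42
events:
  - type: blink
    start: 2.0
    frames: 6
  - type: blink
    start: 10.0
    frames: 8
  - type: yawn
    start: 15.0
    frames: 60
  - type: head_turn
    start: 25.0
    frames: 130
    magnitude: 30
  - type: blink
    start: 45.0
    frames: 6
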