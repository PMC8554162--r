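color:
  fx: 900.0
  fy: 900.0
  u0: 640.0
  v0: 360.0
  width: 1280
  height: 720
  distortion:
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
depth:
  fx: 730.0
  fy: 730.0
  u0: 512.0
  v0: 384.0
  width: 1024
  height: 768
  distortion:
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
registration:
  R:
  - 0.999961923064171
  - 0.0
  - 0.008726535498374
  - 0.0
  - 1.0
  - 0.0
  - -0.008726535498374
  - 0.0
  - 0.999961923064171
  t:
  - 0.015
  - 0.0
  - 0.0
depth_dialect: tsv_mm
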