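# Hip-worn IMU configuration: 100 Hz, 5 s windows (496 samples after
# rounding down to a multiple of 16) with 75% overlap, 6 channels,
# 12 classes.
dataset:
  source: synthetic
  sample_rate: 100
  n_channels: 6
  window_seconds: 5
  slide_mode: overlap_fraction
  slide_value: 0.75
model:
  variant: MCAE
  n_classes: 12
  activation: selu
seed: 1
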