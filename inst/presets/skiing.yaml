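# Smartphone alpine-skiing configuration: 100 Hz, 10 s windows with a 25%
# sliding rate, 6 channels (world-frame acceleration + magnetic field),
# 4 skiing styles.
dataset:
  source: synthetic
  sample_rate: 100
  n_channels: 6
  window_seconds: 10
  slide_mode: stride_fraction
  slide_value: 0.25
model:
  variant: MCAE
  n_classes: 4
  activation: selu
seed: 1
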