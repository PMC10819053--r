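# Waist-worn smartphone benchmark configuration: 6 inertial channels at
# 50 Hz, 128-sample windows (2.56 s) with a 50% sliding rate, 6 classes.
dataset:
  source: synthetic
  sample_rate: 50
  n_channels: 6
  window_seconds: 2.56
  slide_mode: stride_fraction
  slide_value: 0.5
model:
  variant: MCAE
  n_classes: 6
  activation: selu
seed: 1
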