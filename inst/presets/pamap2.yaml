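# Wrist/chest/ankle IMU configuration: 100 Hz, 5.12 s windows (512 samples)
# with a 25% sliding rate, 27 IMU channels, 12 classes.
dataset:
  source: synthetic
  sample_rate: 100
  n_channels: 27
  window_seconds: 5.12
  slide_mode: stride_fraction
  slide_value: 0.25
model:
  variant: MCAE
  n_classes: 12
  activation: selu
seed: 1
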