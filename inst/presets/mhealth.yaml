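# Chest/wrist/ankle multi-sensor configuration: 50 Hz, 2.56 s windows with
# a 50% sliding rate, 23 channels (3 IMUs + 2 ECG leads), 12 classes.
dataset:
  source: synthetic
  sample_rate: 50
  n_channels: 23
  window_seconds: 2.56
  slide_mode: stride_fraction
  slide_value: 0.5
model:
  variant: MCAE
  n_classes: 12
  activation: selu
seed: 1
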