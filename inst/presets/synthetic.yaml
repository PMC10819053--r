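# Default synthetic benchmark: 4 classes (2 periodic, 2 static), 6 channels
# at 50 Hz, 8 subjects with ~30% held out by subject.
dataset:
  source: synthetic
  n_subjects: 8
  test_fraction: 0.3
  sample_rate: 50
  n_channels: 6
  window_seconds: 2.56
  slide_mode: stride_fraction
  slide_value: 0.5
model:
  variant: MCAE
  activation: selu
train:
  max_epochs: 50
seed: 1
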