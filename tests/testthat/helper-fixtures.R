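# Small fixtures shared across test files; everything is generated in code.

# Two-class, two-channel population at 25 Hz with short bouts: one
# locomotion-like periodic class and one posture-like static class.
tiny_spec <- function(noise_sd = 0.1, sigma_freq = 0.1, sigma_amp = 0.2) {
  synthetic_spec(
    archetypes = list(
      class_archetype("move", "periodic", base_freq = 2,
                      amplitude = c(1, 0.6), harmonics = c(0.4, 0.1)),
      class_archetype("rest", "static", offset = c(0.8, -0.5))),
    n_channels = 2L, sample_rate = 25,
    bout_seconds = c(4, 6), bouts_per_class = 2L,
    sigma_amp = sigma_amp, sigma_freq = sigma_freq, noise_sd = noise_sd)
}

# 16-sample windows (0.64 s at 25 Hz), subject-disjoint splits.
tiny_splits <- function(n_subjects = 4L, seed = 1L, spec = tiny_spec()) {
  generate_dataset(spec, n_subjects = n_subjects, seed = seed,
                   window_seconds = 0.64, slide_value = 0.5,
                   filter = filter_config(butter_cutoff = 10))
}

tiny_model <- function(variant = "MCAE", n_classes = 2L, activation = "selu",
                       window_length = 16L, n_channels = 2L) {
  model_config(n_channels = n_channels, window_length = window_length,
               n_classes = if (variant == "AE") NULL else n_classes,
               variant = variant, conv_filters = c(2L, 2L, 2L, 2L),
               latent_channels = 2L, activation = activation)
}

tiny_control <- function(max_epochs = 3L, seed = 1L, variant = "MCAE", ...) {
  w <- switch(variant, AE = c(1, 0), STL = c(0, 1), c(1, 1))
  train_config(max_epochs = max_epochs, seed = seed, loss_weights = w,
               batch_size = 64L, ...)
}

# Writes a small experiment YAML and returns its resolved config.
tiny_experiment_config <- function(..., seed = 1L) {
  over <- list(...)
  base <- list(
    dataset = list(source = "synthetic", n_subjects = 4L, sample_rate = 25,
                   n_channels = 2L, window_seconds = 0.64,
                   slide_value = 0.5, noise_sd = 0.1,
                   filter = list(butter_cutoff = 10)),
    model = list(variant = "MCAE", conv_filters = c(2L, 2L, 2L, 2L),
                 latent_channels = 2L),
    train = list(max_epochs = 2L, batch_size = 64L),
    seed = seed)
  cfg <- utils::modifyList(base, over)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  load_config(path)
}
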