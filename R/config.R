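config_defaults <- function() {
  list(
    dataset = list(source = "synthetic", n_subjects = 8L, test_fraction = 0.3,
                   val_fraction = 0.15, sample_rate = 50, n_channels = 6L,
                   window_seconds = 2.56, slide_mode = "stride_fraction",
                   slide_value = 0.5, channels = NULL, path = NULL,
                   sigma_amp = 0.2, sigma_freq = 0.1, noise_sd = 0.15,
                   filter = list(enabled = TRUE, median_kernel = 3L,
                                 butter_order = 3L, butter_cutoff = 20)),
    model = list(variant = "MCAE", conv_filters = c(8L, 8L, 8L, 8L),
                 kernel_size = 3L, latent_channels = 8L, activation = "selu",
                 fusion = "timestep", n_classes = NULL),
    train = list(learning_rate = 0.001, batch_size = 128L, max_epochs = 50L,
                 loss_weights = c(1, 1), huber_delta = 1, min_delta = 1e-4,
                 patience = 10L, restore_best = TRUE),
    output_dir = NULL, seed = 1L)
}

merge_block <- function(defaults, user, block) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L)
    stop(sprintf("unknown key(s) in '%s' block: %s", block,
                 paste(unknown, collapse = ", ")))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      defaults[[k]] <- merge_block(defaults[[k]], user[[k]],
                                   paste(block, k, sep = "."))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Path of a shipped experiment preset
#'
#' Presets encode the per-dataset windowing settings (window seconds, slide
#' mode and value, sampling rate) of the five benchmark configurations:
#' `ucihar`, `mhealth`, `pamap2`, `uschad`, `skiing`, plus the `synthetic`
#' benchmark default.
#'
#' @param name preset name.
#' @return path to the YAML file.
#' @export
preset_path <- function(name) {
  p <- system.file("presets", paste0(name, ".yaml"), package = "mcae")
  if (!nzchar(p)) {
    avail <- sub("\\.yaml$", "",
                 list.files(system.file("presets", package = "mcae")))
    stop(sprintf("no preset '%s'; available: %s", name,
                 paste(avail, collapse = ", ")))
  }
  p
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML (or JSON) experiment configuration with `dataset`, `model`
#' and `train` blocks, fills defaults, rejects unknown keys, resolves the
#' window length in samples ([window_samples()]) and runs cross-field
#' validation (Nyquist check on the filter cutoff; a cutoff at or above the
#' Nyquist frequency leaves the low-pass disabled with a warning).
#'
#' @param path path to a YAML/JSON file, or the name of a shipped preset
#'   (see [preset_path()]).
#' @return an object of class `experiment_config` with the resolved blocks
#'   and `window_length` (samples).
#' @export
load_config <- function(path) {
  if (!file.exists(path) && !grepl("[/\\\\.]", path)) path <- preset_path(path)
  user <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  defs <- config_defaults()
  top_unknown <- setdiff(names(user), names(defs))
  if (length(top_unknown) > 0L)
    stop("unknown top-level key(s): ", paste(top_unknown, collapse = ", "))
  cfg <- defs
  for (b in c("dataset", "model", "train"))
    cfg[[b]] <- merge_block(defs[[b]], user[[b]], b)
  if (!is.null(user$output_dir)) cfg$output_dir <- user$output_dir
  if (!is.null(user$seed)) cfg$seed <- as.integer(user$seed)

  ds <- cfg$dataset
  if (!ds$slide_mode %in% c("stride_fraction", "overlap_fraction"))
    stop("dataset.slide_mode must be 'stride_fraction' or 'overlap_fraction'")
  if (ds$slide_value <= 0 || ds$slide_value >= 1)
    stop("dataset.slide_value must lie in (0, 1)")
  cfg$window_length <- window_samples(ds$window_seconds, ds$sample_rate)
  if (isTRUE(ds$filter$enabled) && ds$filter$butter_cutoff >= ds$sample_rate / 2)
    warning(sprintf(paste0("filter cutoff %g Hz is not below the Nyquist ",
                           "frequency %g Hz; the low-pass stage will be skipped"),
                    ds$filter$butter_cutoff, ds$sample_rate / 2))
  if (!cfg$model$variant %in% c("AE", "STL", "MCAE", "CAE"))
    stop("model.variant must be one of AE, STL, MCAE, CAE")
  structure(cfg, class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> %s on %s data, T=%d (%g s @ %g Hz), seed %d\n",
              x$model$variant, x$dataset$source, x$window_length,
              x$dataset$window_seconds, x$dataset$sample_rate, x$seed))
  invisible(x)
}

# Small deterministic checksum of the resolved configuration (hex string).
config_checksum <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                        null = "null")
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261 %% 2147483647
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

spec_from_config <- function(cfg) {
  ds <- cfg$dataset
  base <- default_benchmark_spec(sigma_amp = ds$sigma_amp,
                                 sigma_freq = ds$sigma_freq,
                                 noise_sd = ds$noise_sd)
  synthetic_spec(base$archetypes, n_channels = ds$n_channels,
                 sample_rate = ds$sample_rate,
                 bout_seconds = base$bout_seconds,
                 bouts_per_class = base$bouts_per_class,
                 sigma_amp = ds$sigma_amp, sigma_freq = ds$sigma_freq,
                 noise_sd = ds$noise_sd, seed = cfg$seed)
}

config_splits <- function(cfg) {
  ds <- cfg$dataset
  fl <- ds$filter
  generate_dataset(spec_from_config(cfg), n_subjects = ds$n_subjects,
                   test_fraction = ds$test_fraction, seed = cfg$seed,
                   window_seconds = ds$window_seconds,
                   slide_value = ds$slide_value, slide_mode = ds$slide_mode,
                   filter = filter_config(fl$median_kernel, fl$butter_order,
                                          fl$butter_cutoff, fl$enabled),
                   val_fraction = ds$val_fraction)
}

config_model <- function(cfg, n_classes, variant = cfg$model$variant) {
  m <- cfg$model
  model_config(n_channels = cfg$dataset$n_channels,
               window_length = cfg$window_length,
               n_classes = if (variant == "AE") NULL else n_classes,
               variant = variant, conv_filters = m$conv_filters,
               kernel_size = m$kernel_size,
               latent_channels = m$latent_channels,
               activation = m$activation, fusion = m$fusion)
}

config_control <- function(cfg, seed = cfg$seed, variant = cfg$model$variant) {
  tr <- cfg$train
  w <- as.numeric(tr$loss_weights)
  if (variant == "AE") w <- c(w[1], 0)
  if (variant == "STL") w <- c(0, w[2])
  train_config(learning_rate = tr$learning_rate, batch_size = tr$batch_size,
               max_epochs = tr$max_epochs, loss_weights = w,
               huber_delta = tr$huber_delta, min_delta = tr$min_delta,
               patience = tr$patience, restore_best = tr$restore_best,
               seed = seed)
}

#' Run a full experiment from a configuration
#'
#' Chains the whole pipeline — generate (or load) recordings, preprocess
#' into subject-disjoint standardized splits, assemble the configured
#' variant, train, and evaluate on the unseen-subject test split — and
#' writes the artifact files to `out_dir`: the layer table, training
#' history, evaluation report, confusion matrix, per-channel/per-class
#' reconstruction RMSE, the 3-component latent PCA projection, and a
#' manifest with the seed, resolved configuration and headline metrics.
#' Rerunning with the same configuration and seed reproduces every artifact
#' byte for byte.
#'
#' @param cfg an [load_config()] object (or path/preset name).
#' @param out_dir artifact directory; defaults to `cfg$output_dir`, or no
#'   files are written when both are `NULL`.
#' @param verbose print epoch progress.
#' @return (invisibly) a list with `fit`, `report`, `rmse`, `latent_pca`,
#'   `manifest` and `out_dir`.
#' @export
run_experiment <- function(cfg, out_dir = NULL, verbose = FALSE) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  stopifnot(inherits(cfg, "experiment_config"))
  if (is.null(out_dir)) out_dir <- cfg$output_dir
  if (cfg$dataset$source != "synthetic")
    stop("only the synthetic source is supported by run_experiment(); ",
         "use read_recording()/read_presegmented_dir() for file-based data")
  splits <- config_splits(cfg)
  n_classes <- length(unique(c(splits$train$labels, splits$test$labels)))
  variant <- cfg$model$variant
  mcfg <- config_model(cfg, n_classes)
  ctl <- config_control(cfg)
  fit <- mcae(splits$train, splits$val, mcfg, ctl, verbose = verbose)

  report <- NULL; rmse <- NULL; per_class_rmse <- NULL
  if (variant != "AE") {
    pred <- predict(fit, splits$test, type = "class")
    report <- classification_report(splits$test$labels, pred, n_classes)
  }
  if (variant != "STL") {
    xh <- predict(fit, splits$test, type = "reconstruction")
    rmse <- reconstruction_rmse(splits$test$windows, xh)
    per_class_rmse <- vapply(sort(unique(splits$test$labels)), function(cl) {
      sel <- splits$test$labels == cl
      sqrt(mean((splits$test$windows[sel, , , drop = FALSE] -
                   xh[sel, , , drop = FALSE])^2))
    }, 1)
    names(per_class_rmse) <- sort(unique(splits$test$labels))
  }
  emb <- extract_latent(fit, splits$test)
  pca <- pca_project(emb, 3L)

  manifest <- list(seed = cfg$seed, config = unclass(cfg),
                   config_checksum = config_checksum(cfg),
                   n_parameters = count_trainable_parameters(fit$net),
                   epochs_run = fit$history$stop_epoch,
                   best_epoch = fit$history$best_epoch,
                   best_val_loss = fit$history$best_val_loss,
                   metrics = list(
                     test_accuracy = if (!is.null(report)) report$accuracy else NULL,
                     test_macro_f1 = if (!is.null(report)) unname(report$macro_avg["f1"]) else NULL,
                     test_rmse = if (!is.null(rmse)) rmse$overall else NULL))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fit$net$description, file.path(out_dir, "network_description.csv"),
                     row.names = FALSE)
    utils::write.csv(fit$history$epochs, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
    if (!is.null(report)) {
      utils::write.csv(report$per_class, file.path(out_dir, "report_per_class.csv"),
                       row.names = FALSE)
      jsonlite::write_json(list(accuracy = report$accuracy,
                                macro_avg = as.list(report$macro_avg),
                                weighted_avg = as.list(report$weighted_avg)),
                           file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA)
      utils::write.csv(as.data.frame(report$confusion),
                       file.path(out_dir, "confusion.csv"), row.names = FALSE)
    }
    if (!is.null(rmse)) {
      utils::write.csv(data.frame(channel = splits$test$channel_names,
                                  rmse = rmse$per_channel),
                       file.path(out_dir, "rmse_per_channel.csv"), row.names = FALSE)
      utils::write.csv(data.frame(class = names(per_class_rmse),
                                  rmse = per_class_rmse),
                       file.path(out_dir, "rmse_per_class.csv"), row.names = FALSE)
    }
    utils::write.csv(data.frame(pca$projection, label = emb$labels,
                                subject = emb$subject_ids),
                     file.path(out_dir, "latent_projection.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(list(fit = fit, report = report, rmse = rmse,
                 per_class_rmse = per_class_rmse, latent_pca = pca,
                 manifest = manifest, out_dir = out_dir))
}

#' Compare network variants on identical splits
#'
#' Trains each requested variant once per seed on the same subject-disjoint
#' splits (data fixed by `cfg$seed`; the training seed varies over `seeds`)
#' and reports the median unseen-subject macro-F1 together with the
#' trainable-parameter count of each variant.
#'
#' @param cfg an [load_config()] object (or path/preset name).
#' @param variants character vector of at least two classifier-bearing
#'   variants (`"STL"`, `"CAE"`, `"MCAE"`).
#' @param seeds integer vector of training seeds.
#' @param verbose print progress.
#' @return an object of class `variant_comparison`: data frame with one row
#'   per variant (`macro_f1` = median over seeds, `n_params`), with the
#'   per-seed results in `attr(, "runs")`.
#' @export
compare_variants <- function(cfg, variants = c("STL", "CAE", "MCAE"),
                             seeds = 1:3, verbose = FALSE) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  if (length(variants) < 1L) stop("need at least one variant")
  if (any(!variants %in% c("STL", "CAE", "MCAE")))
    stop("variants must be among STL, CAE, MCAE")
  splits <- config_splits(cfg)
  n_classes <- length(unique(c(splits$train$labels, splits$test$labels)))
  runs <- list()
  for (v in variants) {
    mcfg <- config_model(cfg, n_classes, variant = v)
    for (sd in seeds) {
      if (verbose) message(sprintf("variant %s, seed %d", v, sd))
      fit <- mcae(splits$train, splits$val, mcfg,
                  config_control(cfg, seed = sd, variant = v))
      pred <- predict(fit, splits$test, type = "class")
      rep <- classification_report(splits$test$labels, pred, n_classes)
      runs[[length(runs) + 1L]] <- data.frame(
        variant = v, seed = sd, macro_f1 = unname(rep$macro_avg["f1"]),
        accuracy = rep$accuracy,
        n_params = count_trainable_parameters(fit$net))
    }
  }
  runs <- do.call(rbind, runs)
  out <- do.call(rbind, lapply(split(runs, runs$variant), function(d)
    data.frame(variant = d$variant[1], macro_f1 = stats::median(d$macro_f1),
               n_params = d$n_params[1])))
  out <- out[match(intersect(variants, out$variant), out$variant), ]
  rownames(out) <- NULL
  attr(out, "runs") <- runs
  class(out) <- c("variant_comparison", "data.frame")
  out
}

#' @export
print.variant_comparison <- function(x, ...) {
  cat("Variant comparison (macro-F1 median over seeds, unseen subjects):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
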