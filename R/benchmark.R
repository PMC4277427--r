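# End-to-end benchmarks on the synthetic fixture. These fix the study
# conditions used throughout the package's tests and the reproduction
# script: the default fixture (3 classes, 16 x 16, sigma = 0.05, 12 images
# per class, half of them training) and a training configuration scaled to
# that fixture (see the methods vignette for the rationale).

#' Training configuration for the synthetic benchmarks
#'
#' The package's fixed study conditions for 16 x 16 fixture images: 60
#' full-batch epochs with patience 12, at most 13 hidden neurons (4
#' expansions), half the output neurons retained by pruning, and lateral
#' inhibition with radius 2 (the default radius 6 rescaled from 40 x 40 to
#' 16 x 16 images) and strength 17.
#'
#' @param seed Integer seed.
#' @param height,width Image dimensions.
#' @return A [train_config()].
#' @export
benchmark_config <- function(seed = 0L, height = 16L, width = 16L) {
  train_config(height, width,
               max_epochs = 60L, patience = 12L,
               validation_fraction = 0.25, seed = seed,
               n_max = 13L,
               r_keep = max(1L, floor(0.5 * height * width)),
               inhibition = inhibition_config(I = 2L, A = 17, enabled = TRUE))
}

#' Run the 3-class synthetic recognition benchmark
#'
#' Generates the default synthetic fixture under the given seed, trains a
#' full committee (constructive build plus pruning per class) on the
#' training split, and evaluates held-out accuracy on the test split.
#'
#' @param seed Integer seed driving both the fixture and the training.
#' @param spec Optional [synthetic_spec()] override.
#' @param config Optional [train_config()] override.
#' @return A list with `accuracy`, the [evaluate()] report, and the fitted
#'   committee.
#' @export
synthetic_benchmark <- function(seed = 0L,
                                spec = synthetic_spec(seed = seed),
                                config = benchmark_config(seed, spec$height, spec$width)) {
  protos <- make_prototypes(spec)
  ds <- sample_images(protos, spec)
  tr <- ds$split == "train"
  committee <- fit_committee(ds$images[tr], ds$labels[tr], config)
  report <- evaluate(committee, ds$images[!tr], ds$labels[!tr])
  list(accuracy = report$accuracy, report = report, committee = committee)
}

#' One-class separation benchmark
#'
#' Trains a single CANet on the training images of the first synthetic
#' class and compares its mean reconstruction dissimilarity on that class's
#' held-out images against the held-out images of the second class. A
#' working one-class model scores its own class strictly lower.
#'
#' @param seed Integer seed.
#' @param spec Optional [synthetic_spec()] override (needs >= 2 classes).
#' @param config Optional [train_config()] override.
#' @return A list with `within` and `between` mean dissimilarities and
#'   `separated` (`within < between`).
#' @export
separation_benchmark <- function(seed = 0L,
                                 spec = synthetic_spec(seed = seed),
                                 config = benchmark_config(seed, spec$height, spec$width)) {
  stopifnot(spec$n_classes >= 2)
  protos <- make_prototypes(spec)
  ds <- sample_images(protos, spec)
  lab <- names(protos)[1:2]
  tr_a <- ds$labels == lab[1] & ds$split == "train"
  te_a <- ds$labels == lab[1] & ds$split == "test"
  te_b <- ds$labels == lab[2] & ds$split == "test"
  imgs_a <- ds$images[tr_a]
  n_val <- max(1L, round(config$validation_fraction * length(imgs_a)))
  val_idx <- withr::with_seed(sub_seed(config$seed, 5001L),
                              sample(length(imgs_a), min(n_val, length(imgs_a) - 1L)))
  built <- build(imgs_a[-val_idx], imgs_a[val_idx], config)
  model <- prune(built$model, imgs_a[-val_idx], config$r_keep)
  within <- mean(vapply(ds$images[te_a], dissimilarity, numeric(1), model = model))
  between <- mean(vapply(ds$images[te_b], dissimilarity, numeric(1), model = model))
  list(within = within, between = between, separated = within < between)
}
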