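# Synthetic fixture generator: small labelled image classes with
# controllable separation, so the whole pipeline is testable without
# external face databases. Each class has a smooth prototype (a seeded
# mixture of Gaussian bumps plus one oriented sinusoidal grating,
# min-max-normalized to [0, 1]); images are the prototype plus independent
# per-pixel Gaussian noise, clipped to [0, 1].

#' Specification of a synthetic dataset
#'
#' @param n_classes Number of classes.
#' @param images_per_class Images drawn per class.
#' @param height,width Image dimensions.
#' @param sigma Per-pixel Gaussian noise standard deviation.
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @param train_fraction Fraction of each class assigned to the training
#'   split.
#' @return A list of class `canet_synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 3L, images_per_class = 12L,
                           height = 16L, width = 16L, sigma = 0.05,
                           seed = 0L, train_fraction = 0.5) {
  stopifnot(n_classes >= 1, images_per_class >= 1, height >= 1, width >= 1,
            sigma >= 0, train_fraction > 0, train_fraction < 1)
  structure(list(n_classes = as.integer(n_classes),
                 images_per_class = as.integer(images_per_class),
                 height = as.integer(height), width = as.integer(width),
                 sigma = sigma, seed = as.integer(seed),
                 train_fraction = train_fraction),
            class = "canet_synthetic_spec")
}

# One smooth prototype: 2-4 signed Gaussian bumps plus an oriented grating,
# min-max normalized into [0, 1]. Consumes the current RNG stream.
draw_prototype <- function(height, width) {
  u <- matrix(rep(seq(0, 1, length.out = max(height, 2L))[seq_len(height)], width),
              height, width)
  v <- matrix(rep(seq(0, 1, length.out = max(width, 2L))[seq_len(width)],
                  each = height), height, width)
  p <- matrix(0, height, width)
  for (b in seq_len(sample(2:4, 1))) {
    amp <- sample(c(-1, 1), 1) * runif(1, 0.5, 1)
    cu <- runif(1); cv <- runif(1); wd <- runif(1, 0.15, 0.35)
    p <- p + amp * exp(-((u - cu)^2 + (v - cv)^2) / (2 * wd^2))
  }
  theta <- runif(1, 0, pi); freq <- runif(1, 1, 3); phase <- runif(1, 0, 2 * pi)
  p <- p + 0.5 * sin(2 * pi * freq * (u * cos(theta) + v * sin(theta)) + phase)
  rng <- range(p)
  if (diff(rng) < 1e-12) return(p * 0 + 0.5)
  (p - rng[1]) / diff(rng)
}

#' Generate class prototypes
#'
#' Draws one smooth prototype per class under the spec's seed and redraws
#' the whole set (bounded number of retries) until every pair of prototypes
#' is separated by a mean absolute distance of at least `5 * sigma`, so that
#' classes are distinguishable above the pixel noise.
#'
#' @param spec A [synthetic_spec()].
#' @param max_retries Redraw budget before giving up.
#' @return A named list of H x W prototype matrices (`class1`, `class2`, ...).
#' @export
make_prototypes <- function(spec, max_retries = 50L) {
  stopifnot(inherits(spec, "canet_synthetic_spec"))
  min_sep <- 5 * spec$sigma
  for (attempt in seq_len(max_retries)) {
    protos <- withr::with_seed(
      sub_seed(spec$seed, attempt),
      lapply(seq_len(spec$n_classes), function(i) draw_prototype(spec$height, spec$width))
    )
    ok <- TRUE
    if (spec$n_classes > 1 && min_sep > 0) {
      for (i in seq_len(spec$n_classes - 1L)) {
        for (j in (i + 1L):spec$n_classes) {
          if (mean(abs(protos[[i]] - protos[[j]])) < min_sep) ok <- FALSE
        }
      }
    }
    if (ok) {
      names(protos) <- paste0("class", seq_len(spec$n_classes))
      return(protos)
    }
  }
  stop(sprintf("could not draw %d prototypes separated by %.3f in %d attempts",
               spec$n_classes, min_sep, max_retries))
}

#' Sample labelled images in memory
#'
#' Each image is its class prototype plus independent per-pixel Gaussian
#' noise of standard deviation `spec$sigma`, clipped to `[0, 1]`, with a
#' seeded per-class train/test split.
#'
#' @param prototypes Output of [make_prototypes()].
#' @param spec The [synthetic_spec()] used to generate the prototypes.
#' @return A list with `images` (list of matrices), `labels`, `split`
#'   (character vectors).
#' @export
sample_images <- function(prototypes, spec) {
  stopifnot(inherits(spec, "canet_synthetic_spec"))
  images <- list(); labels <- character(0); split <- character(0)
  n <- spec$images_per_class
  n_train <- min(n - (n > 1), max(1L, round(spec$train_fraction * n)))
  for (ci in seq_along(prototypes)) {
    proto <- prototypes[[ci]]
    imgs <- withr::with_seed(sub_seed(spec$seed, 1000L + ci), lapply(seq_len(n), function(k) {
      pmin(pmax(proto + matrix(rnorm(length(proto), sd = spec$sigma),
                               nrow(proto), ncol(proto)), 0), 1)
    }))
    tr_idx <- withr::with_seed(sub_seed(spec$seed, 2000L + ci), sample(n, n_train))
    sp <- rep("test", n); sp[tr_idx] <- "train"
    images <- c(images, imgs)
    labels <- c(labels, rep(names(prototypes)[ci], n))
    split <- c(split, sp)
  }
  list(images = images, labels = labels, split = split)
}

#' Write a synthetic dataset to disk
#'
#' Samples images as in [sample_images()], writes them as binary PGM files
#' under `out_dir`, and writes (and returns) the accompanying manifest.
#'
#' @param prototypes Output of [make_prototypes()].
#' @param spec The matching [synthetic_spec()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest data frame; also written to `manifest.csv` in
#'   `out_dir`.
#' @export
sample_dataset <- function(prototypes, spec, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop(sprintf("cannot create output directory %s", out_dir))
  }
  ds <- sample_images(prototypes, spec)
  n <- spec$images_per_class
  paths <- character(length(ds$images))
  for (k in seq_along(ds$images)) {
    fname <- sprintf("%s_img%03d.pgm", ds$labels[k], ((k - 1L) %% n) + 1L)
    paths[k] <- file.path(out_dir, fname)
    write_image(ds$images[[k]], paths[k])
  }
  manifest <- data.frame(path = paths, label = ds$labels, split = ds$split,
                         stringsAsFactors = FALSE)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

# Load a manifest's images from disk, returning the same shape as
# sample_images().
load_dataset <- function(manifest, base_dir = NULL) {
  paths <- manifest$path
  if (!is.null(base_dir)) {
    missing <- !file.exists(paths)
    paths[missing] <- file.path(base_dir, paths[missing])
  }
  list(images = lapply(paths, read_image),
       labels = manifest$label, split = manifest$split)
}
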