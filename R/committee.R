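# Multi-class recognition: one one-class CANet per class, reconstruction
# dissimilarity over the retained output neurons, minimum-distance decision.

#' Reconstruction dissimilarity
#'
#' Distance from an image to the class a model represents: the mean absolute
#' difference between the reconstructed and the input image over the
#' retained output neurons only. Zero iff the model reproduces the image
#' exactly on every retained pixel.
#'
#' @param model A trained (possibly pruned) `canet_model`.
#' @param image An H x W image matrix.
#' @return A non-negative scalar.
#' @export
dissimilarity <- function(model, image) {
  stopifnot(inherits(model, "canet_model"))
  fs <- forward(model, image)
  mean(abs(fs$outputs - image)[model$retained_mask])
}

#' Train a committee of one-class CANets
#'
#' For each class (in first-appearance order of `labels`), splits that
#' class's images into a training and a validation part with a seeded,
#' class-specific draw, runs the constructive [build()] on them, and prunes
#' the reconstruction layer to `config$r_keep` neurons using the class's
#' training images. Classes are trained independently of each other.
#'
#' @param images List of H x W image matrices.
#' @param labels Character vector of class labels, one per image.
#' @param config A [train_config()].
#' @return An object of class `canet_committee`: a named list of members in
#'   class order plus the shared dimensions.
#' @export
fit_committee <- function(images, labels, config) {
  stopifnot(inherits(config, "canet_config"),
            length(images) == length(labels), length(images) > 0)
  labels <- as.character(labels)
  classes <- unique(labels)
  members <- vector("list", length(classes))
  names(members) <- classes
  for (ci in seq_along(classes)) {
    idx <- which(labels == classes[ci])
    if (length(idx) == 0) stop(sprintf("class '%s' has no images", classes[ci]))
    tag <- label_tag(classes[ci])
    imgs <- images[idx]
    n <- length(imgs)
    n_val <- min(n - 1L, max(1L, round(config$validation_fraction * n)))
    if (n == 1L) {
      tr <- imgs; va <- imgs
    } else {
      val_idx <- withr::with_seed(sub_seed(config$seed, 2000000L + tag),
                                  sample(n, n_val))
      tr <- imgs[-val_idx]; va <- imgs[val_idx]
    }
    cls_config <- config
    cls_config$seed <- sub_seed(config$seed, tag)
    built <- build(tr, va, cls_config)
    members[[ci]] <- prune(built$model, tr, config$r_keep)
  }
  structure(list(members = members,
                 height = config$height, width = config$width),
            class = "canet_committee")
}

#' @export
print.canet_committee <- function(x, ...) {
  cat(sprintf("CANet committee: %d classes (%s), %d x %d images\n",
              length(x$members), paste(names(x$members), collapse = ", "),
              x$height, x$width))
  invisible(x)
}

#' Classify an image with a committee
#'
#' Evaluates the reconstruction dissimilarity of the image under every class
#' model and assigns the class with the minimum distance; exact ties go to
#' the class appearing first in committee order.
#'
#' @param committee A `canet_committee`.
#' @param image An H x W image matrix.
#' @return `list(label, distances)` with the full named distance vector.
#' @export
classify <- function(committee, image) {
  stopifnot(inherits(committee, "canet_committee"))
  d <- vapply(committee$members, dissimilarity, numeric(1), image = image)
  list(label = names(d)[which.min(d)], distances = d)
}

#' Evaluate a committee on labelled images
#'
#' @param committee A `canet_committee`.
#' @param images Non-empty list of test images.
#' @param labels True class labels; every label must have a committee member.
#' @return A list of class `canet_evaluation` with `accuracy`, `confusion`
#'   (row-normalized, rows = true classes present in the test set, columns =
#'   committee classes), `counts` (raw confusion counts), `predicted` and
#'   `distances` (one row per image).
#' @export
evaluate <- function(committee, images, labels) {
  stopifnot(inherits(committee, "canet_committee"),
            length(images) == length(labels), length(images) > 0)
  labels <- as.character(labels)
  classes <- names(committee$members)
  unknown <- setdiff(unique(labels), classes)
  if (length(unknown)) {
    stop(sprintf("label(s) absent from committee: %s",
                 paste(unknown, collapse = ", ")))
  }
  dist_mat <- matrix(NA_real_, length(images), length(classes),
                     dimnames = list(NULL, classes))
  predicted <- character(length(images))
  for (k in seq_along(images)) {
    res <- classify(committee, images[[k]])
    dist_mat[k, ] <- res$distances
    predicted[k] <- res$label
  }
  rows <- classes[classes %in% labels]
  counts <- matrix(0L, length(rows), length(classes),
                   dimnames = list(rows, classes))
  for (k in seq_along(images)) {
    counts[labels[k], predicted[k]] <- counts[labels[k], predicted[k]] + 1L
  }
  confusion <- counts / rowSums(counts)
  structure(list(accuracy = mean(predicted == labels),
                 confusion = confusion, counts = counts,
                 predicted = predicted, distances = dist_mat),
            class = "canet_evaluation")
}

#' @export
print.canet_evaluation <- function(x, ...) {
  cat(sprintf("CANet evaluation: accuracy %.3f over %d images\n",
              x$accuracy, length(x$predicted)))
  cat("Confusion matrix (rows = true, row-normalized):\n")
  print(round(x$confusion, 3))
  invisible(x)
}
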