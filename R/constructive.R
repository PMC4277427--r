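# Constructive-pruning architecture search: quadtree expansion of the hidden
# layer driven by the spread of the per-pixel reconstruction error, freeze-
# and-retrain after each expansion, validation-based snapshot selection, and
# output-layer pruning.

#' Split a region into four quadrants
#'
#' Quadtree division of a receptive field into four disjoint quadrants whose
#' union is the parent, ordered top-left, top-right, bottom-left,
#' bottom-right. For odd side lengths the first block takes the ceiling
#' (`ceiling(h/2)` rows, `ceiling(w/2)` columns).
#'
#' @param reg A [region()] with both sides >= 2.
#' @return A list of four regions.
#' @export
split_region <- function(reg) {
  stopifnot(inherits(reg, "canet_region"))
  if (region_height(reg) < 2 || region_width(reg) < 2) {
    stop("NonDivisible: region sides must both be >= 2 to split")
  }
  rm <- reg$r0 + as.integer(ceiling(region_height(reg) / 2))
  cm <- reg$c0 + as.integer(ceiling(region_width(reg) / 2))
  list(region(reg$r0, reg$c0, rm, cm),
       region(reg$r0, cm, rm, reg$c1),
       region(rm, reg$c0, reg$r1, cm),
       region(rm, cm, reg$r1, reg$c1))
}

# Per-output-pixel mean absolute reconstruction error over a set of images.
mean_error_surface <- function(model, images) {
  if (length(images) == 0) stop("empty image set")
  st <- model_structure(model)
  surf <- matrix(0, model$height, model$width)
  for (x in images) {
    check_image(model, x)
    fs <- forward_internal(model, x, st)
    surf <- surf + abs(fs$outputs - x)
  }
  surf / length(images)
}

#' Expansion scores of the hidden leaves
#'
#' For each hidden neuron, the spread (max minus min) of the per-output-pixel
#' mean error rate over its receptive field, computed on the given images.
#' The constructive loop expands the eligible leaf with the largest spread;
#' leaves whose region cannot be divided (either side of length 1) are
#' marked ineligible.
#'
#' @param model A trained `canet_model`.
#' @param images Non-empty list of images.
#' @return A data frame with columns `id`, `score`, `eligible`.
#' @export
selection_scores <- function(model, images) {
  stopifnot(inherits(model, "canet_model"))
  surf <- mean_error_surface(model, images)
  hid <- model$hidden[order(model$hidden$id), , drop = FALSE]
  score <- numeric(nrow(hid))
  eligible <- logical(nrow(hid))
  for (i in seq_len(nrow(hid))) {
    vals <- surf[(hid$r0[i] + 1L):hid$r1[i], (hid$c0[i] + 1L):hid$c1[i]]
    score[i] <- max(vals) - min(vals)
    eligible[i] <- (hid$r1[i] - hid$r0[i] >= 2L) && (hid$c1[i] - hid$c0[i] >= 2L)
  }
  data.frame(id = hid$id, score = score, eligible = eligible)
}

#' Expand one hidden leaf into four quadrant neurons
#'
#' The expanded neuron keeps the top-left quadrant together with its trained
#' output weight and bias; three new neurons take the remaining quadrants
#' with freshly seeded output weights and biases. The new neurons record the
#' expanded neuron's position (its region's top-left corner) as their parent
#' label. All four quadrant neurons are marked trainable; every other hidden
#' neuron is frozen, so that a subsequent [fit()] retrains only the
#' connections affected by the insertion.
#'
#' @param model A `canet_model`.
#' @param leaf_id Id of the hidden neuron to expand.
#' @param seed Integer seed for the new neurons' initializer.
#' @return The expanded model.
#' @export
expand_leaf <- function(model, leaf_id, seed = 0L) {
  stopifnot(inherits(model, "canet_model"))
  i <- match(leaf_id, model$hidden$id)
  if (is.na(i)) stop(sprintf("unknown leaf id %s", leaf_id))
  parent <- model$hidden[i, ]
  reg <- region(parent$r0, parent$c0, parent$r1, parent$c1)
  quads <- split_region(reg)   # errors with NonDivisible on 1-wide sides
  draws <- withr::with_seed(as.integer(seed), runif_weights(6L))

  model$hidden$frozen <- TRUE
  # parent keeps the top-left quadrant and its trained parameters
  model$hidden$r1[i] <- quads[[1]]$r1
  model$hidden$c1[i] <- quads[[1]]$c1
  model$hidden$frozen[i] <- FALSE
  next_id <- max(model$hidden$id)
  new_rows <- do.call(rbind, lapply(1:3, function(j) {
    q <- quads[[j + 1L]]
    data.frame(id = next_id + j, r0 = q$r0, c0 = q$c0, r1 = q$r1, c1 = q$c1,
               parent_r = parent$r0, parent_c = parent$c0,
               out_weight = draws[2 * j - 1], bias = draws[2 * j],
               frozen = FALSE)
  }))
  model$hidden <- rbind(model$hidden, new_rows)
  rownames(model$hidden) <- NULL
  model
}

# Trainable mask used after expanding `parent_region`: the four quadrant
# neurons (via frozen flags) plus the input-pixel weights inside the parent's
# original receptive field.
expansion_mask <- function(model, parent_region) {
  input <- matrix(FALSE, model$height, model$width)
  input[(parent_region$r0 + 1L):parent_region$r1,
        (parent_region$c0 + 1L):parent_region$c1] <- TRUE
  list(input = input, out_weight = !model$hidden$frozen,
       bias = !model$hidden$frozen)
}

#' Constructive training of a CANet
#'
#' Starts from a single hidden neuron fitted on all parameters, then
#' repeatedly scores the leaves on the training images, expands the eligible
#' leaf with the largest error spread (ties broken by smallest id), and
#' refits with only the affected connections trainable. The loop stops when
#' another expansion would exceed `n_max` hidden neurons or no leaf is
#' divisible. Returns the snapshot with the lowest validation error seen
#' along the way, regardless of its size.
#'
#' @param train_images Non-empty list of training images.
#' @param val_images List of validation images (may be `NULL`; see [fit()]).
#' @param config A [train_config()].
#' @return `list(model, trace)`; `trace` is a data frame with one row per
#'   fitted snapshot (`iteration`, `leaf_id`, `hidden_count`, `train_mae`,
#'   `val_mae`).
#' @export
build <- function(train_images, val_images = NULL, config) {
  stopifnot(inherits(config, "canet_config"))
  if (length(train_images) == 0) stop("empty training set")
  model <- init_model(config$height, config$width, config$inhibition,
                      seed = config$seed)
  fitted <- fit(model, train_images, val_images, config)
  model <- fitted$model
  snap_err <- function(m) {
    st <- model_structure(m)
    c(train = mean(mean_abs_error(m, train_images, st)),
      val = mean(mean_abs_error(m, if (length(val_images)) val_images else train_images, st)))
  }
  e <- snap_err(model)
  trace <- data.frame(iteration = 0L, leaf_id = NA_integer_,
                      hidden_count = 1L, train_mae = e[["train"]],
                      val_mae = e[["val"]])
  best <- list(model = model, val = e[["val"]])

  iteration <- 0L
  repeat {
    if (nrow(model$hidden) + 3L > config$n_max) break
    sc <- selection_scores(model, train_images)
    sc <- sc[sc$eligible, , drop = FALSE]
    if (nrow(sc) == 0) break
    # highest spread wins; ties go to the smallest id (scores are in id order)
    leaf <- sc$id[which.max(sc$score)]
    iteration <- iteration + 1L
    i <- match(leaf, model$hidden$id)
    parent_region <- region(model$hidden$r0[i], model$hidden$c0[i],
                            model$hidden$r1[i], model$hidden$c1[i])
    model <- expand_leaf(model, leaf, seed = sub_seed(config$seed, iteration))
    mask <- expansion_mask(model, parent_region)
    fitted <- fit(model, train_images, val_images, config, trainable_mask = mask)
    model <- fitted$model
    e <- snap_err(model)
    trace <- rbind(trace, data.frame(iteration = iteration, leaf_id = leaf,
                                     hidden_count = nrow(model$hidden),
                                     train_mae = e[["train"]],
                                     val_mae = e[["val"]]))
    if (e[["val"]] < best$val) best <- list(model = model, val = e[["val"]])
  }
  list(model = best$model, trace = trace)
}

#' Prune the reconstruction layer
#'
#' Computes the mean error rate of every output neuron over the training
#' images (mean absolute difference between its output and the target
#' pixel), keeps the `r_keep` neurons with the smallest rates (ties broken in
#' row-major pixel order), and records the survivors in the model's retained
#' mask. Weights are untouched; the mask only restricts which pixels enter
#' the dissimilarity measure.
#'
#' @param model A trained `canet_model`.
#' @param train_images The images the model was trained on.
#' @param r_keep Number of output neurons to retain (1..H*W).
#' @return The model with an updated `retained_mask`.
#' @export
prune <- function(model, train_images, r_keep) {
  stopifnot(inherits(model, "canet_model"))
  n_px <- model$height * model$width
  if (length(r_keep) != 1 || r_keep < 1 || r_keep > n_px) {
    stop(sprintf("r_keep must be in 1..%d", n_px))
  }
  surf <- mean_error_surface(model, train_images)
  model$retained_mask <- retain_smallest(surf, as.integer(r_keep))
  model
}

# Selection core of the pruning rule, exposed separately so it can be checked
# against a brute-force oracle on arbitrary error surfaces.
retain_smallest <- function(surface, r_keep) {
  H <- nrow(surface); W <- ncol(surface)
  row_major <- as.vector(t(matrix(seq_len(H * W), W, H)))  # rm index per col-major cell
  ord <- order(as.vector(surface), row_major)
  mask <- rep(FALSE, H * W)
  mask[ord[seq_len(r_keep)]] <- TRUE
  matrix(mask, H, W)
}
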