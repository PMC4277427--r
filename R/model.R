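# Core data model: regions, inhibition config, the CANet container, and the
# deterministic forward pass.
#
# Conventions used throughout the package:
#   * images are plain numeric H x W matrices with intensities in [0, 1],
#     row 1 = top image row (0-based coordinates appear only inside regions);
#   * regions are 0-based half-open rectangles [r0, r1) x [c0, c1);
#   * the hidden layer is a set of quadtree leaves whose receptive fields
#     tile the grid exactly, with identical footprints in the input and
#     reconstruction (output) layers.

#' Construct a receptive-field region
#'
#' A region is a 0-based half-open rectangle `[r0, r1) x [c0, c1)` used as the
#' receptive field of a hidden neuron in both the input and reconstruction
#' layers.
#'
#' @param r0,c0 Top-left corner (0-based, inclusive).
#' @param r1,c1 Bottom-right corner (0-based, exclusive).
#' @return A list of class `canet_region`.
#' @export
region <- function(r0, c0, r1, c1) {
  stopifnot(length(r0) == 1, length(c0) == 1, length(r1) == 1, length(c1) == 1)
  if (r0 < 0 || c0 < 0 || r0 >= r1 || c0 >= c1) {
    stop("invalid region: need 0 <= r0 < r1 and 0 <= c0 < c1")
  }
  structure(list(r0 = as.integer(r0), c0 = as.integer(c0),
                 r1 = as.integer(r1), c1 = as.integer(c1)),
            class = "canet_region")
}

region_height <- function(reg) reg$r1 - reg$r0
region_width <- function(reg) reg$c1 - reg$c0

#' Lateral-inhibition configuration
#'
#' The reconstruction layer can receive, at each pixel, an inhibitory stimulus
#' from the surrounding output neurons: the mean excitatory stimulus over the
#' square neighborhood of Chebyshev radius `I` (self excluded, truncated at
#' image borders), scaled by `1/A`. Larger `A` therefore means weaker
#' inhibition, and `enabled = FALSE` is the `A -> Inf` limit.
#'
#' @param I Inhibitory field radius in pixels (non-negative integer).
#' @param A Inhibition strength divisor (positive).
#' @param enabled Logical; `FALSE` disables the inhibitory term entirely.
#' @return A list of class `canet_inhibition`.
#' @export
inhibition_config <- function(I = 6L, A = 17, enabled = TRUE) {
  if (length(I) != 1 || I < 0 || I != floor(I)) stop("I must be a non-negative integer")
  if (length(A) != 1 || !is.finite(A) || A <= 0) stop("A must be positive")
  structure(list(I = as.integer(I), A = as.numeric(A), enabled = isTRUE(enabled)),
            class = "canet_inhibition")
}

# Seeded weight/bias initializer: uniform on [-0.1, 0.1]. The scale is fixed
# package-wide so that saved models are self-describing.
init_weight_scale <- 0.1

runif_weights <- function(n) runif(n, min = -init_weight_scale, max = init_weight_scale)

#' Initialize a CANet with a single hidden neuron
#'
#' The starting architecture of the constructive algorithm: one hidden neuron
#' whose receptive field covers the whole grid, all input-pixel weights and
#' the neuron's output weight and bias drawn uniformly from \[-0.1, 0.1\]
#' under the given seed, and all output neurons retained.
#'
#' @param height,width Image dimensions (>= 1).
#' @param inhibition An [inhibition_config()].
#' @param seed Integer seed for the weight initializer.
#' @return An object of class `canet_model`.
#' @export
init_model <- function(height, width, inhibition = inhibition_config(enabled = FALSE),
                       seed = 0L) {
  if (length(height) != 1 || length(width) != 1 || height < 1 || width < 1) {
    stop("height and width must be positive")
  }
  height <- as.integer(height); width <- as.integer(width)
  stopifnot(inherits(inhibition, "canet_inhibition"))
  draws <- withr::with_seed(as.integer(seed), runif_weights(height * width + 2L))
  model <- structure(list(
    height = height,
    width = width,
    input_weights = matrix(draws[seq_len(height * width)], height, width),
    hidden = data.frame(
      id = 1L, r0 = 0L, c0 = 0L, r1 = height, c1 = width,
      parent_r = NA_integer_, parent_c = NA_integer_,
      out_weight = draws[height * width + 1L],
      bias = draws[height * width + 2L],
      frozen = FALSE
    ),
    inhibition = inhibition,
    retained_mask = matrix(TRUE, height, width),
    activation = "sigmoid",
    meta = list(seed = as.integer(seed))
  ), class = "canet_model")
  model
}

#' @export
print.canet_model <- function(x, ...) {
  cat(sprintf("CANet model: %d x %d image, %d hidden neuron(s), %d/%d output neurons retained\n",
              x$height, x$width, nrow(x$hidden), sum(x$retained_mask),
              x$height * x$width))
  inh <- x$inhibition
  cat(sprintf("  lateral inhibition: %s (I = %d, A = %g)\n",
              if (inh$enabled) "enabled" else "disabled", inh$I, inh$A))
  invisible(x)
}

#' Receptive-field regions of the hidden layer
#'
#' @param model A `canet_model`.
#' @return A data frame with one row per hidden neuron, in stable id order,
#'   giving the 0-based half-open bounds `r0, c0, r1, c1` of its receptive
#'   field.
#' @export
leaf_regions <- function(model) {
  stopifnot(inherits(model, "canet_model"))
  h <- model$hidden[order(model$hidden$id), , drop = FALSE]
  data.frame(id = h$id, r0 = h$r0, c0 = h$c0, r1 = h$r1, c1 = h$c1,
             row.names = NULL)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# d(sigmoid)/dz expressed through the output value y = sigmoid(z)
sigmoid_deriv <- function(y) y * (1 - y)

# H x W matrix giving, for each pixel, the row index (into model$hidden) of
# the hidden neuron whose receptive field covers it. Errors if the regions do
# not tile the grid exactly.
owner_matrix <- function(model) {
  H <- model$height; W <- model$width
  owner <- matrix(0L, H, W)
  hid <- model$hidden
  for (i in seq_len(nrow(hid))) {
    rows <- (hid$r0[i] + 1L):hid$r1[i]
    cols <- (hid$c0[i] + 1L):hid$c1[i]
    if (any(owner[rows, cols] != 0L)) stop("hidden regions overlap")
    owner[rows, cols] <- i
  }
  if (any(owner == 0L)) stop("hidden regions do not cover the grid")
  owner
}

# Sum of M over the square Chebyshev-radius-I window centered at each entry
# (window truncated at the borders), via a padded summed-area table.
box_sum <- function(M, I) {
  H <- nrow(M); W <- ncol(M)
  P <- matrix(0, H + 1L, W + 1L)
  P[-1L, -1L] <- t(apply(apply(M, 2L, cumsum), 1L, cumsum))
  lo_r <- pmax(seq_len(H) - I, 1L); hi_r <- pmin(seq_len(H) + I, H)
  lo_c <- pmax(seq_len(W) - I, 1L); hi_c <- pmin(seq_len(W) + I, W)
  P[hi_r + 1L, hi_c + 1L] - P[lo_r, hi_c + 1L] - P[hi_r + 1L, lo_c] + P[lo_r, lo_c]
}

# Number of in-bounds neighbors (self excluded) in each pixel's inhibitory
# window.
neighbor_counts <- function(H, W, I) {
  nr <- pmin(seq_len(H) + I, H) - pmax(seq_len(H) - I, 1L) + 1L
  nc <- pmin(seq_len(W) + I, W) - pmax(seq_len(W) - I, 1L) + 1L
  outer(nr, nc) - 1L
}

# Precomputed per-architecture quantities reused across forward/backward
# passes while the parameters change but the structure does not.
model_structure <- function(model) {
  inh <- model$inhibition
  use_inh <- inh$enabled && inh$I > 0L
  cnt <- if (use_inh) neighbor_counts(model$height, model$width, inh$I) else NULL
  list(owner = owner_matrix(model), use_inh = use_inh,
       I = inh$I, A = inh$A,
       cnt = if (use_inh) pmax(cnt, 1L) else NULL,
       zero_nb = if (use_inh) cnt == 0L else NULL)
}

check_image <- function(model, image) {
  if (!is.matrix(image) || !is.numeric(image)) stop("image must be a numeric matrix")
  if (nrow(image) != model$height || ncol(image) != model$width) {
    stop(sprintf("image is %d x %d but the model expects %d x %d",
                 nrow(image), ncol(image), model$height, model$width))
  }
  if (any(!is.finite(image)) || any(image < 0) || any(image > 1)) {
    stop("image intensities must be finite and in [0, 1]")
  }
  invisible(TRUE)
}

# Internal forward pass against a precomputed structure; no validation.
forward_internal <- function(model, image, st) {
  hid <- model$hidden
  zc <- hid$bias +
    as.vector(rowsum(as.vector(model$input_weights * image), as.vector(st$owner)))
  yc <- sigmoid(zc)
  e <- matrix((hid$out_weight * yc)[st$owner], model$height, model$width)
  if (st$use_inh) {
    h <- (box_sum(e, st$I) - e) / st$cnt / st$A
    if (any(st$zero_nb)) h[st$zero_nb] <- 0
  } else {
    h <- matrix(0, model$height, model$width)
  }
  zo <- e - h
  list(hidden_inputs = zc, hidden_outputs = yc, excitatory = e,
       inhibitory = h, output_inputs = zo, outputs = sigmoid(zo))
}

#' Forward pass of a CANet
#'
#' Computes, in one feed-forward sweep: the weighted-sum input and sigmoid
#' output of every hidden neuron over its receptive field; the excitatory
#' stimulus of every output pixel (the covering hidden neuron's output times
#' its output weight — constant within a receptive field, since output
#' neurons carry no bias); the inhibitory stimulus (mean neighboring
#' excitatory stimulus scaled by `1/A`); and the reconstructed image, the
#' sigmoid of excitatory minus inhibitory stimulus.
#'
#' @param model A `canet_model`.
#' @param image Numeric `height x width` matrix in `[0, 1]`.
#' @return A list of class `canet_forward` with elements `hidden_inputs`,
#'   `hidden_outputs` (per hidden neuron), `excitatory`, `inhibitory`,
#'   `output_inputs`, `outputs` (H x W matrices).
#' @export
forward <- function(model, image) {
  stopifnot(inherits(model, "canet_model"))
  check_image(model, image)
  st <- model_structure(model)
  structure(forward_internal(model, image, st), class = "canet_forward")
}

# Parameter pack used by the trainer and the serializer: everything that
# gradient descent touches, in fixed shapes.
get_params <- function(model) {
  list(input = model$input_weights,
       out_weight = model$hidden$out_weight,
       bias = model$hidden$bias)
}

set_params <- function(model, params) {
  model$input_weights <- params$input
  model$hidden$out_weight <- params$out_weight
  model$hidden$bias <- params$bias
  model
}
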