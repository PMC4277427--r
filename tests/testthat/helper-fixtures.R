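# Shared fixture builders. Everything is generated in code under fixed
# seeds; no binary data is stored.

rand_image <- function(h, w, seed = NULL) {
  draw <- function() matrix(runif(h * w), h, w)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# A seeded model, optionally grown by a few random (eligible) expansions and
# fully unfrozen so gradient checks cover every parameter.
rand_model <- function(h, w, inhibition = inhibition_config(enabled = FALSE),
                       n_expansions = 0, seed = 0) {
  model <- init_model(h, w, inhibition, seed = seed)
  k <- 0
  while (k < n_expansions) {
    hid <- model$hidden
    eligible <- hid$id[(hid$r1 - hid$r0 >= 2) & (hid$c1 - hid$c0 >= 2)]
    if (length(eligible) == 0) break
    pick <- withr::with_seed(seed + 100 + k, sample(length(eligible), 1))
    model <- expand_leaf(model, eligible[pick], seed = seed + 200 + k)
    k <- k + 1
  }
  model$hidden$frozen <- FALSE
  model
}

# Independent coverage oracle: how many hidden regions cover each pixel.
coverage_counts <- function(model) {
  cov <- matrix(0L, model$height, model$width)
  regs <- leaf_regions(model)
  for (i in seq_len(nrow(regs))) {
    rows <- (regs$r0[i] + 1):regs$r1[i]
    cols <- (regs$c0[i] + 1):regs$c1[i]
    cov[rows, cols] <- cov[rows, cols] + 1L
  }
  cov
}

# Largest relative disagreement between analytic and central-difference
# gradients over every parameter of the model.
max_grad_mismatch <- function(model, images, epsilon = 1e-5) {
  grads <- batch_gradients(model, images)
  worst <- 0
  for (type in c("input", "out_weight", "bias")) {
    n <- if (type == "input") length(model$input_weights) else nrow(model$hidden)
    for (i in seq_len(n)) {
      a <- if (type == "input") grads$input[i] else grads[[type]][i]
      num <- numeric_gradient(model, images, list(type = type, index = i), epsilon)
      worst <- max(worst, abs(a - num) / max(abs(a), abs(num), 1e-6))
    }
  }
  worst
}

# A tiny training configuration for fast unit tests.
tiny_config <- function(h = 8, w = 8, seed = 1, ...) {
  train_config(h, w, max_epochs = 25L, patience = 8L, seed = seed,
               n_max = 7L, r_keep = max(1L, floor(0.5 * h * w)),
               inhibition = inhibition_config(I = 1L, A = 17, enabled = TRUE),
               ...)
}

# A (model, image) pair with exactly zero reconstruction error. With all
# input weights zero the reconstruction is independent of the input, so the
# model's own (constant) output is a fixed point of the autoassociation.
perfect_pair <- function(model) {
  model$input_weights[] <- 0
  x <- forward(model, matrix(0.5, model$height, model$width))$outputs
  list(model = model, x = x)
}
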