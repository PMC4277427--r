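# Training: error backpropagation through the inhibited reconstruction layer,
# full-batch gradient assembly, resilient propagation (RProp) updates, and the
# fitting loop with validation-based early stopping.
#
# The loss is E = 1/2 * sum over pixels of (y^O - x)^2, summed over the batch;
# mean absolute reconstruction error (MAE) is used only for monitoring and
# model selection.

#' Training configuration
#'
#' Collects every tunable of the fitting and constructive loops. Defaults
#' follow the parameter study of the underlying method: at most ~25% as many
#' hidden as input neurons, half the output neurons retained by pruning, and
#' an inhibitory field of radius 6 with strength 17.
#'
#' @param height,width Image dimensions the configuration applies to.
#' @param max_epochs Maximum full-batch RProp epochs per fit.
#' @param patience Epochs without validation MAE improvement before stopping.
#' @param validation_fraction Fraction of a class's images held out for
#'   validation when no explicit validation set is given.
#' @param seed Integer seed controlling initialization and data splits.
#' @param n_max Maximum number of hidden neurons the constructive loop may
#'   reach (default: 25% of the pixel count).
#' @param r_keep Number of output neurons kept by pruning (default: 50% of
#'   the pixel count).
#' @param inhibition An [inhibition_config()].
#' @param eta_plus,eta_minus RProp step-size increase/decrease factors.
#' @param delta0,delta_min,delta_max Initial, minimum and maximum RProp step
#'   sizes.
#' @return A list of class `canet_config`.
#' @export
train_config <- function(height, width,
                         max_epochs = 200L, patience = 20L,
                         validation_fraction = 0.25, seed = 0L,
                         n_max = max(1L, ceiling(0.25 * height * width)),
                         r_keep = max(1L, floor(0.5 * height * width)),
                         inhibition = inhibition_config(),
                         eta_plus = 1.2, eta_minus = 0.5,
                         delta0 = 0.1, delta_min = 1e-6, delta_max = 50) {
  stopifnot(height >= 1, width >= 1, max_epochs >= 1, patience >= 1,
            validation_fraction > 0, validation_fraction < 1,
            n_max >= 1, r_keep >= 1, r_keep <= height * width,
            eta_plus > 1, eta_minus > 0, eta_minus < 1,
            delta0 > 0, delta_min > 0, delta_min <= delta_max)
  structure(list(height = as.integer(height), width = as.integer(width),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed),
                 n_max = as.integer(n_max), r_keep = as.integer(r_keep),
                 inhibition = inhibition,
                 rprop = list(eta_plus = eta_plus, eta_minus = eta_minus,
                              delta0 = delta0, delta_min = delta_min,
                              delta_max = delta_max)),
            class = "canet_config")
}

# Deterministic derived seeds kept below 2^31 (Lehmer step on the base seed).
sub_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 48271 + 16807 * as.numeric(tag) + 1) %% 2147483647)
}

# Order-independent numeric tag for a class label, so that per-class seeds
# depend on the label itself and not on its position in the training set.
label_tag <- function(label) {
  Reduce(function(a, b) (a * 31 + b) %% 1048576, utf8ToInt(label), 7)
}

#' Error sensitivities of one image
#'
#' Backpropagates the reconstruction error through the laterally inhibited
#' output layer. `err` is the raw image error `y^O - x`; `delta_out` applies
#' the sigmoid derivative at the output input; `same_layer` is the
#' sensitivity of the excitatory stimulus, i.e. `delta_out` minus the
#' transpose of the inhibition coupling applied to `delta_out`; and
#' `delta_hidden` accumulates `same_layer` times the output weight over each
#' hidden region, times the sigmoid derivative at the hidden input.
#'
#' @param model A `canet_model`.
#' @param image The input (and target) image.
#' @param fstate The result of `forward(model, image)`.
#' @return A list of class `canet_sensitivities` with elements `err`,
#'   `delta_out`, `same_layer` (all H x W) and `delta_hidden` (per hidden
#'   neuron).
#' @export
sensitivities <- function(model, image, fstate) {
  stopifnot(inherits(model, "canet_model"))
  check_image(model, image)
  st <- model_structure(model)
  structure(sensitivities_internal(model, image, fstate, st),
            class = "canet_sensitivities")
}

sensitivities_internal <- function(model, image, fstate, st) {
  err <- fstate$outputs - image
  delta_out <- err * sigmoid_deriv(fstate$outputs)
  if (st$use_inh) {
    q <- delta_out / st$cnt
    tr <- box_sum(q, st$I) - q
    if (any(st$zero_nb)) tr[st$zero_nb] <- 0
    same_layer <- delta_out - tr / st$A
  } else {
    same_layer <- delta_out
  }
  s_region <- as.vector(rowsum(as.vector(same_layer), as.vector(st$owner)))
  delta_hidden <- sigmoid_deriv(fstate$hidden_outputs) *
    model$hidden$out_weight * s_region
  list(err = err, delta_out = delta_out, same_layer = same_layer,
       delta_hidden = delta_hidden, region_sums = s_region)
}

#' Full-batch error gradients
#'
#' Gradients of the half-sum-of-squares reconstruction loss, summed over the
#' batch: per input-pixel weight (hidden sensitivity of the covering neuron
#' times the pixel value), per hidden output weight (hidden output times the
#' excitatory sensitivity summed over the region), and per hidden bias (the
#' hidden sensitivity itself).
#'
#' @param model A `canet_model`.
#' @param images List of H x W image matrices (non-empty).
#' @return A list of class `canet_gradients` with elements `input`
#'   (H x W matrix), `out_weight` and `bias` (per hidden neuron).
#' @export
batch_gradients <- function(model, images) {
  stopifnot(inherits(model, "canet_model"))
  if (length(images) == 0) stop("empty image batch")
  st <- model_structure(model)
  acc <- batch_pass(model, images, st)
  structure(acc$grads, class = "canet_gradients")
}

# One sweep over the batch: accumulated gradients plus per-image MAE.
batch_pass <- function(model, images, st) {
  g_in <- matrix(0, model$height, model$width)
  g_w <- numeric(nrow(model$hidden))
  g_b <- numeric(nrow(model$hidden))
  mae <- numeric(length(images))
  for (k in seq_along(images)) {
    x <- images[[k]]
    check_image(model, x)
    fs <- forward_internal(model, x, st)
    sn <- sensitivities_internal(model, x, fs, st)
    g_w <- g_w + fs$hidden_outputs * sn$region_sums
    g_b <- g_b + sn$delta_hidden
    g_in <- g_in + matrix(sn$delta_hidden[st$owner], model$height, model$width) * x
    mae[k] <- mean(abs(sn$err))
  }
  list(grads = list(input = g_in, out_weight = g_w, bias = g_b), mae = mae)
}

#' Central-difference numeric gradient (testing oracle)
#'
#' Perturbs a single scalar parameter and differentiates the total
#' half-sum-of-squares reconstruction loss over the batch numerically.
#'
#' @param model A `canet_model`.
#' @param images List of image matrices.
#' @param parameter_id A list `list(type, index)` with `type` one of
#'   `"input"`, `"out_weight"`, `"bias"`; for `"input"`, `index` is the
#'   column-major position in the weight matrix.
#' @param epsilon Perturbation half-width.
#' @return The estimated derivative (a scalar).
#' @export
numeric_gradient <- function(model, images, parameter_id, epsilon = 1e-5) {
  stopifnot(is.list(parameter_id),
            parameter_id$type %in% c("input", "out_weight", "bias"))
  idx <- parameter_id$index
  n_ok <- switch(parameter_id$type,
                 input = length(model$input_weights),
                 out_weight = nrow(model$hidden),
                 bias = nrow(model$hidden))
  if (!(is.numeric(idx) && length(idx) == 1 && idx >= 1 && idx <= n_ok)) {
    stop("unknown parameter id")
  }
  st <- model_structure(model)
  loss_at <- function(m) {
    tot <- 0
    for (x in images) {
      fs <- forward_internal(m, x, st)
      tot <- tot + 0.5 * sum((fs$outputs - x)^2)
    }
    tot
  }
  bump <- function(m, h) {
    if (parameter_id$type == "input") m$input_weights[idx] <- m$input_weights[idx] + h
    if (parameter_id$type == "out_weight") m$hidden$out_weight[idx] <- m$hidden$out_weight[idx] + h
    if (parameter_id$type == "bias") m$hidden$bias[idx] <- m$hidden$bias[idx] + h
    m
  }
  (loss_at(bump(model, epsilon)) - loss_at(bump(model, -epsilon))) / (2 * epsilon)
}

#' Initialize an RProp optimizer state
#'
#' @param model A `canet_model`.
#' @param rprop List of RProp constants as in [train_config()]`$rprop`.
#' @return A list of class `canet_rprop` holding per-parameter step sizes and
#'   previous-gradient memory.
#' @export
rprop_init <- function(model, rprop = train_config(model$height, model$width)$rprop) {
  shapes <- get_params(model)
  zero_like <- function(p) p * 0
  d0 <- function(p) p * 0 + rprop$delta0
  structure(list(delta = lapply(shapes, d0),
                 prev = lapply(shapes, zero_like),
                 const = rprop),
            class = "canet_rprop")
}

#' One RProp update step
#'
#' Resilient propagation with per-parameter adaptive step sizes, in the
#' variant without weight backtracking: if the gradient keeps its sign the
#' step size grows by `eta_plus` (capped at `delta_max`) and the parameter
#' moves by `-sign(grad) * delta`; if the sign flips the step size shrinks by
#' `eta_minus` (floored at `delta_min`), the stored gradient is cleared and
#' no step is taken this iteration; a zero gradient leaves step size and
#' parameter unchanged. Frozen (masked) parameters are untouched, including
#' their optimizer state.
#'
#' @param model A `canet_model`.
#' @param grads A `canet_gradients` (or list with the same shapes).
#' @param state A `canet_rprop` state.
#' @param trainable_mask List with logical `input`, `out_weight`, `bias`
#'   matching the parameter shapes; `NULL` means all trainable except hidden
#'   neurons flagged `frozen`.
#' @return `list(model, state)` with updated parameters and optimizer state.
#' @export
rprop_update <- function(model, grads, state, trainable_mask = NULL) {
  mask <- resolve_mask(model, trainable_mask)
  params <- get_params(model)
  cst <- state$const
  for (nm in names(params)) {
    m <- as.vector(mask[[nm]])
    if (length(m) != length(params[[nm]])) stop("mask shape mismatch")
    g <- as.vector(grads[[nm]])
    p <- as.vector(state$prev[[nm]])
    d <- as.vector(state$delta[[nm]])
    w <- as.vector(params[[nm]])
    sgn_prod <- p * g
    grow <- m & (sgn_prod > 0)
    shrink <- m & (sgn_prod < 0)
    d[grow] <- pmin(d[grow] * cst$eta_plus, cst$delta_max)
    d[shrink] <- pmax(d[shrink] * cst$eta_minus, cst$delta_min)
    g_eff <- g
    g_eff[shrink] <- 0   # cleared memory: no step on a sign flip
    w[m] <- w[m] - sign(g_eff[m]) * d[m]
    p[m] <- g_eff[m]
    dim_ref <- params[[nm]]
    params[[nm]] <- `dim<-`(w, dim(dim_ref))
    state$prev[[nm]] <- `dim<-`(p, dim(dim_ref))
    state$delta[[nm]] <- `dim<-`(d, dim(dim_ref))
  }
  list(model = set_params(model, params), state = state)
}

# Default trainable mask honoring per-neuron frozen flags. An explicit mask
# is still intersected with the frozen flags so that frozen parameters can
# never move.
resolve_mask <- function(model, trainable_mask) {
  unfrozen <- !model$hidden$frozen
  if (is.null(trainable_mask)) {
    trainable_mask <- list(input = matrix(TRUE, model$height, model$width),
                           out_weight = unfrozen, bias = unfrozen)
  }
  trainable_mask$out_weight <- trainable_mask$out_weight & unfrozen
  trainable_mask$bias <- trainable_mask$bias & unfrozen
  trainable_mask
}

mean_abs_error <- function(model, images, st) {
  vapply(images, function(x) {
    fs <- forward_internal(model, x, st)
    mean(abs(fs$outputs - x))
  }, numeric(1))
}

#' Fit a CANet with full-batch RProp
#'
#' Runs full-batch RProp epochs until `max_epochs` or until `patience`
#' epochs pass without improvement of the validation mean absolute
#' reconstruction error, then restores the parameters that achieved the best
#' validation error. Deterministic given the model, data and configuration.
#'
#' @param model A `canet_model`.
#' @param train_images Non-empty list of training images.
#' @param val_images List of validation images; if `NULL` or empty the
#'   training images are used for monitoring.
#' @param config A [train_config()].
#' @param trainable_mask Optional mask as in [rprop_update()].
#' @return `list(model, history)` where `history` is a data frame with one
#'   row per epoch (epoch 0 = initial state) of train/validation MAE.
#' @export
fit <- function(model, train_images, val_images = NULL, config, trainable_mask = NULL) {
  stopifnot(inherits(model, "canet_model"), inherits(config, "canet_config"))
  if (length(train_images) == 0) stop("empty training set")
  if (is.null(val_images) || length(val_images) == 0) val_images <- train_images
  mask <- resolve_mask(model, trainable_mask)
  st <- model_structure(model)
  any_trainable <- any(mask$input) || any(mask$out_weight) || any(mask$bias)

  val_mae <- mean(mean_abs_error(model, val_images, st))
  train_mae <- mean(mean_abs_error(model, train_images, st))
  history <- data.frame(epoch = 0L, train_mae = train_mae, val_mae = val_mae)
  best <- list(params = get_params(model), val = val_mae)
  if (!any_trainable) {
    return(list(model = model, history = history))
  }

  state <- rprop_init(model, config$rprop)
  since_best <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    bp <- batch_pass(model, train_images, st)
    upd <- rprop_update(model, bp$grads, state, mask)
    model <- upd$model; state <- upd$state
    train_mae <- mean(mean_abs_error(model, train_images, st))
    val_mae <- mean(mean_abs_error(model, val_images, st))
    history <- rbind(history, data.frame(epoch = epoch, train_mae = train_mae,
                                         val_mae = val_mae))
    if (val_mae < best$val) {
      best <- list(params = get_params(model), val = val_mae)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience) break
    }
  }
  list(model = set_params(model, best$params), history = history)
}
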