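# Backpropagation, gradient assembly, RProp, and the fitting loop.

test_that("perfect reconstruction yields zero sensitivities and gradients", {
  pp <- perfect_pair(rand_model(6, 6, inhibition_config(I = 1, A = 5, enabled = TRUE),
                                n_expansions = 1, seed = 2))
  m <- pp$model; x <- pp$x
  fs <- forward(m, x)
  sn <- sensitivities(m, x, fs)
  expect_true(all(sn$err == 0))
  expect_true(all(sn$delta_out == 0))
  expect_true(all(sn$same_layer == 0))
  expect_true(all(sn$delta_hidden == 0))
  g <- batch_gradients(m, list(x))
  expect_true(all(g$input == 0) && all(g$out_weight == 0) && all(g$bias == 0))
})

test_that("without inhibition the output sensitivity is the plain autoassociator rule", {
  m <- rand_model(5, 5, inhibition_config(enabled = FALSE), n_expansions = 1, seed = 7)
  x <- rand_image(5, 5, seed = 8)
  fs <- forward(m, x)
  sn <- sensitivities(m, x, fs)
  # hand derivation: err * phi'(z^O), with phi' written through the output value
  expected <- (fs$outputs - x) * fs$outputs * (1 - fs$outputs)
  expect_equal(sn$delta_out, expected, tolerance = 1e-12)
  expect_equal(sn$same_layer, expected, tolerance = 1e-12)
})

test_that("analytic gradients match the central-difference oracle on seeded cases", {
  for (seed in 1:4) {
    inh <- inhibition_config(I = 1 + seed %% 2, A = 3 + seed,
                             enabled = seed %% 2 == 0)
    m <- rand_model(6, 6, inh, n_expansions = seed %% 3, seed = seed)
    imgs <- list(rand_image(6, 6, seed = 20 + seed), rand_image(6, 6, seed = 40 + seed))
    expect_lt(max_grad_mismatch(m, imgs), 1e-5)
  }
})

test_that("batch gradients are additive over repeated images", {
  m <- rand_model(4, 6, inhibition_config(I = 1, A = 4, enabled = TRUE),
                  n_expansions = 1, seed = 5)
  x <- rand_image(4, 6, seed = 6)
  g1 <- batch_gradients(m, list(x))
  g3 <- batch_gradients(m, list(x, x, x))
  expect_equal(g3$input, 3 * g1$input, tolerance = 1e-12)
  expect_equal(g3$out_weight, 3 * g1$out_weight, tolerance = 1e-12)
  expect_equal(g3$bias, 3 * g1$bias, tolerance = 1e-12)
  expect_error(batch_gradients(m, list()), "empty")
})

test_that("numeric gradient oracle behaves like a second-order method", {
  m <- rand_model(4, 4, seed = 9)
  imgs <- list(rand_image(4, 4, seed = 10))
  pid <- list(type = "bias", index = 1)
  g_ref <- batch_gradients(m, imgs)$bias[1]
  e1 <- abs(numeric_gradient(m, imgs, pid, epsilon = 2e-3) - g_ref)
  e2 <- abs(numeric_gradient(m, imgs, pid, epsilon = 1e-3) - g_ref)
  # halving epsilon shrinks the truncation error about fourfold
  expect_lt(e2, e1 / 2.5)
  # zero-error configuration differentiates to zero
  pp <- perfect_pair(m)
  expect_lt(abs(numeric_gradient(pp$model, list(pp$x), pid)), 1e-8)
  expect_error(numeric_gradient(m, imgs, list(type = "bias", index = 99)),
               "unknown parameter")
  expect_error(numeric_gradient(m, imgs, list(type = "nope", index = 1)))
})

test_that("RProp follows the documented single-step rules exactly", {
  cfg <- train_config(1, 2)
  m <- init_model(1, 2, inhibition_config(enabled = FALSE), seed = 0)
  m$input_weights[] <- c(1, 2); m$hidden$out_weight <- 3; m$hidden$bias <- 4
  state <- rprop_init(m, cfg$rprop)
  g <- list(input = matrix(c(1, 0), 1, 2), out_weight = -1, bias = 1)

  # first step: no memory, step by -sign(g) * delta0
  s1 <- rprop_update(m, g, state)
  expect_equal(s1$model$input_weights[1, 1], 1 - 0.1)
  expect_equal(s1$model$input_weights[1, 2], 2)       # zero gradient: untouched
  expect_equal(s1$model$hidden$out_weight, 3 + 0.1)
  expect_equal(s1$state$delta$input[1, 1], 0.1)

  # repeated sign: delta grows by eta+ = 1.2 and the step uses the new delta
  s2 <- rprop_update(s1$model, g, s1$state)
  expect_equal(s2$state$delta$input[1, 1], 0.12)
  expect_equal(s2$model$input_weights[1, 1], 1 - 0.1 - 0.12)

  # sign flip: delta shrinks by eta- = 0.5, memory cleared, no step taken
  g_flip <- list(input = matrix(c(-1, 0), 1, 2), out_weight = -1, bias = 1)
  s3 <- rprop_update(s2$model, g_flip, s2$state)
  expect_equal(s3$state$delta$input[1, 1], 0.06)
  expect_equal(s3$state$prev$input[1, 1], 0)
  expect_equal(s3$model$input_weights[1, 1], s2$model$input_weights[1, 1])

  expect_error(rprop_update(m, g, state,
                            list(input = matrix(TRUE, 2, 2),
                                 out_weight = TRUE, bias = TRUE)),
               "mask")
})

test_that("RProp step sizes stay within their bounds under random gradients", {
  m <- rand_model(3, 3, seed = 11)
  cfg <- train_config(3, 3, delta_min = 0.05, delta_max = 0.3)
  state <- rprop_init(m, cfg$rprop)
  withr::with_seed(12, {
    for (it in 1:50) {
      g <- list(input = matrix(rnorm(9), 3, 3),
                out_weight = rnorm(1), bias = rnorm(1))
      upd <- rprop_update(m, g, state)
      m <- upd$model; state <- upd$state
      for (d in state$delta) {
        expect_true(all(d >= 0.05 - 1e-15 & d <= 0.3 + 1e-15))
      }
    }
  })
})

test_that("fit reduces validation error, respects masks and freezes, deterministically", {
  cfg <- tiny_config(6, 6, seed = 2)
  m <- init_model(6, 6, cfg$inhibition, seed = 2)
  imgs <- list(matrix(0.7, 6, 6), matrix(0.7, 6, 6))
  res <- fit(m, imgs, config = cfg)
  expect_lt(min(res$history$val_mae), res$history$val_mae[1])

  # all-false mask: model returned unchanged
  none <- list(input = matrix(FALSE, 6, 6), out_weight = FALSE, bias = FALSE)
  res0 <- fit(m, imgs, config = cfg, trainable_mask = none)
  expect_identical(res0$model$input_weights, m$input_weights)
  expect_identical(res0$model$hidden, m$hidden)

  # frozen neurons are bitwise untouched even when trained alongside others
  m4 <- expand_leaf(m, 1, seed = 3)   # freezes nothing yet (all four trainable)
  m4$hidden$frozen <- c(TRUE, FALSE, FALSE, FALSE)
  res4 <- fit(m4, imgs, config = cfg)
  expect_identical(res4$model$hidden$out_weight[1], m4$hidden$out_weight[1])
  expect_identical(res4$model$hidden$bias[1], m4$hidden$bias[1])
  expect_false(identical(res4$model$hidden$out_weight[2], m4$hidden$out_weight[2]))

  # determinism
  resA <- fit(m, imgs, config = cfg)
  expect_identical(res$history, resA$history)
  expect_identical(res$model$input_weights, resA$model$input_weights)
  expect_error(fit(m, list(), config = cfg), "empty")
})
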