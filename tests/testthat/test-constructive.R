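# Quadtree expansion, leaf selection, constructive build and pruning.

test_that("split_region produces the quadtree quadrants", {
  q <- split_region(region(0, 0, 8, 8))
  expect_equal(lapply(q, unclass),
               lapply(list(region(0, 0, 4, 4), region(0, 4, 4, 8),
                           region(4, 0, 8, 4), region(4, 4, 8, 8)), unclass))
  # odd sides: the first block takes the ceiling
  q5 <- split_region(region(0, 0, 5, 5))
  expect_equal(lapply(q5, unclass),
               lapply(list(region(0, 0, 3, 3), region(0, 3, 3, 5),
                           region(3, 0, 5, 3), region(3, 3, 5, 5)), unclass))
  expect_error(split_region(region(0, 0, 1, 1)), "NonDivisible")
  expect_error(split_region(region(2, 2, 3, 9)), "NonDivisible")
})

test_that("split quadrants are disjoint and reunite to the parent", {
  withr::with_seed(31, {
    for (rep in 1:25) {
      r0 <- sample(0:5, 1); c0 <- sample(0:5, 1)
      reg <- region(r0, c0, r0 + sample(2:9, 1), c0 + sample(2:9, 1))
      q <- split_region(reg)
      cov <- matrix(0L, reg$r1, reg$c1)
      for (s in q) cov[(s$r0 + 1):s$r1, (s$c0 + 1):s$c1] <-
          cov[(s$r0 + 1):s$r1, (s$c0 + 1):s$c1] + 1L
      parent <- matrix(0L, reg$r1, reg$c1)
      parent[(reg$r0 + 1):reg$r1, (reg$c0 + 1):reg$c1] <- 1L
      expect_identical(cov, parent)
    }
  })
})

test_that("selection scores measure the error spread per leaf", {
  m <- rand_model(8, 8, n_expansions = 2, seed = 13)
  # perfectly reconstructed target: uniform (zero) error surface, all scores 0
  pp <- perfect_pair(m)
  sc0 <- selection_scores(pp$model, list(pp$x))
  expect_true(all(sc0$score == 0))

  imgs <- list(rand_image(8, 8, seed = 15), rand_image(8, 8, seed = 16))
  sc <- selection_scores(m, imgs)
  # brute-force oracle over the mean |error| surface
  surf <- Reduce(`+`, lapply(imgs, function(x) abs(forward(m, x)$outputs - x))) /
    length(imgs)
  regs <- leaf_regions(m)
  for (i in seq_len(nrow(regs))) {
    vals <- surf[(regs$r0[i] + 1):regs$r1[i], (regs$c0[i] + 1):regs$c1[i]]
    expect_equal(sc$score[sc$id == regs$id[i]], max(vals) - min(vals),
                 tolerance = 1e-12)
  }
  # the leaf containing both the globally best and worst pixel (if any) tops
  best <- which(surf == min(surf), arr.ind = TRUE)[1, ]
  worst <- which(surf == max(surf), arr.ind = TRUE)[1, ]
  covers <- function(reg, px) reg["r0"] < px[1] & px[1] <= reg["r1"] &
    reg["c0"] < px[2] & px[2] <= reg["c1"]
  both <- apply(regs, 1, function(r) covers(r, best) && covers(r, worst))
  if (any(both)) expect_equal(which.max(sc$score), which(both)[1])
  # batch order invariance
  expect_equal(selection_scores(m, rev(imgs))$score, sc$score)
  # eligibility marks exactly the divisible leaves
  expect_equal(sc$eligible,
               (regs$r1 - regs$r0 >= 2) & (regs$c1 - regs$c0 >= 2))
  expect_error(selection_scores(m, list()), "empty")
})

test_that("expand_leaf keeps the parent in the top-left quadrant and freezes the rest", {
  m <- init_model(8, 8, inhibition_config(enabled = FALSE), seed = 0)
  w_parent <- m$hidden$out_weight[1]; b_parent <- m$hidden$bias[1]
  m1 <- expand_leaf(m, 1, seed = 5)
  expect_equal(nrow(m1$hidden), 4L)
  expect_true(all(coverage_counts(m1) == 1L))
  expect_equal(m1$hidden$out_weight[1], w_parent)
  expect_equal(m1$hidden$bias[1], b_parent)
  expect_equal(c(m1$hidden$r1[1], m1$hidden$c1[1]), c(4L, 4L))
  # new neurons carry the parent's position label
  expect_true(all(m1$hidden$parent_r[2:4] == 0 & m1$hidden$parent_c[2:4] == 0))
  expect_true(is.na(m1$hidden$parent_r[1]))
  expect_identical(m1$hidden$frozen, rep(FALSE, 4))

  # second expansion: exactly the four quadrant neurons are trainable
  m2 <- expand_leaf(m1, 2, seed = 6)
  expect_equal(nrow(m2$hidden), 7L)
  expect_equal(sum(!m2$hidden$frozen), 4L)
  expect_true(all(which(!m2$hidden$frozen) %in% c(2, 5, 6, 7)))
  expect_true(all(coverage_counts(m2) == 1L))
  # hidden count follows 1 + 3k
  for (k in 0:2) expect_equal(nrow(list(m, m1, m2)[[k + 1]]$hidden), 1L + 3L * k)
  expect_error(expand_leaf(m, 99), "unknown leaf")
})

test_that("build honours n_max, the selection contract and divisibility bounds", {
  cfg <- tiny_config(6, 6, seed = 4)
  imgs <- lapply(1:4, function(i) rand_image(6, 6, seed = 60 + i) * 0.3 + 0.3)

  cfg1 <- cfg; cfg1$n_max <- 1L
  b1 <- build(imgs[1:3], imgs[4], cfg1)
  expect_equal(nrow(b1$trace), 1L)
  expect_equal(nrow(b1$model$hidden), 1L)

  b <- build(imgs[1:3], imgs[4], cfg)
  expect_true(all(b$trace$hidden_count == 1L + 3L * b$trace$iteration))
  expect_lte(max(b$trace$hidden_count), cfg$n_max)
  # returned model achieves the minimum validation error in the trace
  st_val <- mean(abs(forward(b$model, imgs[[4]])$outputs - imgs[[4]]))
  expect_equal(st_val, min(b$trace$val_mae), tolerance = 1e-12)
  expect_lte(min(b$trace$val_mae), b$trace$val_mae[1])

  # 2x2 images allow exactly one expansion (children are 1x1)
  cfg2 <- tiny_config(2, 2, seed = 5); cfg2$n_max <- 50L
  imgs2 <- lapply(1:3, function(i) rand_image(2, 2, seed = 80 + i))
  b2 <- build(imgs2, NULL, cfg2)
  expect_lte(max(b2$trace$iteration), 1L)

  expect_error(build(list(), NULL, cfg), "empty")
})

test_that("build is deterministic and never returns worse than the initial fit", {
  cfg <- tiny_config(6, 6, seed = 9)
  imgs <- lapply(1:5, function(i) rand_image(6, 6, seed = 90 + i) * 0.5 + 0.2)
  bA <- build(imgs[1:4], imgs[5], cfg)
  bB <- build(imgs[1:4], imgs[5], cfg)
  expect_identical(bA$trace, bB$trace)
  expect_identical(bA$model$input_weights, bB$model$input_weights)
  expect_lte(min(bA$trace$val_mae), bA$trace$val_mae[1])
})

test_that("pruning keeps the R smallest mean error rates with row-major ties", {
  # worked example: mean errors [[0.1, 0.4], [0.2, 0.3]], R = 2
  surf <- matrix(c(0.1, 0.2, 0.4, 0.3), 2, 2)
  mask <- canet:::retain_smallest(surf, 2L)
  expect_identical(mask, matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))

  # brute-force oracle: repeatedly take the minimum, ties in row-major order
  brute <- function(surface, r_keep) {
    H <- nrow(surface); W <- ncol(surface)
    keep <- matrix(FALSE, H, W)
    err <- surface
    for (k in seq_len(r_keep)) {
      best <- NULL
      for (r in seq_len(H)) for (c in seq_len(W)) {
        if (!keep[r, c] && (is.null(best) || err[r, c] < err[best[1], best[2]])) {
          best <- c(r, c)
        }
      }
      keep[best[1], best[2]] <- TRUE
    }
    keep
  }
  withr::with_seed(41, {
    for (rep in 1:40) {
      H <- sample(2:5, 1); W <- sample(2:5, 1)
      surf <- matrix(sample(seq(0, 0.5, by = 0.1), H * W, replace = TRUE), H, W)
      R <- sample(seq_len(H * W), 1)
      expect_identical(canet:::retain_smallest(surf, R), brute(surf, R))
    }
  })

  # end-to-end on a model: mask matches the mean-error surface rule
  m <- rand_model(6, 6, n_expansions = 1, seed = 17)
  imgs <- list(rand_image(6, 6, seed = 18), rand_image(6, 6, seed = 19))
  pm <- prune(m, imgs, 18L)
  expect_equal(sum(pm$retained_mask), 18L)
  surf_m <- Reduce(`+`, lapply(imgs, function(x) abs(forward(m, x)$outputs - x))) / 2
  expect_identical(pm$retained_mask, brute(surf_m, 18L))
  # R = H*W keeps everything and changes nothing else
  pm_all <- prune(m, imgs, 36L)
  expect_true(all(pm_all$retained_mask))
  expect_identical(pm_all$hidden, m$hidden)
  expect_error(prune(m, imgs, 0), "r_keep")
  expect_error(prune(m, imgs, 37), "r_keep")
})
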