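test_that("attributions vanish at the baseline input", {
  m <- build_cnn(tiny_spec(), seed = 1)
  ig <- integrated_gradients(m, rep(0, 16), target = 0L, n_steps = 8)
  expect_true(all(ig$per_feature == 0))
  expect_equal(ig$residual, 0, tolerance = 1e-6)
})

test_that("IG is exact for a network operating in its linear region", {
  # all-positive weights, zero biases, positive inputs: every pre-activation
  # along the zero-to-x path is positive, so ReLU is the identity and the
  # class score is linear in x. Then IG_i = dF/dx_i * x_i for any number of
  # steps, and the completeness identity holds exactly.
  m <- build_cnn(tiny_spec(), seed = 7)
  m$weights <- lapply(m$weights, abs)
  x <- matrix(runif(16, 0.5, 1), 1, 16)

  grad <- cpp_cnn_input_grad(m$weights, m$spec$layers,
                             as_input_cube(x, m$spec), 1L, 2L)
  expected <- as.vector(grad) * as.vector(x)

  for (ns in c(2, 16, 128)) {
    ig <- integrated_gradients(m, x, target = 1L, n_steps = ns)
    expect_equal(as.vector(ig$per_feature), expected, tolerance = 1e-5)
  }
  ig <- integrated_gradients(m, x, target = 1L, n_steps = 16)
  expect_equal(ig$sum_attr, ig$delta_f, tolerance = 1e-4)
})

test_that("backpropagated input gradients match finite differences", {
  m <- train_cnn(build_cnn(tiny_spec(12), seed = 3),
                 separable_data(8, len = 12, seed = 5)$x,
                 separable_data(8, len = 12, seed = 5)$labels,
                 epochs = 15, seed = 3)
  x <- separable_data(8, len = 12, seed = 6)$x[1, , drop = FALSE]
  xc <- as_input_cube(x, m$spec)
  grad <- as.vector(cpp_cnn_input_grad(m$weights, m$spec$layers, xc, 1L, 2L))
  h <- 1e-3
  fd <- vapply(seq_len(12), function(i) {
    xp <- x; xp[1, i] <- xp[1, i] + h
    xm <- x; xm[1, i] <- xm[1, i] - h
    (predict(m, xp, type = "logit")[1, "cis"] -
       predict(m, xm, type = "logit")[1, "cis"]) / (2 * h)
  }, numeric(1))
  expect_equal(grad, fd, tolerance = 5e-3)
})

test_that("Riemann sums self-converge and completeness residual shrinks", {
  dat <- separable_data(12, seed = 9)
  m <- train_cnn(build_cnn(tiny_spec(), seed = 4), dat$x, dat$labels,
                 epochs = 30, seed = 4)
  x <- dat$x[3, , drop = FALSE]
  ig_512 <- integrated_gradients(m, x, n_steps = 512)
  ig_4096 <- integrated_gradients(m, x, n_steps = 4096)
  rel <- sum(abs(ig_512$per_feature - ig_4096$per_feature)) /
    sum(abs(ig_4096$per_feature))
  expect_lt(rel, 0.01)
  ig_8 <- integrated_gradients(m, x, n_steps = 8)
  expect_lte(ig_4096$residual, ig_8$residual + 1e-8)
  expect_lt(ig_4096$residual, 0.01 * abs(ig_4096$delta_f) + 1e-8)
  expect_error(integrated_gradients(m, x, n_steps = 1), "n_steps")
})

test_that("metapixel importance is channel-aggregated, normalized and scale-invariant", {
  # 2-channel toy model: importance has one entry per channel, max 1
  sp <- cnn_spec("pruned", n_channels = 2, input_length = 16)
  sp$layers <- cbind(filters = c(4L, 4L), kernel = c(3L, 3L), stride = c(1L, 1L))
  x <- with_seed_local(11, array(runif(6 * 2 * 16, 0.2, 1), c(6, 2, 16)))
  y <- factor(rep(c("trans", "cis"), 3), levels = c("trans", "cis"))
  m <- train_cnn(build_cnn(sp, seed = 2), x, y, epochs = 10, seed = 2)
  imp <- metapixel_importance(m, x, n_steps = 32)
  expect_length(imp, 2)
  expect_equal(max(imp), 1)
  expect_true(all(imp >= 0 & imp <= 1))

  # normalization makes the importance invariant to input scaling that
  # keeps the network linear-region structure (doubling all attributions)
  ig <- integrated_gradients(m, x, n_steps = 32)
  per_channel <- apply(abs(ig$per_feature), c(1, 2), sum)
  manual <- colMeans(per_channel)
  expect_equal(imp, manual / max(manual))
  expect_equal(manual * 2 / max(manual * 2), imp)
})
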