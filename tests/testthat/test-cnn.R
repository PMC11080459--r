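test_that("architecture specs match the two study networks", {
  sp_o <- cnn_spec("original")
  expect_equal(sp_o$layers[, "filters"], c(128, 100, 80, 60, 40, 20))
  expect_equal(sp_o$layers[, "kernel"], c(5, 3, 1, 1, 1, 1))
  expect_equal(sp_o$layers[, "stride"], c(2, 1, 1, 1, 1, 1))
  expect_equal(sp_o$n_channels, 49L)
  # valid convolution: floor((251 - 5)/2) + 1 = 124 after the first layer
  expect_equal(conv_output_lengths(sp_o)[1], 124L)

  sp_p <- cnn_spec("pruned")
  expect_equal(nrow(sp_p$layers), 4)
  expect_equal(sp_p$layers[, "filters"], c(8, 16, 32, 32))
  expect_equal(sp_p$layers[, "kernel"], c(7, 5, 5, 5))
  expect_equal(sp_p$n_channels, 1L)

  expect_error(cnn_spec("pruned", input_length = 3), "kernel")
})

test_that("softmax output is a probability vector", {
  m <- build_cnn(tiny_spec(), seed = 1)
  x <- matrix(runif(3 * 16), 3, 16)
  p <- predict(m, x, type = "prob")
  expect_equal(dim(p), c(3, 2))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_true(all(p >= 0))
})

test_that("stratified split is exact, disjoint and seed-stable", {
  ds <- list(x = array(runif(20 * 1 * 16), c(20, 1, 16)),
             labels = factor(rep(c("trans", "cis"), each = 10),
                             levels = c("trans", "cis")))
  sp <- split_dataset(ds, 0.7, seed = 5)
  expect_equal(as.vector(table(sp$train$labels)), c(7, 7))
  expect_equal(as.vector(table(sp$validation$labels)), c(3, 3))
  expect_length(intersect(sp$train$idx, sp$validation$idx), 0)
  expect_equal(sort(c(sp$train$idx, sp$validation$idx)), 1:20)

  sp2 <- split_dataset(ds, 0.7, seed = 5)
  expect_identical(sp$train$idx, sp2$train$idx)
  sp3 <- split_dataset(ds, 0.7, seed = 6)
  expect_false(identical(sp$train$idx, sp3$train$idx))

  ds_bad <- list(x = ds$x[1:3, , , drop = FALSE],
                 labels = factor(c("trans", "trans", "cis"),
                                 levels = c("trans", "cis")))
  expect_error(split_dataset(ds_bad), "at least 2")
  expect_error(split_dataset(ds, 1.2), "fraction")
})

test_that("training is deterministic, exact-epoch and learns separable data", {
  dat <- separable_data()
  m0 <- build_cnn(tiny_spec(), seed = 2)

  # zero epochs is a no-op
  m_no <- train_cnn(m0, dat$x, dat$labels, epochs = 0)
  expect_identical(m_no$weights, m0$weights)

  m1 <- train_cnn(m0, dat$x, dat$labels, epochs = 40, lr = 5e-3, seed = 3)
  m2 <- train_cnn(m0, dat$x, dat$labels, epochs = 40, lr = 5e-3, seed = 3)
  expect_identical(m1$weights, m2$weights)
  m3 <- train_cnn(m0, dat$x, dat$labels, epochs = 40, lr = 5e-3, seed = 4)
  expect_false(identical(m1$weights, m3$weights))

  expect_equal(nrow(m1$log), 40)
  expect_equal(tail(m1$log$train_acc, 1), 1)

  ev <- evaluate_cnn(m1, dat$x, dat$labels)
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / sum(ev$confusion))
  expect_equal(sum(ev$confusion), 40)
})

test_that("evaluation report counts follow the predicted-by-actual convention", {
  dat <- separable_data(n_per_class = 15)
  m <- train_cnn(build_cnn(tiny_spec(), seed = 1), dat$x, dat$labels,
                 epochs = 40, lr = 5e-3, seed = 1)
  ev <- evaluate_cnn(m, dat$x, dat$labels)
  # perfect predictor on 15/15: diagonal (15, 15), accuracy 1
  expect_equal(unname(diag(ev$confusion)), c(15, 15))
  expect_equal(ev$accuracy, 1)
  pred <- predict(m, dat$x, type = "class")
  # rows = predicted, columns = actual
  expect_equal(ev$confusion["trans", "cis"],
               sum(pred == "trans" & dat$labels == "cis"))
  expect_error(evaluate_cnn(m, dat$x[0, , drop = FALSE], factor(NULL)), "empty")
})

test_that("input validation catches shape and label errors", {
  m <- build_cnn(tiny_spec(), seed = 1)
  expect_error(predict(m, matrix(0, 3, 10)), "dimensions|match")
  expect_error(train_cnn(m, matrix(0.1, 4, 16), factor(rep("cis", 3), levels = c("trans", "cis"))),
               "mismatch")
})

test_that("time-series classification carries exclusion flags through", {
  dat <- separable_data(n_per_class = 10)
  m <- train_cnn(build_cnn(tiny_spec(), seed = 1), dat$x, dat$labels,
                 epochs = 40, lr = 5e-3, seed = 1)
  frames <- dat$x[1:5, , drop = FALSE]
  ts <- classify_timeseries(m, frames, time_s = (0:4) * 64,
                            excluded = c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(nrow(ts), 5)
  expect_equal(ts$excluded, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_true(all(!is.na(ts$p_cis)))          # excluded frames still predicted
  # single frame input -> single prediction
  ts1 <- classify_timeseries(m, dat$x[1, , drop = FALSE])
  expect_equal(nrow(ts1), 1)
})

test_that("top-metapixel selection ranks by importance with nu0 tie-break", {
  imp <- c(0.2, 1.0, 0.5, 1.0, 0.1)
  nu0 <- c(1400, 1500, 1450, 1420, 1480)
  # tie between metapixels 2 and 4 -> lower nu0 (metapixel 4) first
  expect_equal(select_top_metapixels(imp, nu0, 1), 4L)
  expect_equal(select_top_metapixels(imp, nu0, 2), c(4L, 2L))
  expect_equal(select_top_metapixels(imp, nu0, 5), c(4L, 2L, 3L, 1L, 5L))
  expect_error(select_top_metapixels(imp, nu0, 6), "exceeds")
  expect_error(select_top_metapixels(imp, nu0[1:3], 1), "length")
})
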