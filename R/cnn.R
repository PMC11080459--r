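#' 1D CNN architecture specification
#'
#' The two classifier architectures used in the pipeline:
#'
#' * `"original"` — six convolutional layers of 128, 100, 80, 60, 40, 20
#'   filters with kernels 5, 3, 1, 1, 1, 1 and strides 2, 1, 1, 1, 1, 1,
#'   ReLU after each of the first five, then a fully connected layer to the
#'   two classes with softmax. Its input is the full set of averaged
#'   metapixel spectra, stacked as channels of a length-251 signal
#'   (`n_channels = 49` by default), so the 1D kernels slide along the
#'   wavenumber axis only.
#' * `"pruned"` — the simplified four-layer network (8, 16, 32, 32 filters,
#'   kernels 7, 5, 5, 5, stride 1) that inputs a single selected metapixel
#'   spectrum (`n_channels = 1`).
#'
#' All convolutions are unpadded ("valid"), so layer output lengths follow
#' `L_out = floor((L_in - kernel)/stride) + 1`.
#'
#' @param variant `"original"` or `"pruned"`.
#' @param n_channels Number of input spectra stacked as channels; defaults
#'   to 49 for the original variant (the averaged target-barcode set) and 1
#'   for the pruned variant.
#' @param input_length Samples per spectrum (251 on the model grid).
#' @param n_classes Number of output classes (2: trans, cis).
#' @return A `cnn_spec` object: list with `variant`, `layers` (matrix with
#'   columns filters/kernel/stride), `n_channels`, `input_length`,
#'   `n_classes`.
#' @export
cnn_spec <- function(variant = c("original", "pruned"), n_channels = NULL,
                     input_length = 251, n_classes = 2) {
  variant <- match.arg(variant)
  layers <- if (variant == "original") {
    cbind(filters = c(128L, 100L, 80L, 60L, 40L, 20L),
          kernel  = c(5L, 3L, 1L, 1L, 1L, 1L),
          stride  = c(2L, 1L, 1L, 1L, 1L, 1L))
  } else {
    cbind(filters = c(8L, 16L, 32L, 32L),
          kernel  = c(7L, 5L, 5L, 5L),
          stride  = c(1L, 1L, 1L, 1L))
  }
  if (is.null(n_channels)) n_channels <- if (variant == "original") 49L else 1L
  if (input_length < layers[1, "kernel"]) {
    stop("cnn_spec: input shorter than the first kernel")
  }
  structure(list(variant = variant, layers = layers,
                 n_channels = as.integer(n_channels),
                 input_length = as.integer(input_length),
                 n_classes = as.integer(n_classes)),
            class = "cnn_spec")
}

#' Conv-layer output lengths of a specification
#' @param spec A [cnn_spec()].
#' @return Integer vector of per-layer output lengths.
#' @export
conv_output_lengths <- function(spec) {
  stopifnot(inherits(spec, "cnn_spec"))
  L <- spec$input_length
  out <- integer(nrow(spec$layers))
  for (i in seq_len(nrow(spec$layers))) {
    k <- spec$layers[i, "kernel"]
    s <- spec$layers[i, "stride"]
    if (L < k) stop("conv_output_lengths: length underflow at layer ", i)
    L <- (L - k) %/% s + 1L
    out[i] <- L
  }
  out
}

#' Build (initialize) a CNN classifier
#'
#' @param spec A [cnn_spec()].
#' @param seed Integer seed of the He-uniform weight initialization.
#' @return A `cnn1d` model object (untrained).
#' @export
build_cnn <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cnn_spec"))
  weights <- cpp_cnn_init(spec$layers, spec$n_channels, spec$input_length,
                          spec$n_classes, as.integer(seed))
  structure(list(spec = spec, weights = weights, trained = FALSE,
                 init_seed = as.integer(seed), log = NULL,
                 classes = c("trans", "cis")),
            class = "cnn1d")
}

#' @export
print.cnn1d <- function(x, ...) {
  np <- sum(vapply(x$weights, length, numeric(1)))
  cat(sprintf("<cnn1d> %s variant, %d channels x %d samples, %d parameters%s\n",
              x$spec$variant, x$spec$n_channels, x$spec$input_length, np,
              if (x$trained) ", trained" else ""))
  invisible(x)
}

## items-first array (n x C x L), matrix (n x L, single channel) or single
## item (C x L matrix / length-L vector) -> (C, L, n) cube for the C++ side
as_input_cube <- function(x, spec, single_ok = TRUE) {
  C <- spec$n_channels
  L <- spec$input_length
  if (is.null(dim(x))) {
    if (C != 1 || length(x) != L) stop("input vector length mismatch")
    x <- array(x, dim = c(1, 1, L))
  } else if (length(dim(x)) == 2) {
    if (single_ok && nrow(x) == C && ncol(x) == L && C > 1) {
      x <- array(x, dim = c(1, dim(x)))     # one multichannel item
    } else if (C == 1 && ncol(x) == L) {
      x <- array(x, dim = c(nrow(x), 1, L)) # n single-channel items
    } else if (nrow(x) == C && ncol(x) == L) {
      x <- array(x, dim = c(1, dim(x)))
    } else {
      stop("input matrix dimensions do not match the model spec")
    }
  }
  d <- dim(x)
  if (length(d) != 3 || d[2] != C || d[3] != L) {
    stop(sprintf("input must be n x %d x %d for this model", C, L))
  }
  aperm(x, c(2, 3, 1))
}

labels_to_int <- function(y) {
  if (is.factor(y)) {
    if (!identical(levels(y), c("trans", "cis"))) {
      y <- factor(as.character(y), levels = c("trans", "cis"))
    }
    as.integer(y) - 1L
  } else if (is.numeric(y)) {
    as.integer(y)
  } else {
    as.integer(factor(as.character(y), levels = c("trans", "cis"))) - 1L
  }
}

#' Stratified train/validation split
#'
#' Splits a labeled dataset 70/30 (by default) per class: `floor(fraction *
#' n_class)` items of each class go to training, the rest to validation;
#' the two parts are disjoint and exhaustive, and the split is reproducible
#' from the seed.
#'
#' @param dataset A `labeled_dataset` (from [generate_labeled_dataset()]) or
#'   a list with `x` (items-first array) and `labels`.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `validation`, each a list with `x`,
#'   `labels` and the original item `idx`.
#' @export
split_dataset <- function(dataset, fraction = 0.7, seed = 1) {
  if (fraction <= 0 || fraction >= 1) stop("split_dataset: fraction must be in (0, 1)")
  y <- dataset$labels
  if (any(table(y) < 2)) stop("split_dataset: every class needs at least 2 items")
  idx_tr <- integer(0)
  with_local_seed(seed, {
    for (cl in levels(y)) {
      icl <- which(y == cl)
      ntr <- floor(fraction * length(icl))
      idx_tr <- c(idx_tr, sort(sample(icl, ntr)))
    }
  })
  idx_tr <- sort(idx_tr)
  idx_va <- setdiff(seq_along(y), idx_tr)
  take <- function(idx) {
    list(x = dataset$x[idx, , , drop = FALSE], labels = y[idx], idx = idx)
  }
  list(train = take(idx_tr), validation = take(idx_va))
}

#' Train a CNN classifier
#'
#' Minibatch Adam training of the cross-entropy loss for exactly `epochs`
#' epochs, with inverted dropout on the flattened features entering the
#' classification head (active in training mode only). Initialization,
#' batch order, and dropout masks are all deterministic functions of the
#' seeds, so two runs with the same seed give identical weights.
#'
#' @param model A [build_cnn()] model.
#' @param x Training inputs, items-first array `n x channels x length` (or
#'   `n x length` matrix for single-channel models).
#' @param y Labels: factor with levels trans/cis, or integers 0 (trans) / 1
#'   (cis).
#' @param epochs Training epochs (160 in the study protocol).
#' @param dropout Dropout probability (0.2 in the study protocol).
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param seed Seed for batch shuffling and dropout.
#' @return The trained `cnn1d` model, with a `log` data.frame (epoch, loss,
#'   train_acc).
#' @export
train_cnn <- function(model, x, y, epochs = 160, dropout = 0.2, lr = 1e-3,
                      batch_size = 32, seed = 1) {
  stopifnot(inherits(model, "cnn1d"))
  if (epochs < 0) stop("train_cnn: epochs must be >= 0")
  xc <- as_input_cube(x, model$spec, single_ok = FALSE)
  yi <- labels_to_int(y)
  if (length(yi) != dim(xc)[3]) stop("train_cnn: label/input count mismatch")
  if (any(is.na(yi)) || any(yi < 0) || any(yi >= model$spec$n_classes)) {
    stop("train_cnn: labels must be trans/cis (0/1)")
  }
  if (epochs == 0) return(model)
  res <- cpp_cnn_train(model$weights, model$spec$layers, xc, yi,
                       model$spec$n_classes, as.integer(epochs),
                       as.integer(batch_size), lr, dropout, as.integer(seed))
  model$weights <- res$weights
  model$trained <- TRUE
  model$log <- data.frame(epoch = seq_len(epochs), loss = res$loss,
                          train_acc = res$train_acc)
  model$train_config <- list(epochs = epochs, dropout = dropout, lr = lr,
                             batch_size = batch_size, seed = seed)
  model
}

#' Predict membrane states
#'
#' @param object A trained `cnn1d` model.
#' @param x Inputs (items-first array, matrix, or a single item).
#' @param type `"prob"` for class probabilities (softmax), `"class"` for
#'   hard labels, `"logit"` for pre-softmax scores.
#' @param ... Unused.
#' @return Matrix `n x 2` (columns trans, cis) or a factor of labels.
#' @export
predict.cnn1d <- function(object, x, type = c("prob", "class", "logit"), ...) {
  type <- match.arg(type)
  xc <- as_input_cube(x, object$spec)
  out <- cpp_cnn_forward(object$weights, object$spec$layers, xc,
                         object$spec$n_classes)
  if (type == "class") {
    return(factor(object$classes[max.col(out$probs, ties.method = "first")],
                  levels = object$classes))
  }
  m <- if (type == "prob") out$probs else out$logits
  colnames(m) <- object$classes
  m
}

#' Evaluate a classifier
#'
#' @param model A trained `cnn1d`.
#' @param x,y Validation inputs and labels.
#' @return An `eval_report`: list with `confusion` (2 x 2 counts, rows =
#'   predicted class, columns = actual class) and `accuracy`
#'   (= trace / total).
#' @export
evaluate_cnn <- function(model, x, y) {
  if (length(y) == 0) stop("evaluate_cnn: empty validation set")
  pred <- predict(model, x, type = "class")
  actual <- factor(model$classes[labels_to_int(y) + 1L], levels = model$classes)
  confusion <- table(predicted = pred, actual = actual)
  structure(list(confusion = unclass(confusion),
                 accuracy = sum(diag(confusion)) / sum(confusion),
                 n = length(y)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.3f on %d items\n", x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}

#' Integrated-gradients attribution
#'
#' Computes integrated gradients of the pre-softmax score of the target
#' class with respect to each input feature, against an all-zeros baseline,
#' using a midpoint Riemann sum:
#' \deqn{IG_i = x_i \cdot \frac{1}{n} \sum_{k=1}^{n}
#'   \left.\frac{\partial F}{\partial x_i}\right|_{((k-1/2)/n)\,x}.}
#' The completeness residual `|sum_i IG_i - (F(x) - F(0))|` is reported per
#' item; it vanishes as the number of steps grows.
#'
#' @param model A trained `cnn1d`.
#' @param x A single item (`channels x length` matrix or vector) or an
#'   items-first array.
#' @param target Class index per item (0 = trans, 1 = cis), a factor, or
#'   `NULL` to attribute the predicted class.
#' @param n_steps Number of Riemann steps (>= 2; default 512).
#' @return An `attribution` object: list with `per_feature` (items-first
#'   array `n x channels x length`), `target`, `sum_attr`, `delta_f`
#'   (= F(x) - F(0) per item), `residual`, `n_steps`.
#' @export
integrated_gradients <- function(model, x, target = NULL, n_steps = 512) {
  stopifnot(inherits(model, "cnn1d"))
  if (n_steps < 2) stop("integrated_gradients: n_steps must be >= 2")
  xc <- as_input_cube(x, model$spec)
  n <- dim(xc)[3]
  if (is.null(target)) {
    probs <- cpp_cnn_forward(model$weights, model$spec$layers, xc,
                             model$spec$n_classes)$probs
    target <- max.col(probs, ties.method = "first") - 1L
  } else if (is.factor(target) || is.character(target)) {
    target <- labels_to_int(target)
  }
  target <- rep_len(as.integer(target), n)
  mean_grad <- cpp_cnn_ig_mean_grad(model$weights, model$spec$layers, xc,
                                    target, model$spec$n_classes,
                                    as.integer(n_steps))
  attr_cube <- mean_grad * xc
  f_x <- cpp_cnn_forward(model$weights, model$spec$layers, xc,
                         model$spec$n_classes)$logits
  zero <- array(0, dim = dim(xc))
  f_0 <- cpp_cnn_forward(model$weights, model$spec$layers, zero,
                         model$spec$n_classes)$logits
  delta_f <- f_x[cbind(seq_len(n), target + 1L)] -
    f_0[cbind(seq_len(n), target + 1L)]
  sum_attr <- apply(attr_cube, 3, sum)
  structure(list(per_feature = aperm(attr_cube, c(3, 1, 2)),
                 target = target, sum_attr = sum_attr, delta_f = delta_f,
                 residual = abs(sum_attr - delta_f), n_steps = n_steps),
            class = "attribution")
}

#' Per-metapixel importance scores
#'
#' Aggregates integrated-gradients attributions to one importance score per
#' metapixel: the absolute attributions are summed over each metapixel's
#' wavenumber block (its input channel), averaged over the supplied items,
#' and normalized so the most important metapixel scores 1.
#'
#' @param model A trained `cnn1d` (original variant).
#' @param x Items-first input array (typically the validation set).
#' @param target Per-item target class or `NULL` for the predicted class.
#' @param n_steps Riemann steps of the underlying IG computation. The
#'   default 128 is well inside the IG self-convergence regime for these
#'   models; raise it to 512 to reproduce the attribution-op default.
#' @return Numeric vector of per-metapixel importances in `[0, 1]`,
#'   normalized to max 1.
#' @export
metapixel_importance <- function(model, x, target = NULL, n_steps = 128) {
  ig <- integrated_gradients(model, x, target = target, n_steps = n_steps)
  per_channel <- apply(abs(ig$per_feature), c(1, 2), sum)  # items x channels
  imp <- colMeans(per_channel)
  mx <- max(imp)
  if (mx > 0) imp <- imp / mx
  imp
}

#' Select the most informative metapixels
#'
#' @param importance Per-metapixel importance scores.
#' @param nu0 Resonance positions of the metapixels (same order), used to
#'   break ties toward the lower resonance wavenumber.
#' @param k Number of metapixels to select.
#' @return Integer vector of metapixel indices (into `importance`), ordered
#'   by decreasing importance.
#' @export
select_top_metapixels <- function(importance, nu0 = seq_along(importance),
                                  k = 1) {
  if (k < 1) stop("select_top_metapixels: k must be >= 1")
  if (k > length(importance)) stop("select_top_metapixels: k exceeds metapixel count")
  if (length(nu0) != length(importance)) {
    stop("select_top_metapixels: nu0 length must match importance")
  }
  ord <- order(-importance, nu0)
  ord[seq_len(k)]
}

#' Classify a spectral time series
#'
#' Applies a trained (typically pruned) model to the per-frame spectra of
#' the selected metapixel. Excluded frames (LED on, or pre-equilibration)
#' are carried through flagged but still receive predictions.
#'
#' @param model A trained `cnn1d`.
#' @param frame_spectra Array `n_frames x channels x length` (or
#'   `n_frames x length` for a single-channel model).
#' @param time_s Frame time stamps (s).
#' @param excluded Logical exclusion flags per frame (default none).
#' @return Data.frame with `time_s`, `p_cis`, `label`, `excluded`.
#' @export
classify_timeseries <- function(model, frame_spectra, time_s = NULL,
                                excluded = NULL) {
  stopifnot(inherits(model, "cnn1d"))
  probs <- predict(model, frame_spectra, type = "prob")
  n <- nrow(probs)
  if (is.null(time_s)) time_s <- seq_len(n) - 1
  if (is.null(excluded)) excluded <- rep(FALSE, n)
  if (length(time_s) != n || length(excluded) != n) {
    stop("classify_timeseries: time_s/excluded length must match frame count")
  }
  data.frame(time_s = time_s, p_cis = probs[, "cis"],
             label = factor(ifelse(probs[, "cis"] >= 0.5, "cis", "trans"),
                            levels = c("trans", "cis")),
             excluded = excluded)
}
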