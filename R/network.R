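#' Convolutional network architecture specification
#'
#' Describes the family of architectures used for sweep detection and
#' selection-coefficient estimation: a stack of 2-D convolutional layers
#' (stride 1x1, no zero-padding, ReLU activations), each followed by a
#' max-pooling layer, then an optional fully-connected ReLU layer, and a
#' softmax output over the classes. The reference architectures use three
#' convolutional layers with 32/32/32, 32/64/64 or 32/64/128 filters and a
#' 3x3 kernel (5x5 as a variant), 2x2 max pooling, a 64-unit dense layer
#' (omitted for double-sorted images, where the spatial arrangement of
#' features already carries the signal), and a mini-batch size of 32.
#'
#' @param conv_filters integer vector of filter counts, one per
#'   convolutional layer.
#' @param kernel square kernel size (3 default, 5 variant).
#' @param pool_size max-pooling kernel (2 default; `<= 1` disables pooling).
#' @param dense_units units in the fully-connected layer, or `NULL` to omit
#'   it.
#' @param n_outputs number of output classes.
#' @param batch_size mini-batch size for training.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(conv_filters = c(32, 32, 32), kernel = 3,
                         pool_size = 2, dense_units = 64, n_outputs = 2,
                         batch_size = 32) {
  if (any(conv_filters < 1)) stop("filter counts must be >= 1", call. = FALSE)
  if (kernel < 1 || n_outputs < 2 || batch_size < 1)
    stop("invalid kernel, n_outputs or batch_size", call. = FALSE)
  structure(list(conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel),
                 pool = as.integer(max(pool_size, 0)),
                 dense_units = as.integer(if (is.null(dense_units)) 0 else dense_units),
                 n_outputs = as.integer(n_outputs),
                 batch_size = as.integer(batch_size)),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("CNN spec: conv filters [", paste(x$conv_filters, collapse = ", "),
      "], kernel ", x$kernel, "x", x$kernel,
      if (x$pool > 1) paste0(", max-pool ", x$pool, "x", x$pool) else ", no pooling",
      if (x$dense_units > 0) paste0(", dense ", x$dense_units) else ", no dense layer",
      ", ", x$n_outputs, " outputs\n", sep = "")
  invisible(x)
}

#' Per-layer output dimensions of a network
#'
#' Computes the feature-map chain implied by stride-1 valid (unpadded)
#' convolution — output side `in - kernel + 1` — and max pooling — output
#' side `floor(in / pool)` — and the flattened feature count entering the
#' dense/output stage. Errors, naming the offending layer, if any dimension
#' would fall below 1.
#'
#' @param spec a [network_spec].
#' @param input_height,input_width input image dimensions.
#' @return A list with `layers` (data frame of layer name, output height,
#'   width and channels) and `n_flat` (flattened feature count).
#' @examples
#' plan <- layer_shape_plan(network_spec(), 128, 128)
#' plan$layers
#' plan$n_flat   # 14 * 14 * 32 = 6272
#' @export
layer_shape_plan <- function(spec, input_height, input_width) {
  stopifnot(inherits(spec, "network_spec"))
  h <- input_height; w <- input_width; ch <- 1L
  rows <- list(data.frame(layer = "input", height = h, width = w, channels = ch))
  for (l in seq_along(spec$conv_filters)) {
    h <- h - spec$kernel + 1L
    w <- w - spec$kernel + 1L
    if (h < 1 || w < 1)
      stop("conv layer ", l, ": output would be ", h, "x", w,
           " (input too small for kernel ", spec$kernel, ")", call. = FALSE)
    ch <- spec$conv_filters[l]
    rows <- c(rows, list(data.frame(layer = paste0("conv", l), height = h,
                                    width = w, channels = ch)))
    if (spec$pool > 1) {
      h <- h %/% spec$pool
      w <- w %/% spec$pool
      if (h < 1 || w < 1)
        stop("pool layer ", l, ": output would be ", h, "x", w, call. = FALSE)
      rows <- c(rows, list(data.frame(layer = paste0("pool", l), height = h,
                                      width = w, channels = ch)))
    }
  }
  list(layers = do.call(rbind, rows), n_flat = h * w * ch)
}

#' Cross-entropy between two class distributions
#'
#' The training loss: `-sum(target * log(predicted))`, with predicted
#' entries clipped to `[eps, 1]` before the logarithm. It is bounded below
#' by the entropy of the target, with equality iff the distributions agree.
#'
#' @param predicted,target probability vectors of equal length.
#' @param eps clipping floor for predicted probabilities.
#' @return Scalar loss (nats).
#' @export
cross_entropy <- function(predicted, target, eps = 1e-12) {
  if (length(predicted) != length(target))
    stop("predicted and target must have equal length", call. = FALSE)
  validate_distribution(target)
  -sum(target * log(pmin(pmax(predicted, eps), 1)))
}

init_weights <- function(spec, input_height, input_width) {
  plan <- layer_shape_plan(spec, input_height, input_width)
  k <- spec$kernel
  conv_w <- list(); conv_b <- list()
  ch <- 1L
  for (l in seq_along(spec$conv_filters)) {
    fan_in <- ch * k * k
    f <- spec$conv_filters[l]
    conv_w[[l]] <- matrix(stats::rnorm(f * fan_in, sd = sqrt(2 / fan_in)), f, fan_in)
    conv_b[[l]] <- numeric(f)
    ch <- f
  }
  n_flat <- plan$n_flat
  if (spec$dense_units > 0) {
    dense_w <- matrix(stats::rnorm(spec$dense_units * n_flat,
                                   sd = sqrt(2 / n_flat)),
                      spec$dense_units, n_flat)
    dense_b <- numeric(spec$dense_units)
    n_prev <- spec$dense_units
  } else {
    dense_w <- matrix(0, 0, 0); dense_b <- numeric(0); n_prev <- n_flat
  }
  out_w <- matrix(stats::rnorm(spec$n_outputs * n_prev, sd = sqrt(1 / n_prev)),
                  spec$n_outputs, n_prev)
  out_b <- numeric(spec$n_outputs)
  list(conv_w = conv_w, conv_b = conv_b, dense_w = dense_w, dense_b = dense_b,
       out_w = out_w, out_b = out_b)
}

batch_pixels <- function(x) {
  if (inherits(x, "image_batch")) x$pixels
  else if (is.array(x) && length(dim(x)) == 3) x
  else stop("x must be an image_batch or an N x H x W array", call. = FALSE)
}

targets_matrix <- function(y, n, n_outputs) {
  if (is.matrix(y)) {
    if (nrow(y) != n || ncol(y) != n_outputs)
      stop("target matrix must be n_images x n_classes", call. = FALSE)
    apply(y, 1, validate_distribution)
    return(y)
  }
  y <- as.integer(y)
  if (length(y) != n) stop("one label per image required", call. = FALSE)
  if (any(y < 1 | y > n_outputs)) stop("labels out of class range", call. = FALSE)
  t(vapply(y, categorical_label, numeric(n_outputs), n_classes = n_outputs))
}

#' Fit a convolutional sweep-detection network
#'
#' Trains the architecture described by `spec` on a batch of haplotype
#' images with cross-entropy loss against categorical or soft (Gaussian /
#' perturbed-categorical) target distributions, using Adam updates on
#' mini-batches of `spec$batch_size`. Two schedules are available:
#' `"epochs"` performs standard multi-epoch training over the whole set
#' (reshuffled each epoch); `"one-pass"` partitions the training set into
#' `n_chunks` chunks, each visited exactly once, so that no example is seen
#' twice — the reproducible counterpart of training on freshly simulated
#' data at every iteration. All randomness (weight initialisation,
#' mini-batch order) derives from `seed`, so a fit is reproducible on a
#' single CPU thread.
#'
#' @param x an `image_batch` or an `N x H x W` array of pixel values in
#'   `[0, 1]`.
#' @param y integer class labels (1-based) or an `N x K` matrix of target
#'   distributions (see [label_targets()]). Defaults to the batch labels.
#' @param spec a [network_spec].
#' @param epochs training epochs (schedule `"epochs"` only).
#' @param learning_rate Adam learning rate.
#' @param schedule `"epochs"` or `"one-pass"`.
#' @param n_chunks number of one-pass chunks.
#' @param validation optional `image_batch` (with labels) used to record
#'   validation loss/accuracy at the end of every epoch or chunk.
#' @param seed integer seed for weight initialisation and batch order.
#' @return An object of class `sweep_cnn` with components `weights`,
#'   `spec`, `input_dim`, `history` (per-iteration data frame), `seed`,
#'   `schedule` and `learning_rate`.
#' @seealso [predict.sweep_cnn()], [evaluate_model()], [plot.sweep_cnn()]
#' @export
sweep_cnn <- function(x, y = NULL, spec = network_spec(), epochs = 5,
                      learning_rate = 1e-3,
                      schedule = c("epochs", "one-pass"), n_chunks = epochs,
                      validation = NULL, seed = 1) {
  schedule <- match.arg(schedule)
  stopifnot(inherits(spec, "network_spec"))
  px <- batch_pixels(x)
  n <- dim(px)[1]
  if (is.null(y)) {
    if (!inherits(x, "image_batch"))
      stop("y is required when x is a plain array", call. = FALSE)
    y <- x$labels
  }
  Y <- targets_matrix(y, n, spec$n_outputs)
  plan <- layer_shape_plan(spec, dim(px)[2], dim(px)[3])  # validates dims

  with_local_seed(seed, {
    weights <- init_weights(spec, dim(px)[2], dim(px)[3])
    history <- NULL
    passes <- plan_batches(n, schedule, epochs, n_chunks, spec$batch_size)
    iter0 <- 0L
    for (pass in seq_along(passes)) {
      batches <- passes[[pass]]
      res <- cnn_train_cpp(px, Y, weights, unclass(spec), batches,
                           learning_rate)
      weights <- res$weights
      h <- data.frame(iteration = iter0 + seq_along(res$iter_loss),
                      pass = pass,
                      train_loss = res$iter_loss, train_acc = res$iter_acc,
                      val_loss = NA_real_, val_acc = NA_real_)
      if (!is.null(validation) && length(validation) > 0) {
        vp <- predict_probs(weights, spec, batch_pixels(validation))
        vy <- targets_matrix(validation$labels, nrow(vp), spec$n_outputs)
        h$val_loss[nrow(h)] <-
          mean(vapply(seq_len(nrow(vp)),
                      function(i) cross_entropy(vp[i, ], vy[i, ]), 0))
        h$val_acc[nrow(h)] <-
          mean(max.col(vp, ties.method = "first") ==
                 max.col(vy, ties.method = "first"))
      }
      history <- rbind(history, h)
      iter0 <- iter0 + nrow(h)
    }
    structure(list(weights = weights, spec = spec,
                   input_dim = c(dim(px)[2], dim(px)[3]),
                   shape_plan = plan, history = history,
                   schedule = schedule, epochs = epochs, n_chunks = n_chunks,
                   learning_rate = learning_rate, seed = seed,
                   n_train = n),
              class = "sweep_cnn")
  })
}

# Minibatch plan: a list of passes, each a list of 1-based index vectors.
# "epochs": every pass reshuffles and covers the whole set.  "one-pass":
# the set is permuted once and partitioned into n_chunks chunks, so every
# example is visited exactly once overall.
plan_batches <- function(n, schedule, epochs, n_chunks, batch_size) {
  chop <- function(idx) split(idx, ceiling(seq_along(idx) / batch_size))
  if (schedule == "epochs") {
    lapply(seq_len(max(epochs, 1)), function(e) chop(sample.int(n)))
  } else {
    perm <- sample.int(n)
    chunks <- split(perm, cut(seq_along(perm), max(n_chunks, 1), labels = FALSE))
    lapply(chunks, chop)
  }
}

predict_probs <- function(weights, spec, pixels) {
  cnn_forward_cpp(pixels, weights, unclass(spec))
}

#' Predict from a fitted sweep-detection network
#'
#' @param object a fitted `sweep_cnn`.
#' @param newdata an `image_batch` or `N x H x W` array; dimensions must
#'   match the fit.
#' @param type `"prob"` for the `N x K` matrix of softmax class
#'   probabilities (each row a posterior distribution over classes) or
#'   `"class"` for 1-based maximum a posteriori class indices.
#' @param ... ignored.
#' @return Matrix of probabilities or integer vector of classes.
#' @export
predict.sweep_cnn <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  px <- batch_pixels(newdata)
  if (!all(dim(px)[2:3] == object$input_dim))
    stop("image dimensions ", dim(px)[2], "x", dim(px)[3],
         " do not match the fitted network (", object$input_dim[1], "x",
         object$input_dim[2], ")", call. = FALSE)
  p <- predict_probs(object$weights, object$spec, px)
  if (type == "class") max.col(p, ties.method = "first") else p
}

#' @export
print.sweep_cnn <- function(x, ...) {
  print(x$spec)
  cat("Input ", x$input_dim[1], "x", x$input_dim[2], ", trained on ",
      x$n_train, " images (", x$schedule, " schedule, seed ", x$seed, ")\n",
      sep = "")
  cat("Final training loss ", signif(utils::tail(x$history$train_loss, 1), 4),
      ", accuracy ", signif(utils::tail(x$history$train_acc, 1), 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.sweep_cnn <- function(object, ...) {
  h <- object$history
  out <- list(spec = object$spec, shape_plan = object$shape_plan,
              n_iterations = nrow(h),
              final_train_loss = utils::tail(h$train_loss, 1),
              final_train_acc = utils::tail(h$train_acc, 1),
              final_val_loss = utils::tail(stats::na.omit(h$val_loss), 1),
              final_val_acc = utils::tail(stats::na.omit(h$val_acc), 1))
  class(out) <- "summary.sweep_cnn"
  out
}

#' @export
print.summary.sweep_cnn <- function(x, ...) {
  print(x$spec)
  print(x$shape_plan$layers, row.names = FALSE)
  cat("Flattened features:", x$shape_plan$n_flat, "\n")
  cat("Iterations:", x$n_iterations, "\n")
  cat("Final train loss/acc:", signif(x$final_train_loss, 4), "/",
      signif(x$final_train_acc, 4), "\n")
  if (length(x$final_val_loss))
    cat("Final validation loss/acc:", signif(x$final_val_loss, 4), "/",
        signif(x$final_val_acc, 4), "\n")
  invisible(x)
}

#' @export
coef.sweep_cnn <- function(object, ...) object$weights

#' Plot training history
#'
#' Training loss per iteration, with validation loss points where recorded.
#'
#' @param x a fitted `sweep_cnn`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sweep_cnn <- function(x, ...) {
  h <- x$history
  graphics::plot(h$iteration, h$train_loss, type = "l",
                 xlab = "iteration", ylab = "cross-entropy loss", ...)
  ok <- !is.na(h$val_loss)
  if (any(ok)) {
    graphics::points(h$iteration[ok], h$val_loss[ok], pch = 19, col = 2)
    graphics::legend("topright", c("train", "validation"),
                     lty = c(1, NA), pch = c(NA, 19), col = c(1, 2), bty = "n")
  }
  invisible(x)
}

#' Evaluate a fitted network on a labelled test batch
#'
#' @param model a fitted `sweep_cnn`.
#' @param test a labelled `image_batch`.
#' @return An object of class `cnn_evaluation`: `confusion` (true class in
#'   rows, predicted MAP class in columns), `rates` (row-normalised
#'   confusion) and `accuracy` (trace over total).
#' @export
evaluate_model <- function(model, test) {
  stopifnot(inherits(model, "sweep_cnn"))
  if (!length(test)) stop("empty test set", call. = FALSE)
  pred <- predict(model, test, type = "class")
  k <- model$spec$n_outputs
  confusion <- table(factor(test$labels, levels = seq_len(k)),
                     factor(pred, levels = seq_len(k)))
  confusion <- unclass(confusion)
  dimnames(confusion) <- list(true = seq_len(k), predicted = seq_len(k))
  rates <- confusion / pmax(rowSums(confusion), 1)
  structure(list(confusion = confusion, rates = rates,
                 accuracy = sum(diag(confusion)) / sum(confusion)),
            class = "cnn_evaluation")
}

#' @export
print.cnn_evaluation <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted):\n")
  print(x$confusion)
  cat("Accuracy:", signif(x$accuracy, 4), "\n")
  invisible(x)
}

#' Save and restore fitted networks; export training history
#'
#' `save_sweep_cnn`/`load_sweep_cnn` persist the full fitted object
#' (weights, spec, history, seed) in R's native serialisation format.
#' `write_training_run` exports the per-iteration history as CSV with a
#' JSON sidecar recording the architecture, schedule and seed.
#'
#' @param model a fitted `sweep_cnn`.
#' @param path file path (`.rds` for checkpoints, `.csv` for history).
#' @return The path, invisibly (`load_sweep_cnn` returns the model).
#' @export
save_sweep_cnn <- function(model, path) {
  stopifnot(inherits(model, "sweep_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_sweep_cnn
#' @export
load_sweep_cnn <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "sweep_cnn")) stop("not a sweep_cnn checkpoint", call. = FALSE)
  m
}

#' @rdname save_sweep_cnn
#' @export
write_training_run <- function(model, path) {
  stopifnot(inherits(model, "sweep_cnn"))
  utils::write.csv(model$history, path, row.names = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(spec = unclass(model$spec), schedule = model$schedule,
         epochs = model$epochs, n_chunks = model$n_chunks,
         learning_rate = model$learning_rate, seed = model$seed,
         input_dim = model$input_dim),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
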