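#' Discretisation of the selection coefficient into classes
#'
#' Divides the parameter range `[minimum, maximum]` into `n_classes`
#' linearly spaced bins represented by their midpoints, which include both
#' bounds. The worked analyses use 11 classes over selection coefficients
#' 0 to 400 (in `2 * Ne` units), so the midpoints are 0, 40, ..., 400 and
#' neutrality (`S = 0`) is its own class. Class indices are 1-based
#' throughout the package.
#'
#' @param minimum,maximum parameter bounds, `minimum < maximum`.
#' @param n_classes number of classes `K >= 2`.
#' @return An object of class `binning_scheme` with a `midpoints` field of
#'   length `K`.
#' @examples
#' sc <- binning_scheme(0, 400, 11)
#' sc$midpoints
#' assign_class(120, sc)   # class 4, midpoint 120
#' @export
binning_scheme <- function(minimum = 0, maximum = 400, n_classes = 11) {
  if (maximum <= minimum) stop("maximum must exceed minimum", call. = FALSE)
  if (n_classes < 2) stop("need at least 2 classes", call. = FALSE)
  structure(list(minimum = minimum, maximum = maximum,
                 n_classes = as.integer(n_classes),
                 midpoints = seq(minimum, maximum, length.out = n_classes)),
            class = "binning_scheme")
}

#' @export
print.binning_scheme <- function(x, ...) {
  cat("Binning scheme: ", x$n_classes, " classes over [", x$minimum, ", ",
      x$maximum, "], midpoints ", paste(signif(x$midpoints, 4), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Assign parameter values to classes
#'
#' Maps each value to the class with the nearest midpoint; a value exactly
#' halfway between two midpoints goes to the lower class. Values outside
#' the scheme's range are an error.
#'
#' @param value numeric vector of parameter values.
#' @param scheme a [binning_scheme].
#' @return Integer vector of 1-based class indices.
#' @export
assign_class <- function(value, scheme) {
  stopifnot(inherits(scheme, "binning_scheme"))
  if (any(value < scheme$minimum | value > scheme$maximum))
    stop("value outside [", scheme$minimum, ", ", scheme$maximum, "]",
         call. = FALSE)
  spacing <- (scheme$maximum - scheme$minimum) / (scheme$n_classes - 1)
  raw <- (value - scheme$minimum) / spacing
  idx <- as.integer(ceiling(raw - 0.5))   # round half down -> lower class
  pmin(pmax(idx, 0L), scheme$n_classes - 1L) + 1L
}

validate_distribution <- function(p) {
  if (any(p < 0)) stop("label distribution has negative entries", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9)
    stop("label distribution does not sum to 1", call. = FALSE)
  p
}

#' Categorical (one-hot) label distribution
#'
#' All probability mass on the true class: the Dirac-delta representation
#' of the target distribution.
#'
#' @param class_index 1-based true class.
#' @param n_classes number of classes `K`.
#' @return Numeric probability vector of length `K`.
#' @export
categorical_label <- function(class_index, n_classes) {
  if (class_index < 1 || class_index > n_classes)
    stop("class_index out of range", call. = FALSE)
  p <- numeric(n_classes)
  p[class_index] <- 1
  p
}

#' Gaussian label distribution
#'
#' A soft target centred on the true class: weights
#' `exp(-(k - c)^2 / (2 sd^2))` evaluated at the integer class indices and
#' renormalised to sum to one. Unlike the categorical target this
#' increasingly penalises predictions farther from the truth. At
#' `sd = 0.5` the centre class receives about 0.787 of the mass and each
#' immediate neighbour about 0.106.
#'
#' @param class_index 1-based true class.
#' @param n_classes number of classes `K`.
#' @param sd standard deviation in class-index units, `> 0`.
#' @return Numeric probability vector of length `K` with argmax at
#'   `class_index`.
#' @export
gaussian_label <- function(class_index, n_classes, sd = 0.5) {
  if (class_index < 1 || class_index > n_classes)
    stop("class_index out of range", call. = FALSE)
  if (sd <= 0) stop("sd must be positive", call. = FALSE)
  k <- seq_len(n_classes)
  w <- exp(-(k - class_index)^2 / (2 * sd^2))
  w / sum(w)
}

#' Randomly perturb class labels
#'
#' Shifts each true class by a step drawn uniformly from the valid subset
#' of `{-max_step, ..., +max_step}` (steps that would leave `[1, K]` are
#' excluded from the draw rather than clamped, so boundary classes are not
#' inflated). Deterministic given the RNG state.
#'
#' @param class_index integer vector of 1-based true classes.
#' @param n_classes number of classes `K`.
#' @param max_step maximum shift in either direction.
#' @return Integer vector of perturbed classes, same length as input.
#' @export
perturb_label <- function(class_index, n_classes, max_step = 1) {
  if (any(class_index < 1 | class_index > n_classes))
    stop("class_index out of range", call. = FALSE)
  if (max_step == 0) return(as.integer(class_index))
  vapply(as.integer(class_index), function(ci) {
    valid <- (ci - max_step):(ci + max_step)
    valid <- valid[valid >= 1L & valid <= n_classes]
    valid[sample.int(length(valid), 1L)]
  }, integer(1))
}

#' Build target distributions for a vector of class labels
#'
#' @param class_index integer vector of 1-based classes.
#' @param n_classes number of classes `K`.
#' @param representation `"categorical"`, `"gaussian"` or `"perturbed"`
#'   (perturbed categorical, maximum step `max_step`).
#' @param sd standard deviation for the Gaussian representation.
#' @param max_step maximum shift for the perturbed representation.
#' @return `length(class_index) x K` matrix of row distributions.
#' @export
label_targets <- function(class_index,
                          n_classes,
                          representation = c("categorical", "gaussian", "perturbed"),
                          sd = 0.5, max_step = 1) {
  representation <- match.arg(representation)
  ci <- as.integer(class_index)
  if (representation == "perturbed")
    ci <- perturb_label(ci, n_classes, max_step)
  t(vapply(ci, function(c) {
    if (representation == "gaussian") gaussian_label(c, n_classes, sd)
    else categorical_label(c, n_classes)
  }, numeric(n_classes)))
}

#' Shuffle and split an image batch
#'
#' Applies a uniform random permutation, then takes `test_fraction` of the
#' whole data as the test set and `validation_fraction` of the remaining
#' training portion as the validation set. With fractions (0.1, 0.1) and
#' 1000 images this gives 100 test, 90 validation and 810 training images.
#' The three index sets are disjoint and exhaustive and the split is
#' reproducible via `seed`.
#'
#' @param batch an `image_batch` (see [build_image_batch()]).
#' @param test_fraction,validation_fraction fractions in `[0, 1)`.
#' @param seed optional integer seed.
#' @return A list with `train`, `validation`, `test` (image batches, the
#'   latter two possibly zero-length when their fraction is 0), `indices`
#'   (the three index vectors into the input batch) and
#'   `label_proportions` (per-split class proportions).
#' @export
shuffle_split <- function(batch, test_fraction = 0.1,
                          validation_fraction = 0.1, seed = NULL) {
  stopifnot(inherits(batch, "image_batch"))
  if (test_fraction < 0 || test_fraction >= 1 ||
      validation_fraction < 0 || validation_fraction >= 1)
    stop("fractions must lie in [0, 1)", call. = FALSE)
  n <- length(batch)
  with_local_seed(seed, {
    perm <- sample.int(n)
    n_test <- round(test_fraction * n)
    test_idx <- if (n_test > 0) perm[seq_len(n_test)] else integer()
    rest <- if (n_test > 0) perm[-seq_len(n_test)] else perm
    n_val <- round(validation_fraction * length(rest))
    val_idx <- if (n_val > 0) rest[seq_len(n_val)] else integer()
    train_idx <- if (n_val > 0) rest[-seq_len(n_val)] else rest
    if (!length(train_idx))
      stop("training split is empty", call. = FALSE)
    if (test_fraction > 0 && !length(test_idx))
      stop("test split is empty", call. = FALSE)
    if (validation_fraction > 0 && !length(val_idx))
      stop("validation split is empty", call. = FALSE)
    props <- function(idx) {
      if (!length(idx)) return(numeric())
      prop.table(table(factor(batch$labels[idx],
                              levels = sort(unique(batch$labels)))))
    }
    list(train = batch[train_idx],
         validation = batch[val_idx],
         test = batch[test_idx],
         indices = list(train = train_idx, validation = val_idx,
                        test = test_idx, seed = seed),
         label_proportions = list(train = props(train_idx),
                                  validation = props(val_idx),
                                  test = props(test_idx)))
  })
}
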