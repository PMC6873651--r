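#' Run a self-contained detection or quantification experiment
#'
#' Composes the whole pipeline on generated fixtures: one class per entry
#' of `intensities` (class 1 should be 0, i.e. neutrality), imaging with
#' the requested sorting at `image_size` pixels, a shuffled
#' train/validation/test split, a CNN fit, and held-out evaluation. This is
#' the programmatic counterpart of [run_pipeline()] used for quick
#' experiments and for the package's own validation runs.
#'
#' @param intensities sweep intensity per class (first entry 0 for the
#'   neutral class).
#' @param n_replicates fixtures per class.
#' @param sorting image sorting option, as in [image_config()].
#' @param image_size square image side in pixels.
#' @param n_haplotypes,target_sites,core_width fixture dimensions, as in
#'   [generate_fixture()].
#' @param conv_filters,kernel,dense_units architecture, as in
#'   [network_spec()]. By default the dense layer is dropped for
#'   double-sorted images (their spatial feature arrangement makes it
#'   unnecessary) and kept otherwise.
#' @param epochs training epochs.
#' @param test_fraction,validation_fraction split fractions.
#' @param label_representation,label_sd target-distribution representation
#'   for training, as in [label_targets()].
#' @param seed master seed for fixtures, split and fit.
#' @return A list with `model` (the [sweep_cnn()] fit), `evaluation`
#'   (held-out [evaluate_model()] result), `accuracy`, `splits`
#'   and `test_probs` (softmax class probabilities on the test set).
#' @examples
#' \donttest{
#' ex <- detection_experiment(c(0, 0.8), n_replicates = 100,
#'                            image_size = 32, epochs = 2, seed = 1)
#' ex$accuracy
#' }
#' @export
detection_experiment <- function(intensities = c(0, 0.8), n_replicates = 500,
                                 sorting = "rows_and_columns",
                                 image_size = 64, n_haplotypes = 64,
                                 target_sites = 96, core_width = 0.5,
                                 conv_filters = c(32, 32, 32), kernel = 3,
                                 dense_units = if (sorting == "rows_and_columns") NULL else 64,
                                 epochs = 2, test_fraction = 0.15,
                                 validation_fraction = 0.1,
                                 label_representation = "categorical",
                                 label_sd = 0.5, seed = 1) {
  fs <- generate_fixture_set(intensities, n_replicates, n = n_haplotypes,
                             target_sites = target_sites,
                             core_width = core_width, seed = seed)
  cfg <- image_config(sorting = sorting, target_height = image_size,
                      target_width = image_size)
  batch <- build_image_batch(fs$alignments, fs$class, cfg)
  splits <- shuffle_split(batch, test_fraction, validation_fraction,
                          seed = seed + 1L)
  spec <- network_spec(conv_filters = conv_filters, kernel = kernel,
                       dense_units = dense_units,
                       n_outputs = length(intensities))
  y <- with_local_seed(seed + 2L,
    label_targets(splits$train$labels, length(intensities),
                  representation = label_representation, sd = label_sd))
  model <- sweep_cnn(splits$train, y, spec = spec, epochs = epochs,
                     validation = splits$validation, seed = seed + 3L)
  ev <- evaluate_model(model, splits$test)
  list(model = model, evaluation = ev, accuracy = ev$accuracy,
       splits = splits,
       test_probs = predict(model, splits$test, type = "prob"))
}
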