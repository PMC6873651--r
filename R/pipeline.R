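config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("sweepimage_config_error",
                                             "error", "condition")))
}
missing_input_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("sweepimage_missing_input",
                                             "error", "condition")))
}

config_schema <- list(
  seed = NULL, outdir = NULL, log_file = NULL,
  simulate = list(
    intensities = NULL, n_replicates = NULL, n_haplotypes = NULL,
    target_sites = NULL, core_width = NULL,
    msms = list(selection_coefficients = NULL, demography = NULL,
                sample_size = NULL, region_length = NULL,
                mutation_rate = NULL, recombination_rate = NULL,
                reference_Ne = NULL, n_replicates = NULL)),
  images = list(
    polarization = NULL, maf_threshold = NULL, sorting = NULL,
    sort_criterion = NULL, target_height = NULL, target_width = NULL,
    resize_policy = NULL, interpolation = NULL,
    test_fraction = NULL, validation_fraction = NULL),
  network = list(conv_filters = NULL, kernel = NULL, pool_size = NULL,
                 dense_units = NULL, batch_size = NULL),
  training = list(epochs = NULL, learning_rate = NULL, schedule = NULL,
                  n_chunks = NULL, label_representation = NULL,
                  label_sd = NULL, label_max_step = NULL),
  inference = list(alpha = NULL, n_samples = NULL,
                   binning = list(minimum = NULL, maximum = NULL,
                                  n_classes = NULL))
)

check_unknown_keys <- function(cfg, schema, path = "") {
  if (!is.list(cfg)) return(invisible())
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    config_error("unknown configuration key(s): ",
                 paste0(path, unknown, collapse = ", "))
  for (nm in names(cfg))
    if (is.list(schema[[nm]]))
      check_unknown_keys(cfg[[nm]], schema[[nm]], paste0(path, nm, "."))
  invisible()
}

#' Read and validate a pipeline run configuration
#'
#' A run configuration is a single YAML file with per-stage sections
#' (`simulate`, `images`, `network`, `training`, `inference`) plus a global
#' `seed` and `outdir`. Unknown keys anywhere in the file are rejected, and
#' every downstream constructor's validation runs at load time so that a
#' bad configuration fails before any stage starts.
#'
#' @param path path to a YAML file.
#' @param overrides named list merged over the file's values (CLI flags).
#' @return A validated configuration of class `run_config`, including a
#'   `hash` field identifying its exact content.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) missing_input_error("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  check_unknown_keys(cfg, config_schema)
  defaults <- list(
    seed = 1, outdir = "sweepimage_out",
    simulate = list(intensities = c(0, 0.8), n_replicates = 100,
                    n_haplotypes = 64, target_sites = 96, core_width = 0.5),
    images = list(maf_threshold = 0.01, sorting = "rows_and_columns",
                  target_height = 64, target_width = 64,
                  test_fraction = 0.1, validation_fraction = 0.1),
    network = list(conv_filters = c(32, 32, 32), kernel = 3,
                   dense_units = 64, batch_size = 32),
    training = list(epochs = 3, learning_rate = 1e-3, schedule = "epochs",
                    label_representation = "categorical"),
    inference = list(alpha = 0.05, n_samples = 100000)
  )
  cfg <- utils::modifyList(defaults, cfg)
  # eager validation through the constructors
  ic <- do.call(image_config, cfg$images[intersect(names(cfg$images),
                                                   names(formals(image_config)))])
  n_classes <- length(cfg$simulate$intensities)
  ns <- network_spec(conv_filters = unlist(cfg$network$conv_filters),
                     kernel = cfg$network$kernel,
                     dense_units = cfg$network$dense_units,
                     n_outputs = n_classes,
                     batch_size = cfg$network$batch_size %||% 32)
  layer_shape_plan(ns, cfg$images$target_height, cfg$images$target_width)
  if (!is.null(cfg$inference$binning))
    do.call(binning_scheme, cfg$inference$binning)
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  cfg$hash <- unname(tools::md5sum(tmp))
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_line <- function(cfg, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(cfg$log_file))
    cat(msg, "\n", file = cfg$log_file, append = TRUE)
}

artifact <- function(cfg, name) file.path(cfg$outdir, name)

need_artifact <- function(cfg, name, producer) {
  f <- artifact(cfg, name)
  if (!file.exists(f))
    missing_input_error("required artifact '", f, "' is missing; run the '",
                        producer, "' stage first")
  f
}

stamp <- function(cfg, extra = list()) {
  c(list(config_hash = cfg$hash, seed = cfg$seed), extra)
}

#' Run one pipeline stage
#'
#' Orchestrates the analysis end to end through five stages, each reading
#' the previous stage's artifacts from `outdir`:
#' \describe{
#'   \item{simulate}{writes per-class ms-format fixture files (and, when an
#'     `msms` section is configured, a script of simulator command lines).}
#'   \item{images}{parses the ms files, builds image batches, splits them
#'     into train/validation/test and writes the three batches plus the
#'     split indices.}
#'   \item{train}{fits the configured network and writes the checkpoint and
#'     the training history (CSV plus JSON sidecar).}
#'   \item{predict}{writes per-image posterior summaries (JSON and CSV)
#'     for the test batch.}
#'   \item{summarize}{writes the confusion matrix and accuracy.}
#' }
#' Every artifact is stamped with the configuration hash and seed; a stage
#' refuses to run if a required upstream artifact is missing or was
#' produced by a different configuration.
#'
#' @param stage one of `"simulate"`, `"images"`, `"train"`, `"predict"`,
#'   `"summarize"`.
#' @param config a `run_config` from [read_run_config()].
#' @return Invisibly, the paths of the artifacts written.
#' @export
run_stage <- function(stage = c("simulate", "images", "train", "predict",
                                "summarize"),
                      config) {
  stage <- match.arg(stage)
  if (!inherits(config, "run_config"))
    config_error("config must come from read_run_config()")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  switch(stage,
         simulate = stage_simulate(config),
         images = stage_images(config),
         train = stage_train(config),
         predict = stage_predict(config),
         summarize = stage_summarize(config))
}

#' Run the whole pipeline
#'
#' Convenience wrapper calling [run_stage()] for all five stages in order.
#'
#' @param config a `run_config`.
#' @return Invisibly, all artifact paths.
#' @export
run_pipeline <- function(config) {
  paths <- lapply(c("simulate", "images", "train", "predict", "summarize"),
                  run_stage, config = config)
  invisible(unlist(paths))
}

stage_simulate <- function(cfg) {
  s <- cfg$simulate
  set <- generate_fixture_set(unlist(s$intensities), s$n_replicates,
                              n = s$n_haplotypes, target_sites = s$target_sites,
                              core_width = s$core_width, seed = cfg$seed)
  paths <- character()
  for (k in seq_along(s$intensities)) {
    f <- artifact(cfg, sprintf("sims_class%d.ms", k))
    write_ms(set$alignments[set$class == k], f)
    paths <- c(paths, f)
  }
  if (!is.null(s$msms)) {
    cmds <- vapply(unlist(s$msms$selection_coefficients), function(S) {
      demo <- if (identical(s$msms$demography, "3-epoch"))
        example_demography("3-epoch") else NULL
      build_simulator_command(sim_params(
        sample_size = s$msms$sample_size %||% 128,
        region_length = s$msms$region_length %||% 80000,
        mutation_rate = s$msms$mutation_rate %||% 1.5e-8,
        recombination_rate = s$msms$recombination_rate %||% 1e-8,
        reference_Ne = s$msms$reference_Ne %||% 10000,
        selection_coefficient = S, demography = demo,
        n_replicates = s$msms$n_replicates %||% 1000, seed = cfg$seed))
    }, "")
    f <- artifact(cfg, "simulator_commands.sh")
    writeLines(c("#!/bin/sh", cmds), f)
    paths <- c(paths, f)
  }
  jsonlite::write_json(stamp(cfg, list(files = basename(paths))),
                       artifact(cfg, "simulate.json"), auto_unbox = TRUE)
  log_line(cfg, "simulate: wrote ", length(paths), " file(s)")
  invisible(paths)
}

stage_images <- function(cfg) {
  k_classes <- length(cfg$simulate$intensities)
  alignments <- list(); labels <- integer()
  for (k in seq_len(k_classes)) {
    f <- need_artifact(cfg, sprintf("sims_class%d.ms", k), "simulate")
    reps <- parse_ms(f)
    alignments <- c(alignments, reps)
    labels <- c(labels, rep.int(k, length(reps)))
  }
  ic <- do.call(image_config,
                cfg$images[intersect(names(cfg$images),
                                     names(formals(image_config)))])
  batch <- build_image_batch(alignments, labels, ic)
  splits <- shuffle_split(batch, cfg$images$test_fraction,
                          cfg$images$validation_fraction, seed = cfg$seed)
  paths <- character()
  for (nm in c("train", "validation", "test")) {
    f <- artifact(cfg, paste0("batch_", nm, ".rds"))
    b <- splits[[nm]]
    attr(b, "config_hash") <- cfg$hash
    saveRDS(b, f)
    paths <- c(paths, f)
  }
  jsonlite::write_json(stamp(cfg, list(indices = splits$indices,
                                       n_dropped = batch$n_dropped)),
                       artifact(cfg, "splits.json"), auto_unbox = TRUE)
  log_line(cfg, "images: ", length(batch), " images; splits ",
           paste(vapply(splits[c("train", "validation", "test")], length, 0L),
                 collapse = "/"))
  invisible(c(paths, artifact(cfg, "splits.json")))
}

check_hash <- function(cfg, obj, name) {
  h <- attr(obj, "config_hash")
  if (!is.null(h) && !identical(h, cfg$hash))
    missing_input_error("artifact '", name, "' was produced by a different ",
                        "configuration (hash mismatch); re-run upstream stages")
  obj
}

stage_train <- function(cfg) {
  train <- check_hash(cfg, readRDS(need_artifact(cfg, "batch_train.rds", "images")),
                      "batch_train.rds")
  val <- readRDS(need_artifact(cfg, "batch_validation.rds", "images"))
  n_classes <- length(cfg$simulate$intensities)
  ns <- network_spec(conv_filters = unlist(cfg$network$conv_filters),
                     kernel = cfg$network$kernel,
                     dense_units = cfg$network$dense_units,
                     n_outputs = n_classes,
                     batch_size = cfg$network$batch_size %||% 32)
  tr <- cfg$training
  y <- with_local_seed(cfg$seed,
    label_targets(train$labels, n_classes,
                  representation = tr$label_representation %||% "categorical",
                  sd = tr$label_sd %||% 0.5,
                  max_step = tr$label_max_step %||% 1))
  model <- sweep_cnn(train, y, spec = ns, epochs = tr$epochs,
                     learning_rate = tr$learning_rate,
                     schedule = tr$schedule %||% "epochs",
                     n_chunks = tr$n_chunks %||% tr$epochs,
                     validation = if (length(val)) val else NULL,
                     seed = cfg$seed)
  f <- artifact(cfg, "model.rds")
  attr(model, "config_hash") <- cfg$hash
  saveRDS(model, f)
  write_training_run(model, artifact(cfg, "training_run.csv"))
  log_line(cfg, "train: final training accuracy ",
           signif(utils::tail(model$history$train_acc, 1), 4))
  invisible(c(f, artifact(cfg, "training_run.csv")))
}

inference_scheme <- function(cfg) {
  if (!is.null(cfg$inference$binning))
    do.call(binning_scheme, cfg$inference$binning)
  else {
    k <- length(cfg$simulate$intensities)
    # map class index directly: midpoints 1..K
    binning_scheme(1, k, k)
  }
}

stage_predict <- function(cfg) {
  model <- check_hash(cfg, readRDS(need_artifact(cfg, "model.rds", "train")),
                      "model.rds")
  test <- readRDS(need_artifact(cfg, "batch_test.rds", "images"))
  if (!length(test)) missing_input_error("test batch is empty")
  probs <- predict(model, test, type = "prob")
  scheme <- inference_scheme(cfg)
  tab <- posterior_table(probs, scheme, alpha = cfg$inference$alpha,
                         n_samples = cfg$inference$n_samples,
                         seed = cfg$seed)
  tab$true_class <- test$labels
  f_csv <- artifact(cfg, "posteriors.csv")
  write_posterior_csv(tab, f_csv)
  summaries <- lapply(seq_len(nrow(probs)), function(i)
    selection_posterior(probs[i, ], scheme, alpha = cfg$inference$alpha,
                        n_samples = cfg$inference$n_samples,
                        seed = cfg$seed + i))
  f_json <- artifact(cfg, "posteriors.json")
  write_posterior_json(summaries, f_json)
  log_line(cfg, "predict: wrote posterior summaries for ", nrow(probs),
           " test images")
  invisible(c(f_csv, f_json))
}

stage_summarize <- function(cfg) {
  model <- check_hash(cfg, readRDS(need_artifact(cfg, "model.rds", "train")),
                      "model.rds")
  test <- readRDS(need_artifact(cfg, "batch_test.rds", "images"))
  ev <- evaluate_model(model, test)
  f_conf <- artifact(cfg, "confusion.csv")
  utils::write.csv(as.data.frame.matrix(ev$confusion), f_conf)
  f_json <- artifact(cfg, "metrics.json")
  jsonlite::write_json(stamp(cfg, list(accuracy = ev$accuracy,
                                       rates = ev$rates)),
                       f_json, auto_unbox = TRUE, digits = NA)
  log_line(cfg, "summarize: test accuracy ", signif(ev$accuracy, 4))
  invisible(c(f_conf, f_json))
}
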