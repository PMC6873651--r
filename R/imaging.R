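#' Image-processing configuration
#'
#' Settings controlling how haplotype alignments are converted into
#' fixed-size binary images. The processing order is fixed:
#' polarise, then filter on minor allele frequency, then sort, then resize.
#'
#' @param polarization `"major-minor"` recodes each column so the most
#'   frequent allele becomes 0 and the least frequent becomes 1 (used when
#'   the ancestral state is unknown); `"derived"` leaves alleles as
#'   simulated (0 = ancestral, 1 = derived).
#' @param maf_threshold columns with minor allele frequency strictly below
#'   this are removed; must be in `[0, 0.5)`. The worked analyses use 0.01,
#'   which with 128 chromosomes removes singletons but keeps doubletons.
#' @param sorting which axes to sort by frequency of occurrence:
#'   `"none"`, `"rows"`, `"columns"` or `"rows_and_columns"`.
#' @param sort_criterion `"pattern"` sorts by pattern-occurrence
#'   multiplicity (identical rows/columns grouped, most frequent first);
#'   `"allele_count"` sorts by per-row/per-column count of 1-alleles.
#' @param target_height,target_width output dimensions in pixels.
#' @param resize_policy `"fixed"` resizes every image to
#'   `target_height x target_width`; `"mean"` uses the rounded mean column
#'   count across the batch (after filtering) as the width.
#' @param interpolation `"nearest"` (default; preserves binary values and is
#'   deterministic across platforms) or `"bilinear"`.
#' @return An object of class `image_config`.
#' @export
image_config <- function(polarization = c("major-minor", "derived"),
                         maf_threshold = 0.01,
                         sorting = c("none", "rows", "columns", "rows_and_columns"),
                         sort_criterion = c("pattern", "allele_count"),
                         target_height = 128, target_width = 128,
                         resize_policy = c("fixed", "mean"),
                         interpolation = c("nearest", "bilinear")) {
  polarization <- match.arg(polarization)
  sorting <- match.arg(sorting)
  sort_criterion <- match.arg(sort_criterion)
  resize_policy <- match.arg(resize_policy)
  interpolation <- match.arg(interpolation)
  if (maf_threshold < 0 || maf_threshold >= 0.5)
    stop("maf_threshold must be in [0, 0.5)", call. = FALSE)
  if (target_height < 1 || target_width < 1)
    stop("target dimensions must be at least 1", call. = FALSE)
  structure(list(polarization = polarization, maf_threshold = maf_threshold,
                 sorting = sorting, sort_criterion = sort_criterion,
                 target_height = as.integer(target_height),
                 target_width = as.integer(target_width),
                 resize_policy = resize_policy, interpolation = interpolation),
            class = "image_config")
}

#' Polarise alleles to major/minor coding
#'
#' Recodes every column of an alignment so that the most frequent allele is
#' 0 and the least frequent is 1, the representation used when the
#' ancestral allelic state is unknown. A column exactly at a 50/50 split is
#' left unchanged (the allele coded 1 stays "minor"), which makes the
#' operation deterministic and order-independent. Idempotent.
#'
#' @param a a [haplotype_alignment].
#' @return The polarised [haplotype_alignment]; positions unchanged.
#' @export
polarize_major_minor <- function(a) {
  validate_alignment(a)
  m <- a$matrix
  if (ncol(m)) {
    flip <- colSums(m) > nrow(m) / 2
    m[, flip] <- 1L - m[, flip, drop = FALSE]
  }
  a$matrix <- m
  a
}

#' Filter columns on minor allele frequency
#'
#' Removes columns whose minor allele frequency is strictly below
#' `threshold`, together with their positions; relative column order is
#' preserved. Frequency exactly at the threshold is retained. Idempotent.
#'
#' @param a a [haplotype_alignment].
#' @param threshold minimum minor allele frequency, in `[0, 0.5)`.
#' @return The filtered [haplotype_alignment] (possibly with zero columns,
#'   in which case the validity invariant on columns is vacuous).
#' @export
filter_maf <- function(a, threshold = 0.01) {
  if (threshold >= 0.5 || threshold < 0)
    stop("threshold must be in [0, 0.5)", call. = FALSE)
  validate_alignment(a)
  m <- a$matrix
  if (!ncol(m)) return(a)
  maf <- pmin(colSums(m), nrow(m) - colSums(m)) / nrow(m)
  keep <- maf >= threshold
  a$matrix <- m[, keep, drop = FALSE]
  a$positions <- a$positions[keep]
  a
}

# Deterministic frequency-of-occurrence ordering of the rows of `m`:
# identical patterns grouped, groups in non-increasing multiplicity order,
# ties broken lexicographically descending on the pattern.
pattern_order <- function(m) {
  keys <- apply(m, 1, paste, collapse = "")
  mult <- as.vector(table(keys)[keys])
  order(mult, keys, method = "radix", decreasing = c(TRUE, TRUE))
}

#' Sort alignment rows and/or columns by frequency of occurrence
#'
#' Reorders rows (and/or columns) so that identical patterns are grouped
#' and groups appear in non-increasing multiplicity order — rows from top
#' to bottom, columns from left to right. Ties between groups of equal
#' multiplicity are broken lexicographically descending on the pattern, so
#' the operation is a pure, idempotent function. With `axis = "both"`, rows
#' are sorted first, then columns. Content is only permuted, never altered;
#' positions travel with their columns.
#'
#' The alternative criterion `"allele_count"` orders rows (columns) by
#' their number of 1-alleles, non-increasing, with the same tie-break.
#'
#' @param a a [haplotype_alignment].
#' @param axis `"rows"`, `"columns"` or `"both"`.
#' @param criterion `"pattern"` (multiplicity of identical patterns) or
#'   `"allele_count"`.
#' @return The sorted [haplotype_alignment].
#' @export
sort_by_frequency <- function(a, axis = c("rows", "columns", "both"),
                              criterion = c("pattern", "allele_count")) {
  axis <- match.arg(axis)
  criterion <- match.arg(criterion)
  validate_alignment(a, check_sorted_positions = FALSE)
  ord_fun <- function(m) {
    if (criterion == "pattern") pattern_order(m)
    else {
      keys <- apply(m, 1, paste, collapse = "")
      order(rowSums(m), keys, method = "radix", decreasing = c(TRUE, TRUE))
    }
  }
  if (axis %in% c("rows", "both") && nrow(a$matrix) > 1)
    a$matrix <- a$matrix[ord_fun(a$matrix), , drop = FALSE]
  if (axis %in% c("columns", "both") && ncol(a$matrix) > 1) {
    ord <- ord_fun(t(a$matrix))
    a$matrix <- a$matrix[, ord, drop = FALSE]
    # positions become a permutation of the original coordinates: they are
    # kept as provenance of where each column came from, not as monotone
    # genomic coordinates
    a$positions <- a$positions[ord]
  }
  a
}

#' Resize a numeric matrix to fixed dimensions
#'
#' Maps a matrix of values in `[0, 1]` to `target_height x target_width`
#' using pixel-centre index mapping. Nearest-neighbour interpolation (the
#' default) samples source pixels directly, so binary inputs stay binary
#' and the operation is the identity when the target equals the input size;
#' bilinear interpolation averages the four surrounding pixels. Values stay
#' within `[0, 1]` in both cases.
#'
#' @param m non-empty numeric matrix.
#' @param target_height,target_width output dimensions, `>= 1`.
#' @param method `"nearest"` or `"bilinear"`.
#' @return A `target_height x target_width` numeric matrix.
#' @export
resize_image <- function(m, target_height, target_width,
                         method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  if (!is.matrix(m) || nrow(m) == 0 || ncol(m) == 0)
    stop("cannot resize an empty matrix; drop replicates with no columns ",
         "left after filtering", call. = FALSE)
  if (target_height < 1 || target_width < 1)
    stop("target dimensions must be at least 1", call. = FALSE)
  storage.mode(m) <- "double"
  if (method == "nearest") {
    ri <- floor((seq_len(target_height) - 0.5) * nrow(m) / target_height) + 1
    ci <- floor((seq_len(target_width) - 0.5) * ncol(m) / target_width) + 1
    return(m[pmin(ri, nrow(m)), pmin(ci, ncol(m)), drop = FALSE])
  }
  # bilinear, pixel-centre aligned
  src_r <- (seq_len(target_height) - 0.5) * nrow(m) / target_height - 0.5
  src_c <- (seq_len(target_width) - 0.5) * ncol(m) / target_width - 0.5
  r0 <- pmin(pmax(floor(src_r), 0), nrow(m) - 1)
  c0 <- pmin(pmax(floor(src_c), 0), ncol(m) - 1)
  r1 <- pmin(r0 + 1, nrow(m) - 1)
  c1 <- pmin(c0 + 1, ncol(m) - 1)
  fr <- pmin(pmax(src_r - r0, 0), 1)
  fc <- pmin(pmax(src_c - c0, 0), 1)
  A <- m[r0 + 1, c0 + 1, drop = FALSE]; B <- m[r0 + 1, c1 + 1, drop = FALSE]
  C <- m[r1 + 1, c0 + 1, drop = FALSE]; D <- m[r1 + 1, c1 + 1, drop = FALSE]
  Wfr <- matrix(fr, target_height, target_width)
  Wfc <- matrix(fc, target_height, target_width, byrow = TRUE)
  (A * (1 - Wfr) * (1 - Wfc) + B * (1 - Wfr) * Wfc +
     C * Wfr * (1 - Wfc) + D * Wfr * Wfc)
}

#' Convert alignments into a batch of fixed-size images
#'
#' Applies the full imaging pipeline — polarisation (if configured),
#' minor-allele-frequency filtering, sorting, resizing — in that fixed
#' order to every alignment, and stacks the results into an `image_batch`.
#' Replicates left with zero columns after filtering are dropped with a
#' warning; the count is recorded in the batch.
#'
#' @param alignments list of [haplotype_alignment] objects.
#' @param labels integer class label per alignment (1-based).
#' @param config an [image_config].
#' @return An object of class `image_batch` with fields `pixels`
#'   (`N x H x W` array, values in `[0, 1]`), `labels`, `config`,
#'   `n_dropped` and `source` (per-image provenance).
#' @export
build_image_batch <- function(alignments, labels, config = image_config()) {
  if (inherits(alignments, "haplotype_alignment")) alignments <- list(alignments)
  if (length(alignments) != length(labels))
    stop("alignments and labels must have equal length", call. = FALSE)
  if (!inherits(config, "image_config"))
    stop("config must be an image_config", call. = FALSE)
  processed <- vector("list", length(alignments))
  keep <- logical(length(alignments))
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    if (config$polarization == "major-minor") a <- polarize_major_minor(a)
    a <- filter_maf(a, config$maf_threshold)
    if (ncol(a$matrix) == 0) next
    if (config$sorting != "none") {
      axis <- switch(config$sorting, rows = "rows", columns = "columns",
                     rows_and_columns = "both")
      a <- sort_by_frequency(a, axis, config$sort_criterion)
    }
    processed[[i]] <- a
    keep[i] <- TRUE
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    warning(n_dropped, " replicate(s) had no columns left after MAF ",
            "filtering and were dropped", call. = FALSE)
  processed <- processed[keep]
  if (!length(processed))
    stop("no replicates left after filtering", call. = FALSE)
  width <- if (config$resize_policy == "mean")
    as.integer(round(mean(vapply(processed, function(a) ncol(a$matrix), 0))))
  else config$target_width
  height <- config$target_height
  pixels <- array(0, dim = c(length(processed), height, width))
  for (i in seq_along(processed))
    pixels[i, , ] <- resize_image(processed[[i]]$matrix, height, width,
                                  config$interpolation)
  structure(list(pixels = pixels,
                 labels = as.integer(labels[keep]),
                 config = config, n_dropped = n_dropped,
                 source = lapply(processed, function(a) a$provenance)),
            class = "image_batch")
}

#' @export
print.image_batch <- function(x, ...) {
  d <- dim(x$pixels)
  cat("Image batch: ", d[1], " images of ", d[2], "x", d[3], " pixels\n", sep = "")
  cat("Labels:", paste(names(table(x$labels)), table(x$labels),
                       sep = ":", collapse = "  "), "\n")
  if (x$n_dropped) cat("Dropped replicates:", x$n_dropped, "\n")
  invisible(x)
}

#' @export
length.image_batch <- function(x) dim(x$pixels)[1]

#' Subset an image batch
#'
#' @param x an `image_batch`.
#' @param i integer or logical index over images.
#' @param ... ignored.
#' @return The subsetted `image_batch`.
#' @export
`[.image_batch` <- function(x, i, ...) {
  structure(list(pixels = x$pixels[i, , , drop = FALSE],
                 labels = x$labels[i], config = x$config,
                 n_dropped = x$n_dropped, source = x$source[i]),
            class = "image_batch")
}

#' Persist and restore image batches
#'
#' Batches are stored in R's native serialisation format with all logical
#' content intact (pixels, labels, configuration, provenance), so a restored
#' batch is bit-identical to the saved one.
#'
#' @param batch an `image_batch`.
#' @param path file path.
#' @return `write_image_batch` returns `path` invisibly; `read_image_batch`
#'   returns the `image_batch`.
#' @export
write_image_batch <- function(batch, path) {
  stopifnot(inherits(batch, "image_batch"))
  saveRDS(batch, path)
  invisible(path)
}

#' @rdname write_image_batch
#' @export
read_image_batch <- function(path) {
  batch <- readRDS(path)
  if (!inherits(batch, "image_batch"))
    stop("file does not contain an image_batch", call. = FALSE)
  batch
}
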