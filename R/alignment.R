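#' Haplotype alignment objects
#'
#' A `haplotype_alignment` holds one simulation replicate: a binary allele
#' matrix (rows = sampled haplotypes, columns = segregating sites) together
#' with the relative position of each site in `[0, 1]` and a provenance
#' record (where the replicate came from and which replicate index it was).
#'
#' Every column must be segregating, i.e. contain both a 0 and a 1:
#' monomorphic sites are neither recorded in coalescent simulations nor
#' converted into images, and the imaging steps (polarisation, minor-allele
#' frequency filtering) rely on this.
#'
#' @param matrix integer or numeric matrix with entries in `{0, 1}`.
#' @param positions numeric vector of per-column relative coordinates,
#'   non-decreasing, within `[0, 1]`. Length must equal `ncol(matrix)`.
#' @param provenance list describing the source (free-form; typically the
#'   simulator command or fixture parameters plus a replicate index).
#'
#' @return An object of class `haplotype_alignment` with fields `matrix`,
#'   `positions` and `provenance`.
#' @examples
#' a <- haplotype_alignment(rbind(c(0, 1), c(1, 0), c(1, 1)), c(0.25, 0.75))
#' dim(a$matrix)
#' @export
haplotype_alignment <- function(matrix, positions, provenance = list()) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "integer"
  positions <- as.numeric(positions)
  obj <- structure(
    list(matrix = matrix, positions = positions, provenance = provenance),
    class = "haplotype_alignment"
  )
  validate_alignment(obj)
}

validate_alignment <- function(a, check_sorted_positions = TRUE) {
  m <- a$matrix
  if (!is.matrix(m)) stop("alignment matrix must be a matrix", call. = FALSE)
  if (length(m) && !all(m %in% c(0L, 1L)))
    stop("alignment entries must all be 0 or 1", call. = FALSE)
  if (ncol(m) != length(a$positions))
    stop("number of columns (", ncol(m), ") does not match number of positions (",
         length(a$positions), ")", call. = FALSE)
  if (length(a$positions)) {
    if (any(a$positions < 0 | a$positions > 1))
      stop("positions must lie in [0, 1]", call. = FALSE)
    if (check_sorted_positions && is.unsorted(a$positions))
      stop("positions must be non-decreasing", call. = FALSE)
  }
  if (ncol(m) > 0 && nrow(m) > 0) {
    cs <- colSums(m)
    bad <- which(cs == 0L | cs == nrow(m))
    if (length(bad))
      stop("monomorphic column(s) at index ", paste(utils::head(bad, 5), collapse = ", "),
           ": every recorded site must be segregating", call. = FALSE)
  }
  a
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat("Haplotype alignment: ", nrow(x$matrix), " haplotypes x ",
      ncol(x$matrix), " segregating sites\n", sep = "")
  if (!is.null(x$provenance$source))
    cat("Source:", x$provenance$source, "\n")
  invisible(x)
}

#' Parse ms-format simulation output
#'
#' Reads text in the `ms` dialect emitted by Hudson's \code{ms} and its
#' derivatives such as \code{msms}: an optional command-echo line and seed
#' line, then replicates delimited by `//`, each with a `segsites: k` line,
#' a `positions:` line of `k` relative coordinates, and one haplotype string
#' of `k` characters (`0`/`1`) per sampled chromosome. A replicate with
#' `segsites: 0` yields an alignment with zero columns.
#'
#' Multi-allelic sites (characters other than `0`/`1`, which \code{ms} can
#' emit) are rejected: the imaging pipeline is strictly diallelic.
#'
#' @param x path to an ms-format file, or a character vector of lines
#'   (a single string containing newlines is split).
#' @return A list of [haplotype_alignment] objects, one per replicate.
#' @seealso [write_ms()] for the exact inverse.
#' @examples
#' txt <- c("//", "segsites: 2", "positions: 0.25 0.75", "01", "10", "11")
#' parse_ms(txt)[[1]]$matrix
#' @export
parse_ms <- function(x) {
  if (length(x) == 1 && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
    src <- x
  } else {
    lines <- unlist(strsplit(as.character(x), "\n", fixed = TRUE), use.names = FALSE)
    src <- "<text>"
  }
  lines <- sub("\r$", "", lines)
  starts <- which(trimws(lines) == "//")
  out <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (r in seq_along(starts)) {
    block <- lines[seq(bounds[r] + 1L, bounds[r + 1L] - 1L)]
    block <- block[nzchar(trimws(block))]
    out[[r]] <- parse_ms_replicate(block, r, src)
  }
  out
}

parse_ms_replicate <- function(block, r, src) {
  fail <- function(...) stop("replicate ", r, ": ", ..., call. = FALSE)
  if (!length(block) || !grepl("^segsites:", block[1]))
    fail("expected a 'segsites:' line after '//'")
  k <- suppressWarnings(as.integer(sub("^segsites:\\s*", "", block[1])))
  if (is.na(k) || k < 0) fail("malformed segsites count")
  prov <- list(source = src, replicate = r)
  if (k == 0L)
    return(haplotype_alignment(matrix(integer(), 0, 0), numeric(), prov))
  if (length(block) < 2 || !grepl("^positions:", block[2]))
    fail("expected a 'positions:' line")
  pos <- as.numeric(strsplit(trimws(sub("^positions:\\s*", "", block[2])), "\\s+")[[1]])
  if (length(pos) != k)
    fail("position count (", length(pos), ") does not equal segsites (", k, ")")
  rows <- block[-(1:2)]
  if (!length(rows)) fail("no haplotype rows")
  if (any(nchar(rows) != k))
    fail("ragged haplotype rows (expected ", k, " characters each)")
  chars <- strsplit(rows, "", fixed = TRUE)
  flat <- unlist(chars, use.names = FALSE)
  if (any(!flat %in% c("0", "1")))
    fail("characters outside {0,1}: multi-allelic ms output is not supported")
  m <- matrix(as.integer(flat == "1"), nrow = length(rows), ncol = k, byrow = TRUE)
  haplotype_alignment(m, pos, prov)
}

#' Write alignments in ms format
#'
#' Emits ms-dialect text that [parse_ms()] inverts exactly (positions are
#' printed with full double precision). Useful for feeding generated
#' fixtures through the same path as simulator output.
#'
#' @param alignments a list of [haplotype_alignment] objects (a single
#'   alignment is accepted and wrapped).
#' @param file path or connection to write to; `""` writes to stdout.
#' @return Invisibly, the character vector of lines written.
#' @export
write_ms <- function(alignments, file = "") {
  if (inherits(alignments, "haplotype_alignment")) alignments <- list(alignments)
  lines <- c("sweepimage write_ms", "")
  for (a in alignments) {
    validate_alignment(a)
    lines <- c(lines, "//", paste0("segsites: ", ncol(a$matrix)))
    if (ncol(a$matrix) > 0) {
      lines <- c(lines,
        paste0("positions: ", paste(sprintf("%.17g", a$positions), collapse = " ")),
        apply(a$matrix, 1, paste, collapse = ""))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, file)
  invisible(lines)
}

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# one neutral column over n rows: derived-allele count i with P(i) proportional
# to 1/i (standard neutral site-frequency spectrum), carriers uniform
neutral_column <- function(n) {
  i <- sample.int(n - 1L, 1L, prob = 1 / seq_len(n - 1L))
  col <- integer(n)
  col[sample.int(n, i)] <- 1L
  col
}

#' Generate a synthetic sweep or neutral haplotype alignment
#'
#' Desk-scale stand-in for a coalescent simulator, emulating the haplotype
#' signature that distinguishes a selective sweep from neutrality: a sweep
#' creates one common haplotype carried by many chromosomes, with the
#' remaining chromosomes carrying less frequent variants.
#'
#' Neutral columns draw a derived-allele count `i` from the standard neutral
#' site-frequency spectrum, `P(i)` proportional to `1/i` for
#' `i = 1, ..., n - 1`, with carriers chosen uniformly. When
#' `sweep_intensity > 0`, a central block of `round(core_width * target_sites)`
#' columns forms the sweep core: a fixed, randomly chosen set of
#' `round(sweep_intensity * n)` rows (capped at `n - 1` so that every column
#' stays segregating) shares one identical haplotype pattern across the core,
#' while the remaining rows carry neutral draws. Positions are sorted
#' uniform draws on `[0, 1]`. Columns that come out monomorphic are redrawn,
#' up to 1000 attempts each, then the generator errors.
#'
#' @param n number of haplotypes (rows); at least 4.
#' @param target_sites number of segregating sites (columns); at least 2.
#' @param sweep_intensity fraction of rows carrying the swept haplotype,
#'   in `[0, 1]`; 0 gives a fully neutral alignment.
#' @param core_width fraction of (central) columns inside the sweep core.
#' @param seed optional integer; with a seed the result is reproducible and
#'   the caller's RNG state is left untouched.
#' @return A [haplotype_alignment] whose provenance records the parameters.
#' @examples
#' neu <- generate_fixture(16, 32, sweep_intensity = 0, seed = 1)
#' swp <- generate_fixture(16, 32, sweep_intensity = 0.9, seed = 1)
#' @export
generate_fixture <- function(n, target_sites, sweep_intensity = 0,
                             core_width = 0.5, seed = NULL) {
  if (n < 4) stop("n must be at least 4", call. = FALSE)
  if (target_sites < 2) stop("target_sites must be at least 2", call. = FALSE)
  if (sweep_intensity < 0 || sweep_intensity > 1)
    stop("sweep_intensity must be in [0, 1]", call. = FALSE)
  if (core_width < 0 || core_width > 1)
    stop("core_width must be in [0, 1]", call. = FALSE)
  with_local_seed(seed, {
    m <- matrix(0L, n, target_sites)
    n_core <- if (sweep_intensity > 0) round(core_width * target_sites) else 0L
    lo <- floor((target_sites - n_core) / 2) + 1L
    core_cols <- if (n_core > 0) seq(lo, lo + n_core - 1L) else integer()
    carriers <- integer()
    n_carriers <- min(round(sweep_intensity * n), n - 1L)
    if (n_core > 0 && n_carriers >= 1)
      carriers <- sort(sample.int(n, n_carriers))
    core_pattern <- if (length(core_cols))
      sample(c(0L, 1L), length(core_cols), replace = TRUE) else integer()
    for (j in seq_len(target_sites)) {
      in_core <- j %in% core_cols && length(carriers) >= 1
      for (attempt in seq_len(1000L)) {
        if (in_core) {
          col <- integer(n)
          free <- setdiff(seq_len(n), carriers)
          h <- core_pattern[match(j, core_cols)]
          col[carriers] <- h
          q <- length(free)
          if (q >= 2) {
            # neutral draw among the non-carrier rows
            i <- sample.int(max(q - 1L, 1L), 1L, prob = 1 / seq_len(max(q - 1L, 1L)))
            sub <- integer(q)
            sub[sample.int(q, i)] <- 1L
            col[free] <- sub
          } else if (q == 1) {
            col[free] <- sample(c(0L, 1L), 1L)
          }
        } else {
          col <- neutral_column(n)
        }
        s <- sum(col)
        if (s > 0L && s < n) break
        if (attempt == 1000L)
          stop("column ", j, ": could not draw a segregating column in 1000 attempts",
               call. = FALSE)
      }
      m[, j] <- col
    }
    haplotype_alignment(
      m, sort(stats::runif(target_sites)),
      provenance = list(source = "fixture", n = n, target_sites = target_sites,
                        sweep_intensity = sweep_intensity,
                        core_width = core_width, core_columns = core_cols,
                        seed = seed)
    )
  })
}

#' Generate a set of fixtures with one label per alignment
#'
#' Convenience wrapper around [generate_fixture()]: draws `n_replicates`
#' alignments per requested sweep intensity, with per-replicate seeds
#' derived deterministically from `seed`.
#'
#' @param intensities numeric vector of sweep intensities, one class each.
#' @param n_replicates alignments per intensity.
#' @param n,target_sites,core_width passed to [generate_fixture()].
#' @param seed integer master seed.
#' @return list with `alignments` (list) and `class` (integer vector,
#'   1-based index into `intensities`).
#' @export
generate_fixture_set <- function(intensities, n_replicates, n = 64,
                                 target_sites = 96, core_width = 0.5,
                                 seed = 1) {
  alignments <- vector("list", length(intensities) * n_replicates)
  cls <- integer(length(alignments))
  idx <- 0L
  for (k in seq_along(intensities)) {
    for (r in seq_len(n_replicates)) {
      idx <- idx + 1L
      alignments[[idx]] <- generate_fixture(
        n, target_sites, sweep_intensity = intensities[k],
        core_width = core_width,
        seed = (seed * 7919L + k * 1009L + r) %% 2147483647L)
      cls[idx] <- k
    }
  }
  list(alignments = alignments, class = cls)
}
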