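#' Simulation parameters for a single-population sweep scenario
#'
#' Bundles the demographic and selection parameters used to drive a
#' coalescent simulator with selection (the \code{msms} dialect). Defaults
#' describe the worked scenario used throughout the package: 128 sampled
#' chromosomes over an 80 kb region, mutation rate 1.5e-8 and recombination
#' rate 1.0e-8 per base per generation, a reference effective population
#' size of 10,000, and a beneficial allele that arose 15,000 years ago at
#' an initial population frequency of 1%.
#'
#' The selection coefficient `S` is expressed in units of `2 * Ne` (so
#' `S = 0` is neutrality). `demography` is a data frame with columns
#' `time` (in units of `4 * Ne` generations, strictly increasing) and
#' `size` (population size relative to `Ne`, positive); it describes
#' single-population size changes only.
#'
#' @param sample_size number of haplotypes to sample.
#' @param region_length region length in base pairs.
#' @param mutation_rate per-base per-generation mutation rate.
#' @param recombination_rate per-base per-generation recombination rate.
#' @param reference_Ne diploid effective population size used for scaling.
#' @param selection_coefficient `S` in `2 * Ne` units, `>= 0`.
#' @param selection_onset_years when the beneficial allele arose, in years
#'   before present.
#' @param generation_time years per generation, used to convert the onset
#'   into coalescent time units of `4 * Ne` generations.
#' @param initial_frequency population frequency of the beneficial allele
#'   at onset, in `(0, 1)`.
#' @param dominance_ratio heterozygote selection coefficient as a fraction
#'   of `S`; 0.5 is semidominance, the usual convention.
#' @param demography optional data frame of `(time, size)` epoch changes.
#' @param n_replicates number of replicates to request.
#' @param seed optional integer passed to the simulator.
#' @return An object of class `sim_params`.
#' @examples
#' p <- sim_params(selection_coefficient = 300)
#' build_simulator_command(p)
#' @export
sim_params <- function(sample_size = 128,
                       region_length = 80000,
                       mutation_rate = 1.5e-8,
                       recombination_rate = 1.0e-8,
                       reference_Ne = 10000,
                       selection_coefficient = 0,
                       selection_onset_years = 15000,
                       generation_time = 25,
                       initial_frequency = 0.01,
                       dominance_ratio = 0.5,
                       demography = NULL,
                       n_replicates = 1,
                       seed = NULL) {
  if (sample_size < 2) stop("sample_size must be at least 2", call. = FALSE)
  if (mutation_rate < 0 || recombination_rate < 0)
    stop("rates must be non-negative", call. = FALSE)
  if (selection_coefficient < 0)
    stop("selection_coefficient must be non-negative", call. = FALSE)
  if (initial_frequency <= 0 || initial_frequency >= 1)
    stop("initial_frequency must be in (0, 1)", call. = FALSE)
  if (region_length < 1 || reference_Ne < 1 || n_replicates < 1)
    stop("region_length, reference_Ne and n_replicates must be positive",
         call. = FALSE)
  if (generation_time <= 0) stop("generation_time must be positive", call. = FALSE)
  if (!is.null(demography)) {
    demography <- as.data.frame(demography)
    if (!setequal(names(demography), c("time", "size")))
      stop("demography must have exactly the columns 'time' and 'size' ",
           "(single-population size changes only)", call. = FALSE)
    if (nrow(demography) > 0) {
      if (any(diff(demography$time) <= 0))
        stop("demography times must be strictly increasing", call. = FALSE)
      if (any(demography$size <= 0) || any(demography$time < 0))
        stop("demography times must be >= 0 and sizes > 0", call. = FALSE)
    }
  }
  structure(list(
    sample_size = as.integer(sample_size), region_length = region_length,
    mutation_rate = mutation_rate, recombination_rate = recombination_rate,
    reference_Ne = reference_Ne, selection_coefficient = selection_coefficient,
    selection_onset_years = selection_onset_years,
    generation_time = generation_time, initial_frequency = initial_frequency,
    dominance_ratio = dominance_ratio, demography = demography,
    n_replicates = as.integer(n_replicates), seed = seed
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters: n =", x$sample_size, ", L =", x$region_length,
      "bp, Ne =", x$reference_Ne, "\n")
  cat("  S =", x$selection_coefficient, "(2*Ne units), onset",
      x$selection_onset_years, "years ago, f0 =", x$initial_frequency, "\n")
  if (!is.null(x$demography))
    cat("  demography:", nrow(x$demography), "epoch change(s)\n")
  invisible(x)
}

#' Example demographic histories
#'
#' A 1-epoch (constant size) history and an illustrative 3-epoch history
#' for a European-like population (bottleneck followed by regrowth). The
#' 3-epoch values are placeholders in the right regime for such histories,
#' not a published calibration; treat demography as configuration.
#'
#' @param model `"1-epoch"` or `"3-epoch"`.
#' @return A data frame with columns `time` (units of `4 * Ne` generations)
#'   and `size` (relative to the reference `Ne`), or `NULL` for 1-epoch.
#' @export
example_demography <- function(model = c("3-epoch", "1-epoch")) {
  model <- match.arg(model)
  if (model == "1-epoch") return(NULL)
  data.frame(time = c(0.02, 0.05), size = c(0.2, 1.5))
}

fmt_num <- function(x) sprintf("%.10g", x)

#' Build an msms command line
#'
#' Encodes a [sim_params] scenario as an \code{msms}-dialect command string:
#' scaled mutation and recombination parameters `theta = 4*Ne*mu*L` and
#' `rho = 4*Ne*r*L`, epoch size changes as `-eN` flags, and (when
#' `selection_coefficient > 0`) selection flags giving the scaled
#' homozygote/heterozygote coefficients (`-SAA S`, `-SAa dominance_ratio*S`),
#' the onset time converted to coalescent units of `4 * Ne` generations via
#' `generation_time`, and the initial allele frequency, with the selected
#' site at the region midpoint. The command is not executed; run it with
#' your own msms installation and feed the output to [parse_ms()]. Exact
#' selection flags follow msms documentation conventions (the combination
#' is configuration, not a reproduction of any published invocation).
#'
#' @param params a [sim_params] object.
#' @return A single command string; deterministic for fixed parameters.
#' @examples
#' build_simulator_command(sim_params())
#' @export
build_simulator_command <- function(params) {
  if (!inherits(params, "sim_params"))
    stop("params must be a sim_params object", call. = FALSE)
  p <- params
  theta <- 4 * p$reference_Ne * p$mutation_rate * p$region_length
  rho <- 4 * p$reference_Ne * p$recombination_rate * p$region_length
  parts <- c("msms", p$sample_size, p$n_replicates,
             "-t", fmt_num(theta),
             "-r", fmt_num(rho), fmt_num(p$region_length),
             "-N", fmt_num(p$reference_Ne))
  if (!is.null(p$demography) && nrow(p$demography) > 0)
    for (i in seq_len(nrow(p$demography)))
      parts <- c(parts, "-eN", fmt_num(p$demography$time[i]),
                 fmt_num(p$demography$size[i]))
  if (p$selection_coefficient > 0) {
    onset_gen <- p$selection_onset_years / p$generation_time
    onset_coal <- onset_gen / (4 * p$reference_Ne)
    parts <- c(parts,
               "-SAA", fmt_num(p$selection_coefficient),
               "-SAa", fmt_num(p$dominance_ratio * p$selection_coefficient),
               "-Saa", "0",
               "-SI", fmt_num(onset_coal), "1", fmt_num(p$initial_frequency),
               "-Sp", "0.5", "-SFC")
  }
  if (!is.null(p$seed)) parts <- c(parts, "-seed", fmt_num(p$seed))
  paste(parts, collapse = " ")
}
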