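#' Maximum a posteriori estimate of the selection coefficient
#'
#' The midpoint of the most probable class; ties go to the lower class.
#'
#' @param p probability vector over the scheme's classes (e.g. one row of
#'   the softmax output of [predict.sweep_cnn()]).
#' @param scheme a [binning_scheme].
#' @return Parameter value (in the scheme's units, here `2 * Ne`).
#' @export
map_estimate <- function(p, scheme) {
  stopifnot(inherits(scheme, "binning_scheme"))
  validate_distribution(p)
  scheme$midpoints[which.max(p)]
}

#' Posterior mean of the selection coefficient
#'
#' `sum(p_k * midpoint_k)` over all classes.
#'
#' @inheritParams map_estimate
#' @return Parameter value.
#' @export
posterior_mean <- function(p, scheme) {
  stopifnot(inherits(scheme, "binning_scheme"))
  validate_distribution(p)
  sum(p * scheme$midpoints)
}

# smallest set of classes, added in decreasing density order, whose
# cumulative mass reaches 1 - alpha; returns the class indices
hpd_set <- function(dens, alpha) {
  ord <- order(dens, decreasing = TRUE)
  cum <- cumsum(dens[ord])
  ord[seq_len(which(cum >= 1 - alpha - 1e-12)[1])]
}

#' Highest posterior density interval over discretised classes
#'
#' Draws `n_samples` class midpoints with replacement according to `p`,
#' then forms the smallest set of classes — added in decreasing
#' empirical-density order — whose cumulative mass reaches `1 - alpha`,
#' and reports the (min, max) midpoints of that set. The MAP class is
#' always included. With `n_samples = NULL` the interval is computed
#' exactly from `p` by the same greedy rule, without sampling.
#'
#' @inheritParams map_estimate
#' @param alpha interval level is `1 - alpha`.
#' @param n_samples Monte Carlo draw count (the worked analyses use
#'   100,000), or `NULL` for the exact greedy computation.
#' @param seed optional integer seed for the Monte Carlo draw.
#' @return Numeric `c(low, high)` in parameter units.
#' @export
hpdi <- function(p, scheme, alpha = 0.05, n_samples = 100000, seed = NULL) {
  stopifnot(inherits(scheme, "binning_scheme"))
  validate_distribution(p)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  k <- scheme$n_classes
  dens <- if (is.null(n_samples)) p else with_local_seed(seed, {
    draws <- sample.int(k, n_samples, replace = TRUE, prob = p)
    tabulate(draws, nbins = k) / n_samples
  })
  set <- union(hpd_set(dens, alpha), which.max(p))
  range(scheme$midpoints[set])
}

#' Bayes factor for selection versus neutrality
#'
#' Posterior odds over prior odds for the model "selection coefficient
#' larger than 0" against "coefficient equal to 0", taking class 1 as the
#' neutral class: `BF = ((1 - p_1) / p_1) / ((1 - prior_1) / prior_1)`.
#' The posterior neutral mass is floored at `1e-12`; when the floor is hit
#' the returned value is a lower bound and a warning is issued.
#'
#' @param p posterior probability vector; class 1 is neutrality.
#' @param prior prior probability vector over the same classes, or the
#'   scalar prior mass of the neutral class. Defaults to the uniform prior
#'   over classes implied by training with selection coefficients drawn
#'   uniformly over the binned range.
#' @return Scalar Bayes factor (`>= 0`).
#' @export
bayes_factor <- function(p, prior = rep(1 / length(p), length(p))) {
  validate_distribution(p)
  prior0 <- if (length(prior) > 1) prior[1] else prior
  if (prior0 <= 0 || prior0 >= 1)
    stop("neutral-class prior must be strictly between 0 and 1", call. = FALSE)
  p0 <- p[1]
  if (p0 < 1e-12) {
    warning("posterior neutral mass floored at 1e-12; Bayes factor is a ",
            "lower bound", call. = FALSE)
    p0 <- 1e-12
  }
  ((1 - p0) / p0) / ((1 - prior0) / prior0)
}

#' Summarise a class posterior for one genomic region
#'
#' Bundles the class-probability vector with its derived quantities: MAP
#' and posterior-mean point estimates, the `1 - alpha` highest posterior
#' density interval, and the Bayes factor for selection versus neutrality.
#'
#' @inheritParams map_estimate
#' @param alpha HPDI level is `1 - alpha`.
#' @param n_samples Monte Carlo draws for the HPDI (`NULL` = exact).
#' @param prior prior for [bayes_factor()].
#' @param seed seed for the HPDI sampling.
#' @return An object of class `posterior_summary`.
#' @export
selection_posterior <- function(p, scheme, alpha = 0.05, n_samples = 100000,
                                prior = rep(1 / length(p), length(p)),
                                seed = NULL) {
  interval <- hpdi(p, scheme, alpha, n_samples, seed)
  structure(list(probabilities = p, scheme = scheme,
                 map_value = map_estimate(p, scheme),
                 mean_value = posterior_mean(p, scheme),
                 hpdi = interval, alpha = alpha,
                 bayes_factor = bayes_factor(p, prior),
                 n_samples = n_samples, seed = seed),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("Posterior summary over", x$scheme$n_classes, "classes\n")
  cat("  MAP:", signif(x$map_value, 4),
      "  mean:", signif(x$mean_value, 4), "\n")
  cat("  ", 100 * (1 - x$alpha), "% HPDI: [", signif(x$hpdi[1], 4), ", ",
      signif(x$hpdi[2], 4), "]",
      if (!is.null(x$n_samples)) paste0(" (", x$n_samples, " MC samples)"),
      "\n", sep = "")
  cat("  Bayes factor (selection vs neutrality):",
      signif(x$bayes_factor, 4), "\n")
  invisible(x)
}

#' Summarise posteriors for a whole batch of predictions
#'
#' @param probs `N x K` matrix of class probabilities (rows sum to 1).
#' @inheritParams selection_posterior
#' @return A data frame with one row per image: MAP, posterior mean, HPDI
#'   bounds and Bayes factor.
#' @export
posterior_table <- function(probs, scheme, alpha = 0.05, n_samples = 100000,
                            prior = rep(1 / ncol(probs), ncol(probs)),
                            seed = NULL) {
  rows <- lapply(seq_len(nrow(probs)), function(i) {
    s <- selection_posterior(probs[i, ], scheme, alpha, n_samples, prior,
                             seed = if (is.null(seed)) NULL else seed + i)
    data.frame(map = s$map_value, mean = s$mean_value,
               hpdi_low = s$hpdi[1], hpdi_high = s$hpdi[2],
               bayes_factor = s$bayes_factor)
  })
  do.call(rbind, rows)
}

#' Export posterior summaries
#'
#' Writes one JSON record per image (class probabilities plus derived
#' quantities, with the HPDI settings and seed) or a CSV table.
#'
#' @param summaries list of `posterior_summary` objects, or the data frame
#'   from [posterior_table()] for `write_posterior_csv`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_posterior_json <- function(summaries, path) {
  if (inherits(summaries, "posterior_summary")) summaries <- list(summaries)
  recs <- lapply(summaries, function(s)
    list(probabilities = s$probabilities, map = s$map_value,
         mean = s$mean_value, hpdi = s$hpdi, alpha = s$alpha,
         n_samples = s$n_samples, seed = s$seed,
         bayes_factor = s$bayes_factor))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_posterior_json
#' @export
write_posterior_csv <- function(summaries, path) {
  utils::write.csv(summaries, path, row.names = FALSE)
  invisible(path)
}
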