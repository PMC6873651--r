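---
title: "Detecting and quantifying selective sweeps from haplotype images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying selective sweeps from haplotype images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepimage)
```

## The inference problem

A selective sweep — the rapid rise of a beneficial allele — drags linked
neutral variation to high frequency, so that many sampled chromosomes share
one long common haplotype while the remainder carry rarer variants, and
local diversity is reduced. `sweepimage` treats the detection and
quantification of this signature as an image-classification problem: a
sample of $n$ haplotypes over $k$ segregating sites is a binary $n \times k$
matrix, and a convolutional neural network (CNN) is trained on simulated
matrices to discriminate neutral evolution from sweeps of varying strength.

The selection coefficient $S$ is expressed in units of $2N_e$, with
$N_e = 10{,}000$ the reference effective population size; $S = 0$ is
neutrality. Training data come from a coalescent simulator with selection
(the `msms` dialect): `build_simulator_command()` encodes a scenario —
by default 128 chromosomes over 80 kb, mutation rate $1.5\times10^{-8}$
and recombination rate $1.0\times10^{-8}$ per base per generation, so
$\theta = 4N_e\mu L = 48$ and $\rho = 4N_e r L = 32$ — and `parse_ms()`
reads the resulting ms-format output. The simulator itself is not bundled:
the package emits the command line and consumes whatever ms-format file
the user produces, which also makes it straightforward to use any other
simulator that writes ms format.

Two conversion conventions are enforced strictly: sites are diallelic (multi-allelic ms output is
rejected rather than collapsed), and no monomorphic column is ever stored
or imaged.

## From alignment to image

`build_image_batch()` applies four steps in a fixed order:

1. **Polarisation.** When the ancestral allele is unknown, each column is
   recoded so the most frequent allele is 0 and the least frequent is 1.
   A column at an exact 50/50 split is left unchanged; this tie rule makes
   the operation deterministic and order-independent.
2. **Minor-allele-frequency filtering.** Columns with MAF strictly below
   the threshold (default 0.01) are removed. With 128 chromosomes this
   removes singletons (frequency $1/128 \approx 0.0078$) and keeps
   doubletons. Equality at the threshold is retained.
3. **Sorting.** Rows and/or columns are reordered by *frequency of
   occurrence*: identical patterns are grouped and groups placed in
   non-increasing multiplicity order (rows top-to-bottom, columns
   left-to-right). Ties between groups of equal multiplicity are broken
   lexicographically descending on the pattern, which makes single-axis
   sorting a pure, idempotent function. Sorting row patterns by
   multiplicity places the sweep's common haplotype in a solid block at
   the top of the image — the feature the CNN exploits. An alternative
   criterion (per-row/column count of derived alleles) is available as a
   configuration option, since the phrase "frequency of occurrence"
   admits either reading; the multiplicity interpretation is the
   default.
4. **Resizing.** Images are mapped to a fixed size (128×128 in the
   reference configuration; smaller in this package's desk-scale runs) by
   nearest-neighbour sampling at pixel centres, which preserves binary
   values, maps constants to constants, is the identity at native
   resolution, and is deterministic across platforms. Bilinear
   interpolation is available by configuration. Alternatively the target
   width can be the rounded mean post-filter column count of the batch.

The order matters — a rare column removed by the filter can change sort
multiplicities — so the pipeline pins filter-before-sort and the test
suite contains a regression case for it.

For double-sorted images both axes carry arranged structure, so the final
fully-connected layer adds nothing; the architecture default drops the
dense layer for double-sorted images and keeps it otherwise.

## Labels, classes and soft targets

The continuous selection coefficient is estimated by multiclass
classification: `binning_scheme(0, 400, 11)` divides the range into 11
linearly spaced classes whose midpoints include both bounds (0, 40, …,
400), so neutrality is its own class. Values map to the nearest midpoint,
halves rounding down. Class indices are 1-based, the R convention.

Cross-entropy against three target representations is supported:

* **categorical** — all mass on the true class;
* **gaussian** — weights $\exp(-(k-c)^2/2\sigma^2)$ at integer class
  offsets, renormalised; at the default $\sigma = 0.5$ the true class
  holds ≈0.787 of the mass and each neighbour ≈0.106. This penalises
  errors by their distance from the truth, which a one-hot target cannot;
* **perturbed** — the true class is shifted by a step drawn uniformly from
  the valid subset of $\{-1, 0, +1\}$. At the boundary the draw is over
  the valid subset rather than clamped, so edge classes are not inflated.
  Perturbation is applied once per dataset (an option to re-draw per epoch
  exists in the training loop's seeding but the default is once, which
  keeps a dataset a fixed object).

## The network and its training

The reference architectures are three 2-D convolutional layers (32/32/32,
32/64/64 or 32/64/128 filters) with 3×3 kernels (5×5 as a variant),
stride 1, no zero-padding, each followed by 2×2 max pooling; ReLU
activations; an optional 64-unit dense layer; softmax output; mini-batch
size 32. `layer_shape_plan()` gives the implied feature-map chain — at
128×128: 126 → 63 → 61 → 30 → 28 → 14, flattening to $14^2 \times 32 =
6272$ features — and rejects configurations whose maps would shrink below
one pixel.

The engine behind `sweep_cnn()` is a compact deterministic CNN
implementation in C++ (im2col convolution, max-pool argmax caching,
analytic backpropagation verified against finite differences in the test
suite, Adam updates). All randomness — He-style weight initialisation and
mini-batch order — flows from the fit's single seed through R's RNG, so a
fit is bit-reproducible on one CPU thread. Two schedules are provided:
ordinary multi-epoch passes over a fixed training set, and a one-pass
schedule in which the set is partitioned into chunks each visited exactly
once — the reproducible counterpart of training on freshly simulated data
at every iteration, which prevents an example from being seen twice.

Optimiser, learning rate and epoch counts are genuinely open choices in
this design; the defaults here are Adam at $10^{-3}$ with configurable
epochs, recorded in the fitted object. No architecture or
hyperparameter search is attempted.

## Posterior summaries

The softmax output is read as a posterior distribution over classes, from
which `selection_posterior()` derives:

* **MAP** — midpoint of the modal class (ties to the lower class);
* **posterior mean** — $\sum_k p_k\,m_k$ over midpoints $m_k$;
* **HPDI** — on a discrete support the highest-density region is the
  smallest set of classes, added in decreasing density order, reaching
  $1-\alpha$ mass; the interval is that set's midpoint range. The Monte
  Carlo route (default 100,000 draws, seeded) is the default; the exact
  greedy computation (`n_samples = NULL`) is kept as the reference the
  sampling route is validated against.
* **Bayes factor** for selection ($S>0$) versus neutrality ($S=0$):
  posterior odds over prior odds,
  $\mathrm{BF} = \frac{(1-p_1)/p_1}{(1-\pi_1)/\pi_1}$, with the neutral
  class mass floored at $10^{-12}$ (flagged as a lower bound when hit).
  The posterior-odds/prior-odds form uses the training prior — uniform
  over classes when training coefficients are drawn uniformly — and the
  prior is an explicit argument rather than an assumption.

## The fixture generator: what it emulates and what it does not

Tests and desk-scale experiments need sweep-like data without an external
simulator. `generate_fixture()` draws neutral columns from the standard
neutral site-frequency spectrum ($P(i) \propto 1/i$ derived copies among
$n$ chromosomes, carriers uniform) and, for a sweep of intensity $f$,
plants a core block of central columns in which a fixed set of
$\mathrm{round}(f\,n)$ rows shares one haplotype pattern while the
remaining rows carry neutral draws. This reproduces the two features the
CNN learns — one high-multiplicity haplotype and reduced core
heterozygosity — and the test suite verifies both (core heterozygosity at
$f=0.9$ is measurably below neutral levels; the neutral singleton
fraction matches the $1/i$ law within Monte Carlo error).

The generator deliberately omits linkage disequilibrium decay, the
genealogical correlation between columns, recombination breakpoints,
demographic history, and the frequency spectrum distortion that a real
sweep induces *outside* the core. Passing the end-to-end tests therefore
demonstrates that the pipeline and network learn the intended haplotype
structure, not that any particular accuracy carries over to coalescent or
real data — for that the user supplies simulator output via `parse_ms()`.
Carriers are capped at $n-1$ so every column stays segregating even at
intensity 1 (an all-carrier column would be monomorphic, which the data
model forbids); column draws that come out monomorphic are redrawn with a
1000-attempt cap so degenerate parameterisations fail loudly rather than
loop.

## Numerical and design choices

* Positions are printed with 17 significant digits in `write_ms()`, so a
  write/parse round trip is exact.
* After column sorting, the position vector is carried as provenance (a
  permutation of the original coordinates), not as monotone genomic
  coordinates.
* The one demography shipped as an example 3-epoch history is a
  placeholder in the plausible regime for a European-like bottleneck and
  regrowth, not a calibrated history; demography is treated as
  configuration. Conversion of the sweep onset (15,000 years)
  into coalescent units assumes a configurable 25-year generation time
  (600 generations, i.e. $600/4N_e = 0.015$ coalescent time units).
* Selection flags in the command builder assume semidominance
  (heterozygote coefficient $S/2$), the common convention, also
  configurable.
* Image batches, checkpoints and splits are persisted with R's native
  serialisation, which restores them bit-exactly; training history is
  exported as CSV with a JSON sidecar of architecture, schedule and seed;
  split index vectors and seeds are saved so any split is reconstructible.

## Problem sizes used in validation

The package's own validation experiments (test suite and
`scripts/acceptance.R`) run at desk scale, chosen so the whole suite
completes in minutes on one CPU: 1,000 fixture images per class at 64×64
for the binary-detection properties, 300 per class at 128×128 for the
full-resolution double-sorted configuration, and 400–500 per class for
the three-class quantification runs. At these sizes the qualitative
claims reproduce reliably — double-sorted detection accuracy above 0.9 at
strong sweep intensity, accuracy non-decreasing in intensity, row-sorted
at least as accurate as unsorted at low intensity. Accuracies attainable
with tens of thousands of calibrated simulator replicates per class are
not claimed at this scale.

## Known limitations

* Single population, diallelic, phased haplotypes only; no multi-
  population stacking, no colour (nucleotide-frequency) images, no
  genetic-distance hierarchical sorting.
* No ordinal-regression labels or parametric posterior outputs.
* The CNN engine is single-threaded by design (determinism first); large
  training sets are better produced with the one-pass schedule than with
  many epochs.
* Double-axis sorting is the composition row-sort-then-column-sort; it is
  not formally idempotent because row tie-breaks depend on column order,
  though in practice a second application almost always leaves the image
  unchanged.
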