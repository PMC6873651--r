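test_that("simulator command encodes scaled population parameters", {
  p <- sim_params(sample_size = 128, region_length = 80000,
                  mutation_rate = 1.5e-8, recombination_rate = 1.0e-8,
                  reference_Ne = 10000, selection_coefficient = 300)
  cmd <- build_simulator_command(p)
  # theta = 4 * 10000 * 1.5e-8 * 80000 = 48, rho = 4 * 10000 * 1e-8 * 80000 = 32
  expect_match(cmd, "-t 48 ")
  expect_match(cmd, "-r 32 80000")
  expect_match(cmd, "^msms 128 1 ")
  expect_match(cmd, "-SAA 300 -SAa 150")
  # onset: 15000 years / 25 y per gen = 600 generations = 600 / 40000 coalescent units
  expect_match(cmd, "-SI 0.015 1 0.01")
  # deterministic
  expect_identical(cmd, build_simulator_command(p))
})

test_that("neutral parameters produce a command without selection flags", {
  cmd <- build_simulator_command(sim_params(selection_coefficient = 0))
  expect_false(grepl("-S", cmd, fixed = TRUE))
})

test_that("demography is encoded as size-change flags and validated", {
  demo <- data.frame(time = c(0.02, 0.05), size = c(0.2, 1.5))
  cmd <- build_simulator_command(sim_params(demography = demo))
  expect_match(cmd, "-eN 0.02 0.2 -eN 0.05 1.5")
  expect_error(sim_params(demography = data.frame(time = c(0.05, 0.02),
                                                  size = c(1, 1))),
               "strictly increasing")
  expect_error(sim_params(demography = data.frame(time = 0.1, size = 1,
                                                  pop = 2)),
               "single-population")
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(sim_params(sample_size = 1), "sample_size")
  expect_error(sim_params(initial_frequency = 0), "initial_frequency")
  expect_error(sim_params(selection_coefficient = -1), "non-negative")
})

test_that("ms text is parsed into binary matrices with positions", {
  txt <- c("//", "segsites: 2", "positions: 0.25 0.75", "01", "10", "11")
  a <- parse_ms(txt)
  expect_length(a, 1)
  expect_identical(a[[1]]$matrix,
                   matrix(c(0L, 1L, 1L, 1L, 0L, 1L), 3, 2))
  expect_equal(a[[1]]$positions, c(0.25, 0.75))
})

test_that("a replicate with no segregating sites yields zero columns", {
  a <- parse_ms(c("ms 3 1", "12345", "", "//", "segsites: 0"))
  expect_equal(ncol(a[[1]]$matrix), 0)
  expect_length(a[[1]]$positions, 0)
})

test_that("malformed ms input errors name the replicate", {
  expect_error(parse_ms(c("//", "segsites: 2", "positions: 0.1 0.2",
                          "01", "101")), "replicate 1.*ragged")
  expect_error(parse_ms(c("//", "segsites: 1", "positions: 0.5",
                          "0", "2")), "multi-allelic")
  expect_error(parse_ms(c("//", "segsites: 2", "positions: 0.5",
                          "01")), "position count")
})

test_that("write_ms and parse_ms are exact inverses on random alignments", {
  set.seed(42)
  alignments <- replicate(100, random_alignment(), simplify = FALSE)
  txt <- write_ms(alignments, tempfile())
  back <- parse_ms(txt)
  expect_length(back, length(alignments))
  for (i in seq_along(alignments)) {
    expect_identical(back[[i]]$matrix, alignments[[i]]$matrix)
    expect_identical(back[[i]]$positions, alignments[[i]]$positions)
  }
  # empty list: header only
  expect_length(parse_ms(write_ms(list(), tempfile())), 0)
})

test_that("monomorphic columns are rejected as invalid alignments", {
  expect_error(haplotype_alignment(rbind(c(1, 1), c(1, 0)), c(0.1, 0.2)),
               "segregating")
  expect_error(parse_ms(c("//", "segsites: 1", "positions: 0.5", "1", "1")),
               "segregating")
})

test_that("neutral fixtures follow the 1/i site-frequency spectrum", {
  # at n = 4 the singleton probability is (1/1) / (1 + 1/2 + 1/3) = 0.54545
  set.seed(7)
  n_cols <- 0
  singletons <- 0
  for (r in 1:250) {
    a <- generate_fixture(4, 100, sweep_intensity = 0,
                          seed = 1000 + r)
    singletons <- singletons + sum(colSums(a$matrix) == 1)
    n_cols <- n_cols + ncol(a$matrix)
  }
  p_hat <- singletons / n_cols
  p_exp <- 1 / (1 + 1/2 + 1/3)
  se <- sqrt(p_exp * (1 - p_exp) / n_cols)
  expect_gt(n_cols, 20000)
  expect_lt(abs(p_hat - p_exp), 3 * se)
})

test_that("full-intensity sweeps put one near-universal haplotype on top", {
  a <- generate_fixture(16, 20, sweep_intensity = 1, core_width = 1, seed = 5)
  sorted <- sort_by_frequency(a, "rows")
  # carriers are capped at n - 1 so that every column stays segregating
  top <- sorted$matrix[1:15, , drop = FALSE]
  expect_true(all(apply(top, 2, function(col) length(unique(col)) == 1)))
})

test_that("fixtures are deterministic given a seed and leave the RNG alone", {
  set.seed(99)
  before <- .Random.seed
  a <- generate_fixture(8, 10, sweep_intensity = 0.5, seed = 11)
  expect_identical(.Random.seed, before)
  b <- generate_fixture(8, 10, sweep_intensity = 0.5, seed = 11)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$positions, b$positions)
  c <- generate_fixture(8, 10, sweep_intensity = 0.5, seed = 12)
  expect_false(identical(a$matrix, c$matrix))
})

test_that("sweep cores reduce per-column heterozygosity relative to neutrality", {
  set.seed(31)
  core_het <- neutral_het <- numeric()
  for (r in 1:200) {
    swp <- generate_fixture(32, 24, sweep_intensity = 0.9, core_width = 0.5,
                            seed = 5000 + r)
    neu <- generate_fixture(32, 24, sweep_intensity = 0, seed = 6000 + r)
    core <- swp$provenance$core_columns
    core_het <- c(core_het, column_heterozygosity(swp$matrix[, core]))
    neutral_het <- c(neutral_het, column_heterozygosity(neu$matrix))
  }
  expect_lt(mean(core_het), mean(neutral_het))
})

test_that("fixture parameter validation", {
  expect_error(generate_fixture(3, 10), "at least 4")
  expect_error(generate_fixture(8, 1), "at least 2")
  expect_error(generate_fixture(8, 10, sweep_intensity = 1.2), "\\[0, 1\\]")
})
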