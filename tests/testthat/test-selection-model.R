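test_that("expected post-selection frequency follows the two-class closed form", {
  expect_equal(expected_post_frequency(5e-4, 0.3, 1e-4), 0.60012,
               tolerance = 1e-7)
  # no selection pressure: frequency unchanged
  expect_equal(expected_post_frequency(0.01, 0.2, 0.2), 0.01)
  # only catalysts survive
  expect_equal(expected_post_frequency(1e-3, 0.5, 0), 1)
  expect_error(expected_post_frequency(0.5, 0, 0), "degenerate")
})

test_that("expected enrichment is monotone in R, 1 at R = 1, capped at 1/f0", {
  expect_equal(expected_enrichment(1 / 2000, 3000), 1200.24,
               tolerance = 1e-6)
  expect_equal(expected_enrichment(0.1, 1), 1)
  expect_equal(expected_enrichment(1 / 500, 1e12), 500, tolerance = 1e-6)
  expect_error(expected_enrichment(0, 10), "positive")

  for (f0 in c(1 / 500, 1 / 2000, 0.1)) {
    R <- 10^seq(-2, 8, length.out = 40)
    E <- expected_enrichment(f0, R)
    expect_true(all(diff(E) > 0))          # strictly increasing
    expect_true(all(E <= 1 / f0 + 1e-9))   # dilution ceiling
  }
})

test_that("survival-ratio calibration inverts the enrichment closed form", {
  for (f0 in c(1 / 500, 1 / 2000)) {
    for (E in c(1.5, 70, 100, 0.9 / f0)) {
      R <- calibrate_survival_ratio(f0, E)
      expect_equal(expected_enrichment(f0, R), E, tolerance = 1e-10)
    }
  }
  expect_error(calibrate_survival_ratio(1 / 500, 500), "ceiling")
})

test_that("simulated selections conserve depth and honour p_bg = 0", {
  arch <- library_architecture()
  lib <- spike_in(generate_library(arch, 50, seed = 2), arch, 500)
  sim <- simulate_selection(lib, selection_params(0.3, 1e-4, 1e4, 2e4,
                                                  seed = 5))
  expect_equal(total_count(sim$pre), 1e4)
  expect_equal(total_count(sim$post), 2e4)
  expect_identical(
    sim,
    simulate_selection(lib, selection_params(0.3, 1e-4, 1e4, 2e4, seed = 5)))

  hard <- simulate_selection(lib, selection_params(0.3, 0, 1e4, 1e4,
                                                   seed = 5))
  expect_true(all(hard$post$count[hard$post$barcode !=
                                    arch$spike_barcode] == 0))
  expect_error(simulate_selection(lib[0, ],
                                  selection_params(0.3, 0, 10, 10)),
               "empty")
})

test_that("PCR amplification bias is off by default and seedable when on", {
  arch <- library_architecture()
  lib <- spike_in(generate_library(arch, 100, seed = 3), arch, 500)
  plain <- simulate_selection(lib, selection_params(0.3, 1e-4, 1e4, 1e4,
                                                    seed = 9))
  zero_bias <- simulate_selection(lib, selection_params(0.3, 1e-4, 1e4, 1e4,
                                                        pcr_bias_sd = 0,
                                                        seed = 9))
  expect_identical(plain, zero_bias)

  biased <- simulate_selection(lib, selection_params(0.3, 1e-4, 1e4, 1e4,
                                                     pcr_bias_sd = 0.5,
                                                     seed = 9))
  expect_identical(biased,
                   simulate_selection(lib,
                                      selection_params(0.3, 1e-4, 1e4, 1e4,
                                                       pcr_bias_sd = 0.5,
                                                       seed = 9)))
  expect_equal(total_count(biased$pre), 1e4)
  expect_equal(total_count(biased$post), 1e4)
  expect_false(identical(biased$pre$count, plain$pre$count))
})

test_that("Monte-Carlo spike post-frequency matches the closed form", {
  arch <- library_architecture()
  lib <- aggregate_library(arch, 500)
  f_expected <- expected_post_frequency(1 / 500, 0.2495, 0.002)
  depth <- 1e4
  freqs <- vapply(1:200, function(i) {
    sim <- simulate_selection(lib, selection_params(0.2495, 0.002,
                                                    10, depth, seed = i))
    sim$post$count[sim$post$barcode == arch$spike_barcode] / depth
  }, numeric(1))
  se <- sqrt(f_expected * (1 - f_expected) / (depth * 200))
  expect_lt(abs(mean(freqs) - f_expected), 3 * se)
})

test_that("empirical enrichment converges to the closed form at high depth", {
  arch <- library_architecture()
  f0 <- 1 / 2000
  lib <- aggregate_library(arch, 2000)
  depth <- 1e7
  sim <- simulate_selection(lib, selection_params(0.30, 1e-4,
                                                  depth, depth, seed = 31))
  spike_pre <- sim$pre$count[sim$pre$barcode == arch$spike_barcode] / depth
  spike_post <- sim$post$count[sim$post$barcode == arch$spike_barcode] / depth
  emp <- spike_post / spike_pre
  exp_E <- expected_enrichment(f0, 3000)
  f1 <- expected_post_frequency(f0, 0.30, 1e-4)
  # delta-method SE of the frequency ratio from two binomial samples
  se <- exp_E * sqrt((1 - f0) / (f0 * depth) + (1 - f1) / (f1 * depth))
  expect_lt(abs(emp - exp_E), 3 * se)
})

test_that("aggregate and enumerated backgrounds give the same spike draw", {
  arch <- library_architecture()
  agg <- aggregate_library(arch, 500)
  enum <- spike_in(generate_library(arch, 1e4, seed = 8), arch, 500)
  depth <- 5e4
  spike_freq <- function(lib, seed) {
    sim <- simulate_selection(lib, selection_params(0.2495, 0.002,
                                                    10, depth, seed = seed))
    sim$post$count[sim$post$barcode == arch$spike_barcode] / depth
  }
  f_agg <- vapply(1:10, function(s) spike_freq(agg, s), numeric(1))
  f_enum <- vapply(1:10, function(s) spike_freq(enum, 100 + s), numeric(1))
  f1 <- expected_post_frequency(1 / 500, 0.2495, 0.002)
  se <- sqrt(f1 * (1 - f1) / (depth * 10))
  expect_lt(abs(mean(f_agg) - mean(f_enum)), 3 * sqrt(2) * se)
})
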