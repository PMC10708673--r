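test_that("charge sites follow the every-p-th-monomer convention", {
  expect_length(charge_site_indices(202, 3), 68)
  expect_equal(charge_site_indices(10, 3), c(1, 4, 7, 10))
  s <- generate_sequence(202, 3, "pe", seed = 1)
  expect_length(s$site_values, 68)
  expect_length(generate_sequence(3, 3, "pe", seed = 1)$site_values, 1)
})

test_that("generated sequences respect model symbols and net charge", {
  pe <- generate_sequence(202, 3, "pe", markov_params(block_length = 4), seed = 7)
  expect_true(all(pe$site_values %in% c(0L, 1L)))
  expect_identical(net_charge(pe), sum(pe$site_values))
  pa <- generate_sequence(202, 3, "pa", seed = 8)
  expect_true(all(pa$site_values %in% c(-1L, 1L)))
  expect_identical(net_charge(pa), abs(sum(pa$site_values)))
  ## the Fig-style PA composition: 44 majority, 24 minority -> Q = 20
  pa$site_values <- c(rep(1L, 44), rep(-1L, 24))
  expect_identical(net_charge(pa), 20L)
  ## all-neutral PE
  pe$site_values <- rep(0L, 68)
  expect_identical(net_charge(pe), 0L)
})

test_that("identical seeds reproduce sequences bit-for-bit", {
  a <- generate_sequence(202, 3, "pe", markov_params(stay_prob = 0.75), seed = 42)
  b <- generate_sequence(202, 3, "pe", markov_params(stay_prob = 0.75), seed = 42)
  expect_identical(a, b)
  e1 <- generate_sequences(10, 202, 3, "pa", seed = 9)
  e2 <- generate_sequences(10, 202, 3, "pa", seed = 9)
  expect_identical(e1, e2)
})

test_that("invalid parameters are rejected", {
  expect_error(markov_params(stay_prob = 0), "in \\(0, 1\\)")
  expect_error(markov_params(stay_prob = 1), "in \\(0, 1\\)")
  expect_error(markov_params(block_length = 1), "> 1")
  expect_error(generate_sequence(0, 3, "pe"), "positive integer")
  expect_error(generate_sequence(10, 11, "pe"), "p <= N")
})

test_that("block-length estimator matches the exhaustive enumeration oracle", {
  ## 10-site chains: enumerate all 2^10 sequences weighted by chain
  ## probability, compare the generator ensemble to the exact expectation
  for (s in c(0.5, 0.75)) {
    exact <- enum_block_length(10, s)
    ens <- generate_sequences(4000, 28, 3, "pe",
                              markov_params(stay_prob = s), seed = 11)
    expect_length(ens[[1]]$site_values, 10)
    vals <- vapply(ens, average_block_length, numeric(1))
    se <- sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - exact), 3 * se + 1e-9)
    ## the enumeration agrees with the closed-form finite-chain expectation
    ## (1 - s^k)/(1 - s), which converges to the run length 1/(1 - s)
    expect_equal(exact, (1 - s^10) / (1 - s), tolerance = 1e-10)
  }
})

test_that("block length of edge cases", {
  s <- generate_sequence(202, 3, "pe", seed = 1)
  s$site_values <- rep(c(0L, 1L), 34)   # strictly alternating
  expect_equal(average_block_length(s), 1)
  s$site_values <- rep(1L, 68)          # one block
  expect_equal(average_block_length(s), 68)
  s$site_values <- integer(0)
  expect_error(average_block_length(s), "no runs")
})

test_that("marginal frequencies are unbiased and lag-1 autocorrelation is 2s-1", {
  for (s in c(0.5, 0.75)) {
    ens <- generate_sequences(4000, 202, 3, "pe",
                              markov_params(stay_prob = s), seed = 13)
    m <- do.call(rbind, lapply(ens, function(x) x$site_values))
    freq <- colMeans(m)
    se <- sqrt(0.25 / nrow(m))
    expect_true(all(abs(freq - 0.5) < 3 * se + 1e-12))
    x <- m - 0.5
    ac1 <- mean(x[, -ncol(x)] * x[, -1]) / mean(x^2)
    expect_lt(abs(ac1 - (2 * s - 1)), 0.02)
  }
})

test_that("sub-ensemble selection is exact, order-preserving, model-strict", {
  ens <- generate_sequences(1000, 202, 3, "pe", seed = 21)
  sub <- select_subensemble(ens, 34)
  expect_true(all(vapply(sub, net_charge, numeric(1)) == 34))
  expect_identical(sub, ens[vapply(ens, net_charge, numeric(1)) == 34])
  expect_length(select_subensemble(ens, 69), 0)   # infeasible: 68 sites
  pa <- generate_sequences(3, 202, 3, "pa", seed = 22)
  expect_error(select_subensemble(c(ens[1], pa[1]), 10), "mixed")
  ## a blocky sub-ensemble at fixed Q stays blocky
  blocky <- generate_sequences(3000, 202, 3, "pe",
                               markov_params(stay_prob = 0.75), seed = 23)
  sub <- select_subensemble(blocky, 34)
  expect_gt(length(sub), 30)
  expect_gt(average_block_length(sub), 2)
})

test_that("sequence JSON and CSV round-trips preserve the record", {
  ens <- generate_sequences(5, 202, 3, "pa",
                            markov_params(block_length = 4), seed = 31)
  f <- tempfile(fileext = ".json")
  write_sequences(ens, f)
  back <- read_sequences(f)
  for (i in seq_along(ens)) {
    expect_identical(back[[i]]$site_values, ens[[i]]$site_values)
    expect_identical(back[[i]]$Q, ens[[i]]$Q)
    expect_identical(back[[i]]$model, ens[[i]]$model)
  }
  fc <- tempfile(fileext = ".csv")
  write_sequence_csv(ens[[1]], fc)
  tab <- read.csv(fc)
  expect_equal(tab$value, ens[[1]]$site_values)
  expect_equal(tab$monomer_index, charge_site_indices(202, 3))
})
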