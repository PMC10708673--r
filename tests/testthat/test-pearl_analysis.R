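test_that("planted necklaces are decomposed exactly", {
  plan <- necklace_plan(list(segment_string(30, q = 5),
                             segment_pearl(80, q = 20),
                             segment_string(26, q = 4),
                             segment_pearl(40, q = 10),
                             segment_string(26, q = 3)))
  fx <- make_necklace(plan)
  expect_identical(nrow(fx$conformation$positions), 202L)
  d <- identify_pearls(fx$conformation)
  expect_identical(d$n, 2L)
  expect_equal(d$m, c(80, 40))
  expect_equal(d$q, c(20, 10))
  expect_identical(d$labels, fx$truth$labels)
  ## conservation
  expect_equal(d$Mp + d$Ns, d$N)
  expect_equal(d$Qp + d$Qs, d$Q)
  expect_equal(d$ms, d$Ns / 202)
  expect_equal(d$qs, d$Qs / d$Q)
})

test_that("degenerate conformations decompose sensibly", {
  rod <- make_necklace(necklace_plan(list(segment_string(50, q = 8))))
  dr <- identify_pearls(rod$conformation)
  expect_identical(dr$n, 0L)
  expect_equal(dr$ms, 1)
  globule <- make_necklace(necklace_plan(list(segment_pearl(202, q = 34))))
  dg <- identify_pearls(globule$conformation)
  expect_identical(dg$n, 1L)
  expect_equal(dg$ms, 0)
  expect_error(asymmetry(dr), "at least one pearl")
})

test_that("asymmetry follows the excess-mass/charge definitions", {
  fx <- make_necklace(necklace_plan(list(
    segment_string(10), segment_pearl(80, q = 20), segment_string(10),
    segment_pearl(40, q = 10), segment_string(10))))
  a <- asymmetry(identify_pearls(fx$conformation))
  expect_equal(a$x, c(1/6, -1/6), tolerance = 1e-12)
  expect_equal(sum(a$x), 0, tolerance = 1e-12)
  expect_equal(sum(a$y), 0, tolerance = 1e-12)
  ## equal pearls, equal charges -> zero vector
  fe <- make_necklace(necklace_plan(list(
    segment_string(10), segment_pearl(40, q = 10), segment_string(10),
    segment_pearl(40, q = 10), segment_string(10))))
  ae <- asymmetry(identify_pearls(fe$conformation))
  expect_equal(ae$x, c(0, 0)); expect_equal(ae$y, c(0, 0))
  ## uncharged pearls: y undefined
  f0 <- make_necklace(necklace_plan(list(
    segment_string(10, q = 3), segment_pearl(40), segment_string(10))))
  a0 <- asymmetry(identify_pearls(f0$conformation))
  expect_true(all(is.na(a0$y)))
})

test_that("PA charge bookkeeping projects onto the majority sign", {
  ## majority negative chain: Q = |sum|, pearl charges projected
  fx <- make_necklace(necklace_plan(list(
    segment_string(8), segment_pearl(40, q = 12, charge = -1),
    segment_string(10, q = 2, charge = 1), segment_pearl(24, q = 4, charge = 1),
    segment_string(8))))
  d <- identify_pearls(fx$conformation)
  expect_identical(d$model, "pa")
  expect_equal(d$Q, 12 - 2 - 4)
  expect_equal(d$q, c(12, -4))     # projected onto the majority (negative) sign
  expect_equal(d$Qp + d$Qs, d$Q)
})

test_that("density of states is max-normalized with exact point symmetry", {
  set.seed(31)
  decomps <- lapply(1:40, function(k) {
    m1 <- sample(seq(42, 80, by = 2), 1)
    q1 <- sample(8:16, 1)
    fx <- make_necklace(necklace_plan(list(
      segment_string(8), segment_pearl(m1, q = q1), segment_string(12),
      segment_pearl(120 - m1, q = 24 - q1), segment_string(8))))
    identify_pearls(fx$conformation)
  })
  dos <- density_of_states(decomps, kind = "xy", n = 2, bins = 24)
  expect_equal(max(dos$density), 1)
  bins <- nrow(dos$density)
  for (i in seq_len(bins)) for (j in seq_len(bins))
    expect_identical(dos$counts[i, j], dos$counts[bins + 1 - i, bins + 1 - j])
  ## single repeated state -> one bin and its mirror
  dos1 <- density_of_states(decomps[c(1, 1, 1)], kind = "xy", n = 2, bins = 10)
  expect_identical(sum(dos1$counts > 0), 2L)
  expect_equal(max(dos1$density), 1)
  ## ms/qs histogram
  dmq <- density_of_states(decomps, kind = "msqs", bins = 12)
  expect_equal(max(dmq$density), 1)
  expect_error(density_of_states(decomps, kind = "xy", n = 5), "empty selection")
})

test_that("time series, dwell times, and switching paths are exact on fixtures", {
  ser <- make_switching_series(data.frame(n = c(2, 3, 2),
                                          duration = c(50, 20, 30),
                                          nl = c(2, 1, 1)), sampling = 10)
  expect_identical(ser$n, rep(c(2L, 3L, 2L), c(5, 2, 3)))
  w3 <- dwell_times(ser, 3)
  expect_equal(w3$durations, 20)
  expect_equal(w3$mean, 20)
  ## boundary runs are censored
  w2 <- dwell_times(ser, 2)
  expect_length(w2$durations, 0)
  expect_equal(sort(w2$censored), c(30, 50))
  expect_true(is.na(w2$mean))
  expect_equal(dwell_times(ser, 2, include_censored = TRUE)$mean, 40)
  ## all-constant series: one censored run, undefined mean
  serc <- make_switching_series(data.frame(n = 2, duration = 80), sampling = 10)
  wc <- dwell_times(serc, 2)
  expect_true(is.na(wc$mean))
  expect_equal(wc$censored, 80)
  expect_identical(nrow(switching_path(serc)), 0L)
  ## never-visited state
  expect_length(dwell_times(ser, 7)$durations, 0)
  ## switching events carry nearest-vertex annotations
  ev <- switching_path(ser)
  expect_identical(nrow(ev), 2L)
  expect_equal(ev$n_before, c(2, 3))
  expect_equal(ev$n_after, c(3, 2))
  expect_equal(ev$nearest_nl, c(1, 1))
  expect_equal(ev$vertex_distance, c(0, 0))
  ## event count equals the number of changes
  expect_identical(nrow(ev), sum(diff(ser$n) != 0))
})

test_that("count_timeseries never leaves gaps", {
  frames <- list(
    make_necklace(necklace_plan(list(segment_string(8), segment_pearl(40, q = 8),
                                     segment_string(8))))$conformation,
    make_necklace(necklace_plan(list(segment_string(56))))$conformation,
    make_necklace(necklace_plan(list(segment_string(8), segment_pearl(40, q = 8),
                                     segment_string(8))))$conformation)
  frames <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]; f$time <- i * 10; f })
  tr <- trajectory(frames)
  ser <- count_timeseries(tr)
  expect_identical(ser$n, c(1L, 0L, 1L))
  expect_length(ser$decompositions, 3)
})

test_that("concatenating switching patterns concatenates the series", {
  a <- data.frame(n = 2, duration = 30)
  b <- data.frame(n = 3, duration = 20)
  ser_ab <- make_switching_series(rbind(a, b), sampling = 10)
  ser_a <- make_switching_series(a, sampling = 10)
  ser_b <- make_switching_series(b, sampling = 10)
  expect_identical(ser_ab$n, c(ser_a$n, ser_b$n))
  expect_error(make_switching_series(data.frame(n = 2, duration = 25),
                                     sampling = 10), "multiples")
})
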