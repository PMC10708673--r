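## Independent oracles used by the tests. These deliberately re-derive the
## quantities from first principles (enumeration, inline formulas, generic
## optimizers) rather than calling the package's own code paths.

## Exact expectation of the per-sequence block-length estimator
## (sites / number of maximal runs) over all 2^n_sites binary sequences of
## a symmetric two-state Markov chain with stay probability s.
enum_block_length <- function(n_sites, s) {
  total <- 0
  for (code in 0:(2^n_sites - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(n_sites)]
    flips <- sum(abs(diff(bits)))
    stays <- (n_sites - 1) - flips
    prob <- 0.5 * s^stays * (1 - s)^flips
    runs <- flips + 1
    total <- total + prob * n_sites / runs
  }
  total
}

## Charge-equilibrated n-pearl energy, written out inline (the quantity
## the landscape module models): F(m) = sum m^(2/3) + chi / sum m^(1/3)
## - 1 - chi.
oracle_equilibrated <- function(masses, chi) {
  sum(masses^(2/3)) + chi / sum(masses^(1/3)) - 1 - chi
}

## Brute-force global minimization of the charge-equilibrated energy over
## the mass simplex (sorted masses, step-resolution grid). Returns the
## minimizing mass vector and its energy.
oracle_grid_min <- function(n, chi, step = 1e-3) {
  if (n == 2) {
    m1 <- seq(0.5, 1 - step, by = step)
    en <- sapply(m1, function(a) oracle_equilibrated(c(a, 1 - a), chi))
    i <- which.min(en)
    list(masses = c(m1[i], 1 - m1[i]), energy = en[i])
  } else if (n == 3) {
    g <- seq(step, 1 - step, by = step)
    grid <- expand.grid(m1 = g, m2 = g)
    grid$m3 <- 1 - grid$m1 - grid$m2
    grid <- grid[grid$m1 >= grid$m2 & grid$m2 >= grid$m3 & grid$m3 > 0, ]
    en <- grid$m1^(2/3) + grid$m2^(2/3) + grid$m3^(2/3) +
      chi / (grid$m1^(1/3) + grid$m2^(1/3) + grid$m3^(1/3)) - 1 - chi
    i <- which.min(en)
    list(masses = c(grid$m1[i], grid$m2[i], grid$m3[i]), energy = en[i])
  } else stop("oracle supports n = 2, 3")
}

## Independent constrained minimization over the charge distribution at
## fixed masses: generic BFGS over the n-1 free charge fractions, energy
## written inline.
oracle_charge_min <- function(masses, chi, n_starts = 5, seed = 1) {
  n <- length(masses)
  raw_energy <- function(cfrac) {
    if (any(cfrac < 0) || any(masses == 0 & cfrac > 0)) return(Inf)
    es <- ifelse(masses > 0, cfrac^2 / masses^(1/3), 0)
    sum(masses^(2/3)) + chi * sum(es) - 1 - chi
  }
  obj <- function(free) raw_energy(c(free, 1 - sum(free)))
  set.seed(seed)
  best <- Inf
  for (k in seq_len(n_starts)) {
    start <- if (k == 1) rep(1 / n, n - 1) else {
      p <- runif(n); (p / sum(p))[seq_len(n - 1)]
    }
    fit <- tryCatch(
      optim(start, obj, method = "BFGS",
            control = list(reltol = 1e-14, maxit = 2000)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$value < best) best <- fit$value
  }
  best
}

## A quick necklace fixture batch used by several analysis tests.
random_plan <- function(n_pearls, seed) {
  set.seed(seed)
  segs <- list(segment_string(sample(5:20, 1), q = sample(0:3, 1)))
  for (j in seq_len(n_pearls)) {
    m <- sample(seq(8, 96, by = 2), 1)
    segs <- c(segs,
              list(segment_pearl(m, q = sample(1:(m %/% 3), 1))),
              list(segment_string(sample(5:25, 1), q = sample(0:4, 1))))
  }
  necklace_plan(segs)
}
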