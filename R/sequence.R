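#' Markov blockiness parameters
#'
#' A symmetric two-state Markov chain over the charge sites is parametrized
#' by the stay probability `s`: the probability that a site repeats the
#' symbol of the previous site. The expected length of a maximal run of
#' identical symbols (the "block length") is `L = 1/(1 - s)`, so `s = 1/2`
#' gives uncorrelated sites with mean block length 2, and `s = 3/4` gives
#' blocky sequences with mean block length 4.
#'
#' @param stay_prob stay probability in (0, 1). Give either this or
#'   `block_length`.
#' @param block_length target mean block length `L > 1`; converted to
#'   `stay_prob = 1 - 1/L`.
#' @return An object of class `markov_params` with fields `stay_prob` and
#'   `block_length`.
#' @examples
#' markov_params(block_length = 4)  # blocky, stay_prob = 3/4
#' @export
markov_params <- function(stay_prob = NULL, block_length = NULL) {
  if (is.null(stay_prob) && is.null(block_length))
    stop("give either 'stay_prob' or 'block_length'")
  if (is.null(stay_prob)) {
    if (!is.numeric(block_length) || length(block_length) != 1L ||
        block_length <= 1)
      stop("'block_length' must be a single number > 1")
    stay_prob <- 1 - 1 / block_length
  }
  if (!is.numeric(stay_prob) || length(stay_prob) != 1L ||
      stay_prob <= 0 || stay_prob >= 1)
    stop("'stay_prob' must be a single number in (0, 1)")
  structure(list(stay_prob = stay_prob,
                 block_length = 1 / (1 - stay_prob)),
            class = "markov_params")
}

#' Monomer indices of the charge sites
#'
#' Charge sites sit at 1-based monomer indices 1, 1+p, 1+2p, ..., giving
#' `ceiling(N/p)` sites; for the canonical chain N = 202, p = 3 this is 68
#' sites.
#'
#' @param N total monomer count.
#' @param p charge-site spacing (every p-th monomer is a site).
#' @return Integer vector of monomer indices.
#' @export
charge_site_indices <- function(N, p) {
  stopifnot(N >= 1, p >= 1)
  seq.int(1L, N, by = p)
}

new_charge_sequence <- function(model, N, p, stay_prob, seed, site_values) {
  Q <- if (model == "pe") sum(site_values) else abs(sum(site_values))
  structure(list(model = model, N = as.integer(N), p = as.integer(p),
                 stay_prob = stay_prob, seed = seed,
                 site_values = as.integer(site_values), Q = as.integer(Q)),
            class = "charge_sequence")
}

#' Generate a quenched Markovian charge sequence
#'
#' Draws the symbol of the first charge site uniformly from the two allowed
#' symbols (PE: 0/1, PA: -1/+1) and lets each subsequent site repeat the
#' previous symbol with probability `stay_prob`. The chain is stationary and
#' unbiased: the marginal distribution at every site is uniform.
#'
#' @param N total monomer count; charge sites sit at monomers 1, 1+p, ...
#' @param p charge-site spacing.
#' @param model `"pe"` (symbols 0 = neutral, 1 = charged) or `"pa"`
#'   (symbols -1, +1).
#' @param params a [markov_params()] object (or a bare stay probability).
#' @param seed integer RNG seed recorded in the output; `NULL` uses the
#'   current RNG state.
#' @return A `charge_sequence` with fields `model`, `N`, `p`, `stay_prob`,
#'   `seed`, `site_values`, `Q` (PE: number of charges; PA: majority minus
#'   minority count).
#' @examples
#' s <- generate_sequence(202, 3, "pe", markov_params(block_length = 2), seed = 1)
#' length(s$site_values)  # 68
#' @export
generate_sequence <- function(N, p, model = c("pe", "pa"),
                              params = markov_params(stay_prob = 0.5),
                              seed = NULL) {
  model <- match.arg(model)
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("'N' must be a positive integer")
  if (!is.numeric(p) || length(p) != 1L || p < 1 || p != round(p) || p > N)
    stop("'p' must be an integer with 1 <= p <= N")
  if (is.numeric(params)) params <- markov_params(stay_prob = params)
  if (!inherits(params, "markov_params")) stop("'params' must be markov_params")
  if (!is.null(seed)) set.seed(seed)
  n_sites <- length(charge_site_indices(N, p))
  s <- params$stay_prob
  ## two-state symmetric chain: track symbol index in {0,1}
  start <- sample.int(2L, 1L) - 1L
  flips <- if (n_sites > 1L) as.integer(runif(n_sites - 1L) > s) else integer(0)
  state <- (start + cumsum(c(0L, flips))) %% 2L
  vals <- if (model == "pe") state else 2L * state - 1L
  new_charge_sequence(model, N, p, s, seed, vals)
}

#' Generate an ensemble of charge sequences
#'
#' All sequences are drawn from a single seeded RNG stream; the batch seed is
#' recorded on each member.
#'
#' @inheritParams generate_sequence
#' @param count number of sequences.
#' @return List of `charge_sequence` objects.
#' @export
generate_sequences <- function(count, N, p, model = c("pe", "pa"),
                               params = markov_params(stay_prob = 0.5),
                               seed = NULL) {
  model <- match.arg(model)
  stopifnot(count >= 1)
  if (!is.null(seed)) set.seed(seed)
  replicate(count,
            generate_sequence(N, p, model, params, seed = NULL),
            simplify = FALSE) |>
    lapply(function(x) { x$seed <- seed; x })
}

#' Mean block length of a sequence or ensemble
#'
#' A block is a maximal run of identical symbols over the charge sites. For
#' a single sequence the estimator is (number of sites) / (number of runs);
#' for an ensemble it is the mean of the per-sequence ratios, which is an
#' (essentially exactly) unbiased estimator of `1/(1 - stay_prob)` for the
#' stationary symmetric chain: pooling all runs instead would be biased low
#' by the boundary-censored runs.
#'
#' @param x a `charge_sequence` or a list of them.
#' @return Mean run length in charge sites.
#' @export
average_block_length <- function(x) {
  one <- function(s) {
    v <- s$site_values
    if (length(v) == 0L) stop("empty sequence has no runs")
    length(v) / length(rle(v)$lengths)
  }
  if (inherits(x, "charge_sequence")) return(one(x))
  if (!is.list(x) || length(x) == 0L)
    stop("'x' must be a charge_sequence or a non-empty list of them")
  mean(vapply(x, one, numeric(1)))
}

#' Net charge of a sequence
#'
#' PE: number of charged sites. PA: absolute difference between the
#' majority and the minority charge count.
#'
#' @param seq a `charge_sequence`.
#' @return Integer net charge Q.
#' @export
net_charge <- function(seq) {
  stopifnot(inherits(seq, "charge_sequence"))
  if (seq$model == "pe") sum(seq$site_values) else abs(sum(seq$site_values))
}

#' Select the sub-ensemble with an exact net charge
#'
#' @param sequences list of `charge_sequence` objects, all of one model.
#' @param Q_target required net charge (exact equality).
#' @return The (possibly empty) subset, input order preserved.
#' @export
select_subensemble <- function(sequences, Q_target) {
  stopifnot(is.list(sequences))
  if (length(sequences) == 0L) return(sequences)
  models <- vapply(sequences, function(s) s$model, character(1))
  if (length(unique(models)) != 1L)
    stop("mixed PE/PA input: all sequences must share one model")
  sequences[vapply(sequences, net_charge, numeric(1)) == Q_target]
}

#' @export
print.charge_sequence <- function(x, ...) {
  cat(sprintf("<charge_sequence %s> N=%d p=%d sites=%d Q=%d stay_prob=%.3f\n",
              toupper(x$model), x$N, x$p, length(x$site_values), x$Q,
              x$stay_prob))
  invisible(x)
}

#' Write / read sequences as JSON
#'
#' The JSON file holds a list of records with fields `model`, `N`, `p`,
#' `stay_prob`, `seed`, `site_values`, `Q`.
#'
#' @param sequences list of `charge_sequence` objects (or one).
#' @param path file path.
#' @return `write_sequences` returns `path` invisibly; `read_sequences`
#'   returns a list of `charge_sequence` objects.
#' @export
write_sequences <- function(sequences, path) {
  if (inherits(sequences, "charge_sequence")) sequences <- list(sequences)
  recs <- lapply(sequences, function(s)
    list(model = s$model, N = s$N, p = s$p, stay_prob = s$stay_prob,
         seed = if (is.null(s$seed)) NA else s$seed,
         site_values = s$site_values, Q = s$Q))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sequences
#' @export
read_sequences <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(recs, function(r) {
    s <- new_charge_sequence(r$model, r$N, r$p, r$stay_prob,
                             if (is.na(r$seed)) NULL else r$seed,
                             r$site_values)
    if (s$Q != r$Q) stop("corrupt sequence record: stored Q does not match")
    s
  })
}

#' Write a sequence as a flat CSV (site_index, monomer_index, value)
#'
#' @param seq a `charge_sequence`.
#' @param path file path.
#' @export
write_sequence_csv <- function(seq, path) {
  stopifnot(inherits(seq, "charge_sequence"))
  idx <- charge_site_indices(seq$N, seq$p)
  write.csv(data.frame(site_index = seq_along(idx), monomer_index = idx,
                       value = seq$site_values),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-monomer charge vector of a sequence
#'
#' Expands the charge-site symbols to a length-N per-monomer charge vector
#' (0 off the charge sites; PE sites carry 0/+1, PA sites carry -1/+1).
#'
#' @param seq a `charge_sequence`.
#' @return Integer vector of length `N`.
#' @export
monomer_charges <- function(seq) {
  stopifnot(inherits(seq, "charge_sequence"))
  z <- integer(seq$N)
  z[charge_site_indices(seq$N, seq$p)] <- seq$site_values
  z
}
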