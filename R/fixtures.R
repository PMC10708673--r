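## Synthetic necklace conformations and n(t) series with planted ground
## truth, so the analysis operators are testable without MD.

#' Necklace plan
#'
#' An ordered description of a planted pearl-necklace chain: pearl
#' segments (dense blobs) and string/tail segments, in chain order. Pearl
#' blobs are built as serpentine walks on a cubic lattice whose spacing is
#' `density^(-1/3)`; strings are taut lines with 1 sigma bead spacing. The
#' chain advances along a diagonal axis so that every pearl-string
#' junction has full clearance.
#'
#' @param segments list of segments from [segment_pearl()] /
#'   [segment_string()], in chain order.
#' @param density blob density in monomers/sigma^3 (lattice spacing
#'   `density^(-1/3)`; the default 0.9^-3 ~ 1.37 guarantees that every
#'   blob monomer is dense for any contact cutoff r_c between 1.3 and 1.7).
#' @param jitter Gaussian positional noise amplitude in sigma (<= 0.1;
#'   planted recovery is only guaranteed for small jitter).
#' @param seed RNG seed (used by jitter).
#' @return Object of class `necklace_plan`.
#' @export
necklace_plan <- function(segments, density = 0.9^-3, jitter = 0,
                          seed = NULL) {
  stopifnot(is.list(segments), length(segments) >= 1)
  ok <- vapply(segments, function(s)
    is.list(s) && s$type %in% c("pearl", "string"), logical(1))
  if (!all(ok)) stop("segments must come from segment_pearl()/segment_string()")
  if (density < 0.5) stop("blob density must be >= 0.5 monomers/sigma^3")
  if (jitter < 0 || jitter > 0.1) stop("jitter must be in [0, 0.1] sigma")
  types <- vapply(segments, function(s) s$type, character(1))
  if (any(types[-1] == "pearl" & types[-length(types)] == "pearl"))
    stop("two pearl segments must be separated by a string segment")
  N <- sum(vapply(segments, function(s) s$m, numeric(1)))
  structure(list(segments = segments, density = density, jitter = jitter,
                 seed = seed, N = as.integer(N)),
            class = "necklace_plan")
}

#' @rdname necklace_plan
#' @param m monomer count of the segment (pearls: composite, >= 6, so the
#'   blob has a detectable dense core).
#' @param q number of charges planted in the segment (evenly spread).
#' @param charge charge value of the planted charges (+1 or -1).
#' @export
segment_pearl <- function(m, q = 0, charge = 1) {
  stopifnot(m >= 6, q >= 0, q <= m, charge %in% c(-1, 1))
  list(type = "pearl", m = as.integer(m), q = as.integer(q),
       charge = charge)
}

#' @rdname necklace_plan
#' @export
segment_string <- function(m, q = 0, charge = 1) {
  stopifnot(m >= 3, q >= 0, q <= m, charge %in% c(-1, 1))
  list(type = "string", m = as.integer(m), q = as.integer(q),
       charge = charge)
}

## near-cubic box dims for a blob of m beads with all rows full:
## a divides m (row length), rows = m/a split into layers of b rows.
blob_dims <- function(m) {
  divs <- which(m %% seq_len(m) == 0)
  divs <- divs[divs >= 2 & m / divs >= 2]
  if (length(divs) == 0L)
    stop(sprintf("pearl size %d has no divisor a >= 2 with m/a >= 2 rows; use a composite size", m))
  a <- divs[which.min(abs(divs - m^(1/3)))]
  rows <- m / a
  b <- max(2L, ceiling(sqrt(rows)))
  list(a = as.integer(a), b = as.integer(b), rows = as.integer(rows))
}

## serpentine lattice path of m beads: rows of length a along x, b rows
## per layer along y, layers stacked along z; consecutive sites adjacent.
## Returns integer site coordinates (m x 3), starting at (0,0,0).
serpentine_path <- function(m, a, b) {
  rows <- m / a
  out <- matrix(0L, m, 3)
  i <- 0L
  for (row in 0:(rows - 1)) {
    layer <- row %/% b
    yrow <- row %% b
    ## reverse y order on odd layers so layer transitions are adjacent
    y <- if (layer %% 2L == 0L) yrow else b - 1L - yrow
    ## x direction alternates per global row index
    xs <- if (row %% 2L == 0L) 0:(a - 1L) else (a - 1L):0
    out[i + seq_len(a), ] <- cbind(xs, y, layer)
    i <- i + a
  }
  out
}

#' Build a planted pearl-necklace conformation
#'
#' Realizes a [necklace_plan()] as bead coordinates plus the ground-truth
#' [identify_pearls()] decomposition. Pearl blobs are serpentine lattice
#' walks in near-cubic boxes (bond length = lattice spacing); strings are
#' straight 1-sigma-spaced lines along the diagonal axis; junction bonds
#' are 1.1 sigma. The geometry guarantees that `identify_pearls()` at the
#' default parameters recovers the planted masses and charges exactly
#' (for zero jitter).
#'
#' @param plan a `necklace_plan`.
#' @return List with `conformation`, `truth` (a `pearl_decomposition`),
#'   and `plan`.
#' @export
make_necklace <- function(plan) {
  stopifnot(inherits(plan, "necklace_plan"))
  u <- plan$density^(-1/3)
  segs <- plan$segments
  N <- plan$N
  pos <- matrix(NA_real_, N, 3)
  charges <- numeric(N)
  truth_labels <- integer(N)
  pearl_id <- 0L
  cursor <- c(0, 0, 0)   # position of the NEXT bead to place
  ## chain axis direction signs: the chain advances along the steepened
  ## diagonal (sx/2, sy/2, 1/sqrt(2)); the signs flip at each blob so that
  ## the exit corner's forward octant is empty. The steep pitch keeps every
  ## non-bonded string bead >= 1.73 sigma from the blob lattice.
  sx <- 1; sy <- 1
  evec <- function() c(sx / 2, sy / 2, sqrt(0.5))
  i <- 0L
  for (s in segs) {
    idx <- i + seq_len(s$m)
    if (s$type == "pearl") {
      pearl_id <- pearl_id + 1L
      dims <- blob_dims(s$m)
      lat <- serpentine_path(s$m, dims$a, dims$b)
      ## reflect so the box grows along the current chain octant;
      ## entry bead (0,0,0) sits at the cursor
      block <- cbind(sx * lat[, 1], sy * lat[, 2], lat[, 3]) * u
      block <- sweep(block, 2, cursor, "+")
      pos[idx, ] <- block
      truth_labels[idx] <- pearl_id
      ## serpentine exit parity: last row R runs +x when R is even; the
      ## exit layer's free y side depends on the layer parity
      R <- dims$rows - 1L
      sx <- sx * (if (R %% 2L == 0L) 1 else -1)
      sy <- sy * (if ((R %/% dims$b) %% 2L == 0L) 1 else -1)
      cursor <- block[s$m, ] + 1.1 * evec()  # junction bond to the string
    } else {
      ## straight string: first bead at cursor, then 1 sigma spacing
      e <- evec()
      for (k in seq_len(s$m)) pos[idx[k], ] <- cursor + (k - 1) * e
      cursor <- pos[idx[s$m], ] + 1.1 * e    # entry bead of the next pearl
    }
    if (s$q > 0) {
      at <- idx[unique(round(seq(1, s$m, length.out = s$q)))]
      if (length(at) < s$q)
        stop("cannot place the requested charges distinctly; reduce q")
      charges[at] <- s$charge
    }
    i <- i + s$m
  }
  if (plan$jitter > 0) {
    if (!is.null(plan$seed)) set.seed(plan$seed)
    pos <- pos + matrix(rnorm(3 * N, sd = plan$jitter), N, 3)
  }
  conf <- conformation(pos, charges)
  truth <- truth_from_labels(conf, truth_labels)
  list(conformation = conf, truth = truth, plan = plan)
}

## assemble a pearl_decomposition from planted labels (mass-sorted ids,
## same conventions as identify_pearls)
truth_from_labels <- function(conf, labels) {
  N <- length(labels)
  zsum <- sum(conf$charges)
  Q <- abs(zsum)
  sgn <- if (zsum >= 0) 1 else -1
  n_pearl <- max(labels)
  if (n_pearl > 0L) {
    m <- tabulate(labels[labels > 0L], nbins = n_pearl)
    q <- vapply(seq_len(n_pearl), function(k)
      sgn * sum(conf$charges[labels == k]), numeric(1))
    ord <- order(-m, -q, vapply(seq_len(n_pearl),
                                function(k) min(which(labels == k)),
                                numeric(1)))
    relab <- integer(n_pearl)
    relab[ord] <- seq_len(n_pearl)
    labels[labels > 0L] <- relab[labels[labels > 0L]]
    m <- m[ord]; q <- q[ord]
  } else {
    m <- numeric(0); q <- numeric(0)
  }
  Mp <- sum(m); Qp <- sum(q)
  structure(list(labels = labels, n = n_pearl, m = m, q = q,
                 Mp = Mp, Qp = Qp, Ns = N - Mp, Qs = Q - Qp,
                 ms = (N - Mp) / N, qs = if (Q > 0) (Q - Qp) / Q else NA_real_,
                 N = N, Q = Q,
                 model = if (any(conf$charges < 0)) "pa" else "pe",
                 params = c(r_c = NA, n_dense = NA, min_size = NA)),
            class = "pearl_decomposition")
}

#' Synthetic pearl-count series with planted dwell times
#'
#' Builds a `state_series` whose `n(t)` follows a given pattern of
#' (pearl count, duration) segments. Durations must be multiples of the
#' sampling interval. Segments may carry an `nl` vertex index, in which
#' case the samples sit exactly at the vertex V(nl, n-nl) of the state's
#' simplex, so nearest-vertex annotations are planted too.
#'
#' @param pattern data.frame (or list of lists) with columns `n`,
#'   `duration` (tau), and optionally `nl`.
#' @param sampling sampling interval in tau.
#' @return A `state_series` (without decompositions).
#' @export
make_switching_series <- function(pattern, sampling = 10) {
  if (is.data.frame(pattern)) {
    pattern <- lapply(seq_len(nrow(pattern)), function(i) as.list(pattern[i, ]))
  }
  stopifnot(length(pattern) >= 1, sampling > 0)
  n <- integer(0)
  simplex <- list()
  for (seg in pattern) {
    k <- seg$duration / sampling
    if (abs(k - round(k)) > 1e-9)
      stop("durations must be multiples of the sampling interval")
    k <- as.integer(round(k))
    n <- c(n, rep(as.integer(seg$n), k))
    sp <- if (!is.null(seg$nl) && !is.na(seg$nl) && seg$n >= 1)
      as_simplex_point(simplex_vertex(seg$n, seg$nl)) else NULL
    simplex <- c(simplex, rep(list(sp), k))
  }
  state_series(times = seq_along(n) * sampling, n = n, simplex = simplex)
}
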