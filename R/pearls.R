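## Pearl/string decomposition of chain conformations and the derived
## asymmetry observables.

#' Decompose a conformation into pearls and strings
#'
#' A monomer is "dense" iff it has at least `n_dense` non-bonded neighbours
#' (chain distance >= 2) within `r_c`. Pearls are the connected components
#' of the dense monomers (component edges are any pair of dense monomers
#' within `r_c`), post-filtered to size >= `min_size`; components below the
#' size threshold dissolve into strings. Remaining non-dense monomers with
#' a non-bonded contact (within `r_c`) to exactly one surviving pearl are
#' re-attached to it; everything else is string/tail. The decomposition is
#' deterministic for a fixed conformation, and pearls are reported
#' mass-sorted (descending) -- the order along the chain is not retained.
#'
#' Charge bookkeeping: for PE chains the pearl charge `q_i` is the number
#' of charges on the pearl; for PA chains it is the signed charge sum
#' projected onto the chain's majority sign, so that `Qp + Qs = Q` holds
#' with the majority-minus-minority net charge `Q`.
#'
#' @param conf a `conformation`.
#' @param r_c contact cutoff in sigma.
#' @param n_dense minimum number of non-bonded neighbours of a dense
#'   monomer.
#' @param min_size minimum pearl size in monomers.
#' @return Object of class `pearl_decomposition`: `labels` (0 = string or
#'   tail, 1..n = mass-sorted pearl id), `n`, `m` (pearl masses in
#'   monomers), `q` (pearl charges), `Mp`, `Qp`, `Ns`, `Qs`,
#'   `ms = Ns/N`, `qs = Qs/Q` (NA when Q = 0), `N`, `Q`.
#' @export
identify_pearls <- function(conf, r_c = 1.5, n_dense = 3, min_size = 4) {
  stopifnot(inherits(conf, "conformation"), r_c > 0, n_dense >= 1,
            min_size >= 1)
  pos <- conf$positions
  N <- nrow(pos)
  d <- as.matrix(dist(pos))
  within <- d <= r_c
  diag(within) <- FALSE
  chain_sep <- abs(outer(seq_len(N), seq_len(N), "-"))
  nonbond <- chain_sep >= 2L
  dense <- rowSums(within & nonbond) >= n_dense

  labels <- integer(N)
  if (any(dense)) {
    idx <- which(dense)
    ## connected components among dense monomers (edges: any pair within r_c)
    adj <- within[idx, idx, drop = FALSE]
    comp <- integer(length(idx))
    cid <- 0L
    for (s in seq_along(idx)) {
      if (comp[s] != 0L) next
      cid <- cid + 1L
      queue <- s
      comp[s] <- cid
      while (length(queue)) {
        v <- queue[[1]]
        queue <- queue[-1]
        nb <- which(adj[v, ] & comp == 0L)
        comp[nb] <- cid
        queue <- c(queue, nb)
      }
    }
    sizes <- tabulate(comp)
    keep <- which(sizes >= min_size)
    if (length(keep)) {
      relab <- integer(max(comp))
      relab[keep] <- seq_along(keep)
      labels[idx] <- relab[comp]
    }
  }

  n_pearl <- max(labels)
  if (n_pearl > 0L) {
    ## re-attach non-dense monomers with non-bonded contact to exactly one pearl
    loose <- which(!dense & labels == 0L)
    if (length(loose)) {
      contact <- within & nonbond
      pearl_members <- lapply(seq_len(n_pearl), function(k) which(labels == k))
      for (i in loose) {
        touching <- which(vapply(pearl_members,
                                 function(mem) any(contact[i, mem]),
                                 logical(1)))
        if (length(touching) == 1L) labels[i] <- touching
      }
    }
  }

  model <- if (any(conf$charges < 0)) "pa" else "pe"
  zsum <- sum(conf$charges)
  Q <- abs(zsum)
  sgn <- if (zsum >= 0) 1 else -1
  pearl_q <- function(members) sgn * sum(conf$charges[members])

  if (n_pearl > 0L) {
    m <- tabulate(labels[labels > 0L], nbins = n_pearl)
    q <- vapply(seq_len(n_pearl), function(k) pearl_q(which(labels == k)),
                numeric(1))
    ## mass-sorted ids, ties broken by charge then first member (determinism)
    ord <- order(-m, -q, vapply(seq_len(n_pearl),
                                function(k) min(which(labels == k)),
                                numeric(1)))
    relab <- integer(n_pearl)
    relab[ord] <- seq_len(n_pearl)
    labels[labels > 0L] <- relab[labels[labels > 0L]]
    m <- m[ord]
    q <- q[ord]
  } else {
    m <- numeric(0)
    q <- numeric(0)
  }
  Mp <- sum(m)
  Qp <- sum(q)
  Ns <- N - Mp
  Qs <- Q - Qp
  structure(list(labels = labels, n = n_pearl, m = m, q = q,
                 Mp = Mp, Qp = Qp, Ns = Ns, Qs = Qs,
                 ms = Ns / N, qs = if (Q > 0) Qs / Q else NA_real_,
                 N = N, Q = Q, model = model,
                 params = c(r_c = r_c, n_dense = n_dense,
                            min_size = min_size)),
            class = "pearl_decomposition")
}

#' @export
print.pearl_decomposition <- function(x, ...) {
  cat(sprintf("<pearl_decomposition> n=%d  m=(%s)  q=(%s)  ms=%.3f qs=%s\n",
              x$n, paste(x$m, collapse = ","), paste(x$q, collapse = ","),
              x$ms, ifelse(is.na(x$qs), "NA", sprintf("%.3f", x$qs))))
  invisible(x)
}

#' Mass/charge asymmetry of a decomposition
#'
#' Computes the relative excess masses `x_i = m_i/Mp - 1/n` and charges
#' `y_i = q_i/Qp - 1/n` of the pearls (mass-sorted descending) and the
#' simplex-point coordinates (the n-1 largest x's). When the pearls carry
#' no charge (`Qp = 0`) the `y_i` are undefined and reported as NA.
#'
#' @param decomp a `pearl_decomposition` with `n >= 1` and `Mp > 0`.
#' @return List with `n`, `x`, `y`, and `simplex` (a `simplex_point`).
#' @export
asymmetry <- function(decomp) {
  stopifnot(inherits(decomp, "pearl_decomposition"))
  if (decomp$n < 1 || decomp$Mp <= 0)
    stop("asymmetry requires at least one pearl (Mp > 0)")
  n <- decomp$n
  x <- decomp$m / decomp$Mp - 1 / n
  y <- if (decomp$Qp > 0) decomp$q / decomp$Qp - 1 / n else rep(NA_real_, n)
  list(n = n, x = x, y = y, simplex = as_simplex_point(x))
}

#' Density of visited states on a 2D observable plane
#'
#' Histograms either the pearl asymmetry pairs `(x_i, y_i)` of the n-pearl
#' states (`kind = "xy"`; every pearl of each state contributes a point) or
#' the string allocation `(ms, qs)` (`kind = "msqs"`). Counts are
#' normalized by the maximum bin so the density is on a 0..1 scale. For
#' 2-pearl xy-histograms the two pearls of each state contribute the
#' mirror pair `(x, y)` and `(-x, -y)`; the mirror bin index is derived
#' from the first pearl's bin so the point symmetry about the origin is
#' exact at bin level. States with `Qp = 0` (undefined y) are excluded and
#' counted in the `"dropped"` attribute.
#'
#' @param states a `state_series` (see [count_timeseries()]) or a list of
#'   `pearl_decomposition` objects.
#' @param kind `"xy"` or `"msqs"`.
#' @param n pearl count selecting the states to histogram (`NULL` for all;
#'   required for `"xy"`).
#' @param bins number of bins per axis.
#' @param limits optional list(x = c(lo, hi), y = c(lo, hi)); defaults to
#'   the data bounding box (symmetrized for 2-pearl xy).
#' @return Object of class `state_density`: `density` (bins x bins matrix,
#'   max 1), `x_breaks`, `y_breaks`, `kind`, `n`, `npoints`.
#' @export
density_of_states <- function(states, kind = c("xy", "msqs"), n = NULL,
                              bins = 50, limits = NULL) {
  kind <- match.arg(kind)
  decomps <- as_decomp_list(states)
  if (kind == "xy") {
    if (is.null(n)) stop("'n' (pearl count) is required for kind = \"xy\"")
    decomps <- Filter(function(d) d$n == n, decomps)
    dropped <- sum(vapply(decomps, function(d) d$Qp <= 0, logical(1)))
    decomps <- Filter(function(d) d$Qp > 0, decomps)
    if (length(decomps) == 0L) stop("empty selection: no usable states")
    pts <- do.call(rbind, lapply(decomps, function(d) {
      a <- asymmetry(d)
      cbind(a$x, a$y)
    }))
  } else {
    if (!is.null(n)) decomps <- Filter(function(d) d$n == n, decomps)
    decomps <- Filter(function(d) !is.na(d$qs), decomps)
    dropped <- 0L
    if (length(decomps) == 0L) stop("empty selection: no usable states")
    pts <- do.call(rbind, lapply(decomps, function(d) c(d$ms, d$qs)))
  }

  mirror <- kind == "xy" && !is.null(n) && n == 2L
  if (mirror) {
    ## keep one pearl per state; the mirror bin supplies the other
    pts <- pts[seq(1, nrow(pts), by = 2), , drop = FALSE]
  }
  if (is.null(limits)) {
    if (mirror) {
      lx <- max(abs(pts[, 1]), 1e-12) * 1.000001
      ly <- max(abs(pts[, 2]), 1e-12) * 1.000001
      limits <- list(x = c(-lx, lx), y = c(-ly, ly))
    } else {
      pad <- function(r) r + c(-1, 1) * max(diff(r), 1e-12) * 1e-6
      limits <- list(x = pad(range(pts[, 1])), y = pad(range(pts[, 2])))
    }
  }
  xb <- seq(limits$x[1], limits$x[2], length.out = bins + 1)
  yb <- seq(limits$y[1], limits$y[2], length.out = bins + 1)
  ix <- findInterval(pts[, 1], xb, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(pts[, 2], yb, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, bins, bins)
  for (k in seq_len(nrow(pts))) {
    counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
    if (mirror) {
      mi <- bins + 1L - ix[k]
      mj <- bins + 1L - iy[k]
      counts[mi, mj] <- counts[mi, mj] + 1L
    }
  }
  structure(list(density = counts / max(counts), counts = counts,
                 x_breaks = xb, y_breaks = yb, kind = kind, n = n,
                 npoints = nrow(pts) * (1L + mirror)),
            dropped = dropped, class = "state_density")
}

as_decomp_list <- function(states) {
  if (inherits(states, "state_series")) return(states$decompositions)
  if (inherits(states, "pearl_decomposition")) return(list(states))
  if (is.list(states) && length(states) &&
      all(vapply(states, inherits, logical(1), "pearl_decomposition")))
    return(states)
  stop("'states' must be a state_series or a list of pearl_decomposition")
}

#' Per-frame pearl-count time series of a trajectory
#'
#' Runs [identify_pearls()] on every frame. Frames where detection finds
#' no pearl produce `n = 0` entries (never gaps), e.g. fully stretched
#' states.
#'
#' @param traj a `trajectory`.
#' @inheritParams identify_pearls
#' @return Object of class `state_series`: `times` (tau), `n` (pearl count
#'   per frame), `decompositions` (list), `simplex` (list of
#'   `simplex_point` or NULL for n = 0 frames).
#' @export
count_timeseries <- function(traj, r_c = 1.5, n_dense = 3, min_size = 4) {
  stopifnot(inherits(traj, "trajectory"))
  decomps <- lapply(traj$frames, identify_pearls, r_c = r_c,
                    n_dense = n_dense, min_size = min_size)
  state_series(times = traj$times,
               n = vapply(decomps, function(d) d$n, integer(1)),
               decompositions = decomps)
}

#' Construct a state series
#'
#' @param times sample times (tau), fixed spacing.
#' @param n pearl count per sample.
#' @param decompositions optional list of `pearl_decomposition` per sample.
#' @param simplex optional list of `simplex_point` (or NULL) per sample;
#'   derived from the decompositions when omitted.
#' @return Object of class `state_series`.
#' @export
state_series <- function(times, n, decompositions = NULL, simplex = NULL) {
  stopifnot(length(times) == length(n))
  if (!is.null(decompositions)) stopifnot(length(decompositions) == length(n))
  if (is.null(simplex) && !is.null(decompositions)) {
    simplex <- lapply(decompositions, function(d)
      if (d$n >= 1) asymmetry(d)$simplex else NULL)
  }
  if (!is.null(simplex)) stopifnot(length(simplex) == length(n))
  structure(list(times = times, n = as.integer(n),
                 decompositions = decompositions, simplex = simplex),
            class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  cat(sprintf("<state_series> %d samples, n in [%d, %d]\n",
              length(x$n), min(x$n), max(x$n)))
  invisible(x)
}

#' Dwell times of a pearl-count state
#'
#' Maximal runs of `n(t) = n_state`; each dwell lasts (run length) x
#' (sampling interval). Runs touching either end of the series are
#' censored (their true duration is unknown) and excluded from the mean by
#' default.
#'
#' @param series a `state_series` sampled at a fixed interval.
#' @param n_state the pearl count whose dwells are measured.
#' @param include_censored include boundary runs in `durations` and the
#'   mean.
#' @return List with `durations` (tau, uncensored unless
#'   `include_censored`), `censored` (tau), and `mean` (NA when no
#'   uncensored run exists).
#' @export
dwell_times <- function(series, n_state, include_censored = FALSE) {
  stopifnot(inherits(series, "state_series"))
  if (length(series$n) < 1) stop("empty series")
  dtau <- unique(round(diff(series$times), 10))
  if (length(dtau) != 1L)
    stop("dwell_times requires a fixed sampling interval")
  r <- rle(series$n)
  is_state <- r$values == n_state
  if (!any(is_state))
    return(list(durations = numeric(0), censored = numeric(0),
                mean = NA_real_))
  k <- length(r$lengths)
  boundary <- seq_len(k) %in% c(1L, k)
  dur <- r$lengths * dtau
  uncens <- dur[is_state & !boundary]
  cens <- dur[is_state & boundary]
  if (include_censored) uncens <- c(uncens, cens)
  list(durations = uncens, censored = cens,
       mean = if (length(uncens)) mean(uncens) else NA_real_)
}

#' Switching events of a pearl-count series
#'
#' One event per change of `n(t)`, carrying the post-change simplex
#' location and its nearest vertex V(nl, n-nl) (Euclidean distance over
#' the state's own simplex coordinates).
#'
#' @param series a `state_series` of length >= 2.
#' @return data.frame with columns `time`, `n_before`, `n_after`,
#'   `nearest_nl`, `vertex_distance`; the post-change simplex coordinates
#'   are in the `"simplex"` attribute (list, NULL where unavailable).
#' @export
switching_path <- function(series) {
  stopifnot(inherits(series, "state_series"))
  if (length(series$n) < 2) stop("series length must be >= 2")
  chg <- which(diff(series$n) != 0) + 1L
  coords <- vector("list", length(chg))
  out <- data.frame(time = series$times[chg],
                    n_before = series$n[chg - 1L],
                    n_after = series$n[chg],
                    nearest_nl = rep(NA_integer_, length(chg)),
                    vertex_distance = rep(NA_real_, length(chg)))
  for (k in seq_along(chg)) {
    i <- chg[k]
    sp <- if (!is.null(series$simplex)) series$simplex[[i]] else NULL
    if (!is.null(sp) && sp$n >= 1) {
      coords[[k]] <- sp$coords
      nv <- nearest_vertex(sp)
      out$nearest_nl[k] <- nv$nl
      out$vertex_distance[k] <- nv$distance
    }
  }
  attr(out, "simplex") <- coords
  out
}

#' Nearest simplex vertex of a state
#'
#' @param sp a `simplex_point`.
#' @return List with `nl` (vertex index V(nl, n-nl)) and `distance`.
#' @export
nearest_vertex <- function(sp) {
  stopifnot(inherits(sp, "simplex_point"))
  n <- sp$n
  if (n == 1L) return(list(nl = 1L, distance = 0))
  d <- vapply(seq_len(n), function(nl) {
    v <- simplex_vertex(n, nl)
    sqrt(sum((sp$coords - v[seq_len(n - 1)])^2))
  }, numeric(1))
  list(nl = which.min(d), distance = min(d))
}

#' Write per-frame decompositions as CSV
#'
#' Columns: frame, time, n, ms, qs, then the mass-sorted `m_i;q_i` pairs
#' in a single `pearls` column.
#'
#' @param series a `state_series` with decompositions.
#' @param path file path.
#' @export
write_decompositions_csv <- function(series, path) {
  stopifnot(inherits(series, "state_series"),
            !is.null(series$decompositions))
  rows <- lapply(seq_along(series$n), function(i) {
    d <- series$decompositions[[i]]
    data.frame(frame = i, time = series$times[i], n = d$n,
               ms = d$ms, qs = d$qs,
               pearls = paste(sprintf("%d;%g", d$m, d$q), collapse = "|"))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a state density as a CSV grid
#'
#' @param dos a `state_density`.
#' @param path file path.
#' @export
write_density_csv <- function(dos, path) {
  stopifnot(inherits(dos, "state_density"))
  bins <- nrow(dos$density)
  grid <- expand.grid(ix = seq_len(bins), iy = seq_len(bins))
  xc <- (dos$x_breaks[-1] + dos$x_breaks[-(bins + 1)]) / 2
  yc <- (dos$y_breaks[-1] + dos$y_breaks[-(bins + 1)]) / 2
  out <- data.frame(x = xc[grid$ix], y = yc[grid$iy],
                    density = dos$density[cbind(grid$ix, grid$iy)])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
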