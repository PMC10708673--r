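## Stationary points of the charge-equilibrated n-pearl landscape under the
## two-group ansatz: nl pearls of mass a, ns = n - nl pearls of mass b with
## nl*a + ns*b = 1. Parametrized by the small-pearl mass b in (0, 1/n].

## derivative of the equilibrated energy along the constrained b direction:
## g(b) = ns * [ (2/3)(b^{-1/3} - a^{-1/3})
##             - (chi/(3 S^2)) (b^{-2/3} - a^{-2/3}) ],  S = nl a^{1/3} + ns b^{1/3}
two_group_slope <- function(b, n, nl, chi) {
  ns <- n - nl
  a <- (1 - ns * b) / nl
  S <- nl * a^(1/3) + ns * b^(1/3)
  ns * ((2/3) * (b^(-1/3) - a^(-1/3)) -
        (chi / (3 * S^2)) * (b^(-2/3) - a^(-2/3)))
}

two_group_energy <- function(b, n, nl, chi) {
  ns <- n - nl
  a <- (1 - ns * b) / nl
  nl * a^(2/3) + ns * b^(2/3) + chi / (nl * a^(1/3) + ns * b^(1/3)) - 1 - chi
}

## smallest root of the slope in b (the branch continuing from the vertex
## V(nl, ns) at chi -> 0), or NA if the branch has annihilated (chi > chi_c).
## Log-spaced scan: the root scales like chi^3 at small chi.
two_group_root <- function(n, nl, chi, tol = 1e-14) {
  upper <- 1 / n * (1 - 1e-9)
  grid <- c(10^seq(-30, -4, length.out = 300),
            seq(1.2e-4, upper, length.out = 4000))
  g <- two_group_slope(grid, n, nl, chi)
  sc <- which(g[-length(g)] < 0 & g[-1] >= 0)
  if (length(sc) == 0L) return(NA_real_)
  i <- sc[1]
  r <- stats::uniroot(two_group_slope, c(grid[i], grid[i + 1]),
                      n = n, nl = nl, chi = chi, tol = tol)
  r$root
}

## analytic Hessian of E(x, y) = sum m^{2/3} + chi sum c^2 m^{-1/3}
## (m = 1/n + x mass fractions, c = 1/n + y charge fractions), projected
## onto the sum(x)=0, sum(y)=0 subspace via an orthonormal (Helmert)
## basis. Takes the fractions themselves to avoid cancellation when a
## pearl mass is tiny. Returns eigenvalues.
projected_hessian_eigen <- function(n, chi, m, cc) {
  hxx <- -(2/9) * m^(-4/3) + chi * cc^2 * (4/9) * m^(-7/3)
  hxy <- -(2/3) * chi * cc * m^(-4/3)
  hyy <- 2 * chi * m^(-1/3)
  H <- rbind(cbind(diag(hxx, n), diag(hxy, n)),
             cbind(diag(hxy, n), diag(hyy, n)))
  Z <- helmert_basis(n)
  B <- rbind(cbind(Z, matrix(0, n, n - 1)),
             cbind(matrix(0, n, n - 1), Z))
  eigen(t(B) %*% H %*% B, symmetric = TRUE, only.values = TRUE)$values
}

## orthonormal basis of the {v : sum(v) = 0} subspace of R^n
helmert_basis <- function(n) {
  if (n < 2) return(matrix(0, n, 0))
  Z <- matrix(0, n, n - 1)
  for (k in seq_len(n - 1)) {
    Z[seq_len(k), k] <- 1
    Z[k + 1, k] <- -k
    Z[, k] <- Z[, k] / sqrt(k * (k + 1))
  }
  Z
}

classify_eigenvalues <- function(ev, tol = 1e-9) {
  neg <- sum(ev < -tol)
  pos <- sum(ev > tol)
  k <- length(ev)
  stability <- if (neg == 0 && pos == k) "minimum"
  else if (pos == 0 && neg == k) "maximum"
  else sprintf("saddle(%d)", neg)
  list(stability = stability, n_negative = neg, eigenvalues = ev)
}

#' Locate and classify the extremum E(nl, ns) of the n-pearl landscape
#'
#' Solves the stationarity condition of the charge-equilibrated energy
#' restricted to the two-group ansatz (`nl` equal large pearls of mass `a`,
#' `ns = n - nl` equal small pearls of mass `b`, `nl*a + ns*b = 1`) and
#' classifies the stationary point from the analytic Hessian of the full
#' (x, y) energy projected onto the `sum(x) = sum(y) = 0` subspace. Pearls
#' are reported mass-sorted (descending); the order along the chain is not
#' retained. For `chi = 0` the extremum degenerates to the simplex vertex
#' V(nl, ns) itself. Beyond the fold point ([chi_critical()]) the
#' asymmetric branch does not exist and the record is flagged absent.
#'
#' @param n number of pearls (>= 1).
#' @param nl number of evenly large pearls, `1 <= nl <= n`.
#' @param chi control parameter, >= 0.
#' @param compute_chi_c also run [chi_critical()] and store the fold point
#'   (slower; default `FALSE`).
#' @return An object of class `extremum_record`: `n`, `nl`, `ns`, `chi`,
#'   `exists`, masses `a` (large) and `b` (small), `x_large`, `x_small`,
#'   `y_large`, `y_small`, `energy` (Es units), `stability` (`"minimum"`,
#'   `"saddle(k)"` with k negative directions, `"maximum"`), `chi_c`.
#' @export
find_extremum <- function(n, nl, chi, compute_chi_c = FALSE) {
  stopifnot(n >= 1, n == round(n), chi >= 0)
  if (nl < 1 || nl > n || nl != round(nl)) stop("'nl' must be in 1..n")
  ns <- n - nl
  rec <- list(n = as.integer(n), nl = as.integer(nl), ns = as.integer(ns),
              chi = chi, exists = TRUE, a = NA_real_, b = NA_real_,
              x_large = NA_real_, x_small = NA_real_,
              y_large = NA_real_, y_small = NA_real_,
              energy = NA_real_, stability = NA_character_,
              n_negative = NA_integer_, chi_c = NA_real_)
  if (n == 1L) {
    rec[c("a", "b")] <- list(1, NA_real_)
    rec[c("x_large", "x_small", "y_large", "y_small")] <- list(0, NA_real_, 0, NA_real_)
    rec$energy <- 0
    rec$stability <- "minimum"
    rec$n_negative <- 0L
    return(structure(rec, class = "extremum_record"))
  }
  if (nl == n) {
    ## symmetric state: always stationary
    rec$a <- rec$b <- 1 / n
    rec[c("x_large", "x_small", "y_large", "y_small")] <- list(0, 0, 0, 0)
    rec$energy <- symmetric_energy(n, chi)
    cls <- classify_eigenvalues(
      projected_hessian_eigen(n, chi, rep(1 / n, n), rep(1 / n, n)))
    rec$stability <- cls$stability
    rec$n_negative <- cls$n_negative
    rec$chi_c <- Inf
    return(structure(rec, class = "extremum_record"))
  }
  if (chi == 0) {
    ## degenerate vertex solution: nl pearls of mass 1/nl, ns of mass 0
    rec$a <- 1 / nl; rec$b <- 0
    rec$x_large <- 1 / nl - 1 / n; rec$x_small <- -1 / n
    rec$y_large <- 1 / nl - 1 / n; rec$y_small <- -1 / n
    rec$energy <- nl^(1/3) - 1
    ## boundary extremum: growing a small pearl raises the (pure surface)
    ## energy; splitting the nl equal large pearls lowers nothing -- equal
    ## split maximizes the concave surface term, giving nl-1 downhill
    ## directions. nl = 1 is the global minimum.
    rec$stability <- if (nl == 1L) "minimum" else sprintf("saddle(%d)", nl - 1L)
    rec$n_negative <- nl - 1L
    if (compute_chi_c) rec$chi_c <- chi_critical(n, nl)
    return(structure(rec, class = "extremum_record"))
  }
  b <- two_group_root(n, nl, chi)
  if (is.na(b)) {
    rec$exists <- FALSE
    if (compute_chi_c) rec$chi_c <- chi_critical(n, nl)
    return(structure(rec, class = "extremum_record"))
  }
  a <- (1 - ns * b) / nl
  masses <- c(rep(a, nl), rep(b, ns))
  eq <- equilibrated_energy(n, chi, masses)
  rec$a <- a; rec$b <- b
  rec$x_large <- a - 1 / n; rec$x_small <- b - 1 / n
  rec$y_large <- eq$y[1]; rec$y_small <- eq$y[n]
  rec$energy <- eq$energy
  cls <- classify_eigenvalues(
    projected_hessian_eigen(n, chi, masses, masses^(1/3) / sum(masses^(1/3))))
  rec$stability <- cls$stability
  rec$n_negative <- cls$n_negative
  if (compute_chi_c) rec$chi_c <- chi_critical(n, nl)
  structure(rec, class = "extremum_record")
}

#' @export
print.extremum_record <- function(x, ...) {
  if (!x$exists) {
    cat(sprintf("<extremum E(%d,%d)> chi=%.4g: absent (chi > chi_c)\n",
                x$nl, x$ns, x$chi))
  } else {
    cat(sprintf(
      "<extremum E(%d,%d)> chi=%.4g masses (%.6g x%d, %.6g x%d) E=%.6g %s\n",
      x$nl, x$ns, x$chi, x$a, x$nl, x$b, x$ns, x$energy, x$stability))
  }
  invisible(x)
}

#' Fold point chi_c of the asymmetric branch E(nl, ns)
#'
#' Returns the critical value of chi beyond which the asymmetric stationary
#' branch with `nl` large and `ns = n - nl` small pearls ceases to exist.
#' The branch annihilates in a fold where the positive bump of the
#' constrained energy slope collapses; the fold is located by bisection on
#' the sign of `max_b g(b; chi)` over the small-pearl mass `b`, refined by
#' local optimization. For `n = 2` the exchange symmetry `b <-> 1 - b`
#' turns the fold into a (supercritical) pitchfork and `chi_c` equals `n`
#' exactly; for `n >= 3` the fold lies above `n`.
#'
#' @param n number of pearls (>= 2).
#' @param nl number of large pearls, `1 <= nl < n`.
#' @param tol bisection half-width on chi.
#' @param chi_max upper limit of the bracket search.
#' @return chi_c, with attribute `"bracket"` giving the final (lo, hi)
#'   existence bracket.
#' @export
chi_critical <- function(n, nl, tol = 1e-6, chi_max = 1e3) {
  stopifnot(n >= 2, n == round(n))
  if (nl < 1 || nl >= n || nl != round(nl)) stop("'nl' must be in 1..n-1")
  upper <- 1 / n * (1 - 1e-7)
  peak <- function(chi) {
    grid <- c(10^seq(-12, -3, length.out = 60),
              seq(1.5e-3, upper, length.out = 3000))
    g <- two_group_slope(grid, n, nl, chi)
    i <- which.max(g)
    lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
    if (lo < hi) {
      o <- stats::optimize(two_group_slope, c(lo, hi), n = n, nl = nl,
                           chi = chi, maximum = TRUE, tol = 1e-12)
      max(g[i], o$objective)
    } else g[i]
  }
  lo <- 1  # asymmetric branch always exists for small chi
  if (peak(lo) <= 0) stop("bracketing failure: branch absent at chi = 1")
  hi <- 2 * n
  it <- 0
  while (peak(hi) > 0) {
    hi <- hi * 2; it <- it + 1
    if (hi > chi_max)
      stop(sprintf("chi_critical: no annihilation found below chi = %g (lo = %g)",
                   chi_max, lo))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (peak(mid) > 0) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, bracket = c(lo, hi))
}

#' Saddle-to-minimum transition of the symmetric state
#'
#' The smallest eigenvalue of the projected Hessian at the symmetric state
#' changes sign at chi = n: below it the evenly-split state is the highest
#' saddle, above it it is the energy minimum. The transition is located by
#' root finding on the smallest eigenvalue as a function of chi.
#'
#' @param n number of pearls (>= 2).
#' @param tol root-finding tolerance on chi.
#' @return The transition value chi* (equal to n up to `tol`).
#' @export
stability_transition <- function(n, tol = 1e-8) {
  stopifnot(n >= 2, n == round(n))
  lam <- function(chi)
    min(projected_hessian_eigen(n, chi, rep(1 / n, n), rep(1 / n, n)))
  stats::uniroot(lam, c(0.25 * n, 4 * n), tol = tol)$root
}

#' Scan the extremum set over chi
#'
#' Convenience wrapper producing a data frame of extremum records E(nl, ns)
#' for all `nl = 1..n` over a chi grid (the CSV surface of the landscape
#' CLI subcommand).
#'
#' @param n number of pearls.
#' @param chi_values numeric vector of chi values.
#' @param compute_chi_c also compute the fold point per branch (once).
#' @return data.frame with columns n, nl, ns, chi, exists, a, b, x_large,
#'   x_small, energy, stability, chi_c.
#' @export
scan_extrema <- function(n, chi_values, compute_chi_c = FALSE) {
  chic <- rep(NA_real_, n)
  if (compute_chi_c && n >= 2)
    for (nl in seq_len(n - 1)) chic[nl] <- as.numeric(chi_critical(n, nl))
  rows <- list()
  for (nl in seq_len(n)) for (chi in chi_values) {
    r <- find_extremum(n, nl, chi)
    rows[[length(rows) + 1L]] <- data.frame(
      n = n, nl = nl, ns = n - nl, chi = chi, exists = r$exists,
      a = r$a, b = r$b, x_large = r$x_large, x_small = r$x_small,
      energy = r$energy, stability = r$stability,
      chi_c = if (nl == n) Inf else chic[nl])
  }
  do.call(rbind, rows)
}
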