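#' n-pearl asymmetry state
#'
#' An n-pearl state is described by the control parameter `chi` (ratio of
#' electrostatic self-energy to surface energy of the single-globule
#' reference state) and the relative excess masses `x_i` and charges `y_i`,
#' defined through `m_i/Mp = 1/n + x_i` and `q_i/Qp = 1/n + y_i`. Mass and
#' charge conservation force `sum(x) = sum(y) = 0`, and every pearl mass
#' `1/n + x_i` must be non-negative. Energies are measured in units of the
#' reference-globule surface energy (Es = 1).
#'
#' @param n number of pearls (>= 1).
#' @param chi control parameter, >= 0, dimensionless.
#' @param x,y numeric vectors of length `n`; defaults are the symmetric
#'   state (all zeros).
#' @param tol tolerance on the conservation constraints.
#' @return An object of class `asymmetry_state`.
#' @export
asymmetry_state <- function(n, chi, x = rep(0, n), y = rep(0, n),
                            tol = 1e-12) {
  stopifnot(n >= 1, n == round(n), chi >= 0)
  if (length(x) != n || length(y) != n)
    stop("'x' and 'y' must have length n")
  if (abs(sum(x)) > tol || abs(sum(y)) > tol)
    stop("constraint violation: sum(x) and sum(y) must vanish")
  m <- 1 / n + x
  if (any(m < -tol)) stop("negative pearl mass: 1/n + x_i must be >= 0")
  ch <- 1 / n + y
  if (any(m <= tol & abs(ch) > tol))
    stop("a zero-mass pearl must carry zero charge")
  structure(list(n = as.integer(n), chi = chi, x = x, y = y),
            class = "asymmetry_state")
}

#' n-pearl energy (surface + electrostatic self-energy)
#'
#' Energy of an n-pearl state in units of the reference-globule surface
#' energy:
#' `E = sum_i (1/n + x_i)^(2/3) + chi * sum_i (1/n + y_i)^2 / (1/n + x_i)^(1/3)
#'  - 1 - chi`.
#' The single-globule reference state (n = 1, x = y = 0) has energy exactly
#' 0. A pearl with zero mass and zero charge contributes 0; zero mass with
#' nonzero charge is a domain error (infinite self-energy of a charged
#' point).
#'
#' @param state an [asymmetry_state()], or `n` when using the raw-vector
#'   interface.
#' @param chi,x,y raw-vector interface: used when `state` is a number `n`.
#' @return Scalar energy in Es units.
#' @examples
#' pearl_energy(asymmetry_state(2, 0))      # 2^(1/3) - 1
#' pearl_energy(2, chi = 2)                 # 2 * 2^(1/3) - 3
#' @export
pearl_energy <- function(state, chi = NULL, x = NULL, y = NULL) {
  if (!inherits(state, "asymmetry_state")) {
    n <- state
    if (is.null(x)) x <- rep(0, n)
    if (is.null(y)) y <- rep(0, n)
    state <- asymmetry_state(n, chi, x, y)
  }
  n <- state$n
  m <- 1 / n + state$x
  q <- 1 / n + state$y
  m[m < 0] <- 0
  es <- ifelse(m > 0, q^2 / m^(1/3), 0)
  sum(m^(2/3)) + state$chi * sum(es) - 1 - state$chi
}

#' Energy of the symmetric (evenly split) n-pearl state
#'
#' Closed form `n^(1/3) + chi * n^(-2/3) - 1 - chi`.
#'
#' @param n number of pearls.
#' @param chi control parameter.
#' @return Scalar energy in Es units.
#' @export
symmetric_energy <- function(n, chi) {
  stopifnot(n >= 1, chi >= 0)
  n^(1/3) + chi * n^(-2/3) - 1 - chi
}

#' Charge-equilibrated n-pearl energy at fixed masses
#'
#' Minimizes the energy over the charge distribution `{y_i}` at fixed
#' masses under `sum(y) = 0`. The quadratic electrostatic term gives the
#' closed-form optimum `1/n + y_i* = m_i^(1/3) / sum_j m_j^(1/3)` and the
#' equilibrated energy
#' `sum_i m_i^(2/3) + chi / sum_i m_i^(1/3) - 1 - chi`.
#' Smaller pearls receive more charge than their mass share, larger ones
#' less.
#'
#' @param n number of pearls.
#' @param chi control parameter.
#' @param masses pearl mass fractions, `m_i >= 0`, summing to 1.
#' @param tol tolerance on the mass-sum constraint.
#' @return List with `energy` (Es units) and `y` (the optimal excess
#'   charges).
#' @export
equilibrated_energy <- function(n, chi, masses, tol = 1e-9) {
  stopifnot(n >= 1, chi >= 0, length(masses) == n)
  if (any(masses < -tol)) stop("masses must be non-negative")
  masses[masses < 0] <- 0
  if (abs(sum(masses) - 1) > tol) stop("masses must sum to 1")
  if (all(masses == 0)) stop("all masses zero")
  S <- sum(masses^(1/3))
  list(energy = sum(masses^(2/3)) + chi / S - 1 - chi,
       y = masses^(1/3) / S - 1 / n)
}

#' Vertex V(nl, ns) of the mass simplex
#'
#' The state with `nl` pearls of mass `1/nl` and `ns = n - nl` pearls of
#' vanishing mass: `x_i = 1/nl - 1/n` for the large pearls and `x_i = -1/n`
#' for the vanishing ones. `V(n, 0)` is the symmetric state (zero vector).
#'
#' @param n number of pearls.
#' @param nl number of (equal) large pearls, `1 <= nl <= n`.
#' @return Numeric vector `x` of length `n` (mass-sorted, descending).
#' @export
simplex_vertex <- function(n, nl) {
  stopifnot(n >= 1, n == round(n))
  if (nl < 1 || nl > n || nl != round(nl)) stop("'nl' must be in 1..n")
  c(rep(1 / nl - 1 / n, nl), rep(-1 / n, n - nl))
}

#' Simplex-point coordinates of a full excess-mass vector
#'
#' Sorts `x` descending and drops the smallest pearl (whose coordinate is
#' fixed by mass conservation), giving the `(n-1)` coordinates used in the
#' simplex representation.
#'
#' @param x full excess-mass vector of length n (summing to 0).
#' @return Object of class `simplex_point` with fields `n` and `coords`.
#' @export
as_simplex_point <- function(x) {
  n <- length(x)
  xs <- sort(x, decreasing = TRUE)
  structure(list(n = n, coords = xs[seq_len(max(n - 1, 0))]),
            class = "simplex_point")
}

#' Test whether simplex coordinates lie in the (n-1)-simplex
#'
#' The admissible region is bounded by the n linear inequalities
#' `x_1 >= x_2 >= ... >= x_{n-1} >= x_n` (with `x_n = -sum(coords)`) and
#' `1/n + x_n >= 0` (positive smallest pearl). The boundary counts as
#' inside.
#'
#' @param point a `simplex_point`, or a bare coordinate vector of length
#'   `n - 1` with `n` given.
#' @param n pearl count (needed for a bare vector).
#' @param tol slack on the inequalities.
#' @return Logical; attribute `"violated"` lists the indices (1..n) of the
#'   violated inequalities (i = 1..n-1: ranking x_i >= x_{i+1}; i = n:
#'   non-negative smallest mass).
#' @export
in_simplex <- function(point, n = NULL, tol = 1e-12) {
  if (inherits(point, "simplex_point")) {
    coords <- point$coords; n <- point$n
  } else {
    coords <- point
    if (is.null(n)) n <- length(coords) + 1L
  }
  if (length(coords) != n - 1L)
    stop(sprintf("expected %d coordinates for an (n-1)-simplex with n=%d",
                 n - 1L, n))
  xn <- -sum(coords)
  full <- c(coords, xn)
  viol <- integer(0)
  if (n > 1) {
    rank_ok <- diff(full) <= tol
    viol <- which(!rank_ok)
  }
  if (1 / n + xn < -tol) viol <- c(viol, n)
  structure(length(viol) == 0L, violated = viol)
}

#' @export
print.asymmetry_state <- function(x, ...) {
  cat(sprintf("<asymmetry_state> n=%d chi=%.4g\n  x: %s\n  y: %s\n",
              x$n, x$chi, paste(signif(x$x, 4), collapse = " "),
              paste(signif(x$y, 4), collapse = " ")))
  invisible(x)
}
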