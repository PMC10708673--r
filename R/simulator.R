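#' Coarse-grained force field (reduced units)
#'
#' Kremer-Grest-style bead-spring parametrization in reduced units
#' (`sigma = kT = m = 1`, time unit `tau = sigma*sqrt(m/kT) = 1`):
#' FENE bonds `U = -k R0^2/2 * log(1 - r^2/R0^2)`, full (attractive)
#' unshifted Lennard-Jones pairs with cutoff `r_cut` modelling the poor
#' solvent, and bare unscreened Coulomb `U = lambda_B z_i z_j / r` among
#' the chain charges (no counterions, no added salt: single-chain infinite
#' dilution). PE chains default to a rather poor solvent
#' (`eps_lj = 1.5 kT`), PA chains to a marginally poor one
#' (`eps_lj = 1 kT`).
#'
#' @param model `"pe"` or `"pa"`; sets the `eps_lj` default.
#' @param eps_lj LJ well depth in kT.
#' @param sigma bead diameter (length unit).
#' @param r_cut LJ cutoff in sigma (must be >= 2^(1/6) sigma).
#' @param k_fene FENE stiffness in kT/sigma^2.
#' @param R0 FENE maximum extension in sigma.
#' @param lambda_B Bjerrum length in sigma.
#' @param gamma Langevin friction in 1/tau.
#' @param kT thermal energy (1 in reduced units).
#' @return Object of class `force_field`.
#' @export
force_field <- function(model = c("pe", "pa"),
                        eps_lj = NULL, sigma = 1, r_cut = 2.5,
                        k_fene = 30, R0 = 1.5, lambda_B = 3,
                        gamma = 1, kT = 1) {
  model <- match.arg(model)
  if (is.null(eps_lj)) eps_lj <- if (model == "pe") 1.5 else 1.0
  vals <- c(eps_lj = eps_lj, sigma = sigma, r_cut = r_cut, k_fene = k_fene,
            R0 = R0, lambda_B = lambda_B, gamma = gamma, kT = kT)
  if (any(vals <= 0)) stop("all force-field parameters must be positive")
  if (r_cut < 2^(1/6) * sigma) stop("r_cut must be >= 2^(1/6) sigma")
  structure(list(model = model, eps_lj = eps_lj, sigma = sigma,
                 r_cut = r_cut, k_fene = k_fene, R0 = R0,
                 lambda_B = lambda_B, gamma = gamma, kT = kT),
            class = "force_field")
}

#' Bead conformation
#'
#' @param positions N x 3 matrix of bead coordinates (sigma units).
#' @param charges per-bead integer charges.
#' @param time simulation time in tau.
#' @return Object of class `conformation`.
#' @export
conformation <- function(positions, charges, time = 0) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, nrow(positions) == length(charges),
            all(is.finite(positions)))
  structure(list(positions = positions, charges = as.numeric(charges),
                 time = time), class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("<conformation> N=%d  |z|=%d  t=%.6g tau\n",
              nrow(x$positions), sum(x$charges != 0), x$time))
  invisible(x)
}

#' Build an initial chain conformation
#'
#' `extended` places the beads on a straight line with 1 sigma bond length;
#' `random-walk` grows a random walk with 1 sigma steps, rejecting beads
#' closer than 0.9 sigma to any previous bead. Charges are placed on the
#' charge sites according to the sequence.
#'
#' @param seq a `charge_sequence`.
#' @param mode `"extended"` or `"random-walk"`.
#' @param seed RNG seed (random-walk mode).
#' @return A `conformation` at time 0.
#' @export
build_initial_conformation <- function(seq, mode = c("random-walk", "extended"),
                                       seed = NULL) {
  stopifnot(inherits(seq, "charge_sequence"))
  mode <- match.arg(mode)
  N <- seq$N
  z <- monomer_charges(seq)
  if (mode == "extended") {
    pos <- cbind(0, 0, seq_len(N) - 1)
    return(conformation(pos, z))
  }
  if (!is.null(seed)) set.seed(seed)
  min_sep2 <- 0.9^2
  for (restart in 1:50) {
    pos <- matrix(NA_real_, N, 3)
    pos[1, ] <- 0
    ok <- TRUE
    for (i in 2:N) {
      placed <- FALSE
      for (try in 1:200) {
        u <- rnorm(3)
        cand <- pos[i - 1, ] + u / sqrt(sum(u^2))
        ok_sep <- i == 2 ||
          all(rowSums((pos[seq_len(i - 2), , drop = FALSE] -
                         matrix(cand, i - 2, 3, byrow = TRUE))^2) >= min_sep2)
        if (ok_sep) { pos[i, ] <- cand; placed <- TRUE; break }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(conformation(pos, z))
  }
  stop("random-walk placement failed after 50 restarts")
}

ff_list <- function(ff) {
  ff[c("eps_lj", "sigma", "r_cut", "k_fene", "R0", "lambda_B")]
}

#' Potential energy of a conformation
#'
#' @param conf a `conformation`.
#' @param ff a `force_field`.
#' @return Named vector `(bond, lj, coulomb, total)` in kT. A bond at or
#'   beyond `R0` raises an error (diverged state).
#' @export
potential_energy <- function(conf, ff) {
  stopifnot(inherits(conf, "conformation"), inherits(ff, "force_field"))
  pn_energy_cpp(conf$positions, conf$charges, ff_list(ff))
}

#' Forces on the beads
#'
#' Analytic forces consistent with [potential_energy()] (checked against
#' finite differences in the test suite).
#'
#' @inheritParams potential_energy
#' @return N x 3 matrix of forces in kT/sigma.
#' @export
bead_forces <- function(conf, ff) {
  stopifnot(inherits(conf, "conformation"), inherits(ff, "force_field"))
  pn_forces_cpp(conf$positions, conf$charges, ff_list(ff))
}

#' Advance a conformation by Langevin dynamics
#'
#' BAOAB discretization of the Langevin equation at friction `gamma` and
#' temperature `kT`; with `gamma = 0` it reduces to velocity Verlet (no
#' noise, energy conserved to O(dt^2)). Velocities are carried in the
#' `"velocities"` attribute of the conformation; if absent they are drawn
#' from the Maxwell-Boltzmann distribution. Randomness flows from R's RNG:
#' call `set.seed()` (or pass `seed`) for reproducibility.
#'
#' @param conf a `conformation`.
#' @param ff a `force_field`.
#' @param dt time step in tau (must be <= 0.01).
#' @param nsteps number of steps.
#' @param seed optional RNG seed.
#' @param force_cap per-bead force magnitude cap in kT/sigma (Inf = none);
#'   used to tame steep initial overlaps.
#' @return The advanced `conformation` (time increased by `nsteps * dt`),
#'   with updated `"velocities"` attribute.
#' @export
step_langevin <- function(conf, ff, dt = 0.005, nsteps = 1, seed = NULL,
                          force_cap = Inf) {
  stopifnot(inherits(conf, "conformation"), inherits(ff, "force_field"))
  if (dt > 0.01) stop("dt must be <= 0.01 tau")
  if (!is.null(seed)) set.seed(seed)
  vel <- attr(conf, "velocities")
  if (is.null(vel))
    vel <- matrix(rnorm(3 * nrow(conf$positions), sd = sqrt(ff$kT)),
                  ncol = 3)
  out <- pn_run_cpp(conf$positions, vel, conf$charges, ff_list(ff),
                    dt, ff$gamma, ff$kT, as.integer(nsteps), 0L, force_cap)
  res <- conformation(out$pos, conf$charges, conf$time + nsteps * dt)
  attr(res, "velocities") <- out$vel
  res
}

#' Trajectory container
#'
#' @param frames list of `conformation` objects with strictly increasing
#'   times and constant bead count.
#' @param metadata named list (force field, sequence, seed, dt, ...).
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(frames, metadata = list()) {
  stopifnot(is.list(frames), length(frames) >= 1,
            all(vapply(frames, inherits, logical(1), "conformation")))
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  ns <- vapply(frames, function(f) nrow(f$positions), integer(1))
  if (length(unique(ns)) != 1L) stop("all frames must have the same N")
  structure(list(frames = frames, times = times, metadata = metadata),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames, N=%d, t=[%.6g, %.6g] tau\n",
              length(x$frames), nrow(x$frames[[1]]$positions),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Run an equilibration + production Langevin protocol
#'
#' Builds an initial conformation, gently relaxes it (short capped-force
#' warm-up at a reduced time step), equilibrates for `t_equil`, then
#' samples the production run every `sample_every` tau. The warm-up and
#' equilibration are discarded; exactly `floor(t_prod / sample_every)`
#' production frames are returned together with per-sample diagnostics
#' (energy components, kinetic energy, radius of gyration).
#'
#' @param seq a `charge_sequence`.
#' @param ff a `force_field` (default: model-matched [force_field()]).
#' @param t_equil equilibration time in tau.
#' @param t_prod production time in tau.
#' @param sample_every sampling interval in tau.
#' @param dt integration time step in tau.
#' @param seed RNG seed (all randomness flows from it).
#' @param init initial conformation mode, see
#'   [build_initial_conformation()].
#' @param t_warmup capped-force warm-up time in tau (time step dt/5,
#'   force cap 100 kT/sigma).
#' @return A `trajectory`; `metadata$diagnostics` holds a data.frame with
#'   columns time, ke, e_bond, e_lj, e_coulomb, rg.
#' @export
run_protocol <- function(seq, ff = NULL, t_equil = 200, t_prod = 400,
                         sample_every = 10, dt = 0.005, seed = NULL,
                         init = "random-walk", t_warmup = 20) {
  stopifnot(inherits(seq, "charge_sequence"))
  if (is.null(ff)) ff <- force_field(seq$model)
  stopifnot(t_equil > 0, t_prod > 0, sample_every > 0)
  if (dt > 0.01) stop("dt must be <= 0.01 tau")
  if (!is.null(seed)) set.seed(seed)
  conf <- build_initial_conformation(seq, init)
  vel <- matrix(rnorm(3 * seq$N, sd = sqrt(ff$kT)), ncol = 3)
  ffl <- ff_list(ff)

  if (t_warmup > 0) {
    wsteps <- max(1L, as.integer(round(t_warmup / (dt / 5))))
    out <- pn_run_cpp(conf$positions, vel, conf$charges, ffl, dt / 5,
                      ff$gamma, ff$kT, wsteps, 0L, 100)
  } else {
    out <- list(pos = conf$positions, vel = vel)
  }
  esteps <- as.integer(round(t_equil / dt))
  out <- pn_run_cpp(out$pos, out$vel, conf$charges, ffl, dt,
                    ff$gamma, ff$kT, esteps, 0L, Inf)
  every <- as.integer(round(sample_every / dt))
  psteps <- every * as.integer(floor(t_prod / sample_every))
  out <- pn_run_cpp(out$pos, out$vel, conf$charges, ffl, dt,
                    ff$gamma, ff$kT, psteps, every, Inf)

  frames <- lapply(seq_along(out$samples), function(i)
    conformation(out$samples[[i]], conf$charges,
                 time = out$sample_steps[i] * dt))
  rg <- vapply(out$samples, function(p) {
    cm <- colMeans(p); sqrt(mean(rowSums((p - matrix(cm, nrow(p), 3,
                                                     byrow = TRUE))^2)))
  }, numeric(1))
  diagnostics <- data.frame(time = out$sample_steps * dt, ke = out$ke,
                            e_bond = out$e_bond, e_lj = out$e_lj,
                            e_coulomb = out$e_coulomb, rg = rg)
  trajectory(frames,
             metadata = list(force_field = ff, sequence = seq, seed = seed,
                             dt = dt, sample_every = sample_every,
                             t_equil = t_equil, t_prod = t_prod,
                             diagnostics = diagnostics))
}
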