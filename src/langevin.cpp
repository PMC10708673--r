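// Coarse-grained bead-spring chain in implicit poor solvent:
// FENE bonds + full (attractive) Lennard-Jones pairs + bare Coulomb among
// charged beads, integrated with the BAOAB Langevin scheme in reduced
// units (sigma = kT = m = 1, tau = 1). Direct O(N^2) pair summation over
// raw column pointers (N ~ 200: no neighbour list needed).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct FF {
  double eps_lj, sigma, r_cut, k_fene, R0, lambda_B;
};

static FF read_ff(const List& ff) {
  FF f;
  f.eps_lj   = as<double>(ff["eps_lj"]);
  f.sigma    = as<double>(ff["sigma"]);
  f.r_cut    = as<double>(ff["r_cut"]);
  f.k_fene   = as<double>(ff["k_fene"]);
  f.R0       = as<double>(ff["R0"]);
  f.lambda_B = as<double>(ff["lambda_B"]);
  return f;
}

// energy components over column-major coordinates; bond_fail set to the
// 1-based bead index of the first over-stretched bond (r >= R0), or 0
static void energy_components(int n, const double* x, const double* y,
                              const double* z, const double* q, const FF& f,
                              double& e_bond, double& e_lj, double& e_coul,
                              int& bond_fail) {
  e_bond = e_lj = e_coul = 0.0;
  bond_fail = 0;
  const double rc2 = f.r_cut * f.r_cut, R02 = f.R0 * f.R0;
  const double s2u = f.sigma * f.sigma;
  for (int i = 0; i < n - 1; ++i) {
    const double dx = x[i + 1] - x[i], dy = y[i + 1] - y[i],
                 dz = z[i + 1] - z[i];
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= R02) { if (!bond_fail) bond_fail = i + 1; continue; }
    e_bond += -0.5 * f.k_fene * R02 * std::log(1.0 - r2 / R02);
  }
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i], zi = z[i], qi = q[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[j] - xi, dy = y[j] - yi, dz = z[j] - zi;
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < rc2) {
        const double s2 = s2u / r2;
        const double s6 = s2 * s2 * s2;
        e_lj += 4.0 * f.eps_lj * (s6 * s6 - s6);
      }
      if (qi != 0.0 && q[j] != 0.0)
        e_coul += f.lambda_B * qi * q[j] / std::sqrt(r2);
    }
  }
}

static void compute_forces(int n, const double* x, const double* y,
                           const double* z, const double* q, const FF& f,
                           double* fx, double* fy, double* fz,
                           double force_cap, int& bond_fail) {
  std::fill(fx, fx + n, 0.0);
  std::fill(fy, fy + n, 0.0);
  std::fill(fz, fz + n, 0.0);
  bond_fail = 0;
  const double rc2 = f.r_cut * f.r_cut, R02 = f.R0 * f.R0;
  const double s2u = f.sigma * f.sigma;
  for (int i = 0; i < n - 1; ++i) {
    const double dx = x[i + 1] - x[i], dy = y[i + 1] - y[i],
                 dz = z[i + 1] - z[i];
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= R02) { if (!bond_fail) bond_fail = i + 1; continue; }
    // FENE pull: F_{i+1} = -k d / (1 - r^2/R0^2)
    const double fmag = -f.k_fene / (1.0 - r2 / R02);
    fx[i] -= fmag * dx; fy[i] -= fmag * dy; fz[i] -= fmag * dz;
    fx[i + 1] += fmag * dx; fy[i + 1] += fmag * dy; fz[i + 1] += fmag * dz;
  }
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i], zi = z[i], qi = q[i];
    double ax = 0.0, ay = 0.0, az = 0.0;  // accumulated force on i
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[j] - xi, dy = y[j] - yi, dz = z[j] - zi;
      const double r2 = dx * dx + dy * dy + dz * dz;
      double fr = 0.0;  // (dU/dr)/r ; F_j = -fr * d, F_i = +fr * d
      if (r2 < rc2) {
        const double s2 = s2u / r2;
        const double s6 = s2 * s2 * s2;
        fr = -4.0 * f.eps_lj * (12.0 * s6 * s6 - 6.0 * s6) / r2;
      }
      if (qi != 0.0 && q[j] != 0.0) {
        const double r = std::sqrt(r2);
        fr += -f.lambda_B * qi * q[j] / (r2 * r);
      }
      if (fr != 0.0) {
        fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
        ax += fr * dx; ay += fr * dy; az += fr * dz;
      }
    }
    fx[i] += ax; fy[i] += ay; fz[i] += az;
  }
  if (R_finite(force_cap)) {
    for (int i = 0; i < n; ++i) {
      const double fm = std::sqrt(fx[i] * fx[i] + fy[i] * fy[i] +
                                  fz[i] * fz[i]);
      if (fm > force_cap) {
        const double s = force_cap / fm;
        fx[i] *= s; fy[i] *= s; fz[i] *= s;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector pn_energy_cpp(NumericMatrix pos, NumericVector charges, List ff) {
  FF f = read_ff(ff);
  const int n = pos.nrow();
  double eb, el, ec; int bf;
  energy_components(n, &pos(0, 0), &pos(0, 1), &pos(0, 2),
                    charges.begin(), f, eb, el, ec, bf);
  if (bf) stop("diverged state: bond %d-%d at or beyond R0", bf, bf + 1);
  return NumericVector::create(_["bond"] = eb, _["lj"] = el,
                               _["coulomb"] = ec, _["total"] = eb + el + ec);
}

// [[Rcpp::export]]
NumericMatrix pn_forces_cpp(NumericMatrix pos, NumericVector charges, List ff) {
  FF f = read_ff(ff);
  const int n = pos.nrow();
  NumericMatrix force(n, 3);
  int bf;
  compute_forces(n, &pos(0, 0), &pos(0, 1), &pos(0, 2), charges.begin(), f,
                 &force(0, 0), &force(0, 1), &force(0, 2), R_PosInf, bf);
  if (bf) stop("diverged state: bond %d-%d at or beyond R0", bf, bf + 1);
  return force;
}

// BAOAB integrator. Samples positions every `sample_every` steps (0 = no
// sampling). Uses R's RNG, so trajectories are reproducible via set.seed().
// [[Rcpp::export]]
List pn_run_cpp(NumericMatrix pos, NumericMatrix vel, NumericVector charges,
                List ff, double dt, double gamma, double kT, int nsteps,
                int sample_every, double force_cap) {
  FF f = read_ff(ff);
  const int n = pos.nrow();
  NumericMatrix x(clone(pos)), v(clone(vel));
  double* px[3] = {&x(0, 0), &x(0, 1), &x(0, 2)};
  double* pv[3] = {&v(0, 0), &v(0, 1), &v(0, 2)};
  const double* q = charges.begin();
  std::vector<double> fbuf(3 * n);
  double* pf[3] = {fbuf.data(), fbuf.data() + n, fbuf.data() + 2 * n};
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(kT * (1.0 - c1 * c1));
  const double hdt = 0.5 * dt;
  int bf;
  compute_forces(n, px[0], px[1], px[2], q, f, pf[0], pf[1], pf[2],
                 force_cap, bf);
  if (bf) stop("diverged state at step 0: bond %d-%d at or beyond R0", bf, bf + 1);

  const int nsamp = sample_every > 0 ? nsteps / sample_every : 0;
  List samples(nsamp);
  IntegerVector sample_steps(nsamp);
  NumericVector ke_samp(nsamp), eb_samp(nsamp), elj_samp(nsamp), ec_samp(nsamp);
  int isamp = 0;

  for (int step = 1; step <= nsteps; ++step) {
    for (int d = 0; d < 3; ++d)
      for (int i = 0; i < n; ++i) {
        pv[d][i] += hdt * pf[d][i];
        px[d][i] += hdt * pv[d][i];
      }
    if (gamma > 0.0) {
      NumericVector xi = rnorm(3 * n);
      const double* pxi = xi.begin();
      for (int d = 0; d < 3; ++d)
        for (int i = 0; i < n; ++i)
          pv[d][i] = c1 * pv[d][i] + c2 * pxi[d * n + i];
    }
    for (int d = 0; d < 3; ++d)
      for (int i = 0; i < n; ++i)
        px[d][i] += hdt * pv[d][i];
    compute_forces(n, px[0], px[1], px[2], q, f, pf[0], pf[1], pf[2],
                   force_cap, bf);
    if (bf)
      stop("numerical divergence at step %d: bond %d-%d at or beyond R0",
           step, bf, bf + 1);
    for (int d = 0; d < 3; ++d)
      for (int i = 0; i < n; ++i)
        pv[d][i] += hdt * pf[d][i];
    for (int d = 0; d < 3; ++d)
      for (int i = 0; i < n; ++i)
        if (!R_finite(px[d][i]))
          stop("numerical divergence at step %d: non-finite coordinate", step);

    if (sample_every > 0 && step % sample_every == 0) {
      samples[isamp] = clone(x);
      sample_steps[isamp] = step;
      double ke = 0.0;
      for (int d = 0; d < 3; ++d)
        for (int i = 0; i < n; ++i) ke += 0.5 * pv[d][i] * pv[d][i];
      ke_samp[isamp] = ke;
      double eb, el, ec; int bf2;
      energy_components(n, px[0], px[1], px[2], q, f, eb, el, ec, bf2);
      eb_samp[isamp] = eb; elj_samp[isamp] = el; ec_samp[isamp] = ec;
      ++isamp;
    }
  }
  return List::create(_["pos"] = x, _["vel"] = v, _["samples"] = samples,
                      _["sample_steps"] = sample_steps, _["ke"] = ke_samp,
                      _["e_bond"] = eb_samp, _["e_lj"] = elj_samp,
                      _["e_coulomb"] = ec_samp);
}
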