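---
title: "Sequence-dependent pearl necklaces: model, landscape, and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-dependent pearl necklaces: model, landscape, and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pearlnecklace)
```

# The physical problem

A flexible polymer that carries charges in a poor solvent is pulled in two
directions: the hydrophobic backbone wants to collapse into a dense
globule, while the electrostatic self-energy of the accumulated charge
wants to stretch the chain out. The compromise, known from the Rayleigh
instability of charged droplets, is the *pearl necklace*: a small number
of dense droplets ("pearls") joined by stretched strings. This package
studies how the *quenched charge sequence* along the chain — the frozen
pattern of charged and neutral (or positive and negative) sites —
determines which necklace shapes are visited.

Two chain types are supported:

* **PE** (polyelectrolyte): charge sites carry 0 or +1. Net charge
  $Q = \sum \text{sites}$.
* **PA** (polyampholyte): charge sites carry $\pm 1$, the model for
  random heteropolymers and IDP-like chains. Net charge
  $Q = |\#\text{majority} - \#\text{minority}|$.

The canonical chain has $N = 202$ monomers with a charge site on every
third monomer ($p = 3$), i.e. $\lceil N/p \rceil = 68$ sites. This site
convention (sites at monomers $1, 4, 7, \dots$) is the only one
consistent with a 68-site composition of 44 majority plus 24 minority
charges at $Q = 20$.

# Markovian charge sequences

Sequences are generated by a stationary symmetric two-state Markov chain
over the charge sites: the first symbol is drawn uniformly, and each
subsequent site repeats its predecessor with *stay probability* $s$. The
expected length of a maximal constant run ("block") is $L = 1/(1-s)$:
$s = 1/2$ gives uncorrelated sites ($L = 2$), $s = 3/4$ the "blocky"
statistics ($L = 4$). Negative correlations ($s < 1/2$) are possible but
not a study condition here.

`average_block_length()` estimates $L$ as the *mean over sequences of the
per-sequence ratio* (sites / number of runs). For a finite chain of $k$
sites this estimator has expectation $(1 - s^k)/(1-s)$ — equal to
$1/(1-s)$ up to $s^{68} \approx 10^{-9}$ — whereas pooling all runs of the
ensemble (total sites / total runs) converges to $k/(1 + (k-1)(1-s))$,
biased low by about 4% at $L = 4$ because runs truncated at the chain
ends are counted whole. The per-sequence form is therefore the one the
package reports; its finite-$k$ expectation is verified in the test suite
against exhaustive enumeration of all $2^{10}$ ten-site sequences.

Sub-ensembles at fixed net charge are selected by exact equality
(`select_subensemble()`), matching how conformational statistics are
conditioned on $Q$; conditioning changes the effective correlations of
the surviving sequences, which is intended.

# The n-pearl energy landscape

Take a necklace with $n$ pearls holding total pearl mass $M_p$ and total
pearl charge $Q_p$, and write the per-pearl shares as
$m_i/M_p = 1/n + x_i$ and $q_i/Q_p = 1/n + y_i$. Mass and charge
conservation give $\sum_i x_i = \sum_i y_i = 0$. Treating each pearl as a
dense droplet with surface energy $\propto m^{2/3}$ and electrostatic
self-energy $\propto q^2/m^{1/3}$, the energy relative to the
single-globule reference state (whose surface energy $E_s$ sets the
scale) is

$$
E(\{x\},\{y\}) \;=\; \sum_{i=1}^n \left(\tfrac1n + x_i\right)^{2/3}
 + \chi \sum_{i=1}^n \frac{\left(\tfrac1n + y_i\right)^2}
                          {\left(\tfrac1n + x_i\right)^{1/3}}
 \;-\; 1 \;-\; \chi ,
$$

with $\chi$ the ratio of electrostatic to surface energy of the reference
globule. String energies, pearl-pearl and pearl-string interactions, and
the ordering of pearls along the chain are all neglected — the minimal
model whose extrema organize the simulation data. A pearl with zero mass
and zero charge contributes nothing (this makes the simplex vertices
evaluable); zero mass with charge is a domain error, since a charged
point has infinite self-energy.

## Charge equilibration

Because the $y$-dependence is a positive-definite quadratic under a
linear constraint, minimizing over the charge split at fixed masses is
exact and closed-form: $1/n + y_i^\* = m_i^{1/3}/\sum_j m_j^{1/3}$, and

$$
F(\{m\}) = \sum_i m_i^{2/3} + \frac{\chi}{\sum_i m_i^{1/3}} - 1 - \chi .
$$

Smaller pearls therefore receive *more* charge than their mass share and
large pearls less — the origin of the undercharged-large-pearl signature
seen in the 2-pearl densities of states. All stationary points of the
full $(x, y)$ landscape correspond to stationary points of $F$, so
extrema are located in $F$ and classified with the *analytic* Hessian of
the full energy (diagonal per pearl in $(x_i, y_i)$) projected onto the
$\sum x = \sum y = 0$ subspace via an orthonormal Helmert basis.
Eigenvalues beyond $\pm 10^{-9}$ count as signed; the quenched-$y$ energy
`pearl_energy()` remains available for scoring simulation frames.

## Extrema, stability, and the fold

Stationary points come in two-group families $E(n_l, n_s)$: $n_l$ equal
large pearls of mass $a$ and $n_s = n - n_l$ equal small pearls of mass
$b$. Along the constrained coordinate $b \in (0, 1/n]$ the stationarity
condition is a one-dimensional root problem,

$$
g(b) = n_s\left[\tfrac23\!\left(b^{-1/3}-a^{-1/3}\right)
 - \frac{\chi}{3S^2}\left(b^{-2/3}-a^{-2/3}\right)\right] = 0,
\qquad S = n_l a^{1/3} + n_s b^{1/3},
$$

solved by a sign-change scan (log-spaced near $b = 0$, because
$b^\* \sim \chi^3/8S^6$ at small $\chi$) refined with `uniroot` to
$10^{-14}$. The key structural facts, all verified against a brute-force
simplex-grid oracle in the tests:

* for $\chi < n$ the evenly split symmetric state is not a minimum but
  the *highest* saddle; the saddle energies order as
  $E(n,0) \ge E(n-1,1) \ge \dots \ge E(1,n-1)$;
* the absolute minimum has **one** large pearl and $n-1$ equal small
  ones;
* the symmetric state's smallest projected-Hessian eigenvalue is
  $\tfrac{2}{9}n^{1/3}(\chi - n)$: it changes sign exactly at
  $\chi = n$ (`stability_transition()` finds this numerically);
* as $\chi \to 0$ every extremum collapses onto its simplex vertex
  $V(n_l, n_s)$;
* asymmetric branches cease to exist beyond a fold $\chi_c$
  (`chi_critical()` brackets it by bisection on the existence of the
  positive bump of $g$, bracket width $10^{-6}$).

One point deserves emphasis: for $n = 2$ the landscape has the exchange
symmetry $b \leftrightarrow 1-b$, and the asymmetric branch terminates in
a *supercritical pitchfork* at $\chi = 2$ — the quartic coefficient of
$F$ around the symmetric point is $\tfrac{2^{-2/3}}{243}(13\chi - 14) > 0$
there — so $\chi_c(2) = 2$ exactly rather than "somewhat larger" than
$n$. The strict inequality $\chi_c > n$ is a genuine fold property of the
non-symmetric branches for $n \ge 3$ (e.g. $\chi_c(3, 1) \approx 3.0225$).
The acceptance test asserts the strict inequality for both $n = 2$ and
$n = 3$; the $n = 2$ case fails by design of the model and is documented
rather than relaxed.

## The mass simplex

Projecting out the charges and dropping the smallest pearl (fixed by
conservation) leaves the sorted excess masses
$x_1 \ge \dots \ge x_{n-1}$, which fill an $(n-1)$-simplex bounded by the
$n-1$ ranking inequalities plus positivity of the smallest mass.
Vertices $V(n_l, n_s)$ are the states with $n_l$ equal large and $n_s$
vanishing pearls; $V(n, 0)$ is the origin. `in_simplex()` reports which
inequality a point violates; boundary membership counts as inside.
States with more than four pearls are kept in the time series but are not
given a simplex embedding beyond their own coordinates.

# The chain simulator

The MD component is a standard Kremer–Grest-style bead-spring chain in
implicit solvent, in reduced units $\sigma = k_BT = m = 1$ (time unit
$\tau = \sigma\sqrt{m/k_BT}$):

| term | form | default |
|---|---|---|
| bond | FENE, $-\tfrac12 k R_0^2 \ln(1 - r^2/R_0^2)$ | $k = 30\,k_BT/\sigma^2$, $R_0 = 1.5\,\sigma$ |
| pair | full (attractive) unshifted LJ, cutoff $r_c$ | $\varepsilon_{LJ} = 1.5\,k_BT$ (PE, rather poor) / $1.0$ (PA, marginally poor), $r_c = 2.5\,\sigma$ |
| Coulomb | bare $\lambda_B z_i z_j / r$, all pairs, unscreened | $\lambda_B = 3\,\sigma$ |
| thermostat | BAOAB Langevin | $\gamma = 1/\tau$, $dt = 0.005\,\tau$ |

No explicit counterions, no added salt: the single-chain
infinite-dilution necklace regime. These are community-standard choices
for pearl-necklace simulations; the analysis layer is insensitive to
their exact values, and any quantitative lifetime comparison should be
read as indicative only. Pair sums are direct $O(N^2)$ loops in C++
($N \approx 200$ needs no neighbour list). With $\gamma = 0$ the
integrator reduces to velocity Verlet and conserves energy to
$O(dt^2)$ (tested); forces are validated against finite differences of
the energy to $10^{-5}$ relative error. All randomness flows through R's
seeded RNG, so trajectories are bit-reproducible.

`run_protocol()` relaxes the initial random walk with a short
force-capped warm-up (20 τ at $dt/5$, cap $100\,k_BT/\sigma$) before
equilibration, because a freshly grown random walk contains steep LJ
overlaps that would otherwise require an absurdly small global time
step.

# Pearl detection and observables

The paper-level observables require labelling each monomer as pearl or
string. The detection operator is a density-based cluster rule:

1. a monomer is **dense** iff it has at least `n_dense = 3` *non-bonded*
   neighbours (chain distance ≥ 2) within `r_c = 1.5 σ` — bonded
   neighbours never count, which is what separates a taut string (whose
   only contacts are its bonded neighbours) from a droplet interior;
2. pearls are connected components of dense monomers (edges: any pair
   within `r_c`), kept if they hold at least `min_size = 4` monomers;
3. remaining non-dense monomers with a *non-bonded* contact to exactly
   one pearl join it (surface capture); everything else is string/tail.

The non-bonded requirement in step 3 mirrors step 1: a bonded contact
carries no information about density, and counting it would
unconditionally glue the first string monomer (bonded at ~1 σ to the
pearl surface) onto every pearl, making exact fixture recovery
impossible. The defaults are stable under ±20% perturbation of `r_c` on
the planted fixtures (tested for `r_c` from 1.3 to 1.7 σ).

Per decomposition the package reports pearl masses and charges (PA
charges projected onto the chain's majority sign so that
$Q_p + Q_s = Q$), the string allocation $m_s = N_s/N$, $q_s = Q_s/Q$,
the asymmetry vectors and simplex coordinates, pearl-count time series
$n(t)$, dwell times (boundary-censored runs flagged and excluded from
means by default), and switching events with nearest-vertex annotation.

Densities of visited states are 50×50 histograms over the data bounding
box, normalized by the maximum bin (peak = 1). For 2-pearl $(x, y)$
histograms both pearls of each state are binned and the mirror bin index
is derived arithmetically from the first pearl's bin, so the point
symmetry about the origin — an identity forced by the conservation
constraints — is exact at bin level, not merely approximate. States
whose pearls carry no charge have undefined $y$ and are excluded (and
counted).

# Synthetic fixtures

Every analysis operator is testable without MD through planted
necklaces. A `necklace_plan()` lists pearl and string segments in chain
order; `make_necklace()` realizes it geometrically and returns the
ground-truth decomposition.

Pearl blobs are built as serpentine (boustrophedon) walks on a cubic
lattice with spacing 0.9 σ (density ≈ 1.37 monomers/σ³), in near-cubic
boxes whose rows are always complete; strings are straight lines with
1 σ spacing along a steepened diagonal axis, with 1.1 σ junction bonds.
This construction was chosen over random close packing of spheres
because it makes recovery *provably exact*: at 0.9 σ spacing every blob
monomer is dense (or surface-captured) for any `r_c` in [1.3, 1.7] σ,
and the full-row/steep-axis geometry keeps every non-bonded blob monomer
at least 1.73 σ away from the first string bead, so no string monomer is
ever absorbed. The price is that pearl sizes must be composite (≥ 6) so
a full-row box exists, and the blob density is melt-like-dense rather
than tunable downward; both are acceptable for ground-truth fixtures.
Optional Gaussian jitter (≤ 0.1 σ) emulates thermal roughness; exact
recovery is only guaranteed for small jitter.

What fixtures do *not* emulate: thermal surface fluctuations, fluctuating
string conformations, transient merging pearls, and density gradients at
the pearl surface. Passing the planted-recovery tests therefore shows
the detection operator is correct on unambiguous geometry, not that its
thresholds are optimal for every thermalized conformation.

# Study conditions and problem sizes

The package-level checks run at deliberately scaled-down sizes chosen
once as the study conditions:

* sequence statistics: 10⁴ sequences per ensemble;
* landscape oracle: simplex grids at step 10⁻³;
* MD phenomenology: the neutral-collapse run (300 τ equilibration) plus,
  for each net charge $Q \in \{16, 22, 28, 34\}$, five blocky quenched
  sequences at 200 τ equilibration + 400 τ production, sampled every
  2 τ. Five sequences per charge are used because the pearl-number trend
  is an ensemble statement over quenched disorder: individual blocky
  sequences differ strongly, and one or two sequences per charge do not
  represent the ensemble.

At these scales the qualitative necklace phenomenology is reproduced:
neutral collapse to one pearl, pearl numbers non-decreasing in net
charge, larger pearls undercharged relative to their mass share (the
population below the $x = y$ line), strings overcharged
($\bar q_s > \bar m_s$ for blocky chains), and transient extra-pearl
states living shorter than the 2-pearl states they decorate. Full
densities of states and absolute lifetimes (~10 τ small pearls, ~50 τ
two-pearl states, ~1000 τ PA shape switches) require far longer runs and
depend on force-field constants that the minimal model does not pin
down; they are out of scope at desk scale.

# Known limitations

* The landscape model ignores string energetics and pearl-pearl
  interactions; it organizes, but does not quantitatively predict, the
  simulation densities.
* χ is treated as a free control parameter; no attempt is made to map a
  simulated chain onto a χ value (the mean-field relation χ = n/2 is
  deliberately not hard-coded).
* Stability classification of extrema with vanishing pearl masses
  (χ below ~10⁻⁶) is ill-conditioned — the Hessian spans ~30 orders of
  magnitude — although the *location* of those extrema is accurate.
* PA chains use the same detection thresholds as PE; in a marginally
  poor solvent pearl boundaries are physically fuzzier and the
  decomposition inherits that ambiguity.
* Annealed (pH-regulated) charges, counterions, added salt, screening,
  multi-chain systems and knots are out of scope.
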