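# pearlnecklace

Sequence-dependent pearl-necklace physics of charged polymers in poor
solvent, for polymer physicists and IDP-minded biophysicists who want to
go from a *quenched charge sequence* to the conformational statistics it
produces.

A hydrophobic polyelectrolyte (PE, charges of one sign) or polyampholyte
(PA, both signs) in poor solvent collapses into dense droplets — pearls —
joined by stretched strings, the finite-chain descendant of the Rayleigh
instability of a charged drop. This package provides the full toolchain:

1. **`sequence_gen`** — quenched charge sequences from a stationary
   symmetric Markov process over the charge sites (every *p*-th monomer),
   with prescribed blockiness (stay probability *s*, mean block length
   `1/(1-s)`), plus exact sub-ensemble selection at fixed net charge *Q*.
2. **`chain_simulator`** — Langevin dynamics (BAOAB) of a bead-spring
   chain: FENE bonds, full attractive Lennard-Jones (the poor solvent),
   bare unscreened Coulomb with Bjerrum length λ_B, reduced units
   σ = k_BT = m = 1, Rcpp kernel, bit-reproducible from a seed.
3. **`pearl_analysis`** — density-based pearl/string decomposition,
   mass/charge asymmetry, densities of visited states, pearl-count time
   series n(t), dwell times, switching paths.
4. **`energy_landscape`** — the analytical n-pearl model. With pearl mass
   shares `m_i/Mp = 1/n + x_i` and charge shares `q_i/Qp = 1/n + y_i`
   (so Σx = Σy = 0), the energy in units of the reference-globule surface
   energy is

   ```
   E = Σ_i (1/n + x_i)^(2/3) + χ Σ_i (1/n + y_i)^2 / (1/n + x_i)^(1/3) − 1 − χ
   ```

   where χ is the electrostatic-to-surface energy ratio of the single
   globule. The package locates and classifies the extrema E(n_l, n_s)
   (n_l equal large pearls, n_s equal small ones), finds the symmetric
   state's saddle-to-minimum transition at χ = n, the fold χ_c beyond
   which asymmetric states disappear, and the (n−1)-simplex geometry of
   the sorted excess masses with vertices V(n_l, n_s).
5. **`fixtures`** — planted necklace conformations and synthetic n(t)
   series with exact ground truth, so every analysis stage is testable
   without MD.
6. **`cli_io`** — extended-XYZ trajectory I/O, flat TOML-style configs,
   provenance manifests, an end-to-end `pipeline_run()`, and a thin CLI
   (`inst/cli/pnk`) with the matching subcommands.

## Worked example

```r
library(pearlnecklace)

## blocky PE ensemble, N = 202, charge site every 3rd monomer (68 sites)
seqs <- generate_sequences(2000, 202, 3, "pe",
                           markov_params(block_length = 4), seed = 1)
average_block_length(seqs)
#> [1] 4.004383
sel <- select_subensemble(seqs, 22)   # exact net charge Q = 22
length(sel)
#> [1] 26

## landscape at chi = 1 (< n): one large pearl is the minimum,
## the even split is the highest saddle
find_extremum(3, 1, chi = 1)
#> <extremum E(1,2)> chi=1 masses (0.959644 x1, 0.0201778 x2) E=-0.225623 minimum
find_extremum(3, 3, chi = 1)
#> <extremum E(3,0)> chi=1 masses (0.333333 x3, 0.333333 x0) E=-0.0770006 saddle(2)
stability_transition(3)   # symmetric state destabilizes exactly at chi = n
#> [1] 3
chi_critical(3, 1)        # asymmetric branch survives "somewhat" beyond n
#> [1] 3.02253

## planted necklace: two pearls (80 and 40 monomers) on a 202-monomer chain
fx <- make_necklace(necklace_plan(list(
  segment_string(30, q = 5), segment_pearl(80, q = 20),
  segment_string(26, q = 4), segment_pearl(40, q = 10),
  segment_string(26, q = 3))))
identify_pearls(fx$conformation)
#> <pearl_decomposition> n=2  m=(80,40)  q=(20,10)  ms=0.406 qs=0.286
asymmetry(identify_pearls(fx$conformation))$x
#> [1]  0.1666667 -0.1666667
```

The extremum printout reads: at χ = 1 a 3-pearl chain minimizes its
energy by putting 96% of the pearl mass into one pearl
(E = −0.226 E_s below the single-globule reference), while the evenly
split state sits higher (E = −0.077 E_s) and is a saddle with two
downhill directions. The decomposition printout gives the pearl masses
and charges, the string mass fraction `ms = Ns/N` and string charge
fraction `qs = Qs/Q`; here strings hold 41% of the mass but only 29% of
the charge because the planted charges were concentrated in the pearls.

An MD run end-to-end:

```r
tr  <- run_protocol(sel[[1]], force_field("pe"),
                    t_equil = 200, t_prod = 400, sample_every = 2, seed = 7)
ser <- count_timeseries(tr)          # n(t), one decomposition per frame
dos <- density_of_states(ser, kind = "msqs")
dwell_times(ser, 2)                  # dwell durations of the 2-pearl state
```

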