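Package: pearlnecklace
Title: Pearl-Necklace Conformations of Charged Polymers in Poor Solvent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for studying sequence-dependent pearl-necklace
    conformations of polyelectrolytes (PE) and polyampholytes (PA) in poor
    solvent. Generates quenched Markovian charge sequences with prescribed
    blockiness, runs coarse-grained Langevin dynamics of a bead-spring chain
    with unscreened Coulomb interactions, decomposes conformations into
    pearls and strings, and analyses mass/charge asymmetry against an
    analytical n-pearl Rayleigh-type energy landscape on the (n-1)-simplex:
    extrema E(nl,ns), their stability, the saddle-to-minimum transition of
    the symmetric state at chi = n, and the fold point chi_c beyond which
    asymmetric states disappear.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
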