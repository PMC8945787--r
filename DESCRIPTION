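Package: redoxmc
Title: Multi-Conformer Continuum Electrostatics for Metal-Cluster Redox
    Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes in-protein midpoint redox potentials (Em) of
    multi-site metal clusters such as the 4Fe-4S centres of photosystem I
    by multi-conformer continuum electrostatics.  A finite-difference
    linearized Poisson-Boltzmann solver supplies desolvation
    (reaction-field), backbone and pairwise conformer-conformer energies;
    microstate energies are assembled from reference solution chemistry
    (pKsol, Em,sol) and sampled by exact enumeration or Metropolis Monte
    Carlo over Eh/pH grids; cluster midpoints are extracted with the
    second-oxidation convention.  Mean-field energy analysis decomposes an
    in-protein Em into reference, desolvation, backbone and
    occupancy-weighted residue terms, and geometry utilities summarize
    Fe-S/Fe-Fe bond distances.  Synthetic structure and titration
    generators plus bundled reference tables make every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
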