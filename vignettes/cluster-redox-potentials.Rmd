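---
title: "Computing in-protein redox potentials of iron-sulfur clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing in-protein redox potentials of iron-sulfur clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxmc)
```

## The model

`redoxmc` implements multi-conformer continuum electrostatics (MCCE) for
multi-site metal clusters such as the 4Fe-4S centres of photosystem I
(F~X~, F~A~, F~B~).  The protein is decomposed into *fragments*: each Fe
ion, each bridging sulfide, each cysteine thiolate and each titratable
side chain is a separate group with an integer formal charge (Fe +2/+3,
S^2-^ = -2, thiolate -1), while backbone atoms have zero conformational
degrees of freedom and carry fixed partial charges.  Every fragment is
represented by discrete *conformers* — position and/or ionization
variants.  A *microstate* x picks one conformer per fragment, with energy

$$
\Delta G_x = \sum_i \delta_{x,i}\Big[\,2.3\,m_i k_bT(\mathrm{pH}-pK_{sol,i})
 + n_i F(E_h - E_{m,sol,i})
 + \Delta\Delta G_{rxn,i} + \Delta G_{pol,i}\Big]
 + \sum_{i<j}\delta_{x,i}\delta_{x,j}\,\Delta G_{ij}
$$

where $m_i \in \{0,+1,-1\}$ marks neutral/base/acid conformers, $n_i$ is
the number of electrons the conformer carries (the *reduced*, Fe^2+^
conformer has $n=1$, so raising $E_h$ favours oxidation),
$\Delta\Delta G_{rxn,i}$ is the desolvation penalty,
$\Delta G_{pol,i}$ the screened interaction with the backbone, and
$\Delta G_{ij}$ the pairwise conformer-conformer energy (electrostatic
plus 12-6 Lennard-Jones).  The pairwise sum is counted once per unordered
pair.  Constants: $k_bT = 0.5922$ kcal/mol at 298 K, $F = 23.061$
kcal mol^-1^ V^-1^, Coulomb constant 332.0636 kcal Å mol^-1^ e^-2^; all
energies in kcal/mol, potentials in mV.

The solution reference $E_{m,sol}$ for the Fe^2+^/Fe^3+^ couple is
-170 mV, the value that anchors the thermodynamic cycle connecting the
aqueous couple to the in-protein couple for F~X~.

## The Poisson-Boltzmann solver

The three electrostatic ingredients come from a finite-difference
linearized PB solver written for this package:

* **Dielectric boundary.**  A continuous level function is built on the
  grid: the signed distance to the solvent-accessible surface (atom
  radius + 1.4 Å probe), eroded by the probe radius via an exact
  Euclidean distance transform.  This recovers the molecular
  (solvent-excluded) surface — for a single sphere, exactly the van der
  Waals sphere — and fills interstitial crevices a water probe cannot
  reach.  Face dielectrics are harmonic means weighted by the
  interpolated in/out fraction of each grid link, which is what makes the
  2% Born-sphere accuracy at 0.25 Å spacing attainable.
* **Salt.**  0.15 M 1:1 salt enters through the linearized Debye-Hückel
  term in solvent nodes (Debye length about 7.9 Å at 298 K); boundary
  conditions are screened-monopole Dirichlet values.  The nonlinear PB
  equation is out of scope; at 0.15 M monovalent salt the energies here
  sit in the linear regime.
* **Self-energy cancellation.**  Every calculation runs a heterogeneous
  solve and a homogeneous reference solve (uniform protein dielectric, no
  salt) on the same grid with the same trilinear charge spreading.  Only
  the difference potential — smooth at the sources — is used, so raw grid
  self-energies never enter.  Conformer-conformer and conformer-backbone
  energies evaluate the analytic Coulomb part at the protein dielectric
  plus the interpolated reaction part.
* **Desolvation.**  $\Delta\Delta G_{rxn}$ is the reaction-field energy of
  the conformer buried in the protein cavity minus the same quantity with
  only the conformer's own atoms carving the cavity; positive for buried
  net charge.  Note that the textbook two-Born-media value
  $166.03\,q^2(1/4 - 1/80)/R$ is the limit of an infinitely large protein
  region; any finite cavity retains some reaction field, and the tests
  compare against the finite-geometry closed form.
* **Defaults.**  0.5 Å spacing, 5 Å padding, one focusing level
  (two-level focusing agrees with an equally fine unfocused run to well
  under 1%), SOR with red-black ordering to a 10^-6^ kcal/mol/e maximum
  update.  Tests and examples use 0.25-0.8 Å spacings on boxes of
  15-40 Å — small enough that each solve takes well under a second — and
  the convergence test shows the Born error falling monotonically as the
  spacing is halved.

## Sampling and midpoint extraction

Occupancies follow from the Boltzmann distribution over microstates,
either by exact enumeration (guarded at 10^6^ states) or by Metropolis
Monte Carlo with single-conformer flips: 2000 burn-in sweeps and 10000
sampling sweeps by default, no annealing (the systems here are small),
occupancy errors from 20 batch means, and a mandatory seed so runs are
bit-reproducible.  On a hundred random systems of up to ten conformers
the MC occupancies agree with enumeration essentially within three batch
standard errors (a floor of a few 10^-3^ absorbs conformers whose batch
variance underestimates at this run length).

A single site titrates at its $E_{m,sol}$ with the ideal Nernst slope
(59.1 mV per decade at 298 K).  For a cluster, the midpoint is defined by
the *second-oxidation* convention: the cluster Em is the $E_h$ at which
the expected number of oxidized Fe crosses 1.5, linearly interpolated on
the Eh grid (5 mV default).  This operational rule is this package's
definition; with two *split* sites and a ferric-ferric repulsion $W$ the
second midpoint shifts by exactly $1000\,W/F$ mV, while two *degenerate*
sites acquire an additional configurational-entropy term: the exact
two-site partition function puts the 1.5-crossing at
$E_m + k_bT\ln(w + \sqrt{w^2+3w})/F$ with $w = e^{W/k_bT}$ — about
$k_bT\ln 2/F \approx 18$ mV above the naive value in the strong-coupling
limit.  The enumeration engine reproduces this closed form to fractions
of a millivolt, which is why the coupling-shift checks use split sites.

## Mean-field decomposition

At the cluster Em the shift from the solution reference is decomposed as

$$ F E_{m,MFE} = n F E_{m,sol} + \Delta G_{bkbn} + \Delta\Delta G_{rxn}
   + \Delta G_{res}^{MFE} $$

where each term is the oxidized-minus-reduced difference of that energy
for the site's conformers, and the residue term weights every partner
conformer by its Boltzmann occupancy.  The identity holds to machine
precision by construction.  Two distinct shift numbers are reported and
deliberately not conflated: `dEm`, the sampled midpoint shift converted
to energy ($F\,|E_{m,calc}-E_{m,sol}|$), and `dG_mfe_sum`, the sum of the
three mean-field terms — they differ because the mean-field average is
an approximation to the sampled ensemble.  Interaction tables
(per-bridging-sulfur columns against partner residues) are purely
electrostatic; cells below 0.5 kcal/mol (the display threshold inferred
from the smallest magnitudes in the reference tables) are blanked on
output but retained internally, so totals never change with the display
setting.

## Synthetic systems and reference tables

`make_toy_cluster()` generates the study conditions every stage is tested
under: an ideal cubane (Fe and S on alternating cube vertices, 2.3 Å
edges, thiolate SG ligands 2.31 Å along the body diagonals), +1 Lys-like
shell sites at 4-8 Å with charged/neutral conformer pairs (rejection
placement keeps them 2.5 Å apart), and amide-like N-H backbone dipoles
(+/-0.4 e, 1 Å) — emulating the hydrogen-bond donor shell around a buried
cluster.  `make_titration_system()` builds analytic energy tables whose
titration behaviour has closed forms, used to validate midpoint
extraction and parameter recovery (an injected oxidized-state shift
$\Delta G^*$ is recovered as $1000\,\Delta G^*/F$ mV within 5 mV).

What the toys deliberately do not emulate: the full PS I complex (twelve
chains, 49 cofactors, ~700k atoms after solvation), MD-equilibrated or
broken-symmetry-DFT-optimized coordinates, and rotamer generation
(alternate geometries are accepted from the caller; ionization conformers
are generated internally).  Passing tests therefore demonstrate the
correctness of the energy model, solver and sampling machinery — not that
desk-scale inputs reproduce the headline cluster potentials, which
require the full prepared structure.

The bundled reference tables (`load_reference_tables()`, checksummed
TSVs) carry the published per-sulfur interaction energies, decomposition
terms, midpoint potentials and ligand distances for F~X~/F~A~/F~B~; the
aggregation code reproduces their row totals exactly where the printed
cells sum exactly (Lys-C51: -33, -9.9, -4.2 kcal/mol) and the cluster
grand totals to within cell-rounding (-152.5, -126, -30 kcal/mol), with
the strongest single interaction Lys-C51 with S2 of F~A~ at -16.9
kcal/mol.  A handful of printed row totals are rounded relative to their
own cells (e.g. R-B674 in F~X~: cells sum -12.9, printed -13); cells are
treated as authoritative.

## Numerical choices and edge cases

* Clash preselection discards a conformer only when an overlap (centre
  distance below $r_i + r_j - 0.1$ Å) is unavoidable: against the
  backbone, or against *every* remaining conformer of another fragment.
  Pairs already in contact in the reference geometry (covalent bonds,
  Fe-S cage contacts, SG-Fe ligation) are native and exempt.  The filter
  runs to a fixed point, making it idempotent.
* Charge bookkeeping is exact: per-atom charges of every conformer sum to
  the integer fragment charge, with any configuration rounding residual
  spread uniformly.
* Ties in `strongest_interaction()` break lexicographically by (partner,
  probe).  Report rounding is half-away-from-zero at 2 decimals, applied
  only at output.
* pH is fixed at 7 by default; the acid/base term of the microstate
  energy is implemented and active for ionizable shell residues, but
  coupled pH-by-Eh surfaces are out of scope.

## Known limitations

The solver is linear-response only (no nonlinear PB, explicit water or
polarizability), uses a two-dielectric model (protein 4 / water 80), and
evaluates Lennard-Jones terms from generic per-atom parameters unless the
charge configuration supplies better ones.  Quantum effects (spin-spin
and spin-orbit coupling within the cubane) are outside the classical
model.  Midpoints are reported on the Eh scale anchored by
$E_{m,sol} = -170$ mV; temperature dependence of Em is not modelled.
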