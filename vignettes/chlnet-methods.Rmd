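---
title: "Methods: energy-transfer networks and structural comparison of photosystem supercomplexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: energy-transfer networks and structural comparison of photosystem supercomplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chlnet)
```

`chlnet` computes four families of quantities on photosystem supercomplex
coordinate models: cofactor inventories, chlorophyll-to-chlorophyll
Förster transfer-rate networks, core-anchored antenna-subunit
displacements, and conserved water shells around iron–sulfur clusters.
This vignette records the models, the conventions, and the design choices
that were genuinely open, so that any disagreement with numbers computed
elsewhere can be traced to a stated convention rather than to an unstated
one.

## Structure input and cofactor classification

Files are parsed from mmCIF (PDBx) or legacy PDB, gzip-transparently,
through bio3d. Author chain identifiers and residue numbers are the
canonical site labels throughout, because published site names (such as
"a306/i") follow author-style numbering. Atoms with zero occupancy are
dropped; among alternate-location conformers of an atom the
highest-occupancy one is kept, with ties broken to the lexicographically
first alt identifier — an arbitrary but deterministic rule, chosen so that
all downstream geometry is reproducible byte-for-byte.

Residue categories (`chl_a`, `chl_c`, `carotenoid`, `lipid`, `water`,
`fes_cluster`, `ion`, `detergent`, `protein`, `unknown`) are a pure
function of the chemical component code through a *component map*. The
map is data, not code: deposited code vocabularies differ between entries
(the carotenoid codes used for alloxanthin, crocoxanthin and monadoxanthin
are deposition-specific), so the built-in defaults (CLA; KC1/KC2; BCR,
ECH, LUT and friends; LHG/PG, LMG, DGD, SQD; SF4; HOH; LMT/LMU) can be
overridden per key from a YAML file. Codes absent from the map are
classified `unknown` with a warning and are never dropped: a silent drop
would bias inventories invisibly. Waters are counted per residue (one
oxygen each), which is how structure papers report water counts.

## The point-dipole rate model

The pairwise rate is $K_{DA} = C\,\kappa^2 / (n^4 R^6)$ with
$\kappa^2 = [\hat u_D\cdot\hat u_A - 3(\hat u_D\cdot\hat R)
(\hat u_A\cdot\hat R)]^2$. The conventions:

* **Transition dipole** $\hat u$: the unit vector from the N_B to the N_D
  pyrrole nitrogen of the chlorin ring, the standard geometric proxy for
  the Qy transition moment. The sign of this axis is irrelevant to
  $\kappa^2$ (it enters squared); it is fixed as N_B→N_D so intermediate
  vectors are reproducible. A chlorophyll missing any of Mg/N_B/N_D, or
  with $|N_D - N_B| < 0.1$ Å, has no defined dipole and is excluded from
  extraction with an explicit report.
* **Separation** $R$: the Mg–Mg distance. $\hat R$ is taken along the
  donor→acceptor Mg axis; since $\kappa^2$ is insensitive to the sign of
  $\hat R$, the orientation of this convention cannot change any rate.
* **Units**: the formula with $C = 32.26$ and $n = 1.55$ is dimensionally
  ambiguous unless a length unit is fixed. `chlnet` follows the convention
  of the algorithm this constant originates from: $R$ in nanometres,
  rates in ns⁻¹. Both $C$ and $n$ are exposed in `fret_parameters()`, so a
  user preferring another convention can rescale $C$.
* **Pair rule**: only chlorophyll-a pairs are connected (`chl_a_only`),
  because the spectral-overlap constant involving chlorophyll c is not
  established. Chl-c pigments remain nodes of the network, so their
  presence and positions stay visible in exports. A pair excluded by the
  rule yields `NA_real_` from `fret_rate()` — an explicit "excluded"
  result, deliberately distinct from a rate of zero (which is a valid
  physical value at $\kappa^2 = 0$).
* **Cutoff**: edges require Mg–Mg separation ≤ 20 Å, *inclusive*, so that
  boundary membership is deterministic. 20 Å is the neighbour distance
  conventionally used for chlorophyll transfer-pathway analyses.

Network comparison maps edges of structure A through an injective site
correspondence (user-supplied, or derived from spatial site matching
after superposition) and classifies each matched edge by the rate ratio
$K_B/K_A$: *equal* within a relative tolerance of 5 % (default), else
*increased* / *decreased*. The 5 % default sits below the rate jitter that
coordinate uncertainty at typical cryo-EM resolutions induces through the
$R^{-6}$ law, so "equal" is not claimed at a precision the coordinates do
not support. Two matched edges with $\kappa^2 = 0$ on both sides are
classified equal rather than producing 0/0.

## Superposition and subunit shifts

Rigid superposition is the closed-form Kabsch solution via singular value
decomposition with determinant-sign correction, guaranteeing a proper
rotation; it is cross-checked in the test suite against an independent
reference implementation (bio3d's fitting routine). Pairing is by equal
author residue number over a user-supplied chain correspondence — species
differ in chain naming, and the intended source for the correspondence is
the published subunit-name tables, not automatic sequence alignment (a
deliberate non-goal). Degenerate pairings (fewer than three pairs, or
collinear atoms) are rejected.

Antenna-subunit displacement uses a **core-anchored protocol**: the
transform is fitted on conserved core chains only (for PSI, PsaA/PsaB;
for PSII, D1/D2/CP43/CP47), the subunit under test being excluded from
the fit; after applying it, the shift is the distance between the Cα
centroids of the subunit in the two models, plus a per-atom RMSD. The
published shift values this protocol is meant to echo do not state their
measurement convention (figures suggest helix-level measurement); the
centroid convention is this package's documented choice, so small
systematic differences from figure-derived values are expected and
attributable.

Cofactor binding sites are matched across structures by greedy
nearest-first one-to-one assignment of representative centers
(chlorophylls: the Mg atom; other cofactors: the geometric center of
non-hydrogen atoms) within a 3.0 Å default radius — below inter-pigment
spacing, above modelling jitter. Greedy assignment with a deterministic
tie-break (smaller distance, then chain/residue order on each side) is
used instead of optimal assignment because sites are far apart relative
to the radius in practice; the test suite verifies greedy = optimal (by
brute-force enumeration) on well-separated instances, which is the regime
the radius default enforces.

## Water shells and conservation

A water belongs to the shell of a target set (for instance all SF4
residues, the F_X/F_A/F_B clusters) when its oxygen lies within the shell
radius — default 8 Å — of **any atom** of any target. Nearest-atom
distance, rather than cluster centroid, is the default because "within
8 Å of the clusters" most naturally reads as proximity to the cluster
itself; the centroid alternative is exposed as a parameter since the
choice moves waters near the boundary in or out. The boundary is
inclusive, with a 1 × 10⁻⁹ Å slack so that a water deposited at exactly
the radius still counts after its coordinates round-trip through a file
with 10⁻³ Å precision.

Conservation against another (superposed) structure assigns each
reference shell water its nearest comparison-water oxygen, greedily and
one-to-one, and calls it conserved within a match radius of 1.2 Å by
default — roughly the positional uncertainty of ordered waters at ~2 Å
resolution. Published conserved-water counts generally do not state their
threshold; because the counts are threshold-sensitive, the pipeline
supports sweeping the match radius (and the shell radius) and reporting
one row per value, rather than pretending a single number is
convention-free. Conserved counts are monotone non-increasing as the
match radius shrinks, which the test suite asserts.

## The synthetic generator

Every pipeline stage is validated against structures whose ground truth
is planted, not fitted:

* **Chlorophyll frames**: Mg at a chosen center, four pyrrole nitrogens
  at 2.05 Å (the Mg–N coordination distance) in a chosen ring plane, with
  N_B→N_D along a chosen dipole direction. This minimal five-atom
  representation is sufficient because the rate model consumes only Mg,
  N_B and N_D.
* **Fe₄S₄ clusters**: ideal cubane, four Fe and four S on alternating
  vertices of a 2.3 Å cube, component code SF4.
* **Waters**: placed either at explicit positions or at an *exact*
  nearest-atom distance from a cluster: the water sits at radius r beyond
  the cluster atom extending furthest along the requested direction, so a
  projection bound makes the planted minimum distance exactly r — no
  root-finding, no tolerance.
* **Protein chains**: Cα-only helical traces (2.3 Å radius, 1.5 Å rise,
  100°/residue), sufficient for superposition and shift tests.
* **Transformed copies**: a global proper rotation plus translation,
  optional per-chain offsets (planting known subunit shifts), optional
  i.i.d. Gaussian coordinate noise under a fixed seed.

Equal inputs produce byte-identical mmCIF output. The generator emulates
the *geometry* that the analyses consume; it does not emulate real data's
chemistry or noise structure — no full porphyrins or phytol tails, no
anisotropic coordinate uncertainty, no B-factors, no missing density,
no alternate conformers beyond those tests construct explicitly. Passing
tests therefore demonstrate correctness of the geometric computations and
their conventions, not robustness to the modelling errors of real
depositions; the deposited-model checks in the acceptance tests cover
that ground when the (large) coordinate files are locally available.

## Numerical choices and degenerate inputs

* Dipole undefined below 0.1 Å N_B–N_D separation; coincident Mg
  positions are an error for distances, $\kappa^2$ and rates.
* Rotation validity: determinant and orthogonality within 10⁻⁹.
* Kabsch collinearity rejection: second singular value below
  10⁻⁸ × the first.
* All matchings (sites, waters) break ties deterministically; all edge
  and site tables are emitted in a canonical sort order.
* Monte-Carlo checks (isotropic $\kappa^2$ mean of 2/3, noise-RMSD
  expectation $\sigma\sqrt{3}$) use 5 × 10³–2 × 10⁴ draws and 300–600
  atoms respectively — sizes at which the Monte-Carlo error is several
  times smaller than the asserted tolerances while the whole suite stays
  fast.

## Limitations

The rate model is the point-dipole approximation: no spectral-overlap
computation, no transition densities, no excitonic delocalisation, no
kinetic master equation — the networks are geometric summaries, suitable
for comparing pathways between structures, not for simulating dynamics.
Superposition is rigid; flexible or secondary-structure-aware alignment
is out of scope. Chain correspondences across species are configuration,
not inference. Published inventory and conserved-water counts depend on
deposition-specific component codes and unstated thresholds; the
component map and the radius sweeps exist precisely so those dependencies
are explicit.
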