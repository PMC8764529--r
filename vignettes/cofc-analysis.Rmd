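---
title: "Methods: binding-site geometry, residue screening, assay quantification and DSF fits for CofC/CofD studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding-site geometry, residue screening, assay quantification and DSF fits for CofC/CofD studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coftools)
```

## Scope

Coenzyme F420 biosynthesis passes through a guanylyltransferase (CofC/FbiD)
that activates a small C3 phospho-acid — 2-phospho-L-lactate (2-PL),
phosphoenolpyruvate (PEP) or 3-phospho-D-glycerate (3-PG) — with GTP, and a
transferase (CofD/FbiA) that moves the activated moiety onto the deazaflavin
core FO. `coftools` implements the quantitative analyses that this kind of
enzymology study runs downstream of the wet lab: hydrogen-bond geometry in
ligand-bound crystal structures, diagnostic-residue screening of homolog
alignments, quantification of combined CofC/D activity assays, and
dissociation constants from nano-DSF melting curves. Every stage has a
paired synthetic-data generator with machine-readable ground truth, so the
full pipeline is testable without any external downloads.

## Binding-site geometry

### The out-of-pi-plane distortion statistic

A hydrogen bond donated to an sp2 pi-system (a carboxylate, a peptide amide,
a purine ring) is most favourable when the partner atom lies in the plane of
that system. The package's geometric quality statistic is therefore the
perpendicular distance of the H-bond partner from the total-least-squares
plane of the sp2 group:

* `fit_plane()` fits the plane minimising the sum of squared perpendicular
  distances. The normal is the singular vector of the smallest singular
  value of the centred coordinates; its sign is fixed deterministically so
  repeated fits are bit-identical. Collinear or coincident point sets
  (second singular value below 1e-9 of the first) are rejected rather than
  silently fitted.
* `out_of_plane_distance()` is `|(p - centroid) . n|`, and
  `average_pi_distortion()` is the arithmetic mean over the H-bonds that
  carry a pi-group, optionally filtered by group kind.

Both quantities are invariant under rigid motions of the whole structure to
1e-9 Å, which the test suite checks explicitly.

### Hydrogen-bond detection

Crystal structures in this resolution regime (about 2.4 Å) carry no reliable
hydrogen positions, so H-bonds are defined on heavy atoms only: N/O on one
side in the ligand, N/O on the other side in protein or water, with the
donor–acceptor distance inside a window of 2.4–3.5 Å by default. No
donor-H-acceptor angle criterion is applied; the out-of-plane distance is
the geometric filter of interest here, and an angle test would require the
very hydrogen positions the data lack.

The sp2 groups are defined by atom-name sets: side-chain carboxylates of
Asp (CB, CG, OD1, OD2) and Glu (CG, CD, OE1, OE2), peptide amides from
backbone neighbours (CA(i), C(i), O(i), N(i+1)), and configurable ligand
groups (`default_ligand_pi_groups()` covers the toy carboxylate and the
guanine ring of the GPPG-like template). When both bond partners belong to
sp2 groups the ligand-side group takes precedence, so the tabulated
distortion is that of the protein partner against the ligand plane.

### Contacts, bridges and metals

`contact_table()` reports every protein-atom/ligand-atom pair within 4.0 Å
(default), plus contacts bridged by a water oxygen or a metal ion, where
each leg of the bridge must be within 3.5 Å. Those cutoffs are deliberate,
conventional contact-shell choices, exposed as arguments; for bridged
contacts the tabulated distance is the protein-to-bridge leg, which is the
measurable quantity when the ligand leg runs through the coordination
sphere. Distances are averaged over all chains containing the ligand; a
contact present in only some chains is averaged over the chains where it
occurs, and the per-chain values are retained so the averaging is always
auditable. Output ordering is deterministic
(residue number, protein atom, ligand atom).

`metal_coordination()` lists all N/O atoms within 2.6 Å of each ion of the
requested element (Mg by default — the alpha/beta phosphates of the bound
guanylylated product are held by two Mg ions positioned by aspartates),
grouped by source: protein, ligand or water.

### Superposition and pose comparison

`superpose_kabsch()` is the standard SVD solution of the least-squares
rigid-motion problem with reflections excluded (determinant +1). Degenerate
(near-collinear) point sets are still solved but flagged unstable, because
the in-plane rotation is then undetermined. `carboxylate_rotation()`
measures how far a bound carboxylate has rotated about the axis through its
two oxygens between two superposed poses: the axis is the O-to-O direction
averaged over the two poses after sign alignment (the two poses never share
exactly the same axis, and averaging avoids privileging either), and the
angle is taken between the projections of the reference-atom vectors onto
the plane normal to the axis, reported unsigned in [0°, 180°]. A reference
atom within 1e-6 Å of the axis is rejected as degenerate.
`group_displacement()` is the Euclidean displacement of a named atom (e.g.
the substrate phosphorus) between poses; for a pure axis rotation it equals
the chord length `2 r sin(theta/2)`, which the tests use as a closed-form
oracle.

### PDB handling

`read_pdb()`/`write_pdb()` implement the fixed-column ATOM/HETATM subset
needed here: first MODEL only, HETATM flagged, element fallback from the
atom name, and deterministic alternate-location resolution (highest
occupancy wins, ties broken toward altLoc "A" — the standard convention).
Coordinates round-trip to the format's three printed decimals (max error
under 5e-4 Å). mmCIF, electron density and anything crystallographic
upstream of a coordinate file are out of scope.

## Homolog screening

The specificity-linked serine of the 3-PG-activating CofC proteins sits at a
fixed residue position of the reference protein but at an
alignment-dependent column, so the screen is split into:

* `map_residue_to_column()` — ungapped residue number to alignment column
  via the gap pattern of the reference row (and back, a round trip the
  tests fuzz);
* `classify_diagnostic()` — per row: serine or threonine at the column is
  called `tolerant`, a gap `indeterminate`, anything else `non_tolerant`.
  The tolerated set `{S, T}` is an argument, since threonine preserves the
  hydroxyl that the rule is a proxy for.

Alignments are consumed, not computed: structure-guided multiple alignment
belongs to dedicated tools. The one alignment the package does compute is
the pairwise global (Needleman–Wunsch) alignment behind percent identity,
with linear gap penalty and match +1 / mismatch 0 / gap -1 defaults —
identity between near-identical homologs, not remote-homology scoring, is
the use case, so no substitution matrix is offered. Traceback tie-breaking
is fixed (diagonal, then up, then left) so alignments are reproducible.
`percent_identity()` counts identical residue pairs over columns where at
least one row has a residue; columns gapped in both rows are ignored. For
near-identical sequences all reasonable denominator conventions agree to
well under a percentage point, and the chosen one is symmetric and
testable.

## Assay quantification

The combined CofC/D competition assay is read out by LC-MS: each substrate
is credited with the formation rate of its product (3-PG via 3PG-F420-0,
2-PL via F420-0, PEP via DF420-0; `default_substrate_map()`). The
quantification chain is:

1. `extract_xic()` — filter a trace to `|mz - target| <= tol`;
2. `integrate_peak()` — trapezoidal area over a retention-time window,
   after subtracting the straight baseline through the window edges
   (toggleable; a linear baseline removes constant and linear drift and is
   exact for a peak returning to baseline);
3. normalisation — mode `"total"` rescales each replicate by its summed
   product signal (a pure per-replicate scale factor, so time courses stay
   linear and turnover shares are untouched); mode `"reference"` divides
   each time point by the FO trace, which is supplied at fixed input
   concentration and therefore corrects per-injection variability. Both
   are reported explicitly because relative turnover is invariant to the
   choice — a property the tests verify;
4. `fit_linear_rate()` — ordinary least squares on the points inside the
   linear range, 0–20 min inclusive by default; later time points (where
   product formation saturates) are excluded by the window, not by the
   data;
5. `specificity_profile()` — per replicate, each substrate's rate as a
   percentage of the summed rates (exactly 100% per replicate by
   construction); across replicates, arithmetic mean and sample (n-1)
   standard deviation. Negative fitted slopes are clamped to zero with a
   warning, since turnover shares are non-negative by definition.

`quantify_assay()` chains all five steps.

## Nano-DSF unfolding and ligand linkage

The melting model is the minimal standard two-state one: van 't Hoff
unfolding with zero heat-capacity change,

```
dG_u(T) = dH_u * (1 - T/T_m)
```

with `T_m` (K) the apo midpoint and `dH_u` (kJ/mol) the unfolding enthalpy
at `T_m`. A ligand at concentration `L` binding only the native state with
dissociation constant `K_D` adds the linkage term `R*T*log(1 + L/K_D)`
(ligand in large excess, free ≈ total), giving

```
f_u(T, L) = 1 / (1 + exp((dG_u + R*T*log(1 + L/K_D)) / (R*T)))
```

so `f_u(T_m, 0) = 0.5` exactly, `f_u` increases in `T` and decreases in
`L`, and the apparent midpoint rises with ligand — all checked as grid
properties. `dCp = 0` keeps the model identifiable from single-transition
curves; a heat-capacity term is a deliberate omission, not an oversight,
and would be the first extension if curves over a wide ligand range showed
systematic residuals.

When part of the protein co-purifies loaded with a tightly bound reaction
product (as CofC does), the observed signal is modelled as a phi-weighted
mixture of two subpopulations: the loaded fraction `phi`, stabilised
through its own `K_D` by the product released on unfolding (free product
approximated as `phi * protein_conc`), and the free fraction responding to
the titrated ligand. The package states this model explicitly rather than
claiming to reproduce any particular instrument-vendor parameterisation.

`fit_melting()` fits shared `(T_m, dH_u, K_D)` — `K_D` on a log10 scale to
keep it positive — plus per-curve linear native/unfolded baselines by
Levenberg–Marquardt least squares, with data-driven initialisation
(steepest-slope midpoint, edge-fit baselines) and 8 multistarts over
`T_m ± 10 K` and log-spaced `K_D` under a fixed seed. Standard errors come
from the asymptotic covariance at the optimum; a titration with no
non-zero ligand concentration leaves `K_D` flagged unidentifiable instead
of returning a number. Because a tightly pre-bound product makes the two
dissociation constants jointly rather than individually identifiable,
`kd_feasibility_grid()` maps the RSS surface over `(phi, K_D_GTP,
K_D_GPPG)` with the thermodynamic and baseline parameters refit at each
grid point; the feasible set is `RSS <= min(RSS) * (1 + threshold)`
(default 5%), which always contains the argmin. With `phi = 0` the surface
is flat along the product axis, as it must be.

## Synthetic data: what it emulates, what it does not

All generators require an explicit seed (no silent clock seeding) and are
byte-reproducible per seed.

* `make_pocket()` places an idealised planar carboxylate or GPPG-like
  ligand (idealised bond lengths: 1.25 Å carboxylate C–O, 1.6 Å P–O,
  tetrahedral phosphates; geometric truth, not chemical realism), plants
  H-bond donors at exact out-of-plane offsets and distances, adds Mg ions
  with octahedral water shells, and duplicates chains with seeded jitter.
* `make_ligand_pair()` rotates a ligand copy by an exact angle about its
  carboxylate O–O axis and records per-atom chord displacements.
* `make_homolog_set()` mutates a random reference everywhere except the
  diagnostic position, plants the diagnostic labels, and generates
  deletions plus shared insertion columns so that residue-to-column
  mapping is non-trivial; substitutions are i.i.d. and indels simple —
  no realistic evolutionary model is intended.
* `make_assay_run()` emits Gaussian chromatographic peaks whose areas are
  `rate * min(t, 20 min)` with multiplicative noise — it emulates the
  linear-then-saturating kinetics and replicate noise of the real assay,
  not mass spectra, isotope patterns or detector artefacts.
* `make_dsf_curves()` is the forward unfolding model plus Gaussian noise —
  no aggregation, scattering or 350/330 nm ratio preprocessing.

Consequently, green tests demonstrate that the *computational chain* is
correct against planted truth and brute-force oracles; they do not certify
performance on real instrument data, where baselines, peak shapes and
alignment quality are all less benign. The two workflow checks that mirror
crystal-structure-scale results (mean distortions near 1.38/0.74 Å, a 36°
carboxylate rotation moving a phosphate 2–3 Å, two Mg per chain) run on
synthetic stand-ins constructed at those magnitudes, since the deposited
entries are not fetched at test time; running the same functions on real
coordinate files is a one-liner for users who have them.

## Numerical choices and problem sizes

* Coordinates in Å; temperatures in K internally (°C accepted on input);
  R = 8.314 J mol⁻¹ K⁻¹; residue numbering as deposited; first MODEL only.
* Plane-fit degeneracy threshold 1e-9 (relative singular value), H-bond
  window 2.4–3.5 Å, contact cutoff 4.0 Å, bridge cutoff 3.5 Å, metal
  cutoff 2.6 Å — all overridable arguments.
* All list outputs sort deterministically; the geometry module contains no
  randomness at all.
* The test suite runs brute-force-oracle comparisons on 100 seeded pockets,
  100 seeded rotation angles, 50 seeded homolog sets and 50 seeded noisy
  DSF titrations, with smaller replicates of each inside the per-module
  tests; these sizes keep the whole suite under a minute on one core while
  leaving the statistical checks (e.g. ≥90% of K_D fits within 2× truth at
  1% noise) well-powered.

## Known limitations

* The PDB reader covers the coordinate subset of the format, not mmCIF,
  SEQRES or anisotropic records.
* Donor/acceptor labelling between two oxygens is heuristic (no hydrogens);
  it does not affect any distance or distortion, only the label.
* Water/metal bridge detection is distance-based only; no coordination
  valence or geometry test is applied to the bridge.
* The DSF mixture model approximates the free product concentration as
  `phi * protein_conc` and ignores competition between GTP and the bound
  product for the same site.
* Peak integration assumes a single peak per species inside the window;
  overlapping species must be separated by m/z, not by deconvolution.
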