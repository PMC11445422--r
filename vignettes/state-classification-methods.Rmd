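---
title: "Methods: hydrogen-bond geometry, state classification, titration fitting and NCI fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydrogen-bond geometry, state classification, titration fitting and NCI fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfpstate)
```

# The scientific problem

The GFP chromophore sits in a hydrogen-bond network whose geometry
changes with the protonation state of the phenolic oxygen (Oη). Three
ground states matter: **A** (neutral phenol, the dominant state of
wild-type GFP), **B** (anionic phenolate stabilized by the Thr203
hydroxyl) and the photocycle intermediate **I** (anionic phenolate in an
otherwise A-like environment, reached after excited-state proton
transfer). High-resolution crystal structures of state-stabilizing
variants show that the state can be read off two heavy-atom distances:
His148 Nδ1···Oη and the position-203 distal atom···Oη. This package turns
that observation into a reproducible measurement and classification
pipeline, with coordinate-error propagation, titration analysis of the
I-state fraction and a promolecular NCI (non-covalent interaction)
module for characterizing the contacts.

# Structure model and site resolution

Structures are parsed with bio3d (PDB fixed-column v3.3 and mmCIF
`atom_site` records) into one uniform atom table; all ATOM/HETATM
records are retained, including waters and alternative conformations.

**Altloc policy.** Reported distances need one representative position
per atom. When conformers exist we keep the highest-occupancy one,
breaking ties by altloc letter. This is an assumption — depositions do
not record which conformer underlies a printed distance — but it is the
conformer a crystallographer would quote. The selected conformer's
B-factor also feeds the error model, keeping the two modules consistent.

**Semantic site keys.** Measurement code never addresses atoms by serial
number. Keys like `"His148.ND1"`, `"chromophore.OH"` and
`"pos203.distal"` resolve through a small vocabulary that also accepts
the Greek remoteness labels used in the structural literature
(`"His148.Ndelta1"`). The chromophore is recognized by component code
({CRO, GYS, CR2, CSY}, configurable) because naming varies across
depositions; in all of them the phenolic oxygen is `OH`. The distal
atom at position 203 is `OG1` for Thr, `OG` for Ser, `CG2` for Val/Ile.
Insertion codes are rejected: author numbering (65, 148, 203, 205, 222)
is assumed unique, which holds for GFP.

**Wat3.** The conserved proton-relay water has no transferable residue
number, so it is defined operationally: the water oxygen whose summed
distance to the chromophore OH and the Ser205 Oγ is minimal, with both
legs within 3.5 Å. Ties and ordering resolve by residue number, making
the search invariant to record order. Absence of such a water is a valid
result, not an error.

# Geometry

Distances are Euclidean; torsions use the standard IUPAC sign convention
and are validated in tests both against independently constructed
rotations and against bio3d's torsion routine. χ1 is the N–CA–CB–γ
torsion; rotamer wells partition (−180°, 180°] as gauche− [−120°, 0°),
gauche+ [0°, 120°), trans otherwise, with inclusive lower edges — the
literature names only the canonical wells (−60°, +60°, ~180°), so a
full partition is this package's choice and the bin edges sit at the
barriers between wells.

**Hydrogen bonds from heavy atoms only.** Crystal structures at this
resolution contain no hydrogens, and the state diagnostics are stated
entirely in donor–acceptor distances, so no angular criterion is
applied. This is a documented limitation: a heavy-atom distance in the
"normal" range with grossly non-linear geometry would still be binned as
a bond. Strength bins: 2.5 ≤ *d* ≤ 3.0 Å normal, 3.0 < *d* ≤ 3.5 Å weak,
beyond 3.5 Å none, below 2.5 Å flagged as a clash. The published bin
edges overlap at exactly 3.0 and 3.5 Å; we resolve boundary values
toward the stronger class.

**Gln222 orientation.** The amide's Oε1 and Nε2 are distinguished by
which sits closer to the Ser65-derived hydroxyl; the arrangement
reverses between the low-pH (A) and high-pH (I) forms. Differences
below 0.2 Å return `"undetermined"` — a deliberately conservative floor,
about twice the DPI-scale coordinate error of 1.2–1.5 Å-resolution
data, because an orientation call from a smaller margin would be
overinterpretation. A wild-type Glu at 222 goes through the same
comparison with Oε1/Oε2.

# Error model

Refinement supplies one average coordinate error, the diffraction
precision index (DPI); computing it requires refinement statistics that
are out of scope, so it is an input (`read_structure(dpi = )`). It is
scaled per atom by `sigma_i = dpi * sqrt(b_i / b_average)` with
`b_average` the occupancy-weighted mean B over selected conformers, and
distances get `sigma_l = sqrt(sigma_i^2 + sigma_j^2)`. Uniform-B
structures therefore carry identical error bars √2·DPI on every
distance — a property the tests assert. No covariance between atoms is
modelled; for the ~0.07 Å scale involved that refinement-matrix level of
rigor would not change any state call.

# State classification

The classifier is a pure function of two descriptors:

* `his_class` — strength bin of *d*(His148 Nδ1, Oη);
* `pos203_bonded` — whether the 203 distal atom is a hydroxyl **oxygen**
  within 3.2 Å of Oη.

Rule: clash → unclassified; normal + bonded → **B**; normal + not bonded
→ **I**; weak or none → **A**. A carbon at the distal position (Val,
Ile) never counts as bonded regardless of distance: CH···O contacts are
weak attraction in the NCI sense, not hydrogen bonds on these axes.

The published account presents the states as regions on a scatter plot
without boundary equations, and its verbal region labels are hard to
reconcile with the axis directions; we therefore operationalized the
rule from the unambiguous distance statements (an I-context structure at
2.85 Å, an A-context structure at 3.24 Å, B-context structures with both
bonds) and the caption's strength bins. The 3.2 Å O···O cutoff for the
203 hydroxyl sits between the B-exemplar distances (≤ 2.8 Å) and the
A/I-exemplar ones (≥ 3.5 Å), in the middle of the empty margin, and the
classification of every printed exemplar is insensitive to moving it by
±0.2 Å. Tests verify the rule against an independently written
case-table oracle on 10⁴ random inputs, its totality on a grid, and its
stability under perturbations smaller than the distance to the nearest
bin edge.

# Titration fitting

The I-state fraction versus pH is fit with the Henderson–Hasselbalch
form `f = 1 / (1 + 10^(pka - ph))` with the Hill coefficient fixed at 1
(one protonation site — no cooperativity is modelled). The weighted
least-squares objective (weights 1/sd² where per-point standard
deviations exist, 1 otherwise) is minimized over the single parameter by
golden-section/parabolic search (`stats::optimize`, tolerance 1e-10,
interval extending 3 pH units beyond the data). The 1-σ uncertainty
comes from the curvature of the objective: with the analytic sensitivity
`df/dpka = -ln(10) f (1-f)`, `pka_sd = sqrt(s2 / sum(w g^2))` where `s2`
is the weighted residual variance. Datasets whose fractions never leave
[0, 0.1] or [0.9, 1] are rejected as non-identifiable rather than
returning a runaway estimate.

Whether the original experiments fitted fractions or fixed-wavelength
absorbances is not recorded; this package fits fractions, and
`fraction_from_spectra()` provides the two-state unmixing from peak
absorbances with a configurable extinction-coefficient ratio
(default 1.0, since no measured ratio is available) for users starting
from spectra.

# Promolecular NCI fields

The NCI method highlights non-covalent contacts as regions where the
reduced density gradient

$$ s(\mathbf r) = \frac{|\nabla\rho|}{2(3\pi^2)^{1/3}\rho^{4/3}} $$

is small at low density, colored by sign(λ₂)ρ where λ₂ is the middle
eigenvalue of the density Hessian: negative = attractive, near zero =
weak/van der Waals, positive = steric repulsion.

**Density model.** The reference analyses used DFT densities from QM/MM
calculations; those are out of scope, and promolecular densities (sums
of spherical atomic densities) are the standard desk-scale substitute
that preserves the qualitative classification. Each element is a sum of
exponentials `c_j exp(-r/zeta_j)` normalized so each term integrates to
its electron count. Hydrogen is the exact ground-state H atom
(`rho = exp(-2r)/pi`). For heavier elements the valence term's decay
length is set from the first ionization energy, `zeta = 1/(2*sqrt(2*I))`
— the physically correct asymptotic decay of the true atomic density,
which is what matters in the non-covalent region probed by NCI (a
Slater-exponent tail would be several times too steep there) — and core
terms use hydrogenic `1/(2Z)` decays. Parameters ship for H, C, N, O, Ne
and S; custom tables (e.g. a single exponential with known closed-form
*s*) plug in through `density_model(params = )`, which is how the tests
check the grid code against analytic oracles to 1e-6.

Gradients and Hessians are assembled analytically from the radial form
(verified against finite differences), and eigenvalues come from a
vectorized analytic symmetric-3×3 solver checked against base `eigen`.
Atom order is canonicalized inside `density_model()` so the summed field
is bit-identical under input permutation.

**Grid and clusters.** Default spacing 0.15 bohr over the atom bounding
box padded by 2 Å, center-aligned so symmetric fixtures sample their
midplane critical point exactly (where *s* = 0 analytically). Points
with `s <= 0.4` and `rho < 0.05` a.u. (the covalent-region cutoff) form
the interaction mask; 6-connected components are labelled by flood fill
and each cluster is classified by sign(λ₂)ρ at its minimum-*s* voxel
with a ±0.01 a.u. threshold mirroring the conventional color bar. A
resource guard (2×10⁶ cells) rejects accidental huge grids. Fields are
written as Gaussian cube files (z fastest), readable by standard
volumetric viewers. Hydrogens must be supplied by the caller or the
fixture generator — crystallographic heavy-atom models would silently
miss the H-mediated surfaces.

# Synthetic data: what it emulates and what it does not

The generator builds minimal chromophore environments — chromophore
(OH, CZ, N2, O2, OG1), His148, the 203 residue, Ser205, Gln222, optional
bridging water — by explicit constructive placement: the phenolic oxygen
sits at the origin and each partner is placed along a prescribed
direction at the exact prescribed distance; the 203 side chain is built
in an internal frame with the exact χ1 (natural-extension placement) and
rigidly moved into position, so all prescribed quantities are realized
to machine precision by design, not by optimization. Five presets encode
the exemplar state geometries (I-like at *d*_His 2.85 Å with Val203;
A-like at 3.24 Å and a Thr variant; two B-like Thr pairs at ~2.8 Å);
distances not pinned by published values (e.g. the B-like 2.7/2.9 Å
pairs, the 2.7 Å water leg) were chosen once at typical hydrogen-bond
geometry. Default B-factor 20 Ų uniform (a `ramp` profile from 10 to
40 Ų exercises the error model), occupancies 1.0, DPI 0.07 Å.

The fixtures contain only the residues the measurements touch — no
β-barrel, no realistic packing, no solvent beyond Wat3, idealized
backbone geometry away from the measured atoms. Passing tests therefore
demonstrate the correctness of the measurement, propagation and
classification machinery, not robustness to disorder, missing atoms or
crystallographic pathologies in real depositions; the five deposited
variant structures can be dropped into `tests/testthat/deposited/` to
run the real-data checks.

The titration preset mirrors the published experiment's design: true
midpoint 6, ten pH points spanning 4.0–8.5, three replicates per point,
Gaussian fraction noise sd 0.02 (a plain noise scale consistent with
>90 % purity calls; replicate scatter is i.i.d., with no pH-meter drift
or baseline error modelled). Generators save and restore the caller's
RNG state, so they never perturb user code's reproducibility.

# Numerical choices and degenerate inputs

* Torsions: collinear triples raise an error rather than returning an
  arbitrary angle; results live in (−180°, 180°] with −180° mapped to
  +180°.
* `optimize` tolerance 1e-10 recovers noise-free pK_a to < 1e-6.
* Density evaluation guards `r < 1e-10` bohr against the nuclear
  singularity of the gradient (the density itself is finite).
* Eigenvalue solver falls back to the diagonal for numerically spherical
  Hessians (`p < 1e-300`).
* Boundary conventions: H-bond bins resolve toward the stronger class at
  exactly 3.0/3.5 Å; rotamer bins include their lower edge; sign(0) = +1
  in sign(λ₂)ρ.

# Problem sizes

The test suite and the acceptance script run entirely on generated
data: 100 random structure presets for the round-trip property, 200
replicate titration experiments for the bias estimate, 10⁴ random
descriptor pairs for the classifier oracle, and NCI grids of ~2.5×10⁵
points at 0.15 bohr spacing; the whole suite completes in well under a
minute on one core.

# Known limitations

* Heavy-atom-only hydrogen-bond criterion (no angles, no protonation
  logic); the His148 Nδ1–H tautomer is chemical context, not enforced.
* DPI is trusted as given; no refinement-matrix error treatment.
* Promolecular densities cannot show charge-transfer or polarization
  effects; sign(λ₂)ρ magnitudes are comparable to, but not identical
  with, DFT-based values — the qualitative class (attractive / weak /
  repulsive) is the supported output.
* The classifier assumes the construct actually is a GFP-like
  chromophore environment; it does not validate the fold.
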