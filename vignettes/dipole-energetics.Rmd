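---
title: "Dipole-moment energetics of protein self-assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dipole-moment energetics of protein self-assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmdipole)
```

## The model

Many protein assemblies — amyloid fibrils, viral capsids, actin filaments,
microtubules — are *open* systems: monomers keep adding with no
predetermined count. A long-standing idea is that the first, orienting step
of such assembly behaves like a biological membrane: monomers align the way
lipids do, driven by the interplay of hydrophobic and electrostatic
interactions, and only afterwards do the short-range specific contacts
(hydrogen bonds, salt bridges) lock the interface. `asmdipole` implements a
coarse-grained scoring of that picture.

Each monomer is reduced to two vectors:

* **D**, the electrostatic pseudo dipole moment, built from the charged
  residues (Asp/Glu at -1, Lys/Arg at +1), and
* **H**, the hydrophobic pseudo dipole moment, built from *hydrophobic
  charges*: the residue hydrophobicity indices of the Eisenberg normalized
  consensus scale treated formally as signed point charges (hydrophobic
  residues positive, hydrophilic negative).

Because a protein's net charge (of either kind) is rarely zero, the exact
dipole sum q_i r_i is origin-dependent and unusable. The model therefore
uses the pseudo moment

    P = Q+ (c+ - c-)

where Q+ is the total positive charge and c+, c- are the
charge-magnitude-weighted centroids of the positive and negative charges.
This is translation-invariant by construction and coincides with the exact
dipole whenever the set is neutral (a property the test suite checks to
1e-9 on a thousand random neutral sets). When one charge subset is empty
the dipole is *undefined*; it is carried as a zero vector, contributes zero
energy, and is reported as `n/a` — some short amyloidogenic peptides have
no basic residue at all, so no electric dipole exists for them.

Two interacting monomers are then scored by classical point-dipole theory:

    enD = -[3 (u.D1)(u.D2) - D1.D2] / r^3        (prefactor 1)
    enH = +[3 (u.H1)(u.H2) - H1.H2] / (k e^r)    (k = 1)

with r the distance between the two dipoles' application points and u its
unit vector. Both energies are in arbitrary units (a.u.), negative =
attractive. The sign flip in `enH` encodes the inverted affinity of
hydrophobic charges: like signs attract, so *aligned* hydrophobic moments
attract while aligned electric dipoles repel — exactly the lipid-bilayer
geometry. The exponential range law reflects the shorter reach of the
hydrophobic interaction; since any monotone decay only rescales the values,
it changes no sign and no minimum location. For the same reason **enH and
enD are never magnitude-comparable**, neither with each other nor across
systems: only signs, trends and within-system comparisons are meaningful,
and the package never compares the two kinds numerically
(`classify_driver()` works on the sign pattern alone).

## What the package computes

1. **Per-monomer dipoles** (`assembly_energetics()`, `run_vectors()`),
   with BILD/PML arrow exports for ChimeraX/PyMOL.
2. **Consecutive-pair statistics**: mean and sample (n-1) SD of the
   pairwise energy over ordinal pairs (1-2, 2-3, ...) in assembly
   (deposition) order. The SD definition and the ordinal (not spatial)
   notion of "consecutive" are package choices; both are stated here
   because the quantities they summarize are convention-dependent.
3. **Driver classification**: `enH < 0 <= enD` hydrophobically driven,
   `enD < 0 <= enH` electrostatically driven, both negative
   dual-attractive (rare, e.g. hyperthermostable assemblies), both
   non-negative dual-repulsive, undefined components indeterminate.
4. **Growth curves** (`growth_curve()`): the cumulative all-pairs energy
   E(N) of the first N elements, either in assembly order or growing
   outward from a chosen inner element (remaining monomers ranked by
   application-point distance — the ranking rule is a package choice since
   "surrounding" is not otherwise defined). For regular helical systems
   E(N) is quasi-linear in N.
5. **Rotation and translation scans** (`rotation_scan()`,
   `translation_arrangements()`): is the native dimer geometry the energy
   minimum? The second dipole vector is rotated in 10-degree steps about
   three axes — x along the inter-dipole vector, y perpendicular to the
   plane of x and the moment, z completing the right-handed triad — and
   three schematic alternatives (side-by-side, top-down, staggered
   parallel placements at the native separation) are generated and
   re-scanned.

```{r example}
asm <- reference_assembly("hydrophobic_driven", n_monomers = 12)
fit <- assembly_energetics(asm)
fit
coef(fit)
```

## Conventions and tunable parameters

All knobs live in `energetics_control()`; every output file embeds the
effective settings as a fingerprint.

| parameter | default | why |
|---|---|---|
| `site_mode_electrostatic` | `charged_group_centroid` | the charge sits on its carrier atoms (Asp OD1/OD2, Glu OE1/OE2, Lys NZ, Arg NH1/NH2/NE, His ND1/NE2) |
| `site_mode_hydrophobic` | `sidechain_centroid` | hydrophobicity is a side-chain property; Gly falls back to CA |
| `include_his` | `FALSE` | His is mostly neutral at physiological pH |
| `include_termini` | `FALSE` | side-chain-only accounting; the terminal +1/-1 can be restored |
| `scale` | Eisenberg consensus | the standard normalized scale; any two-column table loads via `read_hydrophobicity_scale()` |
| `distance_unit`, `r0` | `"scaled"`, 10 Angstrom | see below |
| `application_point` | `"midpoint"` of c+ and c- | the symmetric choice; `geometric_center` and `c_plus` offered |
| `scan_step` | 10 degrees | grid scan only, no continuous optimization |

**The exponent unit.** The hydrophobic law divides by e^r with k = 1, but
a bare exponential needs a dimensionless argument and the length unit is a
genuine free convention. With r in Angstrom at typical inter-monomer
spacings (~25 A), e^r suppresses enH by ten orders of magnitude; the
default therefore exponentiates r/r0 with r0 = 10 A, the order of the
spacing itself, keeping values O(1). `angstrom` and `nanometer` modes are
provided for sensitivity analysis. Nothing qualitative depends on the
choice: signs, scan-minimum locations and classifications are invariant to
it (a tested property), only magnitudes rescale.

**Centroid separations.** For real protein monomers |c+ - c-| typically
falls between 1 and 10 A; values outside that range trigger a warning
(never an error), as a sanity check on site-mode choices.

**Alternative moment definitions.** `alternative_moment()` computes
Q- (c+ - c-) and the exact sum for sensitivity analysis. Conventions must
never be mixed within one analysis; all three coincide for neutral sets.

## Numerical choices and degenerate inputs

* **Undefined dipoles** (an empty charge subset) propagate as zero-energy
  contributions, are excluded from pair statistics, and make the affected
  classification component indeterminate — never an error.
* **Scan ties.** The minimum of a grid scan is the angle of the global
  minimum; ties — detected within a band of 1e-9 of the scan's energy
  range, so the detection is invariant to rescaling the moments or
  changing the distance unit — are broken toward the angle closest to 0
  degrees and flagged. A constant scan (a moment rotated about its own
  axis) therefore reports 0 degrees with the tie flag set.
* **Degenerate frames.** When the scanned moment is parallel to the
  inter-dipole axis the y-axis construction degenerates; an arbitrary
  perpendicular is used with a warning (silenced inside the top-down
  translational arrangement, where the degeneracy holds by construction).
* **Angle reporting.** Rotations are right-handed about each axis; minima
  are reported on the [0, 350] grid together with a signed alias in
  (-180, 180], since e.g. -60 and 300 degrees name the same point.
* **altLoc / models / hydrogens.** Highest-occupancy alternate locations
  (ties by label order), model 1 of NMR ensembles by default, hydrogens
  and hetero records excluded, non-standard residues dropped with a
  message.
* **Steric clash is not modeled.** Scans annotate every angle; they never
  exclude sterically impossible ones. Off-native minima are therefore
  expected in systems where contact constraints, not dipole energetics,
  pick the final geometry.

## The synthetic generators, and what passing tests do not show

`toy_monomer()` (explicit point charges), `helical_assembly()` (rigid
screw copies of a template: radius 20 A, rise 2 A, twist 22.5 degrees per
element by default, i.e. 16 elements per turn with a small pitch, the
geometry class of helicoidal capsids) and `reference_assembly()` (three
systems whose driving interaction is known by construction, built from
+/-1 charge pairs 4 A apart — inside the 1-10 A separation range) give
the test suite closed-form ground truth: screw symmetry makes every
consecutive pair identical, parallel side-by-side moments make enH
attractive and enD repulsive, axial stacking reverses both, and
alternating the electric dipole sense along the helix yields the
dual-attractive case. `write_toy_pdb()` writes toys as pseudo-CA records
whose residue names regenerate the intended charges through the real
residue tables, so the file-format path is covered end to end.

What the toys deliberately do **not** emulate: real side-chain geometry
(every toy site is a point), sequence-dependent charge patterns,
conformational variability between subunits, and any notion of sterics.
Green synthetic tests therefore certify the arithmetic, the invariances
(translation/rotation equivariance, 1/r^3 and e^-r range laws, growth-curve
additivity) and the classification logic — not that a particular real
assembly is hydrophobically driven. Real-structure conclusions additionally
depend on the site/His/termini conventions above; the test suite's
PDB-entry checks (which download coordinates on demand) pin the sign
patterns and minimum locations for the systems they analyze, and printed
mean magnitudes are reproducible only once a convention set is fixed and
reported alongside them.

## Problem sizes

The test suite and `scripts/acceptance.R` run on assemblies of 3-20
monomers, 1000 random charge sets of 8-50 charges, and 36-point scan
grids; the whole synthetic surface completes in seconds. These sizes are
chosen because every checked property (exact identities, invariances,
symmetry-forced equalities) is size-independent: a 20-element helix
exercises the same code paths as a 500-element one.

## Known limitations

* The energies are pseudo-energies in arbitrary units: no solvation
  physics, no temperature, no free energies, no kinetics — the model
  addresses final-state orientation preferences only.
* The hydrophobic law's range behaviour (exponential, unit choice) is a
  modelling convention, not a fitted potential.
* Classification rests on the sign of a mean over consecutive pairs;
  strongly irregular assemblies (mixed interfaces, alternating stacks) can
  average signs away — inspect the per-pair table, not just the label.
* mmCIF assemblies are read as deposited; no symmetry expansion is
  performed, so analyze the biological-assembly file when the deposited
  asymmetric unit is not the fibril/capsid.
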