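---
title: "Models and methods: from coformer screening to facet surface chemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: from coformer screening to facet surface chemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocryst)
```

# Scope

`cocryst` implements the computational half of a cocrystal development
workflow: given a target molecule (an active ingredient such as a poorly
soluble flavonoid) and a library of candidate coformers, it screens the
library by molecular complementarity, ranks survivors by hydrogen-bond
propensity difference, and — once a crystal structure of a candidate
multicomponent solid is available — quantifies its supramolecular synthons,
predicts the growth morphology, and characterizes the chemistry and
topology of the predicted facets. Everything runs from standard text
formats (CIF, SDF/MOL V2000, MOL2) with no external database or
closed-source modelling environment.

# Stage 1: molecular complementarity

The premise is empirical: molecules that cocrystallize tend to be similar
in shape and polarity. Five descriptors are evaluated per molecule:

* `s_axis` — the short axis (Å) of a rectangular box enclosing the van der
  Waals volume. The box frame is the principal-axis (PCA) frame of the
  atomic point cloud; each axis extent is `max(proj + r_vdw) −
  min(proj − r_vdw)` over atoms. This is deterministic and invariant to
  rigid motion; for a strictly planar molecule the short axis is carried by
  the vdW radii alone, and a single atom gives `2 r_vdw` in all directions.
  An exhaustive minimum-volume box search would differ by at most a few
  percent and is not used — the PCA frame is reproducible and cheap.
* `s_over_l`, `m_over_l` — the sorted axis ratios (dimensionless).
* `no_fraction` — the fraction of N and O among heavy atoms. The
  denominator is heavy atoms by default (`denominator = "all"` switches to
  all atoms); the choice matters at the second decimal for H-rich
  molecules.
* `dipole` — `|Σ qᵢ rᵢ|` in Debye about the centre of charge, from the
  assigned partial charges. For net-charged species the dipole is
  origin-dependent; it is then computed about the centre of mass and a
  warning is raised.

A coformer passes a descriptor when the absolute difference from the target
is inside a window. The shipped windows
(`inst/extdata/mc_thresholds.tsv`: 2.0 Å, 0.20, 0.25, 0.20, 6.0 D) are
package defaults chosen to be of the order of the spread seen among known
cocrystal pairs; they are deliberately conservative, clearly labelled, and
meant to be overridden with calibrated values when available. All tests
construct their libraries *relative to the configured windows*, so the
pipeline's correctness does not hinge on these defaults.

# Stage 2: hydrogen-bond propensity difference

For target T and coformer C the score is

$$\Delta_{HBP} = \max P_{T-C} - \max\left(\max P_{T-T},\; \max P_{C-C}\right)$$

over all donor–acceptor pairs; a positive value means the best heteromeric
hydrogen bond beats the best homomeric one, favouring cocrystallization.
Propensities are *inputs* (a long-format table), because production-grade
propensity models are trained on large structural databases that cannot be
redistributed. Two conventions are fixed here: an empty homomeric set
counts as propensity 0 (the most permissive reading, logged), and ties
among heteromeric maxima are reported in full. The ranking is total and
deterministic (descending score, then coformer name).

`logistic_propensity()` provides a configurable logistic surrogate
`p = 1/(1 + e^{-\beta x})` over functional-group pair features, and
`fit_propensity_model()` fits it by ordinary logistic regression, so the
whole pipeline can run end-to-end on synthetic labelled data. This is a
surrogate for demonstration and testing, not a re-derivation of any trained
model.

# Stage 3: crystal energetics

## Chemistry perception

CIF files are read with a core-dictionary parser (cell, symmetry as
explicit xyz strings or a P1/P-1 symbol, atom sites, occupancy checks);
molecules are reassembled into whole connected units by placing each bonded
neighbour at its nearest periodic image, so no covalent bond crosses a
molecule boundary. Bonds are perceived by covalent radii with a 0.4 Å
tolerance (standard crystallographic practice); rings come from the bond
graph (smallest ring through each cyclic edge); a ring is aromatic when it
is planar (RMS out-of-plane < 0.1 Å) and every member is an sp²-capable C
or N — an ether oxygen keeps a pyranone ring non-aromatic, which is the
behaviour needed for flavonoid cores. Atom types follow the Dreiding
element+hybridization convention; hydrogens on N/O become the H-bonding
type. Hydrogen positions are taken as given in the file (no normalization),
matching the riding-model hydrogens of refined structures.

Partial charges default to iterative Gasteiger-style electronegativity
equalization (PEOE, 8 damped iterations). The scheme is deterministic,
needs no fitting data, and conserves the net molecular charge exactly
because every transfer is antisymmetric per bond. Absolute energies of any
force-field calculation depend strongly on this choice; for that reason
the package targets *relative* synthon rankings and energy partitions, not
absolute agreement with energies computed under other (unpublished) charge
models.

## The potential

All intermolecular energies are sums over atom pairs of two molecules, in
kcal/mol:

* Lennard-Jones 12-6, `D₀[(R₀/r)¹² − 2(R₀/r)⁶]`, with per-type well depths
  and minima from the standard Dreiding table
  (`inst/extdata/dreiding_params.tsv`), geometric combination for unlike
  pairs (arithmetic available).
* Coulomb with a distance-dependent dielectric, `332.0637 qᵢqⱼ/(ε₀ r²)`,
  i.e. ε(r) = ε₀·r with ε₀ = 1 by default. A direct sum (no Ewald) is
  appropriate for neutral molecules in a finite environment; a convergence
  flag compares the sum at `cutoff` and `cutoff + 10 Å` (pass at
  < 0.1 kcal/mol) and net-charged molecules trigger a warning.
* An explicit hydrogen-bond 12-10 well on the donor–acceptor distance,
  `D_hb[5(R_hb/r_{DA})¹² − 6(R_hb/r_{DA})¹⁰]\cos^4\theta` with θ the
  D–H···A angle, active for `r_DA < 4.5 Å` and θ > 90°
  (D_hb = 9.5 kcal/mol, R_hb = 2.75 Å). Where it is active it *replaces*
  the LJ terms of the D···A and H···A pairs: the H-bonding hydrogen's
  near-zero vdW well exists precisely so that the close H···A contact is
  governed by the 12-10 term, and keeping the raw LJ there would inject a
  spurious ~+4 kcal/mol repulsion into every hydrogen bond.

## Environment, lattice energy, synthons

The environment of a reference molecule is every whole symmetry/translation
image whose *centroid* lies within the cutoff (default 30 Å; an any-atom
criterion is a trivial variant but the centroid matches the
centroid-distance bookkeeping of synthon tables). The supercell extent,
`ceil(cutoff/d_axis) + 1` per axis, guarantees completeness — verified in
the tests against an explicit 7×7×7 enumeration. The lattice energy is the
half-sum of pair energies over the environment, summed over the asymmetric
unit; percentages of lattice energy are defined against this
*intermolecular* total (intramolecular terms are out of scope).

Pairs related by a symmetry operation have identical energies and merge
into one synthon with a multiplicity; ranking is by |E| descending with
ties broken by centroid distance, then partner id. Classification is
geometric with precedence H-bond > π–π > offset stacking: an H-bond needs a
donor-H···acceptor contact under 2.5 Å at an angle over 120°; stacking
needs two aromatic ring centroids within 4.0 Å (π–π, lateral offset
< 1.5 Å) or 6.5 Å (offset, ≥ 1.5 Å) with interplanar angle < 20°.
`aggregate_by_type()` coarsens labels (both stacking varieties into
"stacking") and sums |E| and percentage contributions per class.
`group_decomposition()` attributes every pair term half to each
participating atom's functional group (H-bond terms half donor, half
acceptor), so group sums reproduce the lattice energy exactly.

# Stage 4: attachment-energy morphology

For a plane family {hkl} with spacing d, every reference–partner pair is
assigned to the *slice* when the partner centroid lies in a d-thick slab
through the reference centroid (normal to the facet), else to the
*attachment* set. This centroid-slab rule is parameter-free and makes
`E_slice + E_att = E_lattice` an identity by construction — the tests
assert it to 1e-6 kcal/mol on every enumerated facet of randomized
crystals. The polar/nonpolar split of the attachment energy is
Coulomb + H-bond vs LJ, reported in kcal/mol and kJ/mol (factor 4.184
exactly).

Growth rate is assumed proportional to |E_att| (the standard
attachment-energy model; no solvent correction, which is the model's main
idealization). The habit is the intersection of half-spaces at distances
proportional to |E_att| for both Friedel mates of each family, computed by
exact vertex enumeration over plane triples (robust at the ≤ ~30-plane
scale of low-index morphologies). Relative areas come from the face
polygons; an independent Monte-Carlo ray-casting estimator
(`sample_habit_areas()`, weight r²/cosθ per hit) validates them — the
weights are heavy-tailed for elongated habits, so the default is 2×10⁶
rays, giving sub-0.1% agreement in the tests. A facet with zero attachment
energy would collapse the polyhedron (it never grows); its distance is
floored at 2% of the maximum, reproducing the physical plate-like limit
with a warning. Multiplying all |E_att| by a constant leaves the shape
unchanged.

# Stage 5: facet terminations and surface chemistry

A slab for {hkl} is a patch of 2×2 surface cells (in the shortest
integer in-plane lattice basis) and ≥ 2 d-spacings of depth, keeping whole
molecules only. The termination offset — where within one d-spacing the
cut falls — is chosen automatically as the candidate (one per distinct
molecular layer) minimizing the energy crossing the plane, with ties broken
by smaller rugosity; a fixed offset mode exists for reproducibility, and
the automatic choice is tested against a brute-force 50-point offset sweep.

The topology map is the upper envelope of the van der Waals spheres,
sampled on a regular grid over the projected patch (target spacing 0.25 Å,
internally supersampled 3× so the RMS is stable to < 1% under in-plane
translation of the grid origin). Heights are reported relative to the
average plane (zero mean by construction) and rugosity is their RMS.

Surface chemistry counts hydrogen-bond donor hydrogens, acceptor heavy
atoms, and aromatic bonds that are *exposed*, divided by the projected
patch area (counts/Å²). Exposed means the atom's vdW top reaches within
`exposure_depth` (default 3.0 Å, about one atomic layer) of the topmost
vdW surface of the patch. Two conventions deserve note: (a) the reference
is the patch's topmost surface, not a per-position local top — a local-top
rule can never bury an atom that has open sky above it, which would make
donor burial in grooves undetectable; (b) donors are counted as H atoms
and acceptors as heavy atoms, so a hydroxyl contributes one to each.
Densities are intensive: doubling the patch to 4×4 cells changes them by
< 5% in the tests.

# Synthetic data: what it emulates and what it does not

The generators produce geometric idealizations with analytically known
ground truth:

* `make_planar_donor_molecule()` — rigid planar fused-ring scaffolds with a
  chosen number of peripheral hydroxyls: countable donors/acceptors and
  aromatic rings, emulating flavonoid-like planarity.
* `make_ribbon_crystal()` — a two-ring planar monomer with a hydroxyl donor
  and carbonyl acceptor on the tips of its lower ring, packed so that
  O–H···O=C bonds chain the molecules into ribbons along **a** while the
  rings stack along **c** (defaults: donor–acceptor 2.75 Å, stacking
  3.5 Å, inter-ribbon gap 4 Å; P1, or P-1 with `inversion = TRUE`). The
  default spacings make the hydrogen bond the strongest synthon and the
  stack second; stretching the H-bond and scaling charges down flips the
  order. Because the upper ring overhangs the H-bonding row, facets
  parallel to the ribbon expose aromatic edges while the donors sit several
  Å below the top surface — the same structure–surface link seen in
  H-bonded ribbon crystals of planar polyphenols, where the ribbon-normal
  facet is the polar, donor-rich one.
* `make_coformer_library()` / `make_propensity_table()` — libraries and
  propensity tables with planted PASS counts and positive-score counts,
  verified at construction.

These fixtures are *not* chemically accurate molecules: conformational
flexibility, realistic charge distributions, solvent, and disorder are all
absent. Passing tests therefore demonstrate the correctness of the
geometric and energetic machinery (conservation identities, oracle
equivalences, label recovery), not predictive accuracy for any particular
compound.

# Numerical choices and problem sizes

* Bond tolerance 0.4 Å; clash error below 0.5 Å interatomic.
* PEOE: 8 iterations, damping 0.5ᵏ; net charge conserved to < 1e-6 e.
* Energy tests and the acceptance script run at 12–15 Å cutoffs on cells
  of roughly 8–14 Å — small enough that a full 7³-supercell brute force is
  feasible as the oracle, while the potential terms at larger cutoffs only
  rescale totals without exercising different code paths. The shipped
  default cutoff remains 30 Å.
* Wulff validation: 3 randomized triclinic facet sets, 2×10⁶ rays each.
* Tie-breaks: ranking by |E| desc, centroid distance asc, partner id;
  termination by min |crossing energy| then min rugosity; coformer ranking
  by score desc then name.

# Known limitations

* Absolute lattice/synthon energies depend on the (unpublished) charge
  models of commercial tools; only arithmetic aggregations of *printed*
  synthon tables are reproduced exactly, and the package's own energies are
  meant for rankings and partitions.
* The attachment-energy model ignores solvent and supersaturation, so
  predicted and experimentally indexed morphologies can differ in relative
  facet areas.
* Space-group symbols beyond triclinic P1/P-1 require explicit symmetry
  xyz strings in the CIF.
* Disordered structures are rejected unless the majority-occupancy sites
  are explicitly requested.
* The propensity surrogate is a demonstration model; real screening should
  supply propensities from a trained model as the input table.
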