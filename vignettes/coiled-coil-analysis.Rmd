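---
title: "Analysing higher-order coiled-coil assemblies with ccbarrel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing higher-order coiled-coil assemblies with ccbarrel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccbarrel)
```

## Scope and model

Coiled coils (CCs) are bundles of two or more alpha-helices supercoiled
around a common axis. Their structural diagnostic is knobs-into-holes
(KIH) packing: a knob side chain from one helix inserts into a
diamond-shaped hole of four side chains on a neighbouring helix. Above
the classical dimer-to-tetramer range, CC bundles split into two broad
structural classes: *alpha-helical barrels*, with an open, continuous
central channel, and *collapsed bundles*, whose lumen is obliterated by
a consolidated hydrophobic core. Which class a given heptad sequence
adopts is driven largely by side-chain sterics — beta-branched residues
(Ile, Val) at the core positions defend the open barrel state, while
gamma-branched Leu tolerates slipped and collapsed alternatives.

`ccbarrel` provides the computational side of this analysis as a single
package: KIH detection and classification, heptad-register and
interface-type assignment, assembly-symmetry classification, lumen
profiling, sequence-threading specificity matrices, and macroscopic
stepwise pKa fitting for buried ionizable clusters. A deterministic
Crick-parameterised generator supplies idealized bundles of known
symmetry so that every stage can be validated end to end without any
external coordinate files.

## The synthetic-structure generator

The generator traces each chain's C-alpha positions on the standard
minor-helix-on-superhelix curve. Within the frame that rotates with the
supercoil, the minor helix advances exactly 2/7 of a turn per residue,
which is what locks the heptad register onto fixed azimuths (the reason
natural heptad CCs supercoil at all). Parameters, all in Angstroms and
degrees:

* `r1 = 2.26`, `rise = 1.51`: ideal alpha-helix radius and rise per
  residue.
* `resPerTurn = 3.55`: laboratory-frame helical periodicity. Together
  with the register lock this sets the superhelical frequency and gives
  a supercoil pitch angle near 12 degrees at barrel radii, matching
  deposited alpha-helical barrels. Larger values steepen the supercoil
  and eventually break the two-turn geometry of the KIH diamond for wide
  barrels.
* `r0`: superhelical radius. Defaults place adjacent helix axes ~9.2 A
  apart (`r0 = 4.6/sin(pi/n)`; 4.9 for a dimer), the packing distance at
  which side-chain centroids of facing seams fall inside the 7.4 A knob
  cutoff. Radii much below ~8 A per-interface are geometrically
  impossible for alpha-helices and are rejected.
* `phi1 = 185`: interface angle, the azimuth of the heptad *a* position
  measured from the outward radial direction. 185 degrees centres the
  *a/d/e/g* seams on the lumen; the diamond-hole recovery is stable over
  roughly 175-200 degrees, so this is not a knife-edge setting.
* `phases`, `zSlips`, `orientations`: per-chain azimuthal offsets
  (default 360k/n, giving exact Cn symmetry), axial slips (uniform
  increments produce slipped/spiral barrels), and chain directions.

Backbones (N, C, O) are completed from offsets measured once on an
ideal internal-coordinate helix, and C-beta is placed with the standard
L-amino-acid improper torsion. Models carry one side-chain-centroid
(`SCC`) pseudoatom per residue, positioned along CA->CB at a
per-residue-type distance derived from idealized extended side chains;
this is what lets KIH analysis run on models without full rotamers, and
the same convention applies to poly-Ala-like crystallographic models.

The generator is fully deterministic. What it emulates is the geometry
of designed blunt-ended, slipped, two-sheet-collapsed and docked
bundles; what it does **not** emulate is crystallographic reality —
side-chain rotamer diversity, bends and frays at helix termini, solvent,
and refinement noise. Tests passing on generator output therefore
validate the algorithms' correctness on clean geometry, not their
robustness to experimental coordinates (the reader and writer accept
deposited PDB/mmCIF files, so real structures can be analysed with the
same calls).

## Knobs-into-holes analysis

`findKnobs()` implements the classical contact definition: for each
residue on each helix, side-chain centers of every other helix within a
**7.4 A cutoff (inclusive)** are collected; with at least four in range,
the four nearest form the candidate hole, accepted when the hole residue
numbers fit the canonical two-turn diamond `{j, j+3, j+4, j+7}`. A
`relaxedHoles` flag (off by default) accepts any four residues spanning
at most seven positions, for irregular crystal geometry. Each knob's
packing angle is measured between its CA->CB bond vector and the hole
helix's local axis at the hole midpoint, and classified
**perpendicular for angles in [45, 135] (inclusive), parallel
otherwise**. Glycine knobs have no CB and stay unclassified. The choice
of the hole helix axis as the angle reference is the package's own: the
angle's geometric reference is not uniquely fixed by the packing-angle
rule itself, and this choice makes parallel-packing knobs score near 0
or 180 degrees.

Registers are assigned per helix by choosing the cyclic offset that
maximises knobs at {a, d}, tie-broken by {e, g} and then the smallest
offset; interface types follow the knob-register sets: {a,d} = Type N,
plus e or g = Type 1, {a,d,e,g} = Type 2, the two-offset-seam sets
{a,c,d,f}/{a,b,d,f} = Type 3. The donate-and-host rule (every member
helix of a component both donates a knob and hosts a hole) flags
components as coiled coils.

### Symmetry classification

`assemblySymmetry()` superposes every ordered pair of helices (residue
correspondence i -> i, as genuine homomer symmetry operations preserve
sequence register) and keeps maps with rmsd below 1.0 A. A map counts as
a point-group operation only when it carries the *whole assembly* onto
itself; this assembly-level check is essential because two ideal
single-helix chains always superpose almost perfectly, so pairwise rmsd
alone cannot distinguish a symmetric barrel from an arbitrary helix
cluster. The label is then:

* `Cn` — valid operations share one axis; order = 360 / smallest
  rotation.
* `Dn` — a principal cyclic axis plus perpendicular 2-folds.
* `screw` — no closed operation, but one map relays every helix onto
  the next along an open chain with a consistent axial translation of at
  least `slipTol` (1.0 A): the slipped/spiral barrels.
* `E` — no acceptable non-identity map (e.g. a helix docked into the
  concave face of an open arc).

Both tolerances are configuration values; the defaults classify the
generator's ideal fixtures unambiguously and leave headroom (~1 A) for
refined crystal structures.

## Lumen profiling

`barrelAxis()` takes the largest-variance direction of the pooled helix
axis points after centring each helix's points on its own centroid —
without that centring the radial ring of a wide barrel (n = 8, r0 ~ 12 A)
out-weighs the axial spread and PCA returns a perpendicular axis.
`poreProfile()` reports, at 0.5 A stations along the axis, the minimum
over atoms within a +-1.0 A slab of (radial distance - vdW radius), with
radii C 1.70, N 1.55, O 1.52, S 1.80 A. Both the vdW-subtracted and the
atom-center conventions are available because printed pore dimensions in
the literature do not always state which is meant. `poreSummary()`
reports min/max diameter over the central 70% of the span and calls the
channel open when the minimum radius exceeds 0.5 A. SCC pseudoatoms are
excluded from profiles by default so that generator models and deposited
structures are measured on the same (backbone + side chain) footing.

## Threading and the specificity matrix

`mutateOntoBackbone()` rethreads a sequence onto fixed backbone
coordinates with idealized side-chain geometry; `repack()` runs greedy
deterministic sweeps in fixed residue order, letting each residue adopt
the rotamer (chi angles from {-60, 60, 180}, at most 81 per residue)
that minimises its soft-steric interaction with all other residues,
keeping the current rotamer on ties — which both preserves symmetric
fixed points on Cn backbones and makes repacking idempotent.

Scores are reported in "points" with the soft-core form
`k ((s R - d) / (s R))^2` for pairs closer than `s R`
(R = sum of vdW radii, softness `s = 0.90`, scale `k = 100`), summed
over **inter-chain** pairs only and split evenly between the two chains.
The total score additionally rewards inter-chain apolar (C/S) pairs in a
1.5 A shell beyond contact with -1 point each, a minimal burial
surrogate. These numbers are package conventions: no fidelity to any
published force-field parameterisation is claimed, and only relative,
cognate-normalised comparisons are meaningful — which is exactly how
`specificityMatrix()` uses them. Each cell is the mean per-chain score
of a sequence on a structure minus the same sequence's score on its
declared cognate structure, so cognate cells are exactly zero, positive
cells mean a worse-than-cognate fit (steric clashes the repacker cannot
relieve), negative cells a better one. Whether intra-chain clashes
should enter the per-chain value is genuinely open; inter-chain-only is
this package's choice, keeping the matrix a pure measure of packing
*between* helices. Sequence/structure pairs with different chain lengths
are reported as missing cells rather than errors.

On the generator fixtures this machinery reproduces the expected
discrimination: a beta-branched Ile core threaded onto a narrow
two-sheet bundle (inter-sheet gap 8.6 A) scores several points worse
than on its cognate open barrel, while poly-Ala fits every backbone at
least as well as its own.

## Titration of buried ionizable clusters

A ring of x interacting acidic residues is treated as a single
polyprotic acid with macroscopic stepwise pKa values — no enumeration of
the 2^x microstates. The j-fold deprotonated fraction is

P_j proportional to 10^(sum_{i<=j} n_i (pH - pKa_i)),

normalised per pH (computed in log space; sums are exact to machine
precision). Hill coefficients n_i default to 1 and are opt-in, since a
generalised fit may or may not allow them; both modes are provided.
`transitionCurves()` gives the cumulative occupancies f_j = P(charge >= j),
which cross 0.5 at pKa_j when transitions are well separated.

`fitMacroscopicPkas()` performs least squares on the species fractions
over an ordered pKa vector (ordering enforced through a log-difference
parameterisation, the identifiability constraint for stepwise
constants), with multi-start Nelder-Mead from crossing-based initial
values plus spread-out grids, a BFGS polish, and bootstrap intervals by
resampling per-pH multinomial counts (200 resamples by default; refits
start from the point estimate). Transitions whose fitted midpoints fall
outside the pH grid are flagged unidentifiable rather than trusted.
`simulateChargeSeries()` provides the matching synthetic data: i.i.d.
multinomial draws per pH, or a sticky chain (keep the previous state
with probability rho) that preserves the marginals while emulating the
autocorrelation of constant-pH molecular-dynamics output. The package
consumes such tabulated charge-state statistics; it does not run or
parse MD itself, and desk-scale parameter recovery on simulated input —
all in-grid stepwise pKas within +-0.2 at 4000 samples per pH over pH
3.0-10.5 in 0.5 steps — is the tested claim, not reproduction of any
simulation-derived value.

## Problem sizes and numerical choices

The test suite and the acceptance script run on 4-heptad (28-residue)
chains and bundles of 2-8 helices, multinomial titrations at 4000
samples per pH over 16 pH values, and 6x6 threading matrices of
28-residue hexamers; these sizes exercise every code path while keeping
a full run in tens of seconds. Other conventions collected in one
place: knob cutoff boundaries are inclusive; ties in the repacker keep
the incumbent rotamer; helix detection uses C-alpha-only distance
criteria (d(i,i+3) in [4.5, 5.6], d(i,i+4) in [5.7, 6.7] A) so poly-Ala
models classify identically to full-atom ones; superposition enforces a
proper rotation and reports the screw decomposition of the fitted
transform; degenerate (collinear) point sets are rejected rather than
silently fitted.

## Known limitations

* The generator's bundles are idealized: no helix fraying, no loops
  between helices, no rotamer heterogeneity. Accession-grade agreement
  with deposited structures is not claimed by any test.
* The steric score is intentionally minimal; it ranks packing
  compatibility but is not an energy function, and solvation and
  entropy are outside its scope.
* Dn detection requires the perpendicular 2-folds to survive the rmsd
  tolerance; heavily distorted dihedral assemblies may report Cn.
* X-layer-style knob sub-classification is not implemented; knobs are
  parallel or perpendicular only.
* Curved or off-axis channels are not traced; the lumen model assumes a
  straight axis, which is what barrels in scope have.
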