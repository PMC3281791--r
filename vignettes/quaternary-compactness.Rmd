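---
title: "Quaternary compactness and interface analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quaternary compactness and interface analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quatstab)
```

# Scope and model

`quatstab` compares homo-oligomeric protein assemblies — the motivating
family is the tetrameric tRNA m1A58 methyltransferases (TrmI), whose host
organisms grow anywhere between 37 and 103 °C — through three kinds of
quantity: packing (volumes, cavities, surface-to-volume ratios,
contraction on assembly), inter-subunit contacts (salt bridges, hydrogen
bonds, disulfides, van der Waals contacts), and interface statistics
(buried areas, interfacing residues, hydrophobic enrichment). All of them
are deterministic functions of the heavy-atom coordinates plus a small
set of documented parameters; the only stochastic component is the
surface-patch null distribution behind the hydrophobic P-value, which is
seeded.

The underlying assumptions are the usual ones for crystal-structure
analysis: a single conformer per structure (highest-occupancy alternate
locations), no hydrogens (X-ray entries at these resolutions carry none,
so every criterion is heavy-atom and distance based), and waters and
cofactors excluded from every surface, volume and contact computation.
Assemblies are taken from the deposited biological-assembly transforms —
never guessed from crystal symmetry — and when a file already contains
four polymer chains that tetramer is used as is.

# Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| probe radius | 1.4 | Å | water-sized probe for accessible areas and cavities; 0 Å for the bare protein volume |
| grid spacing | 1.0 | Å | lattice resolution for volumes and cavities |
| sphere points | 960 | — | Shrake–Rupley samples per atom |
| salt bridge cutoff | 3.5 | Å | acidic O … basic N, strict `<` |
| H-bond cutoff | 3.5 | Å | N/O/S pairs, strict `<` |
| disulfide cutoff | 2.5 | Å | Cys SG–SG |
| vdW contact cutoff | 4.0 | Å | apolar (C, S) pairs |
| ΔASA threshold | 0.1 | Å² | per-residue drop that defines an interfacing residue |
| P-value patches | 2000 | — | null samples per interface |

Van der Waals radii are element-based Bondi values (C 1.70, N 1.55,
O 1.52, S 1.80, P 1.80, Se 1.90; default 1.70 Å for anything else).
Radii per atom *type* would change absolute areas by a few percent but
not the comparative picture; element-based radii are reproducible and
easy to state. 960 sphere points keep the discretisation error of
protein-sized atoms below about 1% (the test suite checks a 20-atom
cluster against a 10 000-point evaluation); the per-residue ΔASA
threshold of 0.1 Å² simply filters that sampling noise.

Distance cutoffs are strict inequalities, so a pair exactly at a cutoff
does not count. Atom pairs are claimed by at most one interaction kind,
in the order disulfide > salt bridge > H-bond > van der Waals; without
this precedence a 2.05 Å SG–SG pair would also be counted as a hydrogen
bond (S is a donor/acceptor) and as an apolar contact. Counting units
follow the conventions of the original inventories: salt bridges, vdW
contacts and disulfides count residue pairs (a salt bridge is *bidentate*
when two or more atom pairs concur), hydrogen bonds count atom pairs.
Because no hydrogens are present, the H-bond criterion is purely
distance-based, with only the covalent peptide C(i)–N(i+1) pair
excluded; this is deliberately permissive and is best read as a polar
proximity count, not as an angular-quality H-bond assignment.

# Surfaces, volumes, cavities

Shrake–Rupley areas use a golden-section spiral — a deterministic,
quasi-uniform point set — so repeated runs are bit-identical and the
buried-area arithmetic `BSA = ASA(A) + ASA(B) − ASA(A∪B)` is exactly
zero for non-interacting groups (identical neighbour sets give identical
per-atom areas). Interface area is reported as `BSA/2`, the per-side
convention, so one complexation event has one interface area.

Grid volumes count lattice cells whose *centers* lie inside the expanded
atom spheres. The lattice origin is snapped to multiples of the spacing
in the global frame, which makes the count exactly invariant under
lattice-vector translations and makes disjoint unions exactly additive —
the property that lets a synthetic dimer of two far-apart copies have
`Δ2 = 0` identically. Cavity detection marks the same solid cells with a
1.4 Å probe, flood-fills the exterior from the bounding box with
6-connectivity (conservative: diagonal leaks cannot merge cavities), and
reports unreachable empty components; components under 3 cells are
discarded as grid noise. Contraction deltas `Δ2 = b − 2a` and
`Δ4 = c − 4a` sit in the tens-to-hundreds of Å³ on bodies of ~10⁵ Å³:
that is at the reproducibility limit of grid methods across
implementations and settings, so only their *sign* (densification vs
loosening on assembly) is treated as a robust, comparable statement, and
the tests assert signs, not magnitudes. The surface-to-volume ratio uses
the assembly SASA over the assembly grid volume; the basis is recorded in
the report so it is never ambiguous. The per-entry monomer volume is the
mean over the assembly's chains — chains of these homotetramers differ
by well under 1 Å RMSD, so the choice of chain is immaterial, and the
mean avoids an arbitrary pick.

# Interfaces and the hydrophobic P-value

Within a four-chain assembly, the two largest area-disjoint chain pairs
are labelled tight dimers and the remaining non-negligible pairs
tetramer interfaces (pairs under 10 Å² are negligible — grid/sampling
noise scale). This reproduces the dimer-of-dimers description: the tight
pairs bury several-fold more area than the tetramer pairs.

The hydrophobic P-value asks whether an interface is more apolar than a
random surface patch of the same area. The observed statistic is the
fraction of the interface's buried area contributed by C and S atoms
(per-atom ΔASA-weighted). The null grows `n` patches, each seeded at a
uniformly chosen exposed atom and accreted over that chain's exposed
atoms in order of distance from the seed until the patch's
isolated-chain area reaches the interface area; `P` is the fraction of
patches at least as apolar as the observation, ties counting as
exceedances (so the degenerate all-apolar surface gives exactly `P = 1`,
and `P` is never 0). Distance-from-seed accretion gives compact,
contiguous patches and is a deterministic function of the seed atom,
which keeps the sampler simple and reproducible; the suite checks that
`P` is approximately uniform when the observation is itself a null draw
(mean in [0.4, 0.6] over 50 replicates). This statistic is a
re-interpretation of interface-enrichment P-values reported by
interactive services whose exact recipe is not published; numeric values
from such services are not comparable digit-for-digit, only the
qualitative ordering of interfaces is.

# Superposition and correspondence

Kabsch superposition solves the least-squares rotation via SVD with the
determinant sign corrected, so reflections can never masquerade as good
fits; inputs with fewer than three pairs or collinear geometry are
rejected. Residue correspondence between chains uses author numbering
restricted to residues resolved in both chains when the
coordinate-derived sequences are identical (the natural reading of
"equivalent Cα atoms" for identical subunits), and otherwise a global
Needleman–Wunsch alignment with affine gaps (match +1, mismatch 0, a gap
of length L costs 5 + L). The alignment is implemented in compiled code
with fixed traceback preferences (diagonal, then gap in the first
sequence, then gap in the second) so the correspondence is deterministic;
optimality is tested against brute-force enumeration of all alignments
for short sequences. Only identically-lettered aligned columns
contribute superposition pairs.

# What the synthetic generators emulate — and what they do not

The generators produce coordinate sets whose correct analysis results are
known by construction: hollow shells with a single probe-inaccessible
interior; solid clusters with none; ideal α-helices (φ = −57°, ψ = −47°,
standard bond geometry) with the canonical i → i+4 backbone O···N
pattern; two-chain complexes in which every requested interaction exists
at a mid-cutoff distance (salt bridges 3.0 Å, H-bonds 2.9 Å, disulfides
2.05 Å, apolar contacts 3.8 Å — midway placements make detection robust
to small numeric differences) and no other cross-chain pair comes near
any cutoff; and rigid or Gaussian-noise copies of chains for RMSD tests.
Each generator is a pure function of its parameters and seed, and the
planted complexes are also written and re-read through the PDB writer so
fixtures exercise the I/O layer.

These fixtures validate the *computations*, not the biology: planted
complexes have idealised geometry (isolated interaction sites, no
packing, no rotamers), pseudo-atom bodies are uniform carbon lattices,
and the helix has backbone atoms only. Passing tests therefore show the
detectors count exactly what is present at the stated cutoffs and the
geometry kernels are numerically correct; they do not show that any
particular biological interpretation of a real interface is right. The
comparative checks against deposited crystal structures are the part
that touches real data, and those run whenever the entries are present
under `inst/extdata/pdb/` (coordinate files are not redistributed with
the package).

# Numerical choices and degenerate inputs

* Alternate locations: highest occupancy wins, alphabetical alt-loc id
  breaks ties — deterministic and standard.
* Unknown elements fall back to atom-name inference with a warning;
  unknown residues map to `X` and are excluded from composition
  percentages.
* Zero-area interfaces are an error for the P-value (the statistic is
  undefined); empty neighbour queries return empty results, not errors.
* The report runner records per-entry failures (e.g. no obtainable
  tetramer) and continues, so one bad entry cannot take down a
  comparison.
* JSON report serialisation keeps full floating precision, making
  identical inputs byte-identical on disk.

# Problem sizes

The test and acceptance runs use sizes chosen to exercise every code
path at interactive speeds: 960 sphere points for real-entry areas and
240 for toy bodies; hollow shells of 6–8 Å interior radius (cavity
volumes are grid-measured at 0.5 Å or finer when the void is only a few
probe radii across, since a 1 Å grid is too coarse for a ~3 Å void);
200-residue helices for RMSD calibration; 50-seed planted-complex
recovery sweeps; 2000-sample P-value nulls (400 for the uniformity
replicates). All are package choices, stated here so that users scaling
up know which knobs move accuracy versus time.

# Known limitations

* Analytic (exact) SASA and Connolly surfaces are out of scope; areas
  carry the stated ~1% sampling tolerance.
* The H-bond detector is distance-only; angular criteria would need
  hydrogen placement.
* The vdW contact rule (4.0 Å apolar heavy-atom pairs, residue-pair
  counting) replaces what was historically done by visual inspection;
  it is a fixed documented rule, not a reproduction of anyone's eye.
* Crystallographic symmetry expansion beyond the deposited assembly
  transforms (space-group operators, NMR multi-model handling beyond the
  first model) is not implemented.
* The hydrophobic P-value's null is chain-surface based; interfaces that
  cover most of a small chain leave little surface to sample patches
  from, inflating ties.
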