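---
title: "Analysing N-degron recognition by UBR-box domains: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing N-degron recognition by UBR-box domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degronstruct)
```

## Scope

UBR-box domains are ~70-residue, three-zinc E3-ligase modules that read the
N-terminal residue (the N-degron) of substrate proteins. `degronstruct`
implements the quantitative analyses used to characterise how an atypical
UBR box recognises bulky aromatic (type-2) N-degrons through a pair of
surface phenylalanines: aromatic pi-stacking geometry and classification,
zinc coordination-sphere typing, hydrogen-bond and pocket-water censuses,
sequence-paired structural superposition, subfamily typing from a multiple
alignment, and single-site ITC / thermal-shift curve fitting. Every stage
has a seeded synthetic generator so the full pipeline is testable without
downloading structures.

## Pi-stacking geometry

For each aromatic residue (Phe/Tyr: the six-membered CG–CZ ring; His: the
five-membered imidazole; Trp: both rings, treated independently) the ring
plane is fitted by least squares: the plane normal is the smallest principal
axis of the centered ring coordinates (SVD), and the planarity RMS is the
root-mean-square perpendicular deviation. A ring pair is summarised by

* $R_{cen}$ — the distance between ring centroids (Å), and
* $\gamma$ — the angle between the two plane normals, folded into
  $[0°, 90°]$ (acute convention, so the arbitrary sign of a fitted normal
  never matters).

Contacts are classified by left-closed $\gamma$ bands:
parallel $[0°, 30°)$, intermediate $[30°, 50°)$, T-shaped $[50°, 90°]$.
The literature on stacking geometry describes these classes by instance
rather than by sharp boundaries; the 30°/50° cuts used here are consistent
with measured assignments of 44.9°/47.6° pairs to the intermediate class
and 50.8°/77.6° pairs to the T-shaped class, and both boundaries are
configurable (`pi_pi_thresholds()`). Detection uses a deliberately generous
$R_{cen}$ window of 3.0–7.0 Å; the commonly quoted "typical stacking range"
of 4.7–6.5 Å is treated as a report annotation, not a filter, so
near-boundary contacts are never silently dropped.

Pi-cation contacts test Lys NZ and the Arg guanidinium centre (mean of
NE/CZ/NH1/NH2) against every ring, with a 6.0 Å distance cutoff and an
offset angle (centroid-to-cation vector versus ring normal) cutoff of 90°
by default, i.e. no angular filter unless requested.

```{r pi-example}
m <- make_ring_pair(5.5, 50.8)
find_pi_pi_contacts(m)
```

## Crystallographic symmetry mates

Ligand peptides in these crystals are often the N-terminus of a
*neighbouring* molecule, so intermolecular contacts may cross a symmetry
boundary. `expand_symmetry()` applies the stored Cartesian symmetry
operators (PDB `REMARK 290 SMTRY` records, or fractional mmCIF operator
strings converted through the cell orthogonalization matrix) plus lattice
translations in $\{-1,0,1\}^3$, and keeps every image that brings any atom
within the search radius (default 5.0 Å) of the asymmetric unit. Copies are
flagged, labelled by operator index and lattice shift, and given distinct
chain labels, so every downstream report can state whether a contact is
intramolecular, intermolecular within the asymmetric unit, or across a
symmetry interface. Models without cell/operator information raise an
explicit error telling the user to run the contact search unexpanded.

## Zinc sites, hydrogen bonds, waters

A metal site is one metal atom plus all N/O/S donor atoms within the
coordination cutoff (default 3.0 Å — generous against Zn–S ≈ 2.3 Å and
Zn–N/O ≈ 2.1 Å first-shell bonds, but short of the second shell), sorted by
distance. The coordination pattern counts unique donor *residues* by class:
cysteine-S (`C`), histidine-N (`H`), anything else including water (`X`),
e.g. `"C2H2"` for a canonical structural zinc. Hydrogen bonds use a
heavy-atom N/O/S distance criterion (≤ 3.5 Å, > 1.8 Å to exclude covalent
pairs, same-residue pairs excluded); with crystal structures at ~1.7–2.2 Å
resolution no hydrogens are observed, so no angle term or donor/acceptor
assignment is attempted — a documented limitation. The pocket-water census
counts unique water oxygens within a cutoff (default 4.0 Å, exposed as an
option because reported "nearby water" counts are cutoff-sensitive) of an
anchor selection such as a lysine side chain.

## Superposition and subfamily typing

`kabsch_superpose()` is a standard SVD Kabsch solver with the determinant
correction that excludes reflections. `align_structures()` pairs residues by
global Needleman–Wunsch alignment (Gotoh affine gaps; BLOSUM62; gap open 10,
extension 0.5, a gap of length $L$ costing $10 + 0.5L$) of the chain
sequences and superposes the paired Cα atoms, reporting RMSD over Cα only.
Published inter-domain RMSD values depend strongly on unstated alignment
software settings (which atoms were paired, whether rejection cycles ran),
so the package treats cross-structure RMSDs as *ordering* evidence, not
equality targets; an optional iterative trim (drop pairs deviating > 2.0 Å,
repeat to convergence) mimics rejection-cycle behaviour when comparison
against such software is wanted. The default is trim-off, which is fully
deterministic.

Subfamily typing reads one alignment column: UBR boxes whose Zn2 is
coordinated by a histidine form subfamily 1 (UBR1-like), those with a
cysteine there form subfamily 2 (UBR4-like). `progressive_align()` builds
the multiple alignment with the in-package pairwise core under a UPGMA
guide tree (average-linkage clustering on pairwise identity distance), and
`classify_subfamily()` anchors the Zn2 column at a stated position of a
reference sequence and calls H → 1, C → 2, anything else unclassified.

The packaged 7-sequence fixture (`synthetic_ubr_boxes.fasta`) is a
*synthetic* UBR-box-like family: seventy-residue sequences sharing the
canonical zinc-ligand column architecture (C/C/H/H for Zn1; a cysteine
cluster for Zn2/Zn3; H at the Zn2 column in UBR1–3 and C in UBR4–7) over
divergent backgrounds with small loop indels. It exercises the alignment
and anchored-column machinery; it is not a redistribution of the real
human sequences, and passing it demonstrates the machinery, not a
biological re-derivation of the family split.

## ITC single-site isotherm

For total macromolecule $M_t$ and ligand $X_t$ in the cell after each
injection, the fraction of sites occupied solves the single-site quadratic

$$\Theta = \tfrac12\left(b - \sqrt{b^2 - 4X_t/(nM_t)}\right),\quad
b = 1 + \frac{X_t}{nM_t} + \frac{K_D}{nM_t},$$

and the heat content is $Q_i = n\,\Theta_i M_{t,i}\,\Delta H\,V_0$. Dilution
follows the total-volume-constant displacement model (each injected volume
displaces an equal volume of partially saturated cell liquid), with the
standard displacement correction
$\Delta Q_i = Q_i - Q_{i-1} + \frac{dV_i}{V_0}\frac{Q_i + Q_{i-1}}{2}$.
The model is verified in the tests against an independent mass-action
root-finding solver to $10^{-6}$.

Fitting is Levenberg–Marquardt on $(\log n, \log K_D, \Delta H,
\text{baseline})$ with multi-start over $K_D$ decades $10^{-7}$–$10^{-2}$ M
(lowest residual sum wins), first injection excluded by default (routine
ITC practice). Standard errors come from the local curvature with
delta-method back-transforms for the log-scale parameters. The Wiseman
c-value $c = n M_0 / K_D$ is reported, and fits with $c \notin [0.1, 1000]$
carry a low-confidence flag. For low-c experiments — exactly the situation
of a weak binder titrated at elevated concentrations ($c \approx 0.6$ for a
385 µM binder in a 0.225 mM cell) — stoichiometry and $K_D$ are poorly
separable, and the standard remedy of fixing $n = 1$ (`fix_n = TRUE`) is
recommended and used in the package's own recovery studies; with $n$ free
the same studies recover the median $K_D$ with a modest upward bias but
still inside the reported uncertainty.

## Thermal-shift melt curves

Melt curves are fitted with the Boltzmann sigmoid
$S(T) = S_{low} + (S_{high} - S_{low})/(1 + e^{(T_m - T)/k})$ over the
25–95 °C, 0.2 °C-step scan grid of the assay protocol. The start value for
$T_m$ comes from the smoothed-derivative maximum (a ~2 °C moving-average
window prevents single-point noise spikes from seeding the fit in a flat
region), and the derivative estimate is reported alongside the fit as a
model-free cross-check. Curves whose fitted transition amplitude is not
resolved above the residual noise, or whose midpoint sits at the edge of
the scanned range, raise an error rather than returning a meaningless
$T_m$. $\Delta T_m$ is the difference of two fitted midpoints and is
antisymmetric by construction.

## Synthetic generators and study conditions

The generators reproduce the study's measurement conditions as defaults:

* ITC: 1400 µL cell, 300 µL syringe, 5 µL injections (hence at most 60),
  at 0.05 mM protein / 1 mM peptide (standard) or 0.225 mM / 4.5 mM (the
  4.5× protocol for weak binders).
* TSA: 25–95 °C at 0.2 °C per step.
* Ground-truth binding parameters for recovery studies use the reported
  dissociation constants (e.g. 385 µM for the weak aromatic tetrapeptide at
  high concentration, 18.3 µM for the best ligand under the standard
  protocol). The reported measurements do not include the fitted enthalpy,
  so simulations use ΔH = −4000 cal/mol, a typical exotherm for
  peptide–domain binding consistent with the few-kcal/mol per-injectant
  scale of such titrations, with $n = 1$. The apo reference $T_m$ is not
  reported either; the generator uses 50 °C, mid-range for a small
  zinc-finger domain in this scan window, and the top-ligand shift of
  +12 °C defines the sample curve.
* Noise: 2% proportional Gaussian heat noise for titrations and 1% of the
  transition amplitude for melt curves, i.i.d. across points, seeded.

Problem sizes in the recovery studies — 50 titration replicates and 100
melt-curve pairs per condition — give stable medians/means while keeping
each study a few seconds of compute.

What the generators deliberately do **not** emulate: instrument drift and
injection-to-injection baseline wander, the heat of the first (partial)
injection, non-1:1 binding, aggregation above the melt transition, or real
crystal packing (the symmetry generator uses idealized operators, not a
packed lattice). Passing the recovery tests therefore shows the estimators
are unbiased under the stated noise model, not that they are immune to
instrument pathology.

Structural test fixtures are likewise synthetic: idealized benzene
(C–C 1.39 Å) and imidazole ring templates, tetrahedral zinc sites, and a
multi-chain zinc model carrying the subfamily-2 architecture (per chain: a
C2H2 site plus a bi-zinc cluster in which seven distinct cysteines
coordinate two zincs through one bridging thiolate). Users with deposited
coordinates can run the identical analyses on real structures —
`profile_structure()` accepts any PDB/mmCIF file — and the package's
reports label symmetry provenance precisely because deposited ligand
contacts may cross symmetry interfaces.

## Numerical choices and degenerate inputs

* Plane fits reject collinear point sets; ring detection skips (with a
  warning) any ring with missing member atoms rather than crashing.
* Classification bands are left-closed so boundary values are deterministic.
* Altloc handling keeps the highest-occupancy conformer, ties to altloc "A",
  giving single-coordinate geometry downstream.
* Author residue numbering is used throughout, matching how binding-site
  residues are cited in the literature.
* All cutoffs are heavy-atom distances (the relevant crystal structures
  carry no reliable hydrogens).
* Kabsch refuses rank-deficient inputs and always returns a proper rotation
  (det = +1), so mirror images superpose imperfectly instead of silently
  reflecting.
* Flat titrations return ΔH ≈ 0 with `kd_identifiable = FALSE` instead of a
  spurious constant; series shorter than 8 injections are refused.

## Known limitations

* No explicit-hydrogen H-bond geometry, protonation inference, or
  bond-valence validation of metal sites.
* No quantum-mechanical stacking energies; the three-class geometry is a
  descriptive taxonomy.
* Multi-site/competitive ITC models and raw instrument files are out of
  scope (CSV heats in, JSON out).
* Cross-structure RMSD values are comparable within this package's
  alignment settings only; they are not expected to equal numbers produced
  by other alignment software.
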