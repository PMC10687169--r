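# degronstruct

Structural and biophysical analysis of N-degron recognition by UBR-box
domains, in R.

UBR boxes are ~70-residue zinc-finger domains of UBR-family E3 ubiquitin
ligases that read a substrate's N-terminal residue (its *N-degron*). Most
UBR boxes recognise positively charged (type-1) N-termini, but one family
member binds bulky aromatic (type-2) N-termini directly through a pair of
surface phenylalanines. Characterising that recognition mode quantitatively
needs a small toolbox that cuts across structural biology and binding
thermodynamics, which this package provides:

- **Structure I/O** — PDB/mmCIF parsing (atoms via bio3d; unit cell and
  symmetry operators from the file records), deterministic atom selection,
  and crystallographic **symmetry-mate expansion**, so ligand contacts that
  cross a crystal interface are analysable and labelled by operator.
- **Pi-interaction geometry** — aromatic ring detection, least-squares ring
  planes, the pair descriptors R_cen (centroid distance) and γ (inter-plane
  angle folded to [0°, 90°]), classification into parallel / intermediate /
  T-shaped stacking (left-closed bands at 30° and 50°, configurable), and
  pi-cation detection for Lys/Arg side chains.
- **Coordination and contacts** — zinc coordination spheres typed as
  residue-class patterns ("C2H2", "C4", ...), heavy-atom hydrogen bonds,
  and pocket-water censuses.
- **Superposition** — Kabsch superposition with sequence-based Cα pairing
  (in-package Needleman–Wunsch/Gotoh, BLOSUM62) and optional iterative
  outlier trimming.
- **Subfamily typing** — progressive multiple alignment (UPGMA guide tree)
  and classification of UBR-box sequences by the Zn2-coordinating column:
  His → subfamily 1 (UBR1-like), Cys → subfamily 2 (UBR4-like).
- **Binding thermodynamics** — the single-site ITC isotherm
  (Θ from the Wiseman quadratic, total-volume-constant displacement
  dilution), Levenberg–Marquardt fitting of (n, K_D, ΔH, baseline) with
  multi-start and c-value diagnostics, and Boltzmann-sigmoid melt-curve
  fitting with ΔTm between sample and reference.
- **Synthetic data** — seeded generators for idealized ring pairs at
  prescribed (R_cen, γ), tetrahedral zinc sites from a pattern string,
  titration series and melt curves at prescribed ground truth, so every
  analysis stage has a download-free oracle.

## Worked example

Build a ring pair at a prescribed geometry, measure and classify it, then
recover a dissociation constant from a simulated titration:

```r
library(degronstruct)

m <- make_ring_pair(5.5, 50.8)     # R_cen 5.5 A, gamma 50.8 deg
find_pi_pi_contacts(m)
#>                ring_a              ring_b r_cen gamma conformation intermolecular ...
#> 1 A/PHE1/six_membered B/PHE1/six_membered   5.5  50.8     t_shaped           TRUE

z <- make_zinc_site("C2H2")
coordination_pattern(find_metal_sites(z)[[1]])
#> [1] "C2H2"

p   <- itc_protocol(cell_conc = 0.05e-3, syringe_conc = 1e-3)
ser <- simulate_itc(n = 1, kd = 18.3e-6, dh = -4000, protocol = p,
                    noise_prop = 0.02, seed = 1)
fit_itc(ser$heats, p)
#> itc_fit: n = 0.997, K_D = 1.87e-05 M (18.7 uM), dH = -4021 cal/mol, c = 2.67
```

The contact row says the two rings stack in a T-shaped conformation (γ in
the [50°, 90°] band) at a centroid separation inside the typical 4.7–6.5 Å
stacking range; the ITC fit recovers the simulated ground truth
(K_D = 18.3 µM, ΔH = −4000 cal/mol, n = 1) within the 2% heat noise.

Melt curves work the same way:

```r
ref <- simulate_melt(50, noise_sd = 0.01, seed = 2)
smp <- simulate_melt(62, noise_sd = 0.01, seed = 3)
delta_tm(fit_melt(smp$temperature, smp$signal),
         fit_melt(ref$temperature, ref$signal))
#> [1] 12.01779
```

A thin command-line front end covering profile / superpose / subfamily /
itc-fit / tsa-fit / simulate lives at
`system.file("cli/degronstruct.R", package = "degronstruct")`.

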