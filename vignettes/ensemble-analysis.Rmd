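---
title: "Conformational ensemble analysis and MM-GB(SA) energetics with mdensemble"
author: "mdensemble maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational ensemble analysis and MM-GB(SA) energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdensemble)
```

# Scope and model

`mdensemble` analyses conformational ensembles of proteins and
protein--ligand complexes the way an end-state molecular-dynamics study
does: geometric descriptors over frames, hydrogen-bond and water-bridge
occupancies, secondary-structure timelines, essential dynamics with
free-energy landscapes, grid-based pocket volumes, and single-trajectory
MM-GB(SA) binding energetics with per-residue decomposition and
computational alanine scanning. The motivating application is nuclear
receptor pharmacology -- ligand-binding domains such as that of the bile
acid receptor FXR, whose activation involves an agonist (e.g. obeticholic
acid), an LXXLL co-activator peptide, a charge-clamp residue pair gripping
that peptide, and an aromatic "activation trigger" triad stabilising the
C-terminal helix -- but every operation is generic.

Units are consistent throughout: Angstrom for lengths, kcal/mol for
energies, degrees for angles, nanoseconds for times, electron units for
charges. Atom indices are 1-based; residue numbers are stored exactly as
authored, and an optional `numbering_offset` (e.g. the +7 between rat and
human FXR numbering) is used only when *labelling* output, never applied to
storage -- silent renumbering is a classic source of bugs.

The package does not run dynamics, does not prepare structures, and does
not add hydrogens beyond the geometric reconstructions described below:
inputs lacking hydrogens fail loudly at the operations that need them.

# Input model

Structures are read from fixed-column PDB v3 (one ensemble frame per
`MODEL`), trajectories from CHARMM/NAMD 32-bit DCD. Alternate locations
resolve to the highest-occupancy conformer with ties going to altloc `A`.
Force-field parameters (partial charge, Lennard-Jones well depth and
Rmin/2, GB intrinsic radius and screening factor, van der Waals radius)
come from a whitespace-delimited table keyed by residue/atom name or by
serial; a topology is either fully parameterized or not at all, and
energetic operations check this up front. 1-2/1-3 exclusions and the
scaled 1-4 set are derived from the bond list. For inputs that carry no
connectivity, `guess_bonds()` performs distance-based perception against
covalent radii; it exists to identify donor hydrogens, not to substitute
for a force-field bond list.

Atom selections use a small grammar (`name`, `resname`, `resid` with
closed intervals `a:b`, `chain`, `element`, `water`, `protein`,
`backbone`, `calpha`, `heavy`, `hydrogen`, `het`, with `and`/`or`/`not`
and parentheses). Resolution is deterministic, idempotent, and validated
before any computation runs.

# Descriptors

Superposition uses the Kabsch SVD solution with reflection correction; a
fit needs at least three non-collinear atoms. `rmsd_series()` fits on one
selection and may measure on another, which is how backbone-fitted,
all-atom-measured series are built. RMSF is measured about the
*iteratively re-fitted* average structure (`fit_to_mean()`, tolerance
1e-6 A on the mean, at most 10 passes): this removes global
rotation/translation the same way the covariance analysis does, so
`trace(C) = sum(RMSF^2)` holds exactly. A consequence worth knowing: for
very small systems the 6 removed rigid degrees of freedom visibly shrink
fluctuations (by a factor `sqrt(1 - 6/3N)`), which is physics, not error.

SASA is Shrake--Rupley with a deterministic golden-spiral point set
(default 960 points per atom, water probe 1.4 A, Bondi radii; explicit
hydrogens, no united-atom radii). 960 points put the isolated-sphere error
well under 1%. Contact shells are measured between heavy atoms only, for
comparability with crystal structures; classification is `h-bond` if a
geometric hydrogen bond is found, else `polar` for the
S/T/N/Q/H/Y/C/K/R/D/E residue set, else `hydrophobic`, in that priority.
Distribution summaries use 100 equal-width bins by default.

# Hydrogen bonds, water bridges, salt bridges, secondary structure

A hydrogen bond requires donor--acceptor distance at most 3.5 A *and*
angle at the hydrogen (A--H--D) of at least 120 degrees; donors are N/O/S
with a covalently bound hydrogen, acceptors are N/O/S. The angle-at-H
convention is recorded in every output's metadata because the alternative
(angle at the donor heavy atom) is common enough to cause silent
disagreement between tools. Occupancy is the percentage of frames where a
pair forms at least one bond, keyed either at atom level or aggregated per
residue pair. A water bridge counts a frame only when one and the same
water is bonded to both partners in that frame; the bridging water's
identity is free to change across frames. Salt bridges use a 4.0 A
nitrogen--oxygen cutoff between the standard charged groups; the value is
a common convention (not prescribed by the motivating study) and is
configurable.

Secondary structure follows Kabsch--Sander: backbone hydrogen bonds by the
electrostatic criterion
`E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) < -0.5 kcal/mol`,
with the amide hydrogen reconstructed 1.01 A from N opposite the
preceding C=O when absent; n-turn patterns give G/H/I, bridge patterns
give E (ladders) or B (isolated bridges), then turns T and bends S
(kappa > 70 degrees), with priority H > E > B > G > I > T > S. Chain
termini are never H/E. Ladder bookkeeping is simplified (a bridge residue
with a sequence-adjacent bridge residue is E); pi-helix-specific
refinements and bifurcated bonds are out of scope.

# Essential dynamics and free-energy landscapes

The positional covariance `C_ij = <(x_i - <x_i>)(x_j - <x_j>)>` is built
over the fitted backbone (configurable) with the 1/n ensemble-average
normalization -- the `<.>` notation means the ensemble average, and at
thousands of frames the difference from 1/(n-1) is far below sampling
noise. Eigenvectors get a reproducible sign (largest-magnitude component
positive) so exported modes do not flip between runs. Projections satisfy
`var(p_k) = lambda_k` under the same 1/n convention. The DCCM uses
per-residue Calpha displacement vectors; zero-variance atoms yield NA
entries flagged in the result, and the DCCM of pure rigid motion is
deliberately undefined after fitting rather than the misleading all-ones
matrix.

The landscape is `G = -kT ln(P/P_max)` on a 50 x 50 histogram of the
first two projections (padded 1%, T = 300 K, kT = 0.5962 kcal/mol).
Empty bins are `NA` ("n/a" in exports), never a large constant: absent
sampling is missingness, not high free energy. The most populated bin has
G = 0 exactly.

Basin detection needs two numerical defences that a bare
"8-neighbour local minimum" rule lacks on sampled histograms. First, a
candidate minimum must hold at least 0.2% of the frames (at least 1), so
isolated outlier bins cannot found a basin; a single-frame grid still
reports its one occupied bin as the minimum. Second, candidates are merged
upward in G by flood fill over occupied bins within `kT` of the
candidate: Poisson wiggles around one well merge into it, while genuine
basins separated by a super-kT barrier -- or by unvisited territory --
survive. Representative frames are the frames nearest the minimum-bin
centres in projection space.

One estimator caveat, visible in the validation suite: the *difference of
minimum-bin G values* between two basins is biased by extreme-value
statistics (taking a minimum over the m core bins of a basin whose bins
hold n frames biases G downward by roughly `kT sqrt(2 ln m / n)`, about
0.25 kcal/mol for a 20% basin of a 5000-frame ensemble on a 50 x 50
grid). Basin *population* ratios (`kT ln(n1/n2)`) are unbiased and
recover a planted 80/20 two-state split to about 0.02 kcal/mol; both are
checked.

# Pocket volume

Pocket volume is measured on a cubic grid (default 1.0 A spacing) over
the union of inclusion spheres, minus exclusion spheres, minus points
within `vdw + 1.09 A` of occluding heavy atoms, optionally pruned by
6-connectivity cluster size; the defaults are the published defaults of
the grid-based pocket tool this reproduces, since the motivating study
states none. Sphere centres may be fixed points or single-atom selections
re-resolved per frame, so atom-anchored regions track the trajectory. The
default inclusion geometry for a two-anchor pocket is two 8 A spheres on
the named anchor atoms; the radius is configurable because the study
leaves it unstated. One of the study's two stated anchors ("F365") does
not appear among its own binding-site listings (F363/Y366 do), so anchors
here are always explicit configuration rather than hard-coded residues.
Ligand atoms are excluded from the occluding set by default: the quantity
of interest is cavity *capacity*, comparable between holo and apo frames;
passing an occluder selection that includes the ligand measures the
occupied cavity instead.

# MM-GB(SA) energetics

The binding free energy is the single-trajectory end-state estimate
`dG_bind = G_complex - G_receptor - G_ligand`, all three species evaluated
on the same complex coordinates of each frame, with
`G = E_int + E_ele + E_vdw + G_GB + G_np`. The entropy term is set to
zero, matching what the motivating study tabulates. Consequences: the
internal (bond/angle/torsion) terms cancel identically -- `dE_int = 0` is
asserted on every frame -- and receptor--ligand strain is not modelled.
Components are averaged with SD and `SEM = SD/sqrt(n_frames)`.

Electrostatics use `k_e = 332.0637 kcal A / (mol e^2)` and solute
dielectric 1; Lennard-Jones uses AMBER combining
(`R_ij = Rmin/2_i + Rmin/2_j`, `eps_ij = sqrt(eps_i eps_j)`); 1-4 pairs
are scaled by 1/1.2 (ele) and 1/2 (vdW); no nonbonded cutoff anywhere in
the energetics -- cutoffs belong to the dynamics engine, not to end-state
post-processing. Polar solvation is Generalized Born in the OBC-II
flavour (pairwise Hawkins--Cramer--Truhlar descreening integrals, OBC
rescaling alpha = 1.0, beta = 0.8, gamma = 4.85, intrinsic-radius offset
0.09 A, solvent dielectric 80) -- the AMBER default for this kind of
calculation, made explicit here because "GB" alone underdetermines the
model. An isolated ion with effective radius 2 A gives the Born energy
-81.98 kcal/mol exactly. Nonpolar solvation is `gamma * SASA` with
`gamma = 0.0072 kcal/(mol A^2)` and the 1.4 A probe. The
Poisson--Boltzmann branch is intentionally not implemented; the GB column
is the modelled path.

Per-residue decomposition splits every pairwise term half-and-half
between the two atoms' residues; GB self terms and per-atom SASA belong
to the owning residue. Because the split is exact bookkeeping, the ledger
sums to `dG_bind` to 1e-6 in every component separately. Residues with
total contribution at or below -0.5 kcal/mol are flagged as hot spots --
the "-0.5 kcal/mol or above" phrasing is read as *magnitude* at least
0.5, favourable, and that reading is recorded in the output metadata.

Alanine scanning recomputes `ddG = dG[wild type] - dG[mutant]` on the
same frames (no re-simulation): side-chain atoms beyond Cbeta are
deleted, Cbeta is retyped as the alanine methyl carbon whose template
charge absorbs the two implicit methyl hydrogens, and one explicit Hbeta
is placed 1.09 A along the former Cgamma direction. This single-H methyl
is a deliberate simplification -- the scan's signal is the loss of the
side chain's interactions, not the methyl's internal detail -- and the
net-charge change of the mutation is reported so charged-residue scans
can be interpreted with care. Glycine and proline are refused; mutating
alanine is the identity (with a warning). Negative `ddG` means the wild
type is more favourable; scans flag `|ddG| > 1 kcal/mol`.

# Synthetic ground truth: what it does and does not show

Every stage is validated against generators whose answers are known by
construction, all pure functions of their seed: Gaussian ensembles with
prescribed (full, diagonal, or low-rank) covariance; two-state mixtures
with prescribed populations and within-state width; scripted
donor--H--acceptor and water-bridge geometries hitting a target occupancy
in exactly `round(occupancy * n)` frames; a parameterized toy
receptor--ligand complex (a row of serine-like residues with one strongly
charged, ligand-facing "hot spot") with closed-form reference energies;
and ideal helix / type-II'-turn hairpin backbones built from canonical
dihedrals by internal-coordinate chaining.

Default problem sizes are chosen so that estimator noise, not cost,
dominates: 5000 frames for covariance/landscape recovery (eigenvalue
error a few percent, planted-subspace principal angles well under a
degree), hundreds of frames for occupancy scripts, tens of frames for
energetic averages whose per-frame values are exact to 1e-9 against
brute-force summation.

These fixtures emulate the *statistical structure* the analyses assume --
Gaussian fluctuations, basin mixtures, geometric bond criteria,
pairwise-additive energetics -- and none of the things that make real
trajectories hard: anharmonicity beyond two states, correlated solvent,
force-field error, incomplete sampling, protonation ambiguity. Passing
tests therefore demonstrate that the estimators are implemented correctly
and recover planted truth under their own assumptions, not that any
particular biological conclusion is right.

The study this package is patterned on reports numbers from triplicate
500-ns explicit-solvent trajectories of the FXR ligand-binding domain in
four binding states; reproducing those requires the original trajectories
and is out of scope at desk scale. Its crystal-structure worked examples
(backbone RMSD of the two experimental LBD structures, the ligand's
five hydrogen-bonding residues, rat/human sequence identity) are
implemented as operations and wired into the validation suite, which
checks them whenever the two PDB entries are present locally; the entries
are not redistributable with the package, so in an offline checkout that
battery reports itself as unsatisfied rather than silently passing.

# Pipeline and reproducibility

`run_pipeline()` executes a config (R list or YAML) in dependency order --
fit, descriptors, hydrogen bonds, secondary structure, essential dynamics
and landscape, pocket, energetics, alanine scan -- after validating every
selection up front (fail-fast: a typo aborts before any compute). Each
stage writes a TSV; a JSON manifest records the package version, the full
config including defaults actually applied, the seed, and an md5 checksum
per file, so a run is auditable and a rerun is byte-identical.
`compare_systems()` aligns the metric tables of several runs against a
designated reference. Frame windows and strides are explicit parameters
echoed into the manifest, because "the stable part of the trajectory" is
not a reproducible specification. The numbered scripts under `analysis/`
are thin narrative drivers over these functions and write their outputs
under `results/`.

# Known limitations

No PB solvation, no entropy estimates, no separate-trajectory MM-GBSA, no
mmCIF/PSF/PRMTOP parsing, no hydrogen addition or protonation assignment,
no pocket *detection* (regions are declared, not found), simplified DSSP
ladder bookkeeping, a one-hydrogen alanine methyl, and energetics that
scale as O(N^2) pairs per frame -- appropriate for the end-state
post-processing sizes it targets, not for whole-solvent boxes.
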