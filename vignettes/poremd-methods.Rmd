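---
title: "Permeation, gating and electrostatics analysis of K+ channel trajectories"
author: "poremd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permeation, gating and electrostatics analysis of K+ channel trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poremd)
```

# Scope and model

`poremd` post-processes molecular-dynamics trajectories of small
tetrameric potassium channels. The biological picture is the canonical
one: a selectivity filter whose backbone carbonyl oxygens form a stack
of ion-coordination cages (sites S0 at the extracellular mouth down to
S5 at the cavity), through which K+ ions and waters move in single
file; occasional reorientation of individual carbonyls toward the pore
helices disrupts the sites and is a candidate mechanism for fast
gating; and a transmembrane voltage whose spatial profile determines
how much charge each ion hop transfers.

All analyses operate on two containers: a `topology` (atoms with
residue/subunit membership, partial charges and coarse group labels)
and a `trajectory` (per-frame coordinates in Å with orthorhombic box
lengths). Frames are superposed by a least-squares rigid (Kabsch) fit
on a user-chosen selection, and a single global transform maps the
selection's principal axis to +z with the intracellular side at low z.
Every downstream geometric quantity (site slabs, radial distances,
axial profiles) inherits this convention. The superposition is
idempotent, and RMSD is computed after it, so the reference frame has
RMSD 0 by construction.

# Binding-site occupancy and transport bookkeeping

A binding site is realized as the z-slab between the mean heights of
its lower and upper four-oxygen planes, intersected with a cylinder of
radius `radial_cutoff` (default 3 Å) around the pore axis. The
coordinating-oxygen definition fixes the axial extent; the lateral
extent of the coordination volume is not derivable from the oxygen
positions alone, so it is an explicit parameter, as are the cavity
radius (default 5 Å) and the S0 upper bound (a +3.1 Å offset above the
top plane, which has no second plane above it). A particle exactly on
a shared plane is assigned to the lower site (a deterministic
tie-break; the alternative — duplicating or randomizing boundary hits —
would break the partition property that every particle has exactly one
label per frame).

Occupancy is the plain indicator average
$f_i = \sum_k w_{k,i} / N$ over frames and tracked particles. It is
deliberately not capped at 1: if two ions co-occupy a site the formula
counts both, so occupancies are interpretable as mean particle counts
per site.

Configuration strings render the S1–S5 state per frame with ion
presence taking precedence over water (`S2` beats `W` beats `0`).
Permeation events are counted by a per-particle state machine: an
outward event requires the sequence cavity → filter sites →
extracellular with no cavity revisit in between (mirrored for inward
events); an excursion to bulk — leaving the pore laterally — cancels a
pending traversal. Counting is therefore invariant to any frame
subsampling that preserves the state-change frames. The inferred
current is $I = n\,q/t$ reported in pA.

# Carbonyl orientation and gating

Each carbonyl is described per frame by two coordinates: the
(C, Cα, N, O) dihedral (IUPAC sign convention, verified against
`bio3d::torsion.xyz`) and the radial distance of the carbonyl oxygen
from the pore axis. The two-dimensional descriptor cloud is clustered
with DBSCAN (implemented in-package; core points count themselves,
matching the scikit-learn semantics). Two preprocessing decisions
matter and are worth stating:

- **Standardization.** Degrees and Ångströms are incommensurate, so
  each coordinate is divided by its standard deviation before distances
  are computed. `eps` (default 0.5) and `min_samples` (default 10) are
  therefore expressed in standardized units. A consequence of
  standardizing is that a *single* isolated cluster is rescaled to unit
  spread, and its sparse tails can legitimately fall below the core
  density threshold; the clusterer then reports one cluster plus a few
  noise points, which is correct DBSCAN behavior rather than a failure
  to converge.
- **Circularity.** The dihedral lives on a circle; clusters straddling
  ±180° must not be split. Points are replicated at ±360° before
  clustering and the labels folded back, merging any clusters that
  share a replica of the same point.

Clusters are named by the nearer of two reference anchors
(pore-facing / helix-facing) in the same standardized space, with the
dihedral distance computed circularly. With real data the anchors
should be measured from conductive-state reference structures of
K+-selective channels; the packaged defaults are the synthetic
scaffold's own two states and exist so the pipeline is self-contained.
Clustering is done per (residue, subunit) pair by default — matching
how per-subunit orientation traces are usually presented — with pooling
available as a flag.

A *flip* is a state change between the two named states of one
carbonyl; the coincidence analysis pairs each flip with the
nearest-in-time ion site-change and reports the fraction within a
user-chosen window (default 1 ns).

# Grid electrostatics and the electrical distance

Point charges are spread onto a periodic grid (default 1.5 Å spacing)
with cloud-in-cell deposition, the deposition window is deconvolved in
reciprocal space, and a spherical Gaussian of width
$\max(\sigma, h/2)$ is applied, where $h$ is the voxel size. The clamp
exists because a Gaussian much narrower than the grid is not
representable; the nominal default σ = 0.15 Å therefore behaves as a
0.75 Å Gaussian on the default grid, and the clamp is recorded in the
field metadata. Total gridded charge equals the sum of input charges to
machine precision. Poisson's equation ∇²Φ = −4πρ is solved spectrally
with periodic boundaries, the k = 0 mode removed (uniform neutralizing
background) and a zero-mean gauge. Internally the potential is carried
in units of e/Å and converted with 1 e/Å = 14 399.645 mV.

One mesh caveat: cloud-in-cell deposition is first-order accurate in
the sub-voxel offset of a charge, so potential readings in the one or
two voxels adjacent to a point source carry a percent-level,
offset-dependent error. All profile quantities in the package (cylinder
averages, bulk anchors) are read away from source sheets, where the
solver agrees with direct structure-factor summation and with the
single-Gaussian closed form to better than 1%.

The electrical-distance profile is built from two frame-averaged
potential fields — one under applied voltage, one reference — as the
cylinder-averaged (default radius 5 Å) axial profile of their
difference, normalized so that the intracellular-bulk mean is 0 and the
extracellular-bulk mean is 1. Normalizing by the *measured* bulk-to-bulk
drop, rather than the nominal applied voltage, keeps δ well-defined
when the imposed and realized drops differ slightly (grid smearing,
incomplete plateaus). The anchor is the intracellular bulk,
consistent with flat δ in the cavity and C-terminal regions. The gating
charge between two charge configurations is
$Q = \sum_i q_i\,[\delta(z_i^{(2)}) - \delta(z_i^{(1)})]$ with δ
linearly interpolated in z; it telescopes exactly along any path, and a
full bulk-to-bulk traversal of a unit charge carries 1 e.

## The voltage-plate fixture

The synthetic voltage system deserves a note, because the obvious
construction is wrong. Two oppositely charged planes in a periodic box
cannot produce flat bulk potentials: the line integral of the field
around the periodic cell must vanish, so the drop across the slab is
necessarily returned through the surrounding solvent region, which
then has a nonzero field everywhere. Real membrane simulations do not
show this because electrolyte screening (or the applied-field method's
charge redistribution) concentrates the return path at the system
edges. The fixture reproduces that physics explicitly: a second,
compensating plate pair hugs the periodic boundary (2 Å apart by
default) and carries the full counter-drop, leaving the two bulk
regions strictly field-free and the slab interior uniform. The
resulting analytic profile — 0 in the intracellular bulk, linear across
the slab, 1 in the extracellular bulk — is the closed form the solver
is validated against (within 0.02 everywhere outside the plate
neighborhoods, and ±0.01 at the bulk anchors).

# Lipid interface

The occupancy map marks a voxel (default 1 Å) in a frame when any
lipid atom center lies within `atom_radius` (default 1 Å) of the voxel
center, and averages the marks over sampled frames; values are
fractions in [0, 1], invariant to frame order, and thresholding at
0.15 highlights persistently occupied regions. Per-residue contacts
count lipid atoms within a cutoff of any residue atom, reported as
per-frame mean and maximum. The 1 Å default cutoff is unusually tight —
it registers near-overlap contacts only — and is kept for fidelity with
the analysis it reimplements; it is surfaced prominently in the
configuration and should be widened (3–4 Å) for conventional contact
definitions. Counts are monotone non-decreasing in the cutoff.

# Blocker affinity

Binding free energies convert to inhibition constants via
$K_i = e^{\Delta G / RT}$ (R = 8.3145 J K⁻¹ mol⁻¹, T = 298.15 K), with
the exact inverse provided; the round trip is exact to 1e-12 relative.
The packaged five-blocker table (amantadine, TEA, rimantadine, sotalol,
bretylium tosylate) stores dimensionless predicted and experimental
K<sub>i</sub> values. The predicted-vs-experimental Pearson correlation
is computed on log10 K<sub>i</sub> by default: the correlation on the
raw K<sub>i</sub> scale is dominated by the largest values (R ≈ 0.43 on
this table) and does not reflect the free-energy-scale agreement,
whereas log K<sub>i</sub> is affine in ΔG, giving R = 0.874 here —
identical to the correlation of the ΔG values themselves. The linear
scale remains available as an option.

# Synthetic systems: what they emulate and what they do not

The generators are pure functions of their parameters and a seed, and
every generated dataset ships its planted ground truth:

- `make_filter_scaffold()` builds an idealized four-fold filter: six
  square oxygen cages (radius 1.4 Å) at planes 3.1 Å apart — canonical
  K+-filter dimensions — with a backbone template whose CA–N bond runs
  tangentially, so rotating a carbonyl about it (a "flip") swings the
  oxygen away from the axis exactly as a filter carbonyl reorientation
  does. The lowest plane is a threonine-like hydroxyl oxygen.
- `script_trajectory()` moves ions/waters between site centers
  instantaneously per a hop schedule, plus isotropic Gaussian jitter.
  Step-like traces approximate the hop-and-dwell character of real
  conduction; they contain no gradual transitions, so the analyses are
  required to be robust to discontinuous traces but are not exercised
  on diffusive ones.
- `make_plate_capacitor()` — the voltage fixture above.
- `make_toy_bilayer()` plants one lipid whose head atom is held within
  1 Å of a target residue in ≥95% of frames while free lipids drift
  laterally, so persistent binding is separable from transient
  contact by the 0.15 occupancy threshold.
- `make_planted_clusters()` draws labeled Gaussian blobs in
  (dihedral, radius) space for clustering tests.

Because jitter is isotropic Gaussian and hops are instantaneous, a
passing test suite demonstrates the correctness of the bookkeeping and
numerics, not the behavior of the analyses under correlated thermal
noise, force-field artifacts, or slow conformational drift — those
require real trajectories.

# Problem sizes and numerical choices

The test suite and demo run on deliberately small systems: 100-frame
scripted trajectories, 20-residue scaffolds, 16–40³-voxel grids, and
250-frame potential averages — sizes chosen so each property is
exercised meaningfully while the whole suite completes in minutes on a
laptop core. Key numeric decisions: per-frame truncation before
averaging in the contact map (bounded-distance semantics); slab
tie-breaks to the lower site; Gaussian width clamped to half the voxel
size; tin-foil (neutralizing background) boundary with zero-mean gauge
in the Poisson solve; degenerate normalizations (zero applied voltage,
equidistant orientation anchors, zero-variance correlations) raise
errors rather than returning silently wrong numbers.

# Known limitations

- Orthorhombic boxes only; no dielectric continua or
  Poisson–Boltzmann screening in the solver.
- XTC trajectories are not read (DCD and multi-MODEL PDB are); write
  support is multi-MODEL PDB.
- The per-pair clustering default can starve on very short
  trajectories (fewer points than `min_samples`); pooling across
  subunits is the intended remedy.
- Reference orientation anchors must be supplied for real proteins;
  the packaged anchors describe the synthetic scaffold only.
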