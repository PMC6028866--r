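# poremd

Analysis toolkit for molecular-dynamics trajectories of small tetrameric
potassium channels — the class of analyses used to characterize ion
permeation, filter gating and voltage sensing in viral K+ channels such
as Kcv. The package implements the full post-processing layer:

- **Structure/trajectory handling** — PDB/GRO structures (with a partial
  charge sidecar), DCD and multi-MODEL PDB trajectories, least-squares
  (Kabsch) superposition with a fixed pore-axis convention (+z, low z =
  intracellular), per-frame RMSD, and trajectory-averaged residue
  contact maps (minimum inter-atomic distance, truncated at 1.5 nm).
- **Filter transport** — binding sites S0–S5 defined by their eight
  coordinating carbonyl oxygens; per-frame ion/water site assignment;
  the occupancy statistic *f<sub>i</sub>* = Σ<sub>k</sub>
  w<sub>k,i</sub> / N (w<sub>k,i</sub> = 1 when ion k is inside site i);
  configuration strings such as `{W,S2,W,S4,S5}`; permeation-event
  counting; and the inferred single-channel current *I = n·e / t*.
- **Carbonyl gating** — per-residue (C, Cα, N, O) dihedral and
  carbonyl-oxygen radial distance, DBSCAN clustering of the 2-D
  descriptor into pore-facing vs helix-facing states, and a
  flip/ion-relocation coincidence analysis.
- **Electrostatics** — Gaussian charge spreading on a grid, a periodic
  spectral Poisson solver (∇²Φ = −4πΣρ), frame-averaged potential maps,
  the electrical-distance profile δ(z) = ∂Φ/∂V normalized to 0/1 at the
  intracellular/extracellular bulks, and gating charges
  Q = Σ q<sub>i</sub> Δδ<sub>i</sub>.
- **Lipid interface** — time-averaged volumetric lipid occupancy maps
  (VolMap-style) and per-residue lipid contact counts.
- **Blocker affinity** — K<sub>i</sub> = e^(ΔG/RT) conversion and the
  predicted-vs-experimental correlation for channel blockers, with the
  five-blocker table packaged as a fixture.

A seeded synthetic-system module (filter scaffolds, scripted ion-hop
trajectories, parallel-plate voltage systems, toy bilayers, planted
cluster sets) generates every input the pipeline needs, so the whole
analysis chain runs end-to-end without an MD engine and every statistic
can be validated against planted ground truth.

## Worked example

```r
library(poremd)

## blocker affinities: log-scale Pearson R between docking and experiment
affinity_correlation(affinity_table("table3"), scale = "log")
#> [1] 0.8741195

## current inferred from 2 permeation events in a 344 ns trajectory
inferred_current(2, 344)
#> [1] 0.931498        # pA, ~1 pA

## electrical distance on a 500 mV parallel-plate system, 1.5 A grid
cap  <- make_plate_capacitor(c(30, 30, 60), c(20, 40), target_drop = 500)
grid <- grid_spec(cap$charged$box, spacing = 1.5)
prof <- electrical_distance(
  solve_poisson(spread_charges(cap$charged,   grid, sigma = 0.15)),
  solve_poisson(spread_charges(cap$reference, grid, sigma = 0.15)),
  cylinder_radius = 5, bulk_intra = c(4, 16), bulk_extra = c(44, 56))
prof$delta[prof$z == 51]      # extracellular bulk reading
#> [1] 1.000278
gating_charge(prof, data.frame(charge = 1, z = 10),
                    data.frame(charge = 1, z = 50))
#> [1] 1.000278       # e transferred by a full traversal

## end-to-end synthetic demo (all stages, outputs + provenance JSON)
run_demo(output_dir = "poremd_demo", seed = 1)
```

The demo writes RMSD and contact-map CSVs, per-site occupancies,
configuration-string timelines, permeation events, carbonyl orientation
series, the δ(z) profile, lipid occupancy (OpenDX) and contact tables,
the affinity table, and a JSON provenance block per stage.

The interpretation of the numbers above: an affinity correlation of
0.87 indicates the docking ranking tracks experiment on the
free-energy (log K<sub>i</sub>) scale; 0.93 pA is the single-channel
current equivalent of two complete outward K+ translocations in 344 ns;
and a δ value of 1.00 in the extracellular bulk confirms the entire
applied voltage drops across the membrane slab, so a charge crossing it
transfers exactly one elementary charge across the field.

A thin command-line wrapper is included at `inst/scripts/kcv.R`:

```sh
Rscript inst/scripts/kcv.R run --config inst/extdata/demo_config.yaml
Rscript inst/scripts/kcv.R demo --out poremd_demo --seed 1
```

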