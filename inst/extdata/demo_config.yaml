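# End-to-end synthetic demo: scripted conduction trajectory, carbonyl
# flip, parallel-plate voltage pair, toy bilayer, packaged blocker table.
seed: 1
output_dir: poremd_demo
stages: [core, transport, gating, epot, lipids, affinity]
synthetic:
  n_frames: 100
  jitter_sd: 0.2
  n_lipids: 8
core:
  n_samples: 100
transport:
  radial_cutoff: 3.0
  cavity_radius: 5.0
  dt_ns: 0.1
gating:
  eps: 0.5
  min_samples: 10
  window_ns: 1.0
epot:
  spacing: 1.5
  sigma: 0.15
  cylinder_radius: 5.0
  target_drop_mV: 500
lipids:
  voxel: 1.0
  atom_radius: 1.0
  cutoff: 1.0
  threshold: 0.15
affinity:
  table: table3
  scale: log
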