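# Example analysis configuration.
#
# Paths are resolved relative to this file's directory unless absolute.
# For a real system, point `topology` at a PDB file and `trajectory` at one
# or more DCD / multi-model PDB files, and replace the domain map with
# `domains: spycas9` (or your own ranges).
input:
  topology: topology.pdb
  trajectory:
    - traj.pdb
  dt_ns: 1.0

# Named residue ranges (1-based, inclusive, author numbering).
domains:
  BLK1: {chain: A, ranges: [[1, 3]]}
  BLK2: {chain: A, ranges: [[4, 6]]}

# Monitor definitions. Types: distance (two selections, centroid-based),
# salt_bridge (acidic/basic residue ids), contact (residue vs partner
# selection). A selection is {chain, resno, elety}; nucleic-acid conventions
# (e.g. the scissile phosphate at target-strand position -3) are expressed
# here as a concrete {chain, resno, elety: P} entry.
monitors:
  - id: d12
    type: distance
    a: {chain: A, resno: 1, elety: CA}
    b: {chain: A, resno: 6, elety: CA}

# Generalized-correlation parameters.
gc:
  k: 4
  stride: 1
  threshold: 0.6
  normalization: pairs

pca:
  n_modes: 2

# Optional analysis window, fractions of the trajectory, half-open.
# frame_window: [0.75, 1.0]

seed: 7
output_dir: out
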