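# Reference run configuration.  Every tunable threshold is explicit;
# copy and edit rather than relying on implicit defaults.
#
# Structures are either coordinate files ...
#   - label: 4COF
#     path: pdb/4cof.pdb
#     format: pdb            # or mmcif
#     assembly: deposited    # provenance note: asymmetric unit vs assembly
# ... or synthetic generator recipes (no files needed):
seed: 1
output: plgicmap-run
structures:
  - label: BASE
    synthetic:
      seed: 1
      plant: {site_class: 1, chains: [A, B]}
  - label: STATE-A
    synthetic: {seed: 1, noise_sd: 0.15}
  - label: STATE-B
    synthetic: {seed: 1, twist: 28, tilt: 9, noise_sd: 0.15}
alignment:
  # aligned FASTA + anchor sidecar; omit to use the synthetic generator's
  # own alignment when every structure is synthetic
  fasta: null
  sidecar: null
analyses:
  atlas:
    cutoff: 6.5              # 4.0 on real structures, 6.5 on Ca-only fixtures
    vestibule_radius: 8
  rmsd:
    mode: alignment          # or structural
    pentamer: true
  grouping:
    threshold: 2.5           # Angstrom, single-linkage cut
  geometry:
    interface: {plus: A, minus: B}
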