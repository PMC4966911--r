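# Default configuration for the headbem command-line entry points.
# Radii and mesh levels define the built-in layered-sphere surrogate head;
# all randomness derives from `seed`.
version: 1
seed: 1
output_dir: headbem-out
geometry:
  radii: {pial: 78, inner_skull: 81, outer_skull: 87, scalp: 92}   # mm
  ref_levels: {pial: 4, inner_skull: 4, outer_skull: 3, scalp: 3}  # icosphere levels
sensors:
  n_electrodes: 256
  n_magnetometers: 102
  helmet_radius: 120    # mm
verify:
  levels: [2, 3]
  methods: [LC, LG]
  modalities: [EEG, MEG]
  K: 50
  n_sources: 50
  tolerance: {EEG: 0.1, MEG: 0.02}
study:
  modality: EEG
  method: LG
  K_ref: [20, 30, 40, 50, 60, 70, 80]
  K_test_3s: [20, 30, 40, 50, 60, 70, 80, 90, 100, 110, 120, 130, 140, 150, 160, 170]
  n_sources: 200
forward:
  kind: 4C
  K: 50
  method: LC
  modality: EEG
  n_sources: 100
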