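# Example run configuration. Any key may be omitted; omitted keys take the
# study defaults (see ?default_run_config). Units: lengths in shell radii,
# moduli relative to the epithelium, pressure negative for inflation.
geometry:
  shell_length: 4
  shell_thickness: 0.3
  n_rings: 5
  n_longitudinal: 8
  band_width: 0.25
  band_thickness: 0.15
  target_edge_length: 0.2
materials:
  epithelium: {E: 1.0, nu: 0.3}
  muscle: {E: 10.0, nu: 0.3}
program:
  g_target: 2.0
  p_target: -0.2
  n_increments: 20
scenario: growth_only
seed: 1
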