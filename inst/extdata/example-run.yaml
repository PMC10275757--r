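# Example sonosim pipeline configuration.
stages: [retina, licks]
preset: 15MHz
seed: 11
out_dir: sonosim-run
overrides:
  n_cells: 400
  spontaneous_lick_rate: 0.8
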