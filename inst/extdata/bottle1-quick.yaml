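# Example run configuration: small bottle, short warming, coarse mesh.
scenario:
  preset: bottle1
solver:
  dt: 0.2
run:
  end_time: 60
  sample_interval: 10
  target_cells: 1200
  out_dir: milkwarm-out
  snapshot_interval: 30
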