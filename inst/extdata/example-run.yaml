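# Example run configuration; any key omitted falls back to default_config().
cohort:
  n_healthy: 5
  n_inph: 2
  master_seed: 1
  mesh_h: 3.0
registration:
  backend: analytic     # or "demons"
rom:
  d_values: [2, 4, 6]
  subsets: [full]
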