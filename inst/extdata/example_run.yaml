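# Example run configuration for `epifold tissue`.
# Unset keys fall back to default_run_config(); every assumption the model
# leaves open is overridable here.
tissue:
  n_rings: 2          # 19-cell patch
  layout: concentric
  boundary_mode: free
numerics:
  n_nodes: 128
  dt: 0.1
  rd_dt: 0.1
  record_every: 100
coupling:
  c_o: [0.2, -0.8, 2.0, 2.0]
  sigma: 0.0
perturbation:
  cells: initiating
  P_total_factor: 0.9
duration: 2500
seed: 1
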