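# end-to-end demo: conjunctive-truth samples at study-like scale
output_dir: cdm_output_conjunctive
theta_grid: {min: -4.0, max: 4.0, count: 61}
quad_nodes: 21
item_fit_alpha: 0.05
screen: false
lsdm: {constrained: true, epsilon: 1.0e-6}
simulation:
  model: conjunctive
  n_items: 18
  n_fit: 600
  n_cv: 600
  max_weight: 2
  seed: 20251
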