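# Archive-like synthetic experiment: 20 lakes with heavily skewed counts,
# planted near-linear band-ratio distortion, blue-green skew, adjacency
# noise and flag contamination. Bootstrap sizes are the generator defaults
# scaled to a desk-top run; set tuning: {} for the full 10,000 replicates.
seed: 1
algorithms: [oc2, oc3, gilerson, gons05, turbidity]
turbidity_band: b708
synthetic: {}
tuning:
  n_replicates: 200
per_lake: [oc2]
oc2_scaling: true
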