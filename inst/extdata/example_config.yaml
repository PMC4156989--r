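# Example configuration: fully simulated small run.
seed: 42
stage: early
deg_alpha: 0.005
ora_alpha: 0.05
es_max: 0
cmap_p_max: 0.1
ma_p_max: 0.05
het_p: 0.1
weighted: true
simulate:
  expression:
    n_genes: 150
    n_pairs_per_batch: [6, 8]
    effect_mean: 2.5
    noise_sd: 0.8
  drug_scores:
    n_drugs: 15
    true_rho: [-0.6, -0.6, -0.6, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0]
    n_instances: 10
    tau2: 0.02
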