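# Demo analysis: synthetic three-kingdom community, 27 samples in a 7/12/8
# inundation design, four planted cross-kingdom modules, CH4 flux linked to
# module 1. Sequencing depth is scaled to ~10 reads per OTU so the simulated
# tables keep the presence/absence sparsity that Jaccard-based statistics
# need.
synthetic:
  n_otus: {prokaryote: 120, fungus: 40, cercozoa: 40}
  n_modules: 4
  rho_within: 0.9
  n_samples: 27
  depth: {prokaryote: 1200, fungus: 400, cercozoa: 400}
  group_sizes: {IL: 7, IM: 12, IH: 8}
rarefaction_depth: {prokaryote: 1200, fungus: 400, cercozoa: 400}
min_prevalence: 0.8
# per-kingdom thresholds sit above the n = 27 noise-correlation scale
# (~2/sqrt(n) ~ 0.4) but below the depth-attenuated planted correlations
thresholds: {prokaryote: 0.55, fungus: 0.55, cercozoa: 0.55}
# slightly below the paper-scale 0.85 default: at the demo's scaled-down
# sequencing depth, multinomial noise attenuates the planted correlations
interdomain_threshold: 0.80
robustness_replicates: 100
removal_fraction: 0.5
permutations: 999
seed: 1
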