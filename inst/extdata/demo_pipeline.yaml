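# Demonstration pipeline configuration (small, fast).
seed: 11
n_individuals: 5000
horizon: 2025
n_replicates: 2
scale_factor: 100
report_years: [2015, 2020, 2025]
healthexp_years: [2015, 2025]
condition_set: diseases_only
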