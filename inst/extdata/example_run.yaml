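# Example pipeline configuration. Point core_csv at a core table (see
# simulate_scenario() for the schema) and pass this file to run_budget().
core_csv: core.csv
microform: hummock
em_hg0: nh_atmospheric_hg0
em_hgII: nh_rainfall_hgII
period: [1800, 2020]
E199: 0.49
runoff: 0.0
n_draws: 100000
mc_policy: clip
seed: 1
H_cc: 0.25
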