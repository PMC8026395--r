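# Demonstration pipeline configuration: simulate MLH1 and MSH2 cohorts with
# the default calibrated hazards and build the full table set.
genes: [MLH1, MSH2]
n: 50000
seed: 42
output_dir: lynchrrs-output
survival_source: estimate
combined_censoring: both-organs
min_py: 10
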