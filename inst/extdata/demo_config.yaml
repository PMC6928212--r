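# Demonstration configuration: a reduced-size run of all four stages that
# completes in about half a minute on one CPU.
seed: 20191223
n_lines: 100
n_trials: 3
n_permutations: 300
bsa_populations: 2
panel_lines: 60
snp_density: 120
n_rare: 40
min_ratio: 0.66
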