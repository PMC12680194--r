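# Reduced-scale experiment grid: runs in minutes on a laptop and recovers
# the qualitative trends of the full-size study.
family: erdos_renyi
"n": 2000   # quoted: bare n is YAML-1.1 boolean false
mean_degree: 5.0
J1_values: [-2, 0, 2]
J2_values: [-2, 0, 2]
realizations: 20
budget_sweeps: 200
percolation_modes: [random_edge]
percolation_runs: 50
threshold_x: 0.01
master_seed: 1
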