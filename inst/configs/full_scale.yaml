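# Full-size study conditions. Long-running (days of CPU time): each of the
# 100 realizations runs 1e4 * M Metropolis proposals per chain over a
# 5 x 5 coupling grid.
family: powerlaw_configuration
"n": 20000   # quoted: bare n is YAML-1.1 boolean false
gamma: 2.5
k_min: 2
# k_c defaults to the structural cutoff floor(sqrt(n)) = 141
J1_values: [-2, -1, 0, 1, 2]
J2_values: [-2, -1, 0, 1, 2]
realizations: 100
budget_sweeps: 10000
percolation_modes: [random_edge, random_node, targeted_degree]
percolation_runs: 100
threshold_x: 0.01
master_seed: 1
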