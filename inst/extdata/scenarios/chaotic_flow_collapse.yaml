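# Chaotic-flow chain-compaction recovery scenario: replicate R_G(t) traces
# on the 69 microsecond - 17 ms observation window, collapse+growth fits.
scenario: chaotic_flow_collapse
seed: 1
noise_level: 0.02
params:
  n_replicates: 100
  kinetics:
    R_base: 26.0        # angstrom
    A_collapse: 2.0     # angstrom
    tau_collapse: 470.0e-6   # seconds
    A_growth: 3.0       # angstrom
    tau_growth: 36.0e-3      # seconds
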