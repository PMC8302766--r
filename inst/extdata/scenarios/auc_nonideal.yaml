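# Nonideal non-associating sedimentation isotherm: kS recovery.
scenario: auc_nonideal
seed: 1
noise_level: 0.02
params:
  s1: 2.0     # Svedberg
  kS: 28.0    # mL/g
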