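# Two-step isodesmic self-association isotherm: weak dimerization followed
# by more favorable additions; model discrimination against plain isodesmic
# and Gilbert boundary modality.
scenario: auc_two_step
seed: 1
noise_level: 0.02
params:
  K2: 0.02    # per (mg/mL)
  K_iso: 0.6  # per (mg/mL)
  s1: 2.0
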