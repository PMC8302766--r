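# Single-component FCS in dilute and dense phases: diffusion-time ratio
# as the apparent-viscosity proxy.
scenario: fcs_dilute_dense
seed: 1
noise_level: 0.02
params:
  dilute: {G0: 1.0, tau_D: 0.2e-3, kappa: 5.0}
  dense:  {G0: 1.0, tau_D: 20.0e-3, kappa: 5.0}
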