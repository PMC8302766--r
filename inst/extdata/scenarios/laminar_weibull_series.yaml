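# Laminar-flow assembly-metric series: stochastic Weibull-onset replicates
# at several quench depths, per-depth Weibull fits, and barrier-scaling
# extrapolation to a shallow quench with an 80 ms observation-window verdict.
scenario: laminar_weibull_series
seed: 1
noise_level: 0.02
params:
  sigmas: [1.0, 1.5, 2.0]
  stretch_k: 2.0
  n_replicates: 50
  t_min: 1.0e-3
  t_max: 0.5
  sigma_new: 0.4
  window: 0.08          # seconds
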