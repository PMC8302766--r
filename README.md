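# phasekin

Nucleation kinetics of biomolecular liquid–liquid phase separation, as an
R package.

Prion-like low-complexity domains (the archetype being the disordered
domain of hnRNPA1) demix from solution into protein-dense droplets once
quenched past their binodal. In the metastable region this requires
nucleation: classical nucleation theory (CNT) writes the free energy of a
cluster of radius *R* as

    ΔG(R) = 4π R² γ + (4/3) π R³ ε,

an unfavorable surface term against a favorable volume term, giving a
critical radius R\* = −2γ/ε and barrier ΔG\* = (16π/3) γ³/ε². The barrier —
and hence the nucleation time — depends steeply on the supersaturation
σ = c/c_sat − 1 set by the quench depth (here controlled by NaCl).

phasekin implements the full computational pipeline for studying this
process:

* **TR-SAXS operators** — Debye and generalized-polymer (ν-dependent) form
  factors for the disordered monomer, iterative Guinier analysis, and a
  low-angle *assembly metric* (mean excess of measured intensity over the
  calculated monomer form factor, normalized by the monomer I₀) that tracks
  mesoscopic cluster volume after mixing.
* **Stochastic CNT simulator** — an exact event-driven birth–death
  simulation of cluster seeds sharing a monomer pool, with attachment rate
  k₊ = D·R(N)·c∞ and Gibbs–Thomson-enhanced detachment
  k₋ = D·R(N)·c_sat·(1 + 2Γ/R(N)), capillary length Γ = γ/c_den
  (C++ core; bitwise-reproducible given a seed).
* **Kinetics fits** — the collapse+growth model
  R_base + A_c·e^(−t/τ_c) + A_g·(1 − e^(−t/τ_g)) for chain-dimension
  kinetics; the scaled Weibull CDF A_max·(1 − e^(−(t/λ)^k)) for nucleation
  kinetics; the PDF/variance correspondence across replicates; and
  ln λ = a + B/σ² extrapolation across quench depths with an
  observation-window verdict.
* **Equilibrium models** — binodal container with monotone supersaturation
  lookup; monomer–dimer / isodesmic / two-step isodesmic association
  isotherms with 2/3-power hydrodynamic scaling and 1/(1 + k_S·c)
  nonideality; Gilbert asymptotic boundary shapes g(s\*) with modality
  reporting; single-component FCS fits.
* **Synthetic-data generators** — seeded emulators for every measurement,
  so the whole pipeline is testable without any experimental download.

## Worked example

```r
library(phasekin)

# Guinier analysis of a disordered-monomer scattering curve
q <- seq(0.004, 0.25, length.out = 120)
curve0 <- saxs_curve(q, debye_form_factor(q, Rg = 27.5), t_after_mix = 5e-4)
guinier_fit(curve0)
#> Guinier fit
#>   Rg = 25.65 +/- 0.114 Angstrom
#>   I0 = 0.9909 +/- 0.00228
#>   window: q in [0.004, 0.04948] (23 points, q*Rg <=   1.3)
```

The true R_g is 27.5 Å: the ~7% shortfall is the textbook bias of Guinier
analysis applied to a Debye curve at qR_g ≤ 1.3 (the quadratic
approximation truncates ln P = −x/3 + x²/36 − …). `fit_form_factor()`
fits the full Debye model and recovers 27.5 Å exactly.

```r
# stochastic nucleation at two quench depths (reduced units: D = c_sat = 1)
for (sig in c(1, 2)) {
  p  <- nucleation_params(c0 = 1 + sig)
  tr <- simulate_nucleation(p, t_max = 2000, seed = 1)
  cat(sprintf("sigma = %g: t_half = %.0f\n", sig, time_to_half_assembly(tr)))
}
#> sigma = 1: t_half = 385
#> sigma = 2: t_half = 165
```

Deeper quenches nucleate faster; over σ ∈ [0.5, 2.5] the median
half-assembly time follows ln t½ ≈ a + B/σ² with R² ≈ 0.99
(`barrier_scaling_check()`).

```r
# Weibull nucleation kinetics from 100 stochastic assembly trajectories
trs <- gen_assembly_trajectories(seq(5e-3, 0.3, length.out = 40), 100,
                                 scale_lambda = 40e-3, stretch_k = 2,
                                 cfg = generator_config(seed = 2))
fit_weibull(trs)
#> Scaled Weibull CDF fit
#>   amplitude =     1, lambda = 0.04024 s, k = 1.916
#>   mean onset time = 0.03569 s (4000 points)

ex <- extrapolate_timescale(c(1, 1.5, 2), exp(-4.2 + 1.2 / c(1, 1.5, 2)^2),
                            sigma_new = 0.4, window = 0.08)
ex$lambda_pred     # 27.1 s
ex$exceeds_window  # TRUE: no assembly expected within an 80 ms window
```

The fitted λ (40 ms) and stretching exponent k (≈1.9, in the 1.8–2 range
characteristic of nucleation with a lag) recover the generating values;
extrapolating the barrier scaling to a shallow quench (σ = 0.4) predicts a
transition timescale of ~27 s — far beyond an 80 ms measurement window, so
no assembly would be observed there.

Scenario-driven end-to-end runs (`run_pipeline()`, YAML configs under
`inst/extdata/scenarios/`) and a thin CLI (`inst/scripts/phasekin`) wrap
the same functions.

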