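# hfbmtrack

Statistics for 2D single-particle tracking data with **random trajectory
durations** — the situation of organelles (e.g. GFP-Rab5 endosomes) imaged
in a finite focal volume, where fast particles leave the field quickly and
slow ones linger. The package is for tracking labs and modellers who need
to tell genuine anomalous-diffusion physics apart from artefacts of the
observation process.

## What it computes

For a track table (or a simulated ensemble) the package provides:

* **MSD estimators** — ensemble-averaged `emsd()`, per-track time-averaged
  `tmsd()`, and ensemble-time-averaged `etmsd()`, all censoring-aware: at
  lag *t* the ensemble average runs over exactly the *N(t)* trajectories
  still present. Ageing variants discard `t_a` seconds from every track
  (usable duration *T′ = T − t_a*); duration-conditioned variants keep only
  tracks with *T ≥ T_min*.
* **Power-law fits** of MSD(t) = 4 D_α t^α (`fit_power_law()`), optionally
  with a non-negative additive offset for static localization error and
  other quasi-constant short-time terms; bootstrap CIs over trajectories.
* **Ergodicity diagnostics** — the tMSD amplitude scatter
  ζ_i = tMSD_i(t)/e-tMSD(t), the ergodicity-breaking parameter
  EB(t,T) = ⟨ζ²⟩ − 1 with binned and minimum-duration protocols
  (`amplitude_scatter()`, `eb_vs_duration()`), a maximum-likelihood
  generalized-Gamma fit PDF(ζ) ∝ ζ^(ν−1) exp(−a/ζ − ζ/b)
  (`fit_generalized_gamma()`), and single-trajectory ergodicity/mixing
  estimators from the dynamical-functional test
  (`ergodicity_mixing_functionals()`).
* **Duration-resolved summaries** — conditional diffusion coefficients
  D_α(t|T) and their power-law exponent γ
  (`conditional_diffusion_profile()`), the exponential decay a·exp(−bT) of
  e-tMSD at a fixed lag versus duration (`etmsd_vs_duration()`), and an
  ageing sweep with an `ages` flag (`ageing_sweep()`).
* **An exact simulator** (`simulate_hfbm_ensemble()`) of
  ensemble-heterogeneous fractional Brownian motion: durations from a
  truncated Pareto law PDF(T) ∝ T⁻², a persistent FBM component
  (H₁ = 0.75) whose diffusivity decreases with duration
  (D₁ = 0.25·T^−0.1 below 2 s, 0.5·T^−1.15 above), a short-time component
  (H₂ = 0.1, D₂ = 0.009), optional Gaussian localization noise, and a
  homogeneous-FBM control (`simulate_homogeneous_fbm()`). Increments are
  exact fractional Gaussian noise via Davies–Harte circulant embedding
  (`generate_fgn()`).

The point of the simulator: every trajectory is an ergodic FBM, yet the
pooled ensemble shows an apparently subdiffusive long-time MSD and
MSDs that depend on the ageing time. Both are artefacts of duration
censoring plus ensemble heterogeneity — and both disappear in
duration-conditioned sub-ensembles.

## Worked example

```r
library(hfbmtrack)

ens <- simulate_hfbm_ensemble(5000, seed = 7)
ens
#> <track_ensemble 'hFBM simulation': 5000 trajectories, dt = 0.05 s, T in [2, 199.4] s>

curve <- emsd(ens, max_lag = 20)
fit_power_law(curve, c(0.2, 2), with_offset = TRUE)
#> <power_law_fit (eMSD, window 0.2-2 s): alpha = 1.512, D_alpha = 0.1102 um^2/s^alpha, offset = 0.03178 um^2>
fit_power_law(curve, c(3, 20))
#> <power_law_fit (eMSD, window 3-20 s): alpha = 0.386, D_alpha = 0.2304 um^2/s^alpha>
```

The intermediate window keeps the superdiffusive exponent α ≈ 1.5 of the
persistent component (the offset absorbs the short-time term), while the
pooled long-time window looks strongly subdiffusive (α ≈ 0.39) purely
because slow, long-lived trajectories dominate the surviving ensemble.

```r
ageing_sweep(ens, c(0, 2, 5), c(0.2, 1), n_boot = 50, seed = 8)
#> <ageing_sweep over t_a = {0, 2, 5} s, window 0.2-1 s: ages = TRUE>
#>  t_a_s amp_um2  amp_lo  amp_hi
#>      0 0.16821 0.16421 0.17298
#>      2 0.13391 0.12988 0.13766
#>      5 0.07375 0.07075 0.07613

amplitude_scatter(ens, lag = 0.2)
#> <amplitude_scatter at lag 0.2 s: n = 5000, EB = 0.2166>
```

The fitted eMSD amplitude falls monotonically with ageing time — apparent
statistical ageing from a process whose every trajectory is stationary.
The homogeneous control (`simulate_homogeneous_fbm()`) shows neither
effect. `run_pipeline(pipeline_config(...))` bundles all of the above into
one seeded, reproducible report directory, and
`inst/cli/hfbmtrack.R` exposes `simulate`, `msd`, `ageing`, `ergodicity`
and `report` subcommands for shell use.

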