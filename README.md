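# bliscreen

Quantitative triage for biosensor-based fragment screens, written for
biophysics and early-drug-discovery groups who run biolayer
interferometry (BLI) campaigns against difficult targets — here
modelled on a screen against the SHP-motif binding region of the
N-domain of the AAA+ ATPase p97 — and need the downstream analysis to
be reproducible: sensorgram preprocessing, hit statistics, binding
model fits, a composite triage score, ligand-efficiency metrics,
STD-NMR and chemical-shift-perturbation quantification, and
voxel-occupancy analysis of mixed-solvent simulation trajectories. A
synthetic-data module generates every input the chain consumes, so the
whole pipeline is testable without an instrument.

## The models at the core

A 1:1 interaction observed on a biosensor follows

    R(t) = R_eq(C) (1 - exp(-k_obs t)),   k_obs = k_on C + k_off,
    R_eq(C) = R_max C / (C + K_D),        K_D = k_off / k_on

during association, with exponential dissociation at `k_off`; a 2:1
heterogeneous surface is the sum of two independent sites. From a
dilution series the package fits the steady-state Langmuir isotherm,
a global kinetic model across all traces, and the 2:1 alternative, and
condenses three lines of evidence into a composite score

    Score_BLI = (0.4 S_plateau + 0.3 S_shape + 0.3 S_kobs) x penalty

(plateau presence, 1:1-vs-2:1 curve shape via AICc, and linearity of
k_obs in concentration), splitting fragments into high (>= 0.70) and
low scoring groups. Screen quality uses the Z-factor
`1 - 3(sd+ + sd-)/|mu+ - mu-|`; hits are responses above
median + n_sigma * SD with QC flags for negative, overshooting and
non-monotone signals. Ligand efficiencies are computed as
`LE = 1.364 pK_D / HA`, `SILE = pK_D / HA^0.3`, `LELP = clogP / LE`
and `LLE_AT = 0.111 + 1.37 (pK_D - clogP) / HA`. STD-NMR effects are
`I_diff/I_off x 100` with S/N >= 3 filtering, build-up curves give the
initial rate `STD0 = STD_max k_sat`, and HSQC shifts give
`CSP = sqrt(ddH^2 + (0.13 ddN)^2)`. Occupancy maps count the fraction
of trajectory frames visiting each 1 A voxel, are summed over replicas,
and yield top sites, binding-site residues (< 6 A) and representative
poses.

## Worked example

Simulate a dose-response series for a 56 uM binder at 5 % noise and run
the full triage:

```r
library(bliscreen)

m <- kinetic_model(k_on = 1e4, k_off = 0.56, r_max = 1.2)  # K_D 56 uM
ser <- simulate_dose_series(m, schedule_dose(),
                            noise_spec(sigma_noise = 0.06, seed = 1),
                            top_conc = 1e-3)
card <- analyze_dose_series(ser)
card
#> BLI score card
#>   S_plateau 0.833  S_shape 1.000  S_kobs 0.996  penalty 1
#>   Score_BLI = 0.932 -> high (cutoff 0.70)
#>   K_D concordance ratio 1.01 -> concordant
card$fits$steady_state
#> 1:1 Langmuir steady-state fit
#>   K_D   = 5.543e-05 M (SE 7.6e-07)
#>   R_max = 1.196 nm (SE 0.004)
```

The score components read: five of six concentrations reach a plateau
at this noise level, the 2:1 model offers no AICc advantage (pure 1:1
shape), and k_obs is linear in concentration — so the fragment lands
clearly in the high-scoring group, and the steady-state affinity
(55.4 uM) agrees with the kinetic route within 1 %.

The efficiency panel for a 56 uM hit with 11 heavy atoms and
clogP 1.39:

```r
efficiency_metrics(kd = 56e-6, ha = 11, clogp = 1.39)
#>        pkd        le     sile     lelp    lle_at
#> 1 4.251812 0.5274151 2.070886 2.635495 0.4674257

summarize_hits(p97_fragments())
#>      mw   ha      pkd clogp    le  sile  lelp lle_at
#> 1 203.9 14.4 3.530178 1.816 0.357 1.634 5.616  0.296
```

The summary row reproduces the published panel means for these ten
fragments (pK_D 3.5, clogP 1.8, LE 0.35, SILE 1.64, LLE_AT 0.30) to
within the two-decimal reporting convention.

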