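---
title: "Methods: BLI fragment-screen triage, NMR quantification and occupancy analysis"
author: "bliscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BLI fragment-screen triage, NMR quantification and occupancy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bliscreen)
```

## Scope and model

`bliscreen` implements the quantitative chain used to triage a
biolayer-interferometry (BLI) fragment screen against a
protein-protein-interaction target such as the N-domain of the AAA+
ATPase p97, together with the orthogonal NMR quantification and the
voxel-occupancy analysis of mixed-solvent simulation output. Every
input the chain consumes can be produced by the built-in simulators, so
all stages are testable without instrument data.

Units are fixed package-wide: concentrations in molar, time in seconds,
biosensor responses in nm.

### 1:1 binding on a biosensor

The core generative and fitted object is the 1:1 Langmuir model with
association rate $k_{on}$ (M$^{-1}$s$^{-1}$), dissociation rate
$k_{off}$ (s$^{-1}$) and saturation response $R_{max}$ (nm). In the
association phase at analyte concentration $C$,

$$R(t) = R_{eq}(C)\,\bigl(1 - e^{-k_{obs} t}\bigr), \qquad
  k_{obs} = k_{on} C + k_{off}, \qquad
  R_{eq}(C) = \frac{R_{max}\, C}{C + K_D},$$

with $K_D = k_{off}/k_{on}$; dissociation decays exponentially with
$k_{off}$ from the association end value. The heterogeneous (2:1) model
is the sum of two independent such sites; with identical rates it
reduces exactly to 1:1. Both are evaluated in closed form — no ODE
integration — so simulator and fitter share one exact model and
round-trip tests are meaningful to solver precision.

## The synthetic-data generators

The generators emulate the statistical structure the analysis assumes,
under the conditions of the original assay design:

* **Schedules.** Screening: 15 s baseline, 60 s association, 300 s
  dissociation. Dose-response: 15 s / 120 s / 180 s. Default sampling
  5 Hz (typical instrument export density; configurable, and several
  tests use 2 Hz to keep runtimes short — stated sizes below).
* **Dose series.** Two-fold dilution ladder from 1000 uM down to
  31.25 uM, six concentrations, each measured twice.
* **Plates.** Fragments at 500 uM, measured twice by passing the plate
  forward then backward; positive controls (an ADP-like binder, 500 nM,
  $K_D$ 200 nM) and buffer blanks bracket the sample block. Sensor
  activity decays exponentially in elapsed assay time,
  $\exp(-\ln 2\, t/\tau_{1/2})$, applied multiplicatively to the
  specific signal. The exponential form is a declared stand-in — the
  instrument-side correction it emulates is not specified in detail
  anywhere we could follow — and the corrector deliberately shares this
  one model so the pair is self-consistent.
* **Artifacts.** Additive Gaussian noise per sample; linear baseline
  drift (nm/s); non-saturating "unspecific" accretion during
  association (nm/s per M), held during dissociation; a solvent-jump
  step offset during association. All seeded; the same specification
  and seed give byte-identical output.
* **STD build-up.** $STD(t) = STD_{max}(1 - e^{-k_{sat} t})$ on the
  seven-point saturation-time grid 0.5–5.0 s.
* **HSQC peak lists.** Apo peaks uniform in the amide region; bound
  peaks shifted by planted per-residue $(\Delta\delta_H,
  \Delta\delta_N)$ plus noise.
* **Probe trajectories.** Per frame, a designated probe atom is placed
  inside a spherical hotspot with probability `p_bound`, else uniformly
  in the box.

What the simulators do *not* reproduce: mass-transport-limited binding,
spectral overlap and peak picking, correlated instrument noise, and
conformational protein dynamics. Passing tests therefore demonstrate
correctness of the analysis chain under its own model assumptions, not
performance on raw instrument data.

## Preprocessing

Double referencing computes
$(\text{sample} - \text{reference}) - (\text{blank} -
\text{blank reference})$ after zeroing each trace to the mean of the
last 10 s of its baseline, and re-zeroes time at association start.
The operation is linear in its inputs, which the tests exploit.

Bracketing-control correction normalizes each positive-control
steady-state response to the pre-plate control and interpolates the
activity factor linearly in cycle index (cycle order is what the CSV
schema guarantees; wall time is not recorded). Every trace is divided
by its cycle's factor; in N-domain mode also by the sensor's protein
loading signal. Linear interpolation of an exponentially decaying
activity is exact only at the bracket ends; over a plate losing ~20 %
activity the midpoint error is below 1 %, which the round-trip test
tolerances reflect.

Steady-state quantification averages the last 10 s (screen) or 20 s
(dose-response) of association. The plateau flag requires the end slope
(linear regression over the window) to stay below
$0.002 \cdot \max(|R_{eq}|, 0.01\,\text{nm})$ per second. The tolerance
was chosen once so that noiseless 1:1 traces with $k_{obs} t \ge 5$
pass; at 5 % noise the slope estimate is noise-limited for weak
responders and the flag becomes conservative, which feeds through to
the plateau component of the composite score.

## Screen statistics

The screening window statistic is
$Z = 1 - 3(\sigma_+ + \sigma_-)/|\mu_+ - \mu_-|$ with sample standard
deviations; equal means return $-\infty$ with a warning. Hit calling
thresholds at median $+ n_\sigma \cdot$ SD over all sample responses
(`robust = TRUE` switches to MAD). The location/spread convention is a
declared choice: the median tolerates hit contamination while "sigma"
retains its conventional meaning. QC flags replace manual curation:
`negative_signal` below $-3\sigma$, `overshoot` above 3x the
positive-control mean, and `non_monotone` association from the plate
quantifier.

## Dose-response fitting and the composite score

* **Steady-state fit**: least squares on the Langmuir isotherm over all
  replicate points unaveraged; $K_D$ outside
  $[0.01\,C_{min}, 100\,C_{max}]$ flags the fit unreliable
  (saturated series are unidentifiable, not silently reported).
* **Global kinetic fit**: one $(k_{on}, k_{off}, R_{max})$ across all
  traces, association and dissociation jointly, Levenberg–Marquardt on
  log-parameters (positivity by construction) with bounds
  $k_{on} \in [10, 10^9]$, $k_{off} \in [10^{-5}, 10]$ and three
  log-spaced deterministic starts, best residual selected.
* **Model comparison**: the 2:1 fit (six log-parameters, starts derived
  from the 1:1 solution) is compared by small-sample AICc with
  $k$ = parameters + 1. A relative RSS floor of $10^{-10} n\,
  \mathrm{scale}^2$ stabilizes the comparison when both models reach
  machine-precision residuals on noiseless data; the parameter penalty
  then decides, as it should for nested models.
* **k_obs analysis**: per concentration, $A(1 - e^{-k_{obs}t})$ on the
  first 90 % of association (avoiding plateau-dominated
  ill-conditioning), then a linear regression $k_{obs} = k_{on} C +
  k_{off}$ weighted by replicate count. Two deliberate choices: (i)
  per-trace estimates whose standard error exceeds 50 % of the estimate
  are treated as failed fits and dropped — a rate the sampling cannot
  resolve returns an enormous SE and would otherwise poison the
  regression; (ii) the fit SEs are *not* used as regression weights,
  because under a misspecified 1:1 model they grow with lack of fit and
  would down-weight exactly the concentrations carrying the
  heterogeneity signal.

The composite score combines plateau evidence, curve-shape evidence and
rate-linearity evidence:

$$\mathrm{Score} = \bigl(0.4\,S_{plateau} + 0.3\,S_{shape} +
  0.3\,S_{kobs}\bigr) \times \mathrm{penalty}$$

with $S_{plateau}$ the fraction of concentrations reaching a plateau,
$S_{shape} = e^{-\max(0, \Delta AICc)/10}$,
$S_{kobs} = \mathrm{clip}(R^2, 0, 1)$ if both regression rates are
positive (else 0), and penalty 0.5 when the two highest concentrations
both lack a plateau. The weights, shape scale and penalty are a
reconstruction calibrated to the score's qualitative contract — near
1.0 for clean 1:1 binders, well below the 0.70 high/low split for
non-saturating unspecific binders — not to any per-fragment published
value, which is why per-fragment scores are never asserted. Decisions:
`high` at score $\ge 0.70$, `low` below, `reject` when a component is
missing.

Affinity concordance between the kinetic and steady-state routes uses
the fold ratio with defaults flag > 2, reject > 5, bracketing the
published handling of 3.5-fold (retained, flagged) and 9.5-fold
(rejected) discrepancies.

## Ligand efficiencies

With $pK_D = -\log_{10} K_D$ (M): $LE = 2.303\,R\,T\,pK_D/HA$ (T =
298.15 K, prefactor 1.364 kcal/mol; the commonly quoted 1.37 constant
is inside the panel's two-decimal tolerance), $SILE = pK_D/HA^{0.3}$,
$LELP = clogP/LE$, $LLE_{AT} = 0.111 + 1.37\,(pK_D - clogP)/HA$.
Two-decimal reporting uses round-half-even. The hit-table summary
computes the mean $pK_D$ as $-\log_{10}$ of the arithmetic-mean $K_D$
— the convention that reproduces the published summary row — and
panel means as arithmetic means of two-decimal per-fragment values.
Three published cells of the reference hit table are internally
inconsistent with their own $K_D$/HA/clogP columns (one molecular
weight, two $LLE_{AT}$ values); they are flagged in the shipped table
and excluded from exact-match checks. Descriptor PCA standardizes
columns and uses `stats::prcomp`; constant descriptors are dropped with
a warning.

## STD-NMR and CSP

STD effects are $I_{diff}/I_{off} \times 100$ per signal, restricted to
the aromatic window (default 6.0–9.5 ppm) and filtered at S/N
$\ge 3.0$; the per-fragment mean is taken over retained signals only,
and a fragment is confirmed if any signal survives. Build-up curves are
fitted by the two-parameter exponential with multi-start over the
saturation rate (curves within the 0.5–5 s window range from saturated
to almost linear, and a single start does not converge on the linear
end); $STD_0 = STD_{max} k_{sat}$ is the model's exact initial slope.
The NOE R-factor is the root-sum-square form
$\sqrt{\sum (e_i - c_i)^2 / \sum e_i^2}$ — a declared convention, as is
the CSP classification at mean + 1 SD (moderate) and + 2 SD (strong)
of the per-residue CSP
$\sqrt{\Delta\delta_H^2 + (0.13\,\Delta\delta_N)^2}$. Residues present
in only one state are reported missing, never zero.

## Occupancy analysis

Occupancy is binary per frame — the fraction of frames in which at
least one selected atom visits a voxel — with half-open 1.0 A voxels,
floor binning, and the origin snapped to integer Angstrom (bounding box
minus 2 A padding) for bit-reproducible maps; atom-count densities are
an exposed option. Replica maps sum voxel-wise. Site discovery greedily
takes the highest-valued voxels at pairwise separation $\ge$ 6 A,
breaking ties by lexicographic voxel index. Binding-site residues are
all residues with an atom strictly within 6 A of a site center.
Binding-event detection (first frame of the earliest run of $\ge$ 10
consecutive frames within 6 A) and pose agreement (sum of grid values
at the pose's atom positions, ties to the lower replica index) are
declared conventions; the RMSD to the interval-mean structure is
computed without re-superposition because trajectories are assumed
aligned once on C-alpha atoms. Grids are written as text OpenDX scalar
fields with canonical `%.6e` formatting, making read/write round trips
byte-stable.

## Problem sizes and runtimes

The test suite simulates dose series at 2 Hz sampling (twelve traces of
~630 points each), screening plates of up to 93 fragments at 1–2 Hz,
50-seed replicate sweeps for the noise-recovery properties, and
occupancy trajectories of 500–2000 frames on grids of about $10^4$
voxels. These sizes were chosen so the full chain remains interactive
on a single CPU while leaving all statistical contrasts (model
discrimination, hotspot recovery, noise bias) clearly resolved.

## Known limitations

* The score reconstruction reproduces qualitative behavior, not any
  per-fragment published score; with one component saturated the
  composite can be locally flat rather than strictly decreasing in
  heterogeneity.
* Mass transport, bivalent analytes and affinity estimation from a
  single concentration are out of scope.
* The plateau flag is noise-limited for weak responders at 5 % noise.
* CSV byte-stability relies on R's default numeric formatting and is
  guaranteed for data the package itself writes.
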