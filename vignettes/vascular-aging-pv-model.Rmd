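---
title: "A closed-loop pressure-volume model of vascular aging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-loop pressure-volume model of vascular aging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package addresses

Vascular aging stiffens the aorta: equivalent arterial compliance
($C_A$) falls while total peripheral resistance ($R_T$) rises.  How
that loss of compliance feeds back on left-ventricular (LV) function is
usually quantified with the pressure-volume (PV) construct — a
conductance-catheter experiment in which preload is transiently lowered
by a vena caval occlusion (VCO) while LV pressure and volume are
recorded beat by beat.  `pvloopva` reimplements that experiment
*in silico*: a closed-loop lumped-parameter circulation paced at a fixed
rate under autonomic blockade, a graded set of arterial stiffness
settings, a simulated VCO, and the complete analysis stack that turns the
recorded loops into the standard contractility and energetics indices.

## Model structure

The circulation is a closed hydraulic network of fifteen volume states:

* four **time-varying elastance chambers** (LA, LV, RA, RV) with
  $P = E(t)\,(V - V_0)$, pressures clamped at a floor of $-5$ mmHg
  during deep preload reduction;
* an **aortic arch** element — the proximal Windkessel compliance the
  vascular-aging protocol manipulates;
* a lumped **systemic artery** and **five parallel distal beds**
  (coronary, cerebral, skeletal muscle, splanchnic, extrasplanchnic),
  each a compliance fed and drained through its branch resistances;
* lumped **systemic** and **thoracic veins** — the thoracic-vein outflow
  resistance is the VCO site;
* a two-compartment **pulmonary loop**.

Valves are ideal diodes with small open resistances (mitral/tricuspid
0.003, aortic/pulmonic 0.005 mmHg·s/ml) and no inertance: the study's
endpoints need valve-event timing, not regurgitant or inertial dynamics.
Every flow is Ohmic, so each compartment's volume rate is inflow minus
outflow and the rates sum to zero identically — mass conservation is
structural, and the test suite verifies the integrated drift stays below
0.1% per simulated minute.

The arterial tree reduces to $C_A = 0.70$ ml/mmHg (sum of the seven
arterial compliances) and $R_T = 1.28$ mmHg·s/ml (arch outflow in series
with the parallel distal branches).  `apply_vascular_scaling()` retargets
both by one multiplicative factor per quantity, preserving the
proximal/distal split — the minimal reading of "proportional scaling".
The five packaged settings span normal (0.70, 1.28) to stiff
(0.19, 3.66) exactly as printed in the source study.

## The activation waveform, and why it looks the way it does

The literature this model builds on does not specify the elastance
waveform, so its shape is a design decision, made here under a hard
physical constraint: with the printed normal values the arterial time
constant is only $R_T C_A \approx 0.9$ s, yet the calibration targets are
aortic 120/80 mmHg with a 40 mmHg pulse pressure at 80 bpm.  During
diastole the pressure decays with that time constant, so the pulse
pressure is bounded below by roughly
$\bar{P}\,t_{dia}/(R_T C_A)$: a conventional 0.30 s systole leaves
0.45 s of runoff and forces a pulse pressure above 55 mmHg.  Reproducing
120/80/40 therefore requires a long ejection and a short effective
diastole, plus an inflow profile flat enough not to spike the systolic
peak.

The packaged activation has three segments over a systole of duration
$d = k\sqrt{60/HR}$ (k = 0.7 s^1/2^) capped at $0.66\,T$:

1. a fast raised-cosine rise to 0.30 over the first 15% of the rise
   window — a short isovolumic contraction that also sets
   dP/dt~max~ (≈ 1900 mmHg/s at 80 bpm);
2. a linear climb to peak elastance at 78% of systole — sustained
   ejection that spreads the stroke volume across the beat;
3. a raised-cosine relaxation.

With this waveform, LV $E_{max} = 2.6$ mmHg/ml and the packaged venous
parameters, the paced steady state at 80 bpm produces ~122/82 mmHg with
a 39.6 mmHg pulse pressure.  An earlier candidate (double cosine, 0.3 s
systole) was rejected because it violated the pulse-pressure target for
the reason above.

Two related consequences are documented rather than hidden:

* the fitted ESPVR of the normal run is ≈ 2.6 mmHg/ml, the commanded
  $E_{max}$, not the ≈ 1.8 the source study tabulates.  Tuning
  $E_{max}$ down to 1.8 is incompatible with the 120-mmHg systolic
  target at the printed afterload (the chamber could not eject past
  $V_0 + 120/1.8$).  None of the acceptance directions depend on the
  ESPVR level in Phase I, and the Phase II ESPVR-with-rate direction is
  carried by the force-frequency gain;
* with the cap at $0.66\,T$ binding for rates above ~53 bpm, the
  systolic *fraction* is constant across the studied range and the
  absolute systole still shortens with rate.

## Force-frequency and venous return

Contractility rises with rate through an explicit, config-exposed gain:
$E_{max} \mapsto E_{max}\,(1 + s\,(HR-80)/80)$ with $s = 0.3$.  The
mechanism behind the intact force-frequency relationship is not
specified by the source, so it is a documented knob, not physiology.

The systemic-vein outflow resistance is deliberately large for a lumped
venous segment (0.25 mmHg·s/ml).  It makes venous return saturate, so
cardiac output plateaus as the pacing rate rises — the behaviour the
published Phase II tables imply (near-constant output across 60-140 bpm).
Without it the simulated output rises ~45% from 60 to 140 bpm, afterload
pressure climbs, and two Phase II directions (end-systolic volume and
preload-recruitable stroke work falling with rate) invert.  This is the
single most consequential calibration choice in the package.

## The VCO maneuver and the analysis stack

The occlusion multiplies the thoracic-vein outflow resistance by 100
along a geometric ramp over 8 s, starting at a beat onset after the
model has converged to periodic steady state (beat-to-beat spread of
EDV, ESV and mean aortic pressure below 0.5% over five consecutive
beats; three simulated minutes is the give-up bound).  Neither magnitude
nor duration is printed in the source; these defaults yield 9-20 beat
families, the size typical of in-vivo VCO fits.  Beats are harvested
from the last steady beat until EDV has fallen 40% or 12 s elapse.

Per beat: EDV and end-diastolic pressure are read at the pacing onset
(the paced protocol makes end-diastole unambiguous), ESV is the volume
minimum, end-systolic pressure Pes is read at aortic-valve closure
(downward zero-crossing of valve flow; at minimum volume when no flow
trace exists, as with analysis-only CSV input), dP/dt~max~ is a centered
difference at the 1 kHz sampling with no smoothing, stroke work is the
shoelace area of the (V, P) polygon, and
$PVA = SW + \tfrac12 P_{es}(ESV - V_0)$ — the end-systolic
potential-energy triangle, neglecting the area under the end-diastolic
relation.  $V_0$ is taken from the ESPVR fit of the same run, which
fixes the order of operations: fit first, then per-beat PVA, then the
PVA-EDV fit.  Mechanical efficiency is $100\,SW/PVA$ and dynamic
arterial compliance $SV/P_{es}$.

The four relations (ESPVR, PRSW, dP/dt~max~-EDV, PVA-EDV) are unweighted
ordinary least squares over the harvested family, the volume-axis
intercept reported as $-\text{intercept}/\text{slope}$.  The source
prints three of these relations with a "/" between slope and volume
offset; they are implemented as products (slope × volume offset), since
the printed forms are dimensionally inconsistent and the text calls the
coefficients slopes.

## Synthetic fixtures

`make_vco_family()` generates beat families with known linear structure:
EDV descends deterministically; SW, PVA and dP/dt~max~ come straight
from their specified lines; ESV is derived from the potential-energy
identity $PVA - SW = \tfrac12 E_{es}(ESV - V_0)^2$ so all four relations
are simultaneously consistent; Pes follows the ESPVR line.  Optional
Gaussian noise (SD a fraction of each value) is applied to the dependent
metrics only — the volumes stay exact so the OLS error model of the
recovery tests holds; noise on the regressors would bias slopes downward
(errors-in-variables) and turn a fit-quality test into a test of that
bias.  Generators are pure functions of (spec, seed) and leave the
session RNG untouched.  `make_elastance_beat()` is a one-chamber,
two-element-Windkessel miniature used to verify that the end-systolic
point of a relaxing elastance chamber lands on the $E_{max}$ line.

What the fixtures do **not** emulate: measurement artifacts (catheter
whip, drift), respiratory variation, or the curvature real ESPVRs show
at low volumes.  Passing the recovery tests shows the estimators are
correct for clean, linear data of realistic size — not that they are
robust to pathological recordings.

## Numerical choices

* Integrator: `lsoda` (stiffness-switching), rtol = atol = 10^-6^,
  output resampled at 1 kHz; dP/dt needs at least that sampling.
* The compiled C right-hand side is the production path; an identical R
  implementation (`state_derivative()`) is the reference the tests
  cross-check against (trajectory agreement to < 0.01 ml over 1.5 s).
* Steady-state detection operates on beat metrics, not raw state, so a
  limit cycle is recognised as steady.
* Valve diodes make the RHS only piecewise smooth; lsoda's step control
  handles the crossings without event functions at these tolerances.
* Degenerate inputs: open PV loops are closed with a classed warning
  (occlusion beats are genuinely open, so the study pipeline muffles
  exactly that class); a potential-energy term with $ESV < V_0$ is
  clamped at zero with a warning; constant-x regressions and too-few
  beats are errors.

## Problem sizes

The packaged protocols are sized for interactive use: steady state is
reached in ~19 simulated seconds from the packaged initial state, a full
condition (steady state + 12 s occlusion + fits) takes a fraction of a
second of wall time, and both study phases together run in a few
seconds.  The test suite simulates all eleven study conditions plus a
one-minute conservation run.

## Known limitations

* Absolute agreement with the published tables is out of reach by
  construction: the upstream model's full equation set and chamber
  parameters are not printed, and the published stiff-setting row is
  internally inconsistent with steady-state flow times resistance
  (stroke volume 52.7 ml at 80 bpm across $R_T = 3.66$ would demand a
  mean pressure near 260 mmHg, far above the printed 133.6).  The
  package therefore calibrates to the 120/80/40 verification point and
  reproduces the *directions* of both phases, which is what its
  acceptance suite checks.
* The published resistance unit string (mmHg·ml^-1^·s^-1^) is
  dimensionally inconsistent with hydraulic resistance; values are used
  as mmHg·s/ml without rescaling.
* Several percent-change figures quoted in the source's prose conflict
  with its own tables (e.g. a "47%" EDV change whose printed endpoints
  give 33.4%, and a PVA-EDV change printed as both 59% and 68.7%); only
  arithmetic-consistent ratios are asserted by the tests.
* No baroreflex or chemoreflex (the study runs under autonomic
  blockade; the flag is permanently true), no wave reflection or
  pulse-wave velocity, no inertances, no gas exchange or lung
  mechanics, no microvascular beds.
* Stiff-setting pressures are physiologically extreme (the model is
  honest about the printed $R_T$); they are used for directional
  comparison only.

## Reproducing the study drivers

```{r phases}
library(pvloopva)
p1 <- run_phase1()          # five compliance levels at 80 bpm
p2 <- run_phase2()          # normal and stiff at 60 / 100 / 140 bpm
compare_to_paper(p1)        # per-cell deviations + trend-direction flags
compare_to_paper(p2)
```

The same drivers are available from a shell through the launcher in
`inst/cli/` (`pvloop-va run --phase 1 --out results/`), and
`scripts/acceptance.R` recomputes the calibration quantities from a
fresh steady-state run.
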