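---
title: "Models and methods behind the magdrop simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the magdrop simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magdrop)
```

`magdrop` is a digital twin of an automated bead-based digital-microfluidics
immunoassay platform: a sealed oil-filled chip holding reagent droplets sits
on a matrix of planar electromagnets; a small permanent-magnet motor steps
from coil to coil beneath the chip, dragging either a magnetic bead cluster
or a whole droplet, and a colorimetric sandwich assay is executed and read
out without any manual step. This vignette records the models, the
parameters that matter, the numerical choices, and the deliberate
limitations — in enough detail that a maintainer can judge what a passing
test suite does and does not establish.

## Actuation layer

The navigation matrix is a lattice of square four-turn coils, 2 mm on a
side with a 0.1 mm gap (pitch 2.1 mm), each driven independently at 0.4 A.
The stock grid holds 165 elements; the exact row-by-column arrangement is a
configuration choice and the default is 11 × 15. Coils are addressed
through programmable switch devices with 8 output ports each, packed
densely, which yields 21 devices for 165 coils. Ports per device is itself
a parameter: the device count is always `ceiling(n_coils / ports)`.

The motor is modelled as a state machine on the lattice. One actuation step
relocates it to the single energised coil, which must be the current cell
or a 4-neighbour — the step-motion mechanism cannot jump cells, and the
simulator treats a non-adjacent activation as a fault rather than guessing
a trajectory. Speed is realised by dwell time: an adjacent move with dwell
τ implies a commanded speed of pitch/τ. The magnetic field itself is not
spatially resolved; the coupling is abstracted to "motor settles on the
energised cell" plus the lumped forces below. Nothing in the modelled
behaviour depends on a field map, and none is published for this class of
device.

## The force-balance operation diagram

Whether the motor moves the droplet, extracts the bead cluster, or nothing,
is decided by three lumped forces: magnetic pull proportional to bead
loading mass (`F_mag = k_mag * m`), a maximal interfacial restoring force
proportional to the cube root of the mass — the cluster circumference sets
how much of the droplet surface can deform (`F_int_max = k_int * m^(1/3)`)
— and droplet friction proportional to transport speed
(`F_fric = k_fric * v`). The classification rules:

* `DROPLET_OP` when `F_fric <= min(F_mag, F_int_max)`;
* `BEAD_OP` when `F_fric > F_int_max` and `F_mag > F_int_max` (strict);
* `NO_ENGAGEMENT` otherwise.

The three stated proportionalities and the three zone descriptions force
this inequality structure; the coefficients are free parameters with unit
defaults, in internal units of µN, mg and mm/s. Two tie-break decisions are
deliberate: equality of friction with the driving forces still counts as
droplet transport (the less energetic regime), and extraction demands
strict excess of the magnetic force over the interfacial maximum. The
degenerate origin (m = 0, v = 0) is classified `DROPLET_OP`: nothing to
move, no violation. The boundaries have closed forms — critical mass
`m* = (k_int/k_mag)^(3/2)`, the line `v = (k_mag/k_fric) m` below it and
the curve `v = (k_int/k_fric) m^(1/3)` above it — and the test suite
verifies them against the classifier by bisection to 1e-9 rather than
trusting the algebra twice.

```{r phase, fig.width = 6, fig.height = 4.5}
plot(phase_diagram(force_params()))
```

## Fluidic state

Droplets are point objects on the coil lattice carrying a volume and a
composition map (species → amount in pg); footprint and spreading are not
modelled because no droplet geometry is published for this chip. The stock
layout holds one 8 µl bead droplet, four 50 µl wash droplets, one 50 µl
labelling droplet (HRP-conjugated anti-Aβ42 antibody), one 50 µl TMB
substrate droplet sitting in the ~3 mm-high detection chamber, and one
50 µl stop-buffer droplet — 358 µl in total — plus a sample position. The
stop droplet carries its own inert transport beads (configurable mass,
default equal to the assay cluster) so it can be driven in droplet mode;
whether the real chip's stop-buffer beads differ in mass from the assay
beads is not quantified anywhere, so they are modelled as a separate inert
cluster.

Bead extraction drags a configurable carryover fraction (default 0.01) of
every free species in the droplet along with the wet cluster; washing is
therefore geometric, and three transfers leave exactly a fraction f³ of a
contaminant. The default of 1% is a modelling choice — the platform's
washing performance is described only qualitatively — and it is the single
most consequential free parameter for background signal. Mixing within a
droplet is instantaneous and perfect after any merge; merges add volumes
and amounts, and species totals are conserved to machine precision across
arbitrary event sequences (the binding reactions only relocate material
between solution and bead surface, so the conservation ledger maps bound
species back to their solution counterparts).

## Protocol compilation

Assay programs are command lists (`MIX`, `MOVE_DROPLET`, `MOVE_BEADS`,
`MERGE`, `INCUBATE`, `READ`, …) in a one-command-per-line text DSL. The
compiler routes every motion with breadth-first search on the 4-connected
lattice, treating cells occupied by other droplets as obstacles — the
simplest complete algorithm, with a deterministic row-major neighbour
order so replays are bit-identical. Speeds are chosen per command as the
geometric midpoint (log scale) of the feasible interval: below the
droplet/bead boundary for droplet transport (floored at a practical
minimum speed, default 0.05 mm/s), above it for extraction (capped at
50 mm/s). The geometric midpoint maximises the relative margin to both
ends. A command whose verb cannot be realised at any speed — extraction of
a cluster at or below the critical mass, transport of a beadless droplet —
fails at compile time with the violated constraint; a regime that drifts
at run time (the compile-time mass assumption no longer holds) raises an
actuation fault naming the program step.

The stock program mirrors the platform's six assay steps: capture mixing
in the sample droplet; extraction across the water–oil interface into a
first wash; labelling; exactly three wash transfers; delivery into the
substrate chamber and reaction; stop-droplet merge; bead removal and
optical readout. Step durations default to 30 min capture, 30 min
labelling, 30 s per wash and 10 min reaction — ordinary magnitudes for a
bead ELISA with saturating kinetics of this speed; the hardware's actual
commanded dwell times are not published, so all are configuration values.

## Assay chemistry

The chemistry is deliberately phenomenological — the simplest forms
consistent with saturating capture-vs-time and capture-vs-antibody curves:

* **Capture**: first-order approach to a Langmuir equilibrium,
  `Q_eq = capacity * C / (C + K)`, over the total concentration of
  CD63-bearing species (Aβ42-bearing and bare exosomes compete for the
  same sites; free Aβ42 and BSA carry no CD63 and are never captured).
  The equilibrium is evaluated on the total (free + bound) amount, which
  makes accumulation exactly memoryless: two t-steps equal one 2t-step.
* **Labelling**: saturating first-order binding of the HRP conjugate,
  linear in the captured Aβ42-bearing exosomes only — the dual-site
  requirement that gives the assay its specificity. Single-marker inputs
  therefore produce background-level signal end to end, which the suite
  checks through the full chip simulation.
* **Development**: absorbance grows as `gain * bound_HRP * t`; the stop
  event freezes it.

No kinetic constants are published for the real assay; the defaults
(capacity 1 au/mg, k_cap 0.1/min, K 100 pg/ml, gain 0.025 A/au/min,
background absorbance 0.05, signal noise SD 0.01) were chosen once so that
the simulated calibration over the assay's working range (0–50 pg/ml, in
triplicate) has a realistic shape and a blank+3SD limit of detection in
the low-pg/ml regime, matching the class of assay being emulated. They
were not revisited afterwards.

Calibration fits the four-parameter logistic
`y = d + (a - d)/(1 + (x/c)^b)` by Levenberg–Marquardt least squares with
a deterministic initialisation (asymptotes from the extreme-concentration
signals, inflection from the mid-signal concentration, slope 1) and `b, c`
bounded positive. The LOD inverts the fitted curve at blank mean ± 3 SD —
the sign following the curve direction — with a small numerical tolerance
at the asymptotes so that noiseless blanks invert to zero rather than
erroring.

## Optical readout

The sensor model is a baseline intensity scaled by a slow sinusoidal
multiplicative ambient drift (ambient light and warm-up) plus additive
Gaussian noise; light crossing the chamber droplet is attenuated by
`10^(-A)` with A the absorbance-equivalent signal. Acquisition follows the
platform's protocol: `round(duration × rate)` samples (stock: 100 at
10 Hz), a moving-median filter (window 5 — the hardware's filter is
unspecified beyond "digital filtering", and a median is robust to the
impulsive noise such sensors show), then the arithmetic mean.

Drift compensation is the normalized calibration
`I_readout = I_raw * I_ref / I_bg`. Among the possible arrangements of the
three measured intensities, this is the unique one in which a common
ambient factor on the raw and background intensities cancels exactly —
the purpose of the calibration — and it reduces to the identity when
`I_bg = I_ref`. The arrangement is nonetheless kept behind a single
function so an alternative convention could be swapped in. Background and sample reads share the acquisition
window, so the cancellation is exact in the noise-free model rather than
approximate over a drifting interval. Beads scatter light, so measuring a
chamber that still contains a cluster is an error, mirroring the
platform's bead-removal step before readout.

## Synthetic cohorts and diagnostics

The cohort generator emulates the study design of the platform's clinical
arm: 20 Alzheimer's, 10 mild-cognitive-impairment and 30 control subjects,
log-normal plasma concentrations (non-negative, right-skewed, the usual
shape for biomarker levels) rising across CON < MCI < AD. The per-subject
concentration is pushed through the noiseless dose-response and the
Beer–Lambert sensor, plus sensor noise — so the readout *falls* with
disease stage and low scores flag disease, which is why the reported
cutoffs are "≤" thresholds. The group separations on the log scale are set
so the binormal AUC equals the reported diagnostic performance of the real
platform (0.94 for AD vs CON, 0.82 for MCI vs CON) with a common sdlog of
0.5 about a 5 pg/ml control median; since AUC is invariant under the
monotone assay chain, the simulated cohorts reproduce those AUCs at large
n without any further tuning. The per-subject plasma values of the real
study are not published, so cutoff values in sensor units are not
comparable to the hardware's; only the design-level statistics are.

The rank statistics are implemented from scratch (the analysis, not a
wrapper): Mann–Whitney U by midrank summation; exact two-sided p by full
enumeration of group labelings when the smaller sample has ≤ 8
observations and no ties, defined as the probability of a |U − μ| at least
as extreme; otherwise a normal approximation with tie correction and
continuity correction. Two-sided p-values are reported without
multiple-testing correction, matching how such three-group pairwise
comparisons are conventionally reported. The empirical ROC sweeps unique
scores with cumulative counts (O(n log n)), its trapezoid AUC satisfies
AUC = U/(n₁n₂) including ties, and the default operating point maximises
Youden's J with ties broken toward higher specificity. `stats::wilcox.test`
and `pROC` appear in the test suite as independent cross-checks only.

## Determinism, problem sizes, and what the tests show

Every stochastic element (signal noise, sensor noise, cohort draws) is
seeded, and run records include the seed and a config hash, so replays are
bit-identical. The test suite exercises the classifier against direct
force-inequality enumeration on 10⁴ random points, boundary location by
bisection to 1e-9, conservation over 10³ random event sequences at 1e-12
relative, 4PL recovery to 1e-6 on noiseless data, drift invariance to
1e-12, the AUC–U identity on 10³ random instances, exact Mann–Whitney
enumeration for all sample sizes up to 6, and binormal AUC recovery at
10⁴ per group within 0.02 — sizes chosen to make the checks sharp while
keeping the full suite under a minute.

What passing does **not** show: the force model is quasi-static with three
lumped coefficients — it cannot predict actual masses or speeds for a real
chip without calibrating `k_mag`, `k_int`, `k_fric` against measured
operation-zone data; the chemistry has no published rate constants and its
absolute signals are in arbitrary units; the cohort generator reproduces a
*design* (group sizes, separation, direction), not patient data, so
clinical sensitivity/specificity at the simulated cutoff describe the
synthetic population only. Evaporation, surfactant effects, satellite
droplets, droplet footprints, coil heating and field inhomogeneity are all
out of scope.
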