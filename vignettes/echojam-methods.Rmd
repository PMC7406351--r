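---
title: "Simulating group-foraging echolocators: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating group-foraging echolocators: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echojam)
```

## The scientific question

Insectivorous FM bats often hunt in groups, where the loud calls of
conspecifics can mask the faint echoes a bat needs to detect and localize its
prey. A long-standing hypothesis is that bats mitigate this with a *spectral
jamming avoidance response* (JAR) - deliberately shifting call frequencies
away from maskers. `echojam` implements an agent-based sensorimotor
simulation of this situation: many bats fly, call, listen, decide and hunt
erratically flying moths in a 10 x 10 m arena, with the entire acoustics
chain modeled explicitly. The simulation makes it possible to measure
quantities that are inaccessible in field experiments - the exact acoustic
input at each bat's ear, the probability that the pursued prey's echo is
jammed, and the causal breakdown of failed attacks - and to run *null
conditions* no experiment can produce, such as bats that compete and collide
but are immune to acoustic masking.

## Model structure

A trial advances on a fixed 0.5 ms clock. Three layers interact:

**Prey** fly a correlated random walk resembling a moth: speed ~ N(1, 0.1)
m/s bounded to [0.8, 1.2] m/s and angular velocity ~ N(0, 2) rad/s, both
redrawn every 100 ms on each prey's private grid (the alignment of the grid
is arbitrary; we anchor it at the prey's spawn time). At a border the prey
turns onto the inward normal. Prey neither hear nor evade. A captured prey
is replaced immediately at a uniform random position, keeping density
constant.

**Bats** run their decision loop once per inter-pulse interval (IPI), i.e.
once per emitted call. Echolocation parameters follow the distance to the
pursued target through a phase table (search / approach / buzz-I / buzz-II)
with linear interpolation inside the approach and buzz-I segments: IPI 100
-> 5 ms, duration 7 -> 0.5 ms, source level 110 -> 80 dB-SPL at 0.1 m,
bandwidth 8 -> 20 kHz, and terminal frequency 39 kHz dropping to 19 kHz only
in the final buzz. Steering follows a delayed linear law: commanded turn
rate `k_r * phi_target` bounded by a 4 m/s^2 centripetal acceleration, and
speed `V_phase * cos(phi_target)` (3.5 m/s search/approach, 2 m/s buzz).
The speed command is issued per IPI; the turn command is re-issued every
0.5 ms sample toward the position estimated at the last reception - the
per-sample control that the steering law prescribes. Decision priority:
(1) avoid a conspecific whose predicted path over the next 0.1 s comes
within 20 cm (released with 2x hysteresis at 40 cm to prevent chattering in
and out of the maneuver), or the border; (2) pursue the closest detected,
non-jammed prey; (3) search (random walk, new turn rate ~ N(0, 1) rad/s per
IPI, clipped to the same 4 m/s^2 limit). A capture requires passing within
5 cm of the prey.

**Acoustics.** Every call produces, at every bat, the events the receiver
must sort out: the bat's own prey echoes (two-way sonar equation, `D^-4`
spreading), the direct calls of conspecifics (one-way, `D^-2` - these are
tens of dB louder than prey echoes at equal range, which is the entire
masking problem), bistatic echoes of conspecific calls off every prey, and
optionally border clutter (rays at 5.7 degree spacing, leaf-sized discs,
power-summed over the frontal +/-90 degrees). Directivity uses the circular
piston model for mouth (radius 3 mm, unit boresight gain referencing source
levels at 0.1 m) and ear (7 mm, aperture gain `4 pi A / lambda^2`), with an
extra 0-20 dB back-hemisphere attenuation growing linearly from 90 to 180
degrees. Atmospheric absorption is `3.8e-2 f_kHz - 0.3` dB/m; the prey is a
2 cm disc with `sigma = 4 pi A^2 / lambda^2`. Distances are clamped to the
0.1 m source-level reference inside the level equations, which diverge
below it.

## Receivers

Two alternative receiver models turn arrivals into detections.

The **correlation receiver** is the optimal matched filter and assumes the
bat can tell prey echoes from maskers (maskers are never target candidates).
An audible echo (>= 0 dB-SPL) is *jammed* if any audible masker's
cross-correlation peak with the bat's own template falls within 3 ms before
the echo and within 5 dB of the self peak, or within 1 ms after it and
within 0 dB - the law of the first wave-front. Cross-correlation peaks and
lags between FM chirps are computed on complex analytic chirps (envelope
exact) and memoised on quantized chirp parameters (duration 0.5 ms,
terminal frequency 1 kHz, bandwidth 2 kHz); the quantization perturbs peak
ratios by under ~1 dB, small against the 5 dB masking margin.

The **filter-bank receiver** models the auditory periphery: 80 gammatone
channels, `fc_k = 5702 * 2^(k/20.9)` Hz (about 5.9-81 kHz), order 4,
bandwidth constant `b = 0.15 fc`, each envelope-detected (full-wave
rectification plus low-pass by default; a half-wave rectifier with a 10 kHz
low-pass is available as `envelope = "halfwave"`). Channels are shifted to
compensate the chirp's sweep delay and summed; peaks above 7 dB-SPL
(separated by at least one call duration) are candidate detections. The
receiver runs twice per call - echoes only, then echoes plus maskers - and
differences define jamming, time-estimation errors and *false alarms*
(an earliest peak present only with maskers, which the bat pursues as a fake
target). Waveforms are synthesized at 500 kHz only inside reception windows.

Detection feeds noisy estimates: range error combines an SNR-dependent term
(1 cm at 10 dB SNR) with the bat's 50 us timing jitter (a 0.86 cm floor);
direction-of-arrival error combines a 1 degree (at 10 dB) noise term with an
angle-dependent term anchored at 1.5 degrees on-axis and 10 degrees at 90
degrees. SNR enters these error laws in dB, floored at 1 dB so the noise
terms stay bounded near threshold; the calibration anchors at 10 dB hold
under either convention, which the paper-agnostic error laws leave open.

## The JAR and the frequency regimes

Three regimes assign search-phase terminal frequencies: `identical` (all 39
kHz), `random` (per-bat N(39, 4) kHz, the between-individual variation seen
in the field), and `jar` (random draws, truncated to [35, 43] kHz so the
shifting rule's bounds hold from the first call). Under the JAR, a bat whose
*pursued* prey echo is jammed shifts its whole band 2 kHz away from the
masker's terminal frequency, clamped to [35, 43] kHz, and keeps the shifted
repertoire for five calls (a further jam shifts again and resets the
counter). After an uneventful hold the frequency simply stays - no reversion
is modeled, as none is described. Jam detection by the simulated bat uses
the simulator's ground-truth jam flag for the pursued prey's echo; real bats
would have to infer jamming from expectation violations, so this gives the
JAR its best case.

## Attempt accounting

An *attack attempt* is registered once a bat has pursued the same prey
within attack range (approach or buzz, i.e. estimated range <= 1.2 m) on two
consecutive decisions - a one-call flirtation is not an attack. A momentary
interruption (the echo jammed or lost, an avoidance jink, a brief switch to
another candidate) leaves the attempt *pending* for up to 0.25 s (two to
three search IPIs); if the bat re-commits to the same prey the attempt
simply continues, which keeps the attempt count invariant to masking, as it
must be - masking changes how attempts end, not how often bats attack.
A call that returns nothing reverts the bat immediately to search behavior
(the phase machine is driven by the distance to a detected target, and there
is none) - the strict no-memory reading, under which a single jammed echo
costs real ground. This is the mechanism by which masking converts would-be
captures into misses. A pending
attempt closes with the latest interrupting cause: `conspecific_avoidance`
or `obstacle_avoidance` when an avoidance maneuver broke the pursuit,
`lost_to_conspecific` when a competitor captured the prey out from under an
actively pursuing bat (a bat that had already broken off overtly keeps its
avoidance label), `miss` for everything else - insufficient maneuvering and
sensory loss, including jamming. `capture` ends an attempt within 5 cm of
the prey. Attempts still open at trial end are censored (discarded).

## Metrics

`jamming_probability()` is the fraction of *pursued-prey* echoes blocked by
maskers - not the fraction over all echoes, since a call can return several
echoes but at most one is pursued (during search the focal prey is the
closest audible one, the prey the bat would attack). It is also reported per
phase. `masking_effect()` is the percent performance reduction against the
no-masking null; because it is a ratio of noisy estimates its SD uses the
delta method (`ratio_sd()`). `emergent_frequency_shift()` compares the mean
emitted call frequency between group and solo trials with the JAR off; the
default measure is the call's average (sweep-centre) frequency. Under this
measure the shift is small and positive because two compositional effects
nearly cancel: solo bats complete more captures and therefore emit both more
high-centre approach/buzz-I calls and more low-centre (19 kHz terminal)
buzz-II calls. The terminal frequency alone (`measure = "terminal"`) is
dominated by the buzz-II fraction and shifts by kilohertz; it is provided
for comparison but is not what field analyses of search-call frequencies
respond to.

## What the generator emulates, and what it does not

The simulation reproduces the *sensorimotor* texture of group foraging:
distance-adaptive echolocation, realistic levels along the whole acoustic
chain, receiver-limited detection, collision avoidance and competition. It
deliberately underestimates real bats: hearing is monaural (no spatial
unmasking, no HRTF), there is no memory of target positions, no second
harmonic, masking windows are long (3 ms / 1 ms) and thresholds low. Passing
tests therefore show the model's internal consistency and its agreement with
the published rates under these conservative assumptions - not that real
bats behave identically; real bats should do better.

## Numerical and design choices

- Time step 0.5 ms; emissions snap to the tick grid. One global RNG stream
  per trial, seeded per trial, so any `(config, seed)` pair reproduces
  exactly; grid cells and replicates draw independent sub-seeds from the
  master seed.
- Geometry snapshots: own echoes are evaluated with the bat's pose at
  emission and prey positions at the decision time; conspecific calls use
  the transmitter's logged emission pose and the receiver's pose at its own
  last emission. Agents move at most ~0.35 m within a search IPI, small
  against the geometry.
- Chirp directivity: a pure tone can sit exactly in a piston null, but a
  30+ kHz sweep cannot; level bookkeeping therefore averages the piston
  power pattern over five frequencies spanning the call band. The exported
  `piston_gain()` keeps the single-frequency form.
- The level equations are evaluated at the call's centre frequency;
  receivers see the full sweep through the correlation/filter-bank
  machinery.
- Maskers outside any echo's reception window are pruned before the
  correlation stage; the filter-bank, which can false-alarm with no echo at
  all, keeps maskers arriving within plausible detection delays (60 ms).
- Filter-bank peak matching tolerates half a call duration (at least 0.5
  ms); the de-chirped sum is normalized by the response of a unit-amplitude
  copy of the own call, so the 7 dB-SPL threshold is exact by construction,
  and the same calibration fixes the peak-time offset used for ranging.
- Degenerate inputs: distances below the 0.1 m reference are clamped;
  zero-length echo sets short-circuit; an undefined jamming probability
  (no pursued echoes) is reported as `NA`, never 0.
- Problem sizes in the tests and in `scripts/acceptance.R` are desk-scale
  choices: 10 s trials, two to three replicates per 20-bat cell, twenty to
  thirty solo replicates - enough for the pooled attempt counts (300+) and
  SE-based tolerances used there.

## Known limitations

Avoidance geometry (flee direction, border margin, the 0.1 s prediction
horizon and 2x release hysteresis) and the attempt-boundary constants (two
confirming calls; 0.25 s re-commit window) are behavioral conventions the
underlying literature leaves open; the failure-taxonomy fractions shift by a
few percentage points under reasonable alternatives, while capture rates,
jamming probabilities and all acoustic quantities are insensitive to them.
The clutter model treats the border as isotropic point discs; no coherent
multipath, Doppler or frequency-dependent target strength beyond the disc
law is modeled.
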