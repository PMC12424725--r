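---
title: "Models and methods behind loopscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind loopscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

loopscope is a closed-loop microscopy engine with a simulated microscope
behind it. This vignette documents the models it implements, the
parameters that matter, the design decisions that were genuinely open,
and what the simulation does and does not establish about real
experiments.

## The closed loop

An experiment is a master schedule (total length, imaging cadence,
stimulation cadence — two independent clocks), a list of named stage
positions, and one configuration per position naming a segmentation
module and a pattern module. The scheduler expands this into a timeline
of `stimulate`, `image`, `segment` and `compute_pattern` events; at equal
timestamps the order is stimulate < image < segment < compute_pattern,
except at t = 0 where closed-loop positions image first so the first
feedback pattern can derive from a mask.

The ordering contract is the core guarantee: *the pattern projected at
any stimulate event at time t derives from the most recent completed
segmentation of a frame acquired at or before t*. Stimulation cadence is
never broken: before the first computed pattern, or after a module
failure, the most recent completed pattern (initially all-dark) is
re-projected. A replay validator (`validate_record()`) re-checks the
contract on the recorded event log rather than trusting the loop. The
reference execution is a single-threaded event loop on a simulated clock;
the contract, not the threading, is the specification, so a real-time
implementation may overlap computation with acquisition as long as the
replay validator stays clean.

One consequence worth knowing: because stimulation precedes imaging at a
shared timestamp, a feedback decision at time t always acts on the
measurement from the previous imaging round — the loop has an inherent
one-frame latency, exactly as in a real microscope where segmentation of
the current frame cannot finish before the stimulus that accompanies it.

## Coordinates and units

One shared frame: image row index and physical y both increase downward,
origin at the top-left pixel centre, stage coordinates and pixel size in
µm, intervals in seconds (`"16h"`, `"5min"`, `"30s"` accepted in TOML).
Centroids are 0-based (x, y) = (column, row) pixel-centre coordinates.
"Counter-clockwise" is defined in display orientation; with y down the
ccw tangent of radius vector r is (r_y, −r_x)/|r|.

## The simulated biology

### Migration

Each cell carries a polarity vector **p** obeying

    dp/dt = (clamp(α ∇L̃) − p) / τ_p,     dx/dt = v0 p + noise,

where L̃ is the projected pattern smoothed with a Gaussian of σ_sense
(the spatial scale over which a cell integrates illumination) and the
target is clamped to |·| ≤ 1 so v0 is a true speed ceiling. Defaults:
v0 = 20 µm/h, α = 47 µm, τ_p = 10 min, σ_sense = 8 µm, positional noise
0.2 µm/√h. α was set so that the gradient at the edge of a smoothed bar
saturates the polarity target (α ≈ 1.2 / max|∇L̃|); v0 was chosen a
little above the slow wave speeds of interest so that wave-locking has a
stable fixed point. τ_p deserves a note: a first draft used ~20 min, but
with the polarity lag that long the wave-locked state is not a fixed
point of the relative-frame dynamics — cells orbit it in a delay-induced
limit cycle and the phase-binned velocity mixes signs even at slow wave
speeds. At 10 min the lock is overdamped and the slow-wave regime is
clean; 10 min is still a biologically reasonable protrusion-reorientation
time.

With these defaults the two wave regimes emerge from the dynamics rather
than being scripted. Slow waves (≲ v0): a cell caught in the trailing
half of a bar sits in a gradient pointing along the wave; the point where
v0·p equals the wave speed is a stable equilibrium, so cells ride the
wave indefinitely and the population condenses onto the lock phase — the
phase-velocity histogram is one-signed and most bins starve. Fast waves
(≫ v0): the gradient alternates faster than τ_p can follow; cells rock
toward each incoming bar and after each outgoing one with little net
transport, giving the antisymmetric, sign-changing phase profile. The
acceptance script computes the resulting tissue velocities
(≈ 7.8 / 11.8 / 7.7 / 1.6 µm/h at wave speeds 8 / 12 / 25 / 50 µm/h,
seed 1) through the full imaging → segmentation → tracking pipeline.

### Photochromism

Fluorescence follows two-state first-order kinetics: under light it
relaxes toward k·baseline with τ_on, in the dark toward baseline with
τ_off; those are the only fixed points, so F never leaves
[baseline, k·baseline]. Defaults k = 4.5, τ_on = 30 s, τ_off = 120 s;
the fold change is the experimentally motivated number, the time
constants are free model parameters. Illumination is binary (> 0), with
no irradiance calibration — configured power densities are metadata only.
A dimensional detail: after exactly 5 τ_off in the dark, the residual
brightening is e⁻⁵ ≈ 0.67 % *of the light-induced change*, which for
k = 4.5 is ≈ 2.4 % of baseline; reversibility statements in the tests are
therefore normalized to the induced change, the quantity that actually
relaxes exponentially.

### Imaging

Nuclei render as isotropic Gaussians with σ = √(psf² + radius²) whose
integrated intensity is constant in the nuclear channel and equals the
cell's current fluorescence in the red channel; additive background and
Gaussian read noise follow. The blur is circular at the field edge, which
preserves total intensity exactly (handy for conservation tests) at the
price of a little wrap-around light at the border.

### Boundaries

The default boundary is reflection. The traveling-wave assay instead
uses periodic wrap (`boundary = "wrap"` in the `[simulate]` table, with a
field height that is a whole number of bar periods): a reflecting wall
traps wave-locked cells that ride the wave into it, and the pile-up
contaminates the phase analysis with an artifact that real, much larger
tissues do not have. Wrap makes the field a window into an unbounded
periodic tissue, which is the situation the wave analysis assumes.

## Segmentation and measurement

The built-in segmenter is Gaussian smoothing → Otsu threshold →
8-connected labelling → area filter → raster renumbering, operating on
the (uniform-brightness) nuclear channel so that Otsu is not confused by
fluorescence heterogeneity. The labelling is EBImage's 4-connected
`bwlabel` plus an explicit diagonal merge. An adapter slot with the same
signature exists for external learned segmenters; it fails at plan-build
time, not mid-run, when the backend is absent. Per-cell measurement
reports area, unweighted centroid, mean intensity per channel and the
median intensity of background pixels (the background estimate subtracted
in downstream CV analysis).

## Feedback control

The bang-bang module illuminates a cell's whole mask territory at full
power iff its measured mean intensity is below set point minus an
optional hysteresis band (default 0 — a plain thermostat). Set points are
scalar or a grayscale image sampled as the mask-region mean. A projected
pattern stays active until the next projection.

What discrete bang-bang can and cannot do here is worth stating
precisely, because it is the one place where this simulation knowingly
falls short of the real experiment it mimics. With control every 30 s and
τ_on = 30 s, one lit interval moves a cell 63 % of the way to
k·baseline, and one dark interval removes 22 % of its elevation: the
controller's authority per step is enormous, so cells overshoot the set
point and ripple around it. The acceptance script measures the
consequence: starting from CV 0.45, forty control rounds reach a CV
fold-reduction of ≈ 1.15 (and ≈ 27 % of cells within 10 % of a two-level
set-point image), far below what continuous control of the same
population could achieve by pinning every controllable cell at its set
point, and no choice of projection duty within the interval removes the
ripple. Real photochromic feedback systems do much better because their
per-pulse gain is tiny (hundreds-of-millisecond pulses against much
slower effective kinetics) — equivalently, slowing both time constants
at the same 30-s cadence would restore fine-grained authority. The dose the controller delivers nonetheless
carries the heterogeneity information exactly as expected: cumulative
per-cell light dose anti-correlates strongly with baseline brightness
(Spearman ≈ −0.84).

## Analysis choices

* Tracking is greedy mutual-nearest-neighbour linking with a 10 µm/frame
  gate (the live loop deliberately does not track; analysis runs on the
  recorded centroid tables).
* Velocities are central differences (forward/backward at track ends) in
  µm/h; tissue velocity is the mean of per-cell velocity samples over the
  analysis window, which drops the first hour as equilibration.
* Phase bins: 20 over [−1/2, 1/2); bins with fewer than 20 samples are
  reported as missing (their counts are still returned) — a mean and SD
  over a handful of samples is noise, and at slow wave speeds most of
  phase space is legitimately unoccupied.
* CV uses the population (n-divisor) standard deviation over the cells
  present at each frame, after background subtraction.
* Polar decomposition: v_radial positive outward, v_tangential positive
  ccw (same convention as the vortex pattern); speed is preserved
  exactly.

## Problem sizes

The canonical assays are sized for a laptop-class single core: wave
sweep 4 × 240 cells on 480² px for 16 h simulated (5-min imaging, 1-min
stimulation); feedback control 1,000 cells on 512² px for 40 rounds of
30 s; vortex 80 cells on 256² px for 2–3 h; 15-position fault-isolation
run at 96² px. These sizes were chosen so the full suite exercises every
code path at meaningful statistics in minutes.

## Open decisions, resolved

* The TOML schema and the multipoints XML/CSV dialect are defined by this
  package (documented in the function reference); no external dialect is
  assumed.
* Bars are binary at the edge; duty is conserved to one row over
  whole-period windows, the premise under which "illuminated fraction =
  duty" is a theorem.
* The vortex gradient ramps across each cell's own territory (per-cell
  normalization), so every cell receives the same dynamic range; a
  field-wide ramp would under-drive cells far from the centre.
* The per-cell vortex loop produces fast tangential and slightly inward
  radial motion in the simulation; the inward component is not asserted
  as a model prediction since it is sensitive to territory geometry, and
  cell–cell mechanics (absent here) dominate it in real tissue.

## What passing tests do not show

The simulator has no cell division, death, crowding or mechanical
coupling; illumination response is binary; nuclei are Gaussian blobs.
Passing tests establish that the *engine* — scheduling, module plumbing,
pattern geometry, feedback wiring, analysis arithmetic — is correct, and
that the agent model reproduces the qualitative regimes it was built to
reproduce. They do not calibrate any biological magnitude: real tissue
speeds, wave-speed optima or controller convergence times must come from
real cells.
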