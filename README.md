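# loopscope

Closed-loop optogenetic microscopy in R: a master scheduler that sequences
imaging, nuclear segmentation, stimulus-pattern computation and patterned
illumination across multipoint acquisitions — together with a fully
simulated microscope backend so the entire loop can be built, run and
tested without hardware.

## Who this is for

Labs running "smart microscopy" experiments in which a digital micromirror
device (DMD) projects blue-light patterns onto optogenetically responsive
cells, and the next pattern depends on what the camera just saw. The
package reproduces that control loop in software: experiments are declared
in plain TOML files plus an XML stage-position list, and each field of
view runs its own combination of segmentation and pattern modules.

Built-in pattern modules:

* **bars** — traveling horizontal bar waves. A row at physical coordinate
  *y* (µm) is illuminated iff

  ```
  wrap(y − y0 − v·t, P) < d·P
  ```

  with period *P* (µm), signed speed *v* (µm/h), duty cycle *d* ∈ (0, 1]
  and offset *y0*. The wave phase of a position is the signed fractional
  offset from the nearest bar centre, φ ∈ [−1/2, 1/2) cycles, with φ = 0
  when the bar is centred on the position; a pixel is lit iff
  φ ∈ [−d/2, d/2).
* **vortex** — closed loop: nuclei are segmented, the field is divided
  into Voronoi territories, and each territory receives a linear light
  ramp along the tangential direction of its cell about the field centre
  (ccw or cw), driving rotational tissue flow.
* **bangbang** — closed-loop thermostat control of per-cell fluorescence:
  a cell's territory is illuminated at full power iff its measured mean
  intensity is below its set point (scalar, or sampled from a grayscale
  set-point image), exploiting the reversible photochromic brightening of
  the red fluorophore under blue light (fold change k, on/off time
  constants τ_on, τ_off; first-order kinetics toward k·baseline under
  light and baseline in the dark).
* **constant** — static regions.

The simulator models cells as agents whose polarity **p** relaxes with
time constant τ_p toward α·∇L (the illumination gradient sensed at the
cell scale, clamped to |p| ≤ 1) and which translocate at v0·**p** plus
Brownian noise; fluorescence follows the photochromic kinetics; a camera
model renders Gaussian nuclei with background and read noise.

## Worked example

```r
library(loopscope)

sched <- parse_schedule('
[schedule]
length = "16h"
imaging_interval = "5min"
stimulation_interval = "1min"
seed = 1
')
pos  <- parse_multipoints('<positions><position name="A1" x="0" y="0"/></positions>')
cfg  <- parse_position_config('
[position]
name = "A1"
pixel_size_um = 1.0
fov = [480, 480]
[segmentation]
module = "threshold"
[pattern]
module = "bars"
period_um = 32
speed_um_per_h = 12
duty = 0.75
[simulate]
n_cells = 240
boundary = "wrap"
[[channels]]
name = "nuclear"
')
plan <- build_experiment_plan(sched, pos, list(cfg))
rec  <- run_loop(plan)
validate_record(rec)$ok        # TRUE: every stimulus derives from a past frame
```

The canonical assays wrap exactly this kind of run. Sweeping wave speeds
8, 12, 25, 50 µm/h (`simulate_wave_assay(seed = 1)`) prints mean tissue
velocities along the wave of

```
7.83  11.79  7.71  1.58   µm/h
```

— a unimodal curve with an interior optimum at 12 µm/h and near-zero net
transport at 50 µm/h; the phase-binned velocity is one-signed (all
positive, wave-following) at 12 µm/h and sign-changing at 50 µm/h. These
are the two regimes of wave entrainment: slow waves lock cells in the
gradient at a bar's trailing edge, fast waves only rock them back and
forth. `simulate_feedback_assay(seed = 1)` runs 40 rounds of bang-bang
control on 1,000 heterogeneous cells (baseline CV 0.45) and reports, among
other numbers, a Spearman correlation of **−0.84** between each cell's
cumulative light dose and its baseline brightness — the controller pumps
light into dim cells and leaves bright ones alone.

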