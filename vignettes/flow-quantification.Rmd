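---
title: "Quantifying valveless pump output from tracer video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying valveless pump output from tracer video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liebauflow)
```

## The measurement problem

A Liebau (valveless impedance) pump produces net unidirectional flow by
periodically compressing a compliant tube at a position asymmetric with
respect to its junctions with stiffer tubing. Its output is commonly
measured by seeding the working fluid with dark tracer particles (here
~0.5 mm carbon particles), filming a transparent observation segment at
60 frames/s, tracking the particles, and converting their time-averaged
velocity into a volumetric flowrate. `liebauflow` implements that whole
chain — detection, linking, gap closing, velocity averaging, Womersley
correction — together with the closed-form physics used to interpret the
result, and a ground-truthed synthetic scene generator so every stage can
be validated without laboratory video.

## Flow model and the k_w correction

Pulsatile laminar flow in a rigid circular tube is characterized by the
Womersley number
$$W\!o = r\sqrt{\rho\,\omega/\mu},\qquad \omega = 2\pi F,$$
with $r$ the lumen radius, $\rho$ the fluid density, $\mu$ its dynamic
viscosity and $F$ the compression frequency. For $W\!o \lesssim 1$ the
oscillatory velocity profile is parabolic; for $W\!o \gtrsim 10$ it is
nearly flat; the experiments this package targets sit in between
($W\!o \approx 2$–$8$).

Tracked tracers ride near the tube axis, so the quantity the camera sees
is (close to) the centerline velocity. The net flowrate follows from
$$Q = k_w\,A\,\bar v,$$
where $A$ is the lumen cross-section and $k_w \in [0.5, 1]$ maps the
centerline time-average $\bar v$ onto the cross-section mean.
`kw_correction()` defines $k_w$ as the ratio of the cross-section-averaged
to the centerline time-averaged velocity magnitude of the fundamental
oscillatory mode,
$$k_w(W\!o) = 2\int_0^1 u(\xi)\,\xi\,d\xi,\qquad
  u(\xi) = \left|\,1 - \frac{J_0(i^{3/2} W\!o\,\xi)}{J_0(i^{3/2} W\!o)}
  \right| \Big/ \left|\,1 - \frac{1}{J_0(i^{3/2} W\!o)}\right|,$$
evaluated by composite Simpson quadrature on 512 radial intervals. The
exact closed form used by the original k_w reference is not restated in
the source experiment reports, so this numerically integrated definition
is the package's contract; it has the right limits ($0.5$ as
$W\!o \to 0$, $1$ as $W\!o \to \infty$), is monotone, and agrees with a
10$\times$ denser independent quadrature to better than $10^{-3}$. Note
that worked numbers in the experimental literature imply $k_w \approx
0.668$ at the 2.5 Hz water operating point, whereas this definition gives
0.767 at the corresponding $W\!o = 6.1$ (and 0.666 at $W\!o = 5$); since
the reference tabulation is unavailable, consistency checks against such
printed triples use the back-solved $k_w$ rather than the model.

$J_0$ of complex argument is evaluated in-package (ascending series for
$|z| \le 12$, Hankel asymptotic expansion beyond), since no installed
library exposes complex-argument Bessel functions; the real-axis special
case is cross-checked against base R's `besselJ` in the tests.

## Interpretation calculators

All internal units are SI; reporting helpers convert to the units used at
the bench (mm/s, µl/s, ml/min, cP, kPa).

* `young_modulus()`: single-point secant modulus
  $E = g\,m\,L/(A\,\Delta L)$ of a weighted elastomer strip, with $g$
  fixed at 9.81 m/s². For the soft silicones targeted here the linear
  part of the stress–stretch curve extends to 100% strain, so the secant
  at one point suffices; no hyperelastic fitting is attempted.
* `moens_korteweg_speed()`: pressure-wave speed
  $c = \sqrt{E h/(\rho d)}$ of a thin-walled elastic tube.
* `natural_frequency()`: standing-wave resonance estimate $F_n = c/(2L)$.
* `peristaltic_flowrate()`: the reference output $Q = F\,A\,P$ of an
  idealized peristaltic pump with the same lumen, pincher width $P$ and
  frequency — the natural yardstick for valveless output
  (`peristaltic_comparison()` forms the ratio).
* `glycerin_water_viscosity()`: the Cheng (2008) exponential-mixing
  correlation with temperature-dependent component viscosities.
  Glycerol percentages are interpreted as **volume** percent and
  converted to mass fraction with $\rho_{gly} = 1.26$ g/ml: under the
  mass interpretation the correlation under-predicts the conventional
  2.26 cP value for 25% glycerin at 22 °C by roughly 15%, while the
  volume interpretation reproduces all six standard values
  (0.95–2.26 cP) within 2%.
* `poiseuille_resistance_scaling()`: $R \propto \mu L / r^4$, used only
  as a ratio between configurations.

## What the synthetic scenes emulate

`generate_scene()` stands in for the laboratory video: 60 frame/s clips
(default 30 s, three replicates) of dark 0.5-mm tracers advected through
a straight observation window by pulsatile flow carrying a **known** net
flowrate. Key choices:

* **Waveform.** The per-compression velocity pulse is a half-cosine rise
  during the pincher's `time_on` (0.2 s in the emulated protocol)
  followed by an exponential decay with time constant `time_on` during
  `time_off`. This reproduces the observed intermittent
  advance-per-compression without claiming pump mechanics. The series is
  rescaled so that its $k_w$-corrected mean times the lumen area equals
  the target flowrate *exactly*; conservation of the ground truth is by
  construction, not calibration. A symmetric variant (pulse minus its
  half-period mirror) emulates the zero-net-flow behaviour of a mid-tube
  pincher.
* **Radial placement.** Each tracer is assigned a fixed radial position
  at entry, up to 15% of the lumen radius by default, and moves at the
  centerline waveform times the Womersley profile at that radius. Large
  dense tracers in a 3-mm tube genuinely travel near the axis; keeping
  them within 0.15 R keeps their speed within ~1% of the centerline, so
  the tracked aggregate is a faithful centerline proxy. There is no
  radial migration and no out-of-plane motion (thin-slab optics).
* **Camera model.** 0.05 mm/px (a 0.5-mm tracer spans 10 px), field of
  view 15 mm × the tube diameter, pixel centers at integer 0-based
  coordinates, x axial with positive flow toward the shorter segment.
* **Noise.** Detection jitter (Gaussian, default 0.5 px), missed
  detections (default 5%, exercising gap closing), and single-frame false
  positives (default 0.1/frame). Rendered frames draw anti-aliased dark
  discs on a light background with Gaussian sensor noise.
* **Determinism.** Clip $k$ of a configuration uses seed
  `seed + k - 1`; identical seeds give byte-identical detection tables.

What the generator does **not** emulate: real illumination gradients and
shadows, tube-wall refraction, particle size dispersity, overlapping-disc
occlusion statistics of dense seeding, radial migration, or any
position-dependent pump physics — the mapping from protocol to true
flowrate is a declared amplitude model, linear in frequency and vanishing
for a mid-tube pincher, not a fluid–structure simulation. Passing tests
therefore validate the *measurement chain*, not a pump model: they show
the pipeline recovers a known flow under realistic detection noise, not
that a real Liebau pump produces any particular output.

## Tracking design

* **Detection.** One automatic Otsu threshold per stack (per-frame
  thresholds flicker), connected components, darkness-weighted sub-pixel
  centroids over the component dilated by 1 px so the anti-aliased rim
  contributes; components below 25% of the expected particle area are
  discarded. Interior (non-edge-clipped) discs are recovered to well
  under 0.25 px RMS.
* **Linking.** For each consecutive frame pair, a globally optimal
  one-to-one assignment (Jonker–Volgenant LAP in compiled code) with link
  costs equal to Euclidean distance, a hard gate at `max_link_distance`,
  and a no-link alternative at the gate cost. This is deterministic and
  input-order-independent, unlike greedy nearest-neighbor; ties cannot
  depend on row order because detections are sorted by (x, y) within
  frame. The default gate is 1.5× the peak expected per-frame
  displacement **plus** six standard deviations of the apparent jitter
  displacement: without the jitter allowance the gate preferentially
  cuts the largest true displacements once noise is present and biases
  the velocity low.
* **Gap closing.** A second global assignment joins track ends to later
  track starts within `max_gap_frames` (default 2) and
  `max_gap_distance` (default 2× the link gate), each end/start used at
  most once. Velocities across a closed gap of $k$ missed frames divide
  the displacement by $k+1$ frames.
* **Filtering.** Tracks shorter than 5 detections are dropped;
  single-point tracks are excluded from velocity estimation with a
  logged count. No Kalman prediction, no track splitting or merging —
  the target tracker family is nearest-neighbor plus gap closing only.

## Flow quantification

The clip velocity is the duration-weighted mean over all linked steps of
all tracks (each step weighted by its frame span): the camera tracks
whatever particles are visible, and $k_w$ maps that aggregate onto the
mean flow. Replicates are combined as the mean and sample ($n-1$)
standard deviation across clip means (flagged undefined for a single
clip). Velocities are signed, so a reversed or zero-net flow is reported
as such. Whether to pool steps or average per-track means is genuinely
open; duration-weighted pooling is declared here because it weights each
observed particle-frame equally and is robust to many short tracks.

Sweeps (`run_sweep()`) regenerate scenes per grid point (frequency,
viscosity, or pincher offset; per-point seeds derived as base +
1000·index), quantify each, and fit an unweighted ordinary least-squares
line — the experimental trends these sweeps mirror are reported as
unweighted linear relationships. In viscosity sweeps, points with
$W\!o > 5$ are fitted but flagged, since the quasi-steady resistance
argument that predicts linearity degrades there.

## Numerical and degenerate-input choices

* $W\!o < 10^{-3}$ uses the Poiseuille parabola directly (the complex
  ratio suffers cancellation as $W\!o \to 0$); $W\!o = 0$ is the
  Poiseuille limit, not an error; negative or non-finite $W\!o$ raises.
* $k_w$ is clamped to $[0.5, 1]$ after quadrature.
* A forward waveform asked to carry zero net flow, a symmetric waveform
  asked to carry net flow, and a scene whose waveform never puts a
  particle in view all raise immediately rather than generating
  degenerate data.
* Configuration files are flat YAML with units in the key names
  (`inner_diameter_mm: 5`); unknown keys are rejected rather than
  ignored.

## Problem sizes used in the shipped tests

The validation suite runs scenes of 5–10 s at 60 frames/s with 4–6
particles per frame (end-to-end recovery at 5, 15 and 40 µl/s over 10
seeds, noiseless and at default noise; frequency-sweep slope recovery
over 5 seeds), 100 random small instances against the exhaustive
assignment oracle, and exhaustive single-deletion gap-closing checks on
short clips. These sizes were chosen so the full suite exercises every
stage at statistical resolution well below the asserted tolerances
(2% observed worst-case recovery error against a 5%/15% contract).

## Known limitations

* $k_w$ assumes the fundamental oscillatory mode dominates; strongly
  multi-harmonic waveforms are not decomposed (the generator's pulse
  train is treated through its fundamental).
* The Womersley profile is the rigid-tube solution; wall compliance of
  the observation segment is neglected (appropriate for the stiff Tygon
  observation tube, not for the compliant segment itself).
* Tracer inertia and finite size are ignored: particles are perfect flow
  followers at a fixed radius.
* Edge-clipped discs bias rendered-frame centroids inward; detection
  accuracy claims hold for interior particles.
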