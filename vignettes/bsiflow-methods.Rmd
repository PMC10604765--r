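---
title: "Blood speckle velocimetry and wall shear stress: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blood speckle velocimetry and wall shear stress: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsiflow)
options(bsiflow.log_level = "quiet")
```

`bsiflow` implements a complete blood-speckle-imaging (BSI) quantification
chain: a synthetic speckle phantom with analytically known pulsatile flow, a
block-matching velocimeter with a match-confidence channel, and the
hemodynamic post-processing used to characterize outflow-tract flow —
velocity and shear-stress profiles, signed wall shear stress (WSS) series,
the time-averaged wall shear stress (TAWSS), the oscillatory shear index
(OSI), peak-velocity traces and simplified-Bernoulli pressure gradients.
This vignette explains the models, the numerical choices and their limits.

## The data model

A BSI acquisition is represented by a `cine_loop`: a time-ordered stack of
co-registered channels on one pixel grid — tissue brightness, in-plane
velocity `(vx, vy)` in m/s, and a confidence level in [0, 1] where 1 means a
high-fidelity speckle match — plus metadata (pixel pitch in mm/pixel, pulse
repetition frequency PRF in Hz, cardiac period T, frame times). Physical
coordinates are 0-based pixel indices times the pixel pitch, origin at the
image's top-left corner; x is the long axis (flow direction), y the short
axis, with larger y toward the posterior wall. Defaults mirror a pediatric
transesophageal acquisition: 0.0825 mm/pixel and a PRF of 6 kHz, with a
2 m/s tracking limit.

Clinical BSI recordings are not redistributable, so every stage is designed
to be testable against phantoms whose ground truth is known in closed form.

## The speckle phantom

The phantom places point scatterers with Rayleigh-distributed reflectivities
uniformly over the field of view plus a margin, at a default density of 4
scatterers per point-spread-function area — the standard regime for fully
developed speckle (verified by a tile-variance test). Frames are rendered as
sums of Gaussian PSFs (default sigma 1.2 px) plus additive Gaussian
brightness noise, and the cloud is advected through an analytic flow field
with a midpoint (RK2) step at the pulse-repetition interval; first-order
stepping would be adequate almost everywhere, but RK2 is cheap insurance at
jet shear layers. Scatterers leaving the margin are wrapped to the opposite
edge with fresh reflectivities, conserving the count.

Two scaling choices keep phantom studies tractable:

* **Cycle compression.** The cardiac period is `frames_per_cycle / PRF`
  (about 6.7 ms at the defaults), so consecutive *tracked* frames are one
  pulse interval apart while a whole cycle fits in 40 frames. All derived
  quantities are phase-based (t/T) and unaffected; wall-time quantities are
  not the phantom's subject.
* **Geometric scale.** The default field of view is 13.2 x 11.1 mm — an
  outflow-tract-sized window, smaller than a full echocardiographic sector.

The flow models are separable into a short-axis profile and a periodic
envelope `w(t/T)`: a raised-cosine systolic pulse rising from 0 at t/T = 0,
peaking at t/T = 0.2 (peak systole) and closing at t/T = 0.5; the diastolic
half carries no outflow (diastolic mitral inflow is outside the phantom's
scope). Four profiles are available:

* `uniform` and `parabolic` (Poiseuille channel) — calibration fields whose
  tracking error and wall shear are known exactly;
* `tophat_jet` — a nearly uniform core with tanh shear layers and minor
  counter-rotating lobes near both walls: the healthy, post-valvular
  profile;
* `stenotic_jet` — a narrow jet whose centre drifts anteriorly over systole,
  with a broad zone of reversed flow on the posterior aspect that develops
  *after* early systole (recirculation needs time to form), a weak forward
  co-flow pedestal, and a slight anterior tilt of the jet vector.

The axial profile is normalized so the peak axial speed at peak systole
equals `peak_speed`. The early-systole forward co-flow followed by the
developed posterior recirculation is what makes the posterior wall WSS
change sign over the cycle — the mechanism behind a nonzero OSI in stenotic
outflow — while the anterior wall stays unidirectional.

**Resolvability as a design constraint.** Block matching estimates one
displacement per kernel; when the true displacement varies by more than
about one pixel *across* a kernel, the speckle decorrelates and the estimate
degrades in an unrecoverable way. The default phantom therefore uses
shear-layer thicknesses (1.4–1.5 mm) for which the displacement spread
across the default 15 px kernel stays near 1 px at the default peak speeds.
Thinner layers are physically plausible but produce fields that *no*
block-matching tracker at this kernel size could recover; they are the right
stress test for saturation behaviour, not for parameter-recovery claims.
For the same reason the posterior recirculation lobe is positioned with its
maximum-gradient edge (an inflection point of the velocity profile, where
kernel averaging is unbiased) at the posterior wall-sampling location, and
the field of view is tall enough that the lobe lies fully inside the tracked
region.

Image noise defaults to sigma 0.05 in brightness units against a speckle
contrast of order 1 — a clean-acquisition regime. The optional `noise_ramp`
grows the noise with depth to emulate the depth-dependent confidence loss
seen in transesophageal imaging; it is off by default.

## Block-matching velocimetry

For each kernel centre on a regular grid (default 15 px kernels, 2 px
stride), the tracker finds the displacement of the kernel between
consecutive frames by maximizing zero-mean normalized cross-correlation
(NCC) over integer lags, then refines each axis with a three-point peak fit.
The confidence channel is the best integer-lag NCC clamped to [0, 1], which
directly honours the "0 = low, 1 = high fidelity" semantics of the device
channel; kernels whose search window does not fit in the frame carry
confidence 0. SAD (sum of absolute differences) is available as a faster
metric; confidence is still an NCC value at the chosen lag.

Numerical choices:

* **Velocity limit = search geometry.** Candidate lags are restricted to a
  Euclidean magnitude of `v_max / (PRF * pitch)` pixels (about 4.04 px at
  the defaults); the search *window* is one pixel wider so refinement at the
  cap still has neighbouring scores. Speeds beyond `v_max` therefore
  saturate: the estimated peak stays at or below the limit while confidence
  drops, because the best in-window match no longer corresponds to the true
  motion. After post-filtering, any vector pushed past the cap is rescaled
  onto it — the limit is treated as a hard device constraint.
* **Gaussian sub-pixel fit.** The correlation peak of Gaussian speckle is
  Gaussian, so the default refinement fits a parabola to the *log* scores
  (falling back to a plain parabolic fit when a neighbouring score is
  non-positive). The plain parabolic fit is also available; in pilot
  experiments it produced visible peak-locking ripple in velocity profiles,
  which the Gaussian fit removes.
* **Tie-breaks.** Equal scores resolve to the smallest lag magnitude, then
  smallest |dy|, |dx|, then signed order — determinism under replays.
* **Degenerate kernels.** A kernel or window with (near-)zero variance has
  no defined NCC; its score is 0, flowing into confidence 0.
* **Vector post-processing.** `track_cine` (not `track_pair`, which stays
  raw) applies the normalized-median outlier test on the 3 x 3 kernel-grid
  neighbourhood, replacing outliers with the neighbourhood median, followed
  by Gaussian smoothing with sigma of one grid cell. The smoothing pads the
  grid by linear extrapolation before convolving: a truncated kernel at the
  grid edge would otherwise flatten near-wall gradients — precisely the
  quantity wall shear stress depends on. Both steps are the standard
  post-validation chain of block-matching velocimetry.

Displacements convert to velocity as `v = d * pitch * PRF` (2 px at the
defaults is 0.99 m/s). The pixel-dense velocity and confidence channels are
filled by bilinear interpolation of the kernel grid; pixels outside the
tracked hull keep nearest-edge velocities but are forced to confidence 0.

The integer-lag stage is verified in the test suite against an independent
brute-force scan written in plain R, and sub-pixel accuracy against frames
rendered from clouds shifted by known fractional displacements.

## Hemodynamic quantification

Profiles are sampled along user-drawn lines by bilinear interpolation
(exact for fields linear in x and y — which supplies a free exactness test —
and a convex combination, so interpolated confidence stays in [0, 1]). The
default sampling density is one sample per pixel pitch.

The long-axis shear stress is `tau = mu * dV/dy` with central differences in
the interior and one-sided differences at run ends; samples failing the
confidence mask (default threshold 0.5) are excluded and gaps are *not*
bridged — stress is undefined there rather than silently interpolated.
Blood is treated as Newtonian with `mu = 0.0035` Pa s (configurable); the
indicators below scale linearly in `mu`.

The signed wall WSS series samples the shear profile at the valid sample
nearest each endpoint of the profile line — the package's operational
definition of "wall", since no wall-detection scheme is imposed. The sign
convention makes forward (systolic) flow give positive WSS at *both* walls,
so a sign change in the series always means a local flow reversal,
independent of which wall is examined. Because a single pixel column's
tracking error is driven by its frozen speckle realization and persists
across frames, the cycle integral cannot average it away; `wall_series`
therefore averages the wall value over a short wall segment — 7 parallel
lines spaced 1.4 mm (about one kernel, making the columns statistically
independent). Set `n_lines = 1` for the strict single-line definition.

Over one cycle (closed by periodic continuation when the frames stop one
sample short of T):

* `TAWSS = (1/T) integral |WSS| dt`,
* `OSI = 0.5 (1 - |integral WSS dt| / integral |WSS| dt)`,

both by composite trapezoid on the actual frame times (non-uniform safe).
OSI is 0 for unidirectional WSS, 0.5 for balanced reversal, and lies in
[0, 0.5] *exactly* for the trapezoid rule, since the rule is a positive
linear functional — the bound is structural, not approximate. An
identically-zero series raises a quality error rather than returning a
misleading 0. Only the axial WSS component enters OSI; a full in-plane
vector form would be a straightforward extension but is not implemented.

Peak-velocity traces report the per-frame maximum of |V_long| along the
line together with the mean confidence along it — the pair of curves used
to compare BSI against CW Doppler envelopes — and `bernoulli_gradient`
converts a peak velocity to the clinical `4 v^2` mmHg estimate.

## What the phantom does and does not show

Phantom recovery demonstrates that the chain — rendering, tracking,
interpolation, differentiation, integration — is internally consistent and
meets stated tolerances under clean-speckle conditions with in-plane,
resolvable flow. Real acquisitions add out-of-plane motion, depth-dependent
signal loss, clutter and reverberation, tissue motion, and flow structure
finer than the kernel; none of these are modelled (the noise ramp gestures
at depth dependence only). Passing phantom tests therefore bounds
algorithmic error, not clinical error. The saturation experiment shows the
expected failure mode beyond the 2 m/s limit — estimated peaks pinned at the
limit with degraded confidence — but the *pattern* of clinical
underestimation also depends on acquisition factors the phantom omits.

Experiment sizes were chosen to keep the full validation suite in the
minutes range on one CPU: 160 x 136 px frames, 40 frames per cycle, one
cycle per phantom, and two phantom replicates averaged in the
recovery experiment (single-realization wall-TAWSS recovery scatters by
roughly +/-12%; averaging two replicates brings the experiment safely inside
its 15% tolerance band, applied identically to the tracked and ground-truth
arms).

## Reproducibility

Every stochastic step is seeded. A pipeline run (`run_pipeline`) derives
per-stage child seeds from the global seed by a fixed splitting rule, stamps
outputs with the configuration hash and seed, and reproduces its numeric
outputs bit-for-bit under a fixed configuration. The cine container
round-trips losslessly through `write_cine`/`read_cine` with schema
validation that names any missing channel.

## A compact end-to-end example

```{r example, eval = FALSE}
cfg <- imaging_config(frames_per_cycle = 20)
model <- flow_model("stenotic_jet", peak_speed = 1.5)
cine <- generate_cine(model, cfg, seed = 11)
tracked <- track_cine(cine)

line <- line_profile(6.56, 1.2, 6.56, 8.6)
wss_indicators(wall_series(tracked, line, "posterior"))
peak_velocity_trace(tracked, line)

# compare against the analytic ground truth carried by the phantom
wss_indicators(wall_series(truth_cine(cine), line, "posterior"))
```
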