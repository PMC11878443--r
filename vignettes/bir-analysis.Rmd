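---
title: "Quantifying beam-induced reorientation in electron-diffraction dose series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying beam-induced reorientation in electron-diffraction dose series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(birtrack)
```

## The problem

Molecular nanocrystals examined by microcrystal electron diffraction
(MicroED/3DED) are damaged by the very beam used to measure them. The
familiar signature is radiolytic decay: Bragg intensities fade with
accumulated fluence, fine spatial frequencies first. A second, less familiar
signature is *beam-induced reorientation* (BIR): the crystal lattice bends
and reorients under irradiation while the stage and the crystal's outline
remain still, so reflections wander into and out of the excitation
condition. In extreme cases the consensus orientation jumps abruptly after a
critical fluence -- a *crystal quake*. BIR corrupts the constant-orientation
assumption behind still-series processing and inflates apparent mosaicity if
it is absorbed into that parameter instead of being measured.

birtrack measures BIR from three complementary observables, each implemented
as an independent module with a synthetic ground-truth generator behind it:

1. **Intensity traces** of individual Bragg spots across a still-diffraction
   dose series, summarized by derivative profiles and their per-bin
   fluctuation SD.
2. **Per-frame orientation matrices** from serial indexing of the same
   series, cleaned of indexing-setting ambiguity and mis-indexed frames,
   then decomposed into a net rotation axis and angle versus fluence.
3. **Bend-contour migration** in imaging-mode movies, quantified by line
   seismograms (kymographs) and a per-frame fluctuation-SD trace.

## Conventions

* Orientation matrices have the real-space cell vectors **a**, **b**, **c**
  (in Angstrom) as columns, expressed in a right-handed lab frame with the
  beam along +z. Per-cell-vector drift angles are computed directly on these
  columns; the reciprocal basis is derived on demand as the inverse
  transpose.
* Pixel indices are 1-based `(row, col)`, the native R convention. SMV
  headers carry beam centers in millimetres; the conversion happens at the
  I/O boundary and nowhere else.
* Fluence is assigned at the **end** of each frame
  (`fluence_axis[i] = i * flux * exposure`): the intensity of frame *i*
  reflects dose accumulated up to `fluence_axis[i]`. The synthetic
  generators drive decay and drift with the dose accumulated *before* each
  frame, so frame 1 is the zero-dose reference.
* Cluster labels are 1-based (`1..k`), with cluster 1 the earliest-excited.

## The synthetic dose-series model

The generator treats consensus rotation as the primitive (how local bend
angles integrate into a consensus reorientation is not modelled): a
trajectory is a smooth drift at `drift_rate` degrees per e-/A^2 about a
fixed lab axis, plus optional per-frame jitter (small rotation about a
uniformly random axis, angle `|N(0, jitter_sd^2)|`), plus an optional quake
-- a single extra rotation applied to every frame past `quake_fluence`.
Defaults mirror the regimes the analysis is meant to resolve: drift of
1 degree per e-/A^2 sampled at 0.01 e-/A^2 per frame over 150 frames
(net 1.49 degrees), and quakes of ~3 degrees at 0.07-0.1 e-/A^2.

Diffraction frames are rendered from the Ewald construction: a reflection
with reciprocal vector *q* is excited when its angular excitation error
`zeta / |q_perp|` (with `zeta = -(q_z + lambda |q|^2 / 2)` the distance from
the sphere along the beam) is inside the mosaic rocking half-width (default
0.3 degrees, a typical still-frame mosaic scale), with a triangular
rocking-profile weight -- simple, monotone and differentiable, sufficient
for testing recovery. Integrated spot intensity follows the two-parameter
damage law

I(d, D) = I0 exp(-alpha D / d^2),

with D the fluence and d the d-spacing: monotone decay, resolution-dependent
so fine spatial frequencies ablate first. The default
`alpha = 2 A^2/(e-/A^2)` erases a 1 Angstrom reflection within ~2 e-/A^2
while 3 Angstrom data persist, the qualitative phenomenology of
beam-sensitive small-molecule crystals. Base intensities are log-normal
(median 5e3 counts, sigma_log 0.5) drawn reproducibly from the model seed.
Spots are drawn as 2D Gaussians (sigma 1.5 px) on a flat background, with
Poisson noise and a zeroed beamstop disc. The default geometry (512^2
detector, 55 um pixels, 500 mm distance, 200 kV wavelength from the standard
relativistic formula) puts the 1 Angstrom ring at ~230 px radius.

Indexing ambiguity is emulated by post-multiplying each frame's matrix with
a uniformly random proper point-group operator, adding component-wise
Gaussian noise, and replacing a fraction of frames with random orientations
(mis-indexed frames, flagged as ground truth only). Only the 11 proper
rotation groups are supported; improper operations cannot relate indexing
settings of a chiral lattice.

**What the generator does not emulate:** dynamical diffraction, multi-domain
mosaic substructure, support-film crinkling, detector point-spread or gain
texture, and any coupling between intensity decay and reorientation beyond
their common fluence axis. Passing recovery tests therefore demonstrates the
*analysis* is correct and well-conditioned, not that real crystals follow
the rendering model.

## Spot tracing

Detection follows the max-projection recipe: each frame is smoothed with a
one-pixel-radius Gaussian, the stack is projected by pixelwise maximum, and
pixels above `threshold_factor` (default 1.25) times the background are
grouped into connected components. Background `"auto"` is the median of the
detection image outside the beamstop (the reference procedure does not
define background estimation). Components smaller than `min_area` (default
5 px) are discarded as noise exceedances -- with counting-detector Poisson
backgrounds the 1.25x threshold alone admits single-pixel noise clusters.
Component centers are intensity-weighted centroids rounded to the nearest
pixel (ties toward the lower index); centers closer than the diamond mask
radius (default 25 px, center to vertex) are merged greedily in descending
intensity order, which is deterministic and order-independent.

Integration sums counts in the L1 diamond `|dr| + |dc| <= 25` (1301 pixels)
around each center; pixels claimed by overlapping diamonds go to the nearer
center (ties to the lower spot id), and the pixel count each spot actually
owns is recorded (`n_pixels`) so callers can subtract the correct background
expectation. The summed trace takes the brightest 20% of traces, judged by
each trace's maximum wherever it occurs, sums them framewise and normalizes
to the maximum. Derivative profiles are finite differences against fluence,
binned at 0.1 e-/A^2 by default (the discretization scale is not prescribed;
a handful of bins over ~2 e-/A^2); the cumulative sum of
`derivative * dfluence` reconstructs the trace exactly, which the tests
assert to 1e-10. The per-bin SD of the derivative is the fluctuation
statistic, and `fluctuation_summary()` averages it across crystals.

The 1.25x threshold is applied to the smoothed projection (the natural
reading of the procedure's sentence order); per-frame thresholding would be
a one-line change in `detection_image()`/`find_spots()` composition.

## Trace clustering

Traces are normalized to their own maximum and clustered with k-means
(k = 5 by default, 10 restarts, lowest within-cluster sum of squares kept,
fixed seed). The feature vector is the full normalized trace; the argmax
fluence is used only to relabel clusters canonically (cluster 1 excited
earliest). If fewer distinct traces than k exist, k is reduced with a
warning; k equal to the number of traces degenerates to one cluster per
trace. This keeps results comparable across runs and seeds.

## Orientation-series cleaning and net rotation

Serial indexing of a still series can return any symmetry-equivalent setting
per frame. `disambiguate()` anchors on the earliest orientation and walks
forward, replacing each frame by the candidate `M %*% S` (S a proper
point-group operator) nearest the previous corrected frame in Frobenius
norm -- matching the component-wise language of the reference procedure; a
relative-rotation-angle metric is available as an option, and ties resolve
to the lowest operator index. The result is the ground-truth track up to one
global operator, which is unrecoverable in principle and irrelevant to
relative rotations.

`reject_misindexed()` implements the 2-sigma rule: per component index, the
SD over *all* frames (one pass, candidates included) sets the scale; a frame
is discarded when any component differs from that component in *both*
neighbors by more than twice that SD. Endpoints use their single neighbor
twice. One caveat the synthetic work makes visible: when the reorientation
axis is parallel to a cell vector, that vector's components carry no signal,
their SD collapses to the measurement-noise floor, and the rule false-flags
at the noise rate. Real reorientation axes are generically oriented (as the
study conditions here assume), and real indexing noise keeps every
component's SD above threshold scale; for pathological tracks the `sigma_k`
multiplier is adjustable.

Net rotation uses orthogonal Procrustes with `det(R) = +1` (SVD with sign
correction) rather than `Mi %*% solve(M0)`: identical for exact inputs, and
it projects out the small non-orthogonal part of noisy indexed matrices.
Axis-angle extraction uses `atan2(|skew|, trace - 1)`, well conditioned over
the whole range, with the axis taken from the null space of `R - I` (SVD)
beyond 179 degrees where the skew part vanishes; axes are sign-canonicalized
(first nonzero component positive) and the identity returns (0, 0, 1) by
convention. Quakes are the largest frame-to-frame rotation between valid
frames, reported at the later frame's fluence when above a threshold
(default 1 degree per step).

`refine_orientation()` is deliberately minimal plumbing (full serial
auto-indexing is out of scope): predicted and observed spots are matched
within a capture radius, both are back-projected onto the Ewald sphere
through the same pixel mapping (so residuals reflect orientation error, not
each reflection's excitation error), and the Kabsch rotation is iterated to
convergence (at most 10 iterations or an update below 1e-4 degrees). Spot
positions on a single still frame constrain in-plane rotation strongly but
tilt only weakly -- tilt mostly changes *which* reflections are excited, not
where they fall -- so with pixel-rounded centroids a tilt residual of a few
tenths of a degree remains; with exact positions the truth is a fixed point
to machine precision. Refinement refuses (candidate returned, flagged) with
fewer than 3 matches.

## Bend-contour seismograms

Imaging batches are aligned by FFT-based normalized cross-correlation of the
mean-subtracted boundary frames, integer shifts only (subpixel registration
is out of scope); a correlation peak below 0.2 yields a zero shift with a
warning. Stacks are then mean-binned by 5 in all three dimensions and
low-pass filtered in time. The temporal filter is a zero-phase
Hamming-windowed-sinc FIR with replicate padding (passband edge `cutoff`,
default 0.1 cycles/frame; stopband from ~1.5x cutoff at >40 dB): unlike an
IIR filter run forward-backward it leaves constants exactly unchanged and is
exactly linear at the edges, and unlike a short boxcar it actually meets a
20 dB attenuation contract above the cutoff. Seismograms sample the
(manually chosen) line by bilinear interpolation at one-pixel steps, per
frame. The fluctuation amplitude at a position is the absolute deviation
from that position's *temporal mean* -- the per-position reading makes a
static scene exactly zero, which is what "no motion" should mean; the global
scalar mean is available as an alternative reading. The fluctuation trace is
the SD of this amplitude over positions, per frame. `track_band()` recovers
a single band's trajectory by a half-max-thresholded darkness centroid,
which is unbiased against baseline noise weight.

## Problem sizes and numerical tolerances

The test suite and the acceptance script run entirely on synthetic data at
desk scale, chosen to exercise every code path in seconds: orientation
tracks of 100-150 frames, 50 seeds per point group for disambiguation,
100 and 50 replicates for the mis-index operating characteristics, rendered
series of 100 frames on 512^2 (decay recovery) and 50 frames on 256^2
(fluctuation contrast), and 128^2 imaging stacks of 60-100 frames. Exact
identities (derivative reconstruction, I/O round trips, point-group closure)
are asserted at 1e-9..1e-12; axis-angle agreement with an independent
quaternion oracle at 1e-8; statistical recoveries (decay rate, band speed,
net angle) at the 5-10% level appropriate to their Poisson and rounding
noise. The still-pattern fixtures use a fixed, generic crystal orientation
(15 degrees about [111] from the reference setting) so that at least 20
resolvable spots -- no neighbor within the merge radius, bright enough to
detect -- are always present; seeds drive noise and per-reflection
intensities, not the geometry.

## Known limitations

* Only the 11 proper point groups are accepted as symbols; space-group
  symbols must be reduced to their rotational point group by the caller.
* SMV output is unsigned 16-bit (counts clamped at 65535 with a warning);
  MRC output is 32-bit float, exact for integer counts below 2^24.
* `calibrate_flux()` assumes offset-corrected flat fields; detector pedestal
  handling before the counts-per-electron conversion is the caller's
  responsibility.
* The 2-sigma mis-index rule inherits the flat-component caveat described
  above.
* TVIPS container decoding is not implemented; convert to MRC first.
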