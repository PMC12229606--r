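---
title: "Models and numerical methods in ismflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in ismflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ismflux)
```

This vignette is the package's own account of the science it implements: the
measurement model, the estimator and its bound, the synthetic-data
generator, and the numerical and design choices that were genuinely open.

## Measurement model

A doughnut-shaped excitation beam is steered along `N_c` positions on a
circle of diameter `L` (the targeted coordinate pattern, TCP), while a small
detector array images the probed region in descanned mode. A photon detected
at orbit position `i` in detector element `j` occurs with probability
proportional to the molecule detection function (MDF) `p_ij(r)`, which
factorizes — for the simulated model — into the excitation profile at the
emitter position and the detection probability of element `j`:

```
I_0j(r) = Exc(r) * Det_j(r),        values[i][j](r) = I_0j(r - delta_i)
```

with `delta_i` the beam offset of orbit position `i`. Descanned detection is
what makes the second identity exact: excitation and detection move rigidly
together, so the whole map stack translates with the beam. The package
exploits this instead of materializing all `N_c x N_d` maps: an `mdf_set`
stores the base stack and applies the translation at evaluation time with
the same bilinear interpolation an explicit shift would use. At the default
resolution this replaces an ~6 GB expanded stack by a ~200 MB base stack
with no loss of fidelity; `mdf_page()` materializes any page on demand.

### The parametric optical model

The package deliberately uses a closed-form scalar stand-in for the real
focused fields:

* Excitation: `Exc(rho) = (rho^2 / w^2) exp(-2 rho^2 / w^2)`, exactly zero
  at the center and maximal on the ring `rho = w / sqrt(2)`. The default
  waist parameter is `w = 0.61 * lambda_exc / NA` (≈ 277 nm at 635 nm /
  NA 1.4), chosen so the doughnut width is comparable to a vortex focus at
  these settings; it is exposed in `optics_model()`.
* Detection: an isotropic Gaussian PSF with
  `sigma_det = 0.21 * lambda_em / NA` (≈ 99 nm at 660 nm), integrated in
  closed form over each element's square active area. This makes each base
  map a product of the doughnut with two separable 1-D factors.

A full vectorial high-NA diffraction computation (or an instrument-fitted
PSF) would differ in detail, most visibly in the doughnut's side structure.
The parametric model is used because it is closed-form, fast, and testable,
and because it reproduces the magnitude and shape of the localization bound
across the field of view (the acceptance tests check exactly this). Measured
MDF stacks can be imported through `prepare_measured_mdf()` instead, which
applies the experimental post-processing chain: an anisotropic x-rescale
(default 0.8, compensating fast-axis stretch of small galvo scans), a 2D
uniform filter (default 5 px) followed by a Gaussian blur (default 2 px
sigma) — kernel sizes are configuration parameters since "visually smooth"
is not a specification — and the orbit expansion.

### Geometry defaults

| parameter | default | units | rationale |
|---|---|---|---|
| array | 5 x 5 | elements | detector used by the method |
| pitch | 150 | nm (sample space) | projected element spacing |
| element size | 100 | nm | projected active area |
| `L` | 90 | nm | trade-off between central precision and FOV homogeneity |
| `N_c` | 32 | positions/orbit | smooth galvo orbit; the bound changes < 0.1 % down to 8 |
| orbit period | 1.92 | ms | acquisition rate of the instrument |
| grid | 2.5 nm / 1000 px | | simulation resolution; measured MDFs typically 2 nm |

Elements are indexed row-major 0–24 (element 12 central); hot elements
listed in `excluded_elements` are dropped from both the MDF stack and the
counts before any likelihood is formed.

## Estimator

For an event reduced to the count matrix `n_ij`, the position likelihood is
multinomial with cell probabilities

```
p_ij(r) = sbr/(sbr+1) * m_ij(r)/sum(m(r)) + 1/(sbr+1) * 1/(N_c * N_d)
```

— the MDF prediction mixed with a uniform background floor at a fixed
signal-to-background ratio. SBR is a per-dataset constant supplied by the
user (10 for bound calculations under good conditions, ~3 for typical
DNA-PAINT data), not estimated per event. The reported log-likelihood omits
the count-only multinomial constant, so likelihood *differences* between
candidate positions are exact.

`localize_mle()` maximizes by brute force: an exhaustive coarse pass
(default step 8 MDF pixels = 20 nm) over the detector field of view,
followed by up to 3 refinement levels that halve the step down to the MDF
pixel (2.5 nm). The search is derivative-free on purpose — the likelihood
surface has a kink near the doughnut zero — and deterministic: ties break
toward the lowest x, then the lowest y. Tests verify the search against
exhaustive full-grid evaluation. Refinement stops at the pixel size for
event localization; the orbit-calibration path refines to a quarter pixel,
because the circle fit there benefits from sub-pixel resolution while
single-event precision does not. Interpolated MDF values are clipped at
zero; with finite SBR the background floor keeps every `p_ij > 0`, so the
estimator remains defined even on the doughnut zero. An all-zero MDF value
with infinite SBR is a degeneracy and errors.

## Cramér-Rao bound

The Fisher information of the multinomial model is
`F = N Σ_ij (∇p_ij)(∇p_ij)ᵀ / p_ij`, with gradients taken by central finite
differences of step one MDF pixel (validated in tests against a 4x finer
step to ≤ 2 %). The scalar bound is reported as the rms of the two per-axis
bounds, `σ_CRB = sqrt(tr(F⁻¹)/2)`: whether the published scalar is the rms
or the worst-axis bound is not stated in the source material, and rms was
chosen for consistency with the convention used for measured spreads,
`σ = sqrt((σ_x² + σ_y²)/2)`.

`effective_uncertainty_map()` models the constant-laser-power situation:
the expected photon count per localization varies with position as the sum
of all MDFs, `N(x, y)`, anchored to `n_center` at the pattern center, and
the bound is rescaled by `sqrt(n_center / N(x, y))`. "Field-of-view edge"
is operationalized as 300 nm from the center (half the ~600 nm detector
footprint) wherever a single number is needed.

## Synthetic-data generator

`simulate_trace()` draws independent Poisson counts per (orbit, angular
position, element) with rates

```
lambda_ij = rate * m_ij(r) / S(0) + bkg_rate / (N_c * N_d),   S(0) = sum m(center)
```

so `rate` is the signal photons per orbit for an emitter at the TCP center
and the position dependence follows the MDFs exactly, emulating
constant-power acquisition. The emitter follows a piecewise-constant
waypoint script sampled at the midpoint of each angular dwell (0.06 ms,
orders of magnitude below any scripted dynamics). Blinking is a two-state
renewal process with exponential sojourns; `nanoruler_script()` builds
DNA-PAINT-like multi-site scripts where each binding event lights one
docking site at a time. All simulations require an explicit seed and are
bit-reproducible.

What the generator does *not* emulate: detector dead time and afterpulsing,
per-element dark-count structure (a single uniform background stands in),
emitter photophysics beyond on/off (no saturation, no bleaching), drift
(the modeled instrument is actively stabilized), and aberration-induced
asymmetries of the real PSF. Passing tests therefore demonstrate the
correctness and calibration of the estimator and pipeline under the stated
model, not robustness to these instrument effects.

## Event pipeline

The DNA-PAINT analysis chain follows the published procedure: the per-orbit
intensity trace is thresholded at the mean of the lower component of a
two-Gaussian histogram fit (the literal "first peak" reading; a
valley-minimum alternative is available via `method = "valley"` since the
literal rule is unusual, and a manual threshold always wins). Events are
maximal above-threshold runs, filtered on total photons (≥ 2000), duration
(≥ 5 orbits) and the Poisson-fluctuation test: the per-orbit count standard
deviation must not exceed 2.5 x `sqrt(N)`, where `N` is taken as the mean
count per orbit within the event (the reference leaves this `N` ambiguous;
the mean-rate reading makes the test scale-free). Each surviving event is
split into three equal-duration segments — split by orbits, with the last
segment absorbing the remainder — and localized independently; the spread
`σ = sqrt(0.5(σ_x² + σ_y²))` uses the sample (n−1) standard deviation of
the three positions, the convention consistent with the worked value
σ = √4.5 nm for segment positions 3 nm apart on a line. Events with
`σ < σ_TH` (8.25 nm, or 5 nm for the tighter analysis) are accepted and
reported at the mean of their three segment positions.

## Orbit calibration

The realized orbit differs from the commanded one (galvo inertia attenuates
the radius and shifts the phase), so calibration is part of the method.

*Reference path*: with the beam orbiting a bright bead, the descanned image
displaces opposite to the beam; localizing the bead per angular position
against the unshifted base MDF traces the orbit circle. A Kåsa algebraic
circle fit with one geometric Gauss-Newton refinement gives the radius and
center; the start phase is the phase of position 0's beam offset
(`center − r'_0`), and the rotation direction the sign of the mean wrapped
phase increment. The fit reports the *realized* orbit: a simulated 0.8x
inertia-like gain yields 0.8x the imposed radius, by design.

*Self-calibration*: each event is localized in 4 quadrants of 8 consecutive
orbit positions under candidate `L` values (default 60–120 nm in 2 nm
steps); quadrant probabilities are renormalized over the quadrant's support
with the same SBR mixture. The wrong `L` displaces the quadrant estimates
systematically; the rms distance of the 4 positions from their centroid is
minimized at the true `L`. Pooling a handful of events before quadrant
localization deepens and stabilizes the minimum; both per-event and pooled
use are supported.

## Problem sizes and numerical choices

The test suite builds its MDFs on a 480 px, 2.5 nm grid (±600 nm) — the
smallest grid that holds the detector footprint, the orbit shift and the
finite-difference stencils — and sizes its Monte-Carlo runs (200 seeded
events per position for the efficiency checks, 45 s equivalent of blinking
acquisition for the pipeline checks) so that sampling error stays well
inside the tolerances being asserted. The acceptance script uses the full
1000 px grid. Subpixel translation and probing use bilinear interpolation
(monotone, cheap, adequate at 2–2.5 nm pixels), with values clipped at zero
afterwards.

## Known limitations

* The scalar PSF model has no aberrations and no vectorial structure; bound
  values carry model tolerance of order 10–20 % relative to an
  instrument-fitted PSF. In particular the *single-element* bound depends
  delicately on the doughnut tails: in this model its information loss
  concentrates in a ridge at the TCP circle itself and in a broad band
  around the doughnut-maximum ring (where the array/single ratio exceeds
  10), rather than everywhere beyond the TCP.
* SBR is global per dataset; no per-event background estimation.
* Single emitter per event; no multi-emitter joint estimation.
* 2D only; no axial encoding.
* Cluster assignment for per-site uncertainties is supplied by the user
  (e.g. nearest known site, or any clustering of choice); the package does
  not choose clusters.
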