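# ismflux

Single-molecule localization by orbital doughnut scanning with a SPAD array
detector, in R.

## The problem

MINFLUX-style localization probes a fluorophore with the zero of a
doughnut-shaped excitation beam, steered around a circular *targeted
coordinate pattern* (TCP) of diameter *L*. The photon counts collected at the
`N_c` beam positions encode the emitter position with an uncertainty that
scales as `L / sqrt(N)` — far below the diffraction limit — but only while
the molecule sits inside the pattern. With a single-element detector the
estimate degrades rapidly outside the TCP, which is why classical MINFLUX
needs an iterative zoom-in.

Replacing the single detector with a small detector array (here 5 × 5
elements, 150 nm pitch and 100 nm element size in sample space) in
*descanned* mode adds the image of the molecule to the data: each beam
position yields a micro-image, and the full photon record is a tensor
`I(c, α, d)` over orbits, angular positions, and detector elements. The
position information in those micro-images keeps the localization well-posed
across the whole detector field of view (~600 × 600 nm²), removing the need
for iteration.

This package implements the full in-silico stack for that measurement
scheme, for microscopists and method developers who want to simulate,
analyze, or benchmark it:

* a parametric model of the **molecule detection functions** (MDFs)
  `p_ij(r)` — doughnut excitation `(ρ²/w²)·exp(−2ρ²/w²)` times the detection
  PSF integrated over each element — plus import of measured MDF stacks
  (anisotropic rescale, smoothing, orbit expansion);
* the **multinomial maximum-likelihood estimator**: for a reduced event
  matrix `n_ij`, the likelihood `L(r | {n_ij}) ∝ ∏_ij p_ij(r)^{n_ij}` with a
  uniform-background SBR mixture, maximized by a deterministic brute-force
  grid search with local refinement;
* **Fisher information / Cramér-Rao bound** maps,
  `F = N Σ_ij (∇p_ij)(∇p_ij)ᵀ / p_ij`, `σ_CRB = sqrt(tr(F⁻¹)/2)`, including
  the effective (photon-flux-scaled) uncertainty over the field of view;
* a **synthetic photon-trace generator** (Poisson counts, scripted emitter
  motion, DNA-PAINT-like blinking, uniform background);
* the **event-detection pipeline**: trace thresholding by a two-Gaussian
  histogram fit, event segmentation and filtering (total photons, duration,
  Poisson-fluctuation test), three-segment localization with the
  `σ = sqrt(0.5(σ_x² + σ_y²))` consistency check, Gaussian-kernel rendering
  and per-cluster uncertainties;
* **orbit calibration**: circle-fit recovery of the realized orbit diameter,
  start phase and rotation direction from a reference bead measurement, and
  quadrant-based self-calibration of `L` from the single-molecule data
  themselves.

Tabular results come back as tibbles, pipe-friendly, with `autoplot()`,
`tidy()` and `glance()` methods.

## Worked example

```r
library(ismflux)

# MDFs for the default optics (635/660 nm, NA 1.4) on a 480 px, 2.5 nm grid,
# expanded over a 32-position orbit of diameter L = 90 nm
base <- simulate_base_mdf(grid = mdf_grid(pixel_size = 2.5, n_pixels = 480))
mdf  <- expand_orbit(base, orbit_geometry(L = 90))

# localization bound for 100 photons at SBR 10
sigma_crb(mdf, bkg = 10, x = 0,   y = 0, n_photons = 100)
#> [1] 3.471718
sigma_crb(mdf, bkg = 10, x = 300, y = 0, n_photons = 100)
#> [1] 12.70265

# simulate one event at (120, 60) nm and localize it
lam <- expected_counts(mdf, x = 120, y = 60, rate = 600, bkg_rate = 60)
set.seed(42)
n <- matrix(rpois(length(lam), lam), nrow = nrow(lam))
localize_mle(n, mdf, bkg = 10)
#> # A tibble: 1 × 7
#>    x_nm  y_nm  loglik n_photons grid_level on_border degenerate
#>   <dbl> <dbl>   <dbl>     <int>      <int> <lgl>     <lgl>
#> 1   120    60 -18692.      3352          3 FALSE     FALSE
```

The bound is ~3.5 nm for an emitter at the pattern center and grows to
~12.7 nm at 300 nm from the center — still finite, because the micro-images
keep the problem well-posed far outside the 90 nm orbit. The simulated
3352-photon event at (120, 60) nm is recovered exactly on the 2.5 nm search
grid; its bound at that photon count is 1.88 nm. The effective uncertainty —
the bound rescaled by the position-dependent photon flux under constant
laser power — spans 3.5 to 6.7 nm across the 600 nm field of view:

```r
eff <- effective_uncertainty_map(mdf, bkg = 10, n_center = 100,
                                 decimation = 8, fov_radius = 300)
range(eff$sigma_eff)
#> [1] 3.473579 6.714211
autoplot(eff)   # raster map of sigma_eff over the FOV
```

A thin command-line wrapper for the common operations is installed under
`inst/scripts/ismflux` (MDF simulation, CRB maps, trace simulation,
localization, and the event pipeline).

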