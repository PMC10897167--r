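---
title: "Methods: nanoscale strain partitioning in bone from in situ X-ray scattering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nanoscale strain partitioning in bone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and its model

During an in situ tensile test of a hydrated bone, a monochromatic X-ray
beam (10 keV, λ = 12.39842/E = 1.2398 Å) passes through the mid-diaphysis
and scatters onto a 2-D photon-counting detector. Two periodicities matter:
the collagen axial period (d₀ ≈ 670 Å, first-order SAXS reflection, long
camera) and the apatite (002) lattice spacing (d₀ ≈ 3.44 Å, WAXD, short
camera). A Bragg ring appears at scattering vector q = 2π/d; as load is
applied the ring shifts, and the **material strain** of the phase is

ε_m(t) = (d(t) − d₀) / d₀,  d = 2π/q_peak,

with d₀ the mean over the pre-load frames. Simultaneously a CCD camera
records optical markers on the specimen; the **tissue strain** is the
engineering strain of the inter-marker gauge projected on the tensile axis.
The scientific quantity is the **strain slope** of a group — the OLS slope
of material strain on tissue strain over the pooled per-frame scatter of
all its specimens — which measures the fraction of tissue deformation that
phase carries. Two derived analyses follow:

- **Slope comparison.** Two groups are compared by the extra sum-of-squares
  F test between a common-slope model and a separate-slopes model. Both
  models keep *separate intercepts* per group, so the hypothesis concerns
  slopes only; with one constraint, F = (SSE_c − SSE_s) / (SSE_s/(n−4)) on
  (1, n−4) degrees of freedom. This reduces to the square of the two-sample
  slope t-test for equal designs (verified numerically in the test suite).
- **Slope sum.** The collagen and mineral slopes of a group are added and
  their SEs propagated in quadrature. A sum near 1 means the two nanoscale
  phases account for the applied deformation; `deficient`
  (sum + 2·SE < 1) flags deformation lost to unresolved mechanisms such as
  inter-fibrillar sliding; `oversumming` is the converse. Collagen and
  mineral are usually measured on contralateral bones of the same animal,
  so the diagnostic always carries a caveat flag.

## What the generator emulates

`tensile_truth()` + `simulate_tensile_experiment()` generate every input the
pipeline consumes, with known ground truth:

| parameter | default | meaning |
|---|---|---|
| `frame_interval`, `exposure` | 5 s, 0.5 s | exposure cadence of the protocol |
| `dose_per_exposure`, `dose_cap` | 0.5 kGy, 30 kGy | dose budget; caps the run at 60 frames |
| `tissue_strain_rate` | 2.8e-5 s⁻¹ | quasi-static ramp reaching ~0.8% strain in ~5 min |
| `failure_strain` | 0.008 | tensile failure strain typical of cortical bone |
| `n_preload` | 3 | unloaded frames defining d₀ |
| `slope_collagen`, `slope_mineral` | 0.7482, 0.3561 | strain coupling (healthy young-male scale) |
| `d0_collagen`, `d0_mineral` | 670 Å, 3.44 Å | literature unloaded spacings |
| `p2_initial`, `p2_rate` | 0.35, 2 | orientation parameter and its ramp per unit strain |
| `amplitude`, `noise_level` | 100, 5 counts/px | ring peak and flat background |
| `ring_width_collagen/mineral` | 6e-4, 1.2e-2 Å⁻¹ | Gaussian ring σ in q |
| `strain_noise_sd` | 2e-4 | per-frame d-spacing jitter (heterogeneity, beam pointing) |
| `d0_sd_frac` | 0.003 | inter-specimen d₀ scatter |

The detector model is a Pilatus-class 1475 × 1679 grid with 172 µm pixels;
rings are Gaussian in q with Poisson counting noise, and azimuthal
anisotropy follows I(χ) ∝ exp(κ·cos 2χ) with κ solved numerically so the
ring's sin-weighted second-Legendre average equals the programmed P2 — a
smooth, normalizable, single-parameter choice. The per-exposure dose is a
free configuration parameter (the protocol constrains only the 30 kGy
total), and photon flux is not physically calibrated. The per-frame
d-spacing jitter (2 × 10⁻⁴ strain) and the 0.3% inter-specimen d₀ scatter
set a realistic measurement-noise floor and were fixed on physical grounds;
without them a clean synthetic run would imply strain precision far beyond
what photon statistics deliver in practice.

What the generator does **not** emulate — and what passing tests therefore
cannot certify about real data: detector gaps, masks and point-spread,
polarization and solid-angle corrections, beam damage to the specimen
below the dose cap, viscoelastic relaxation between frames, full-field
strain heterogeneity (markers encode a uniform ramp), and non-Gaussian
peak shapes from crystallite size/strain broadening.

## Reduction and numerical choices

- **Geometry.** Exact 2θ mapping throughout, q = (4π/λ)·sin(½·arctan(r/L)),
  valid across both SAXS and WAXD regimes; no small-angle approximation.
  Azimuth χ is measured in degrees from the detector +x axis (the tensile
  axis by default), range [−180, 180); pixels are point-sampled at centers.
- **Calibration.** Beam-center search maximizes ring sharpness (sum of
  squared radial-histogram mass, Nelder–Mead, 0.25 px polish); distance
  comes from a Gaussian fit to the silver behenate 001 ring
  (d = 58.380 Å), L = r/tan 2θ. When the nominal camera length is supplied
  the ring is searched in a ±20% annulus so calibrant harmonics cannot be
  picked up.
- **Binned abscissas.** Radial profiles report, per q-bin, the *mean pixel
  q* rather than the bin midpoint. With bins comparable to a pixel the
  midpoint is a biased abscissa for the lumpy pixel set it holds, and that
  bias drifts systematically as a ring moves — directly biasing strain
  slopes. The pixel-mean abscissa removes the effect. Empty bins are
  flagged (`n_pixels = 0`, `NA` intensity), never zero-filled, and
  count conservation (Σ intensity·n_pixels = Σ selected counts) is exact.
- **Peak fits.** Gaussian + linear background by default (Lorentzian
  selectable); Levenberg–Marquardt on a standardized abscissa (narrow q
  windows are ill-conditioned in raw coordinates). A failed or implausible
  fit returns `converged = FALSE` and the frame carries `NA` downstream —
  never silently interpolated.
- **P2 quadrature.** P2 is the intensity-weighted second-Legendre average
  with the fiber-symmetry weight |sin χ|, computed with closed-form per-bin
  integrals of both |sin χ| and P2(cos χ)|sin χ| (the kink of |sin| at
  χ = 0°/180° otherwise dominates the quadrature error). This is the
  definition under which the anchors hold: uniform → 0, axial → 1,
  transverse → −0.5. An unweighted circular average would give 0.25 for an
  isotropic profile and cannot satisfy those anchors.
- **Reference policy.** d₀ defaults to the mean of the frames recorded
  before loading starts (`first_n_preload(3)`). Tissue strain uses the
  pre-load mean gauge as L₀. Time matching interpolates CCD strain
  linearly to frame timestamps; frames outside CCD coverage use the
  nearest value only within one CCD interval, else they are dropped and
  counted.
- **Pooling.** Group slopes pool all specimens' points (the scatter-plot
  convention); a per-specimen mixed-effects alternative is deliberately
  out of scope. Strains are dimensionless fractions internally.
- **Yield criterion.** The load–displacement yield point uses the
  0.2%-offset-equivalent secant (offset = 0.002 × span at the measured
  stiffness) because whole-bone bend reports rarely define yield; a 10%
  secant-stiffness-loss alternative is selectable
  (`yield_method = "secant"`). Stiffness is the maximum of sliding-window
  OLS slopes (window = 20% of the pre-yield points, below 50% of ultimate
  load), lightly smoothed across neighbouring windows before taking the
  maximum because the raw maximum of noisy slope estimates is biased
  upward. Fracture is the point just before the load collapses below 10%
  of ultimate; a curve ending above 50% of ultimate has no detectable
  fracture and is an error.
- **ANOVA.** Balanced designs use the exact sequential decomposition;
  unbalanced designs use Type II sums of squares (`car::Anova`) — the
  natural choice when interactions are tested but not assumed. Fisher's
  LSD uses the ANOVA residual mean square and is gated by a priori
  Bonferroni alphas, reported exactly and rounded half-even to 3 decimals
  (the 0.007 / 0.008 printing convention).

## Problem sizes and verification

The acceptance checks run the full pipeline — synthetic calibrant,
beam-center search, distance calibration, per-frame reduction, peak
fitting, strain extraction, time matching, pooled OLS — at 3 specimens ×
60 frames per group on the full-size detector, with ground-truth slopes
set to published group values; the recovered slope must fall inside its
own fitted 95% CI. Unit and property tests use smaller cameras
(~200–400 px) so the suite stays fast; the replicated coverage property
uses a shortened 30-frame, 2-specimen protocol. F-test calibration is
checked under the null over 2000 closed-form replicates at α = 0.0125;
least-squares, ANOVA, MOI and q↔d conversions are checked against
independent closed-form oracles at 1e-10.

## Known limitations

Single-ring fitting only (no 2-D unintegrated fits, no Scherrer
crystallite analysis); two-marker gauge rather than full-field DIC; no
detector distortion maps or gap masks; the common-slope F test treats
points as independent, ignoring within-specimen correlation (a
mixed-model would relax this); and the slope-sum caveat about
contralateral limbs applies whenever the two phases come from different
bones.
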