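---
title: "Methods: neural-network-guided ICRS planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neural-network-guided ICRS planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The planning problem

Keratoconus steepens and distorts the anterior cornea; intracorneal ring
segments (ICRS) flatten and regularize it, but the response to a given
segment choice is notoriously variable, and manufacturers' nomograms pick
segments from refraction and astigmatism alone. `icrsplan` implements an
optical-quality-driven alternative: a feedforward neural network, trained
exclusively on surgically *successful* cases, predicts the post-operative
anterior elevation for every candidate configuration of one or two KeraRing
segments (SI5/SI6 families; arcs 90-210 degrees; any thickness and
bisecting line), and the candidate whose predicted cornea has the best
point-spread-function Strehl ratio is proposed as the surgical plan.

The pipeline is, per candidate:

1. Zernike decomposition of the pre-operative elevation on an 8 mm
   aperture (ANSI/OSA double-index ordering, unit-variance normalization,
   radial order <= 7, 36 coefficients, micrometres).
2. Network prediction of the post-operative 36-coefficient vector on the
   same aperture.
3. Analytic rescale to the scoring pupil (default 6 mm), conversion of
   elevation to wavefront OPD by the air-to-stroma index step
   `delta_n = 0.376`, and the second-order toggle: keeping defocus and
   astigmatism ranks plans for uncorrected vision (UDVA); removing them
   ranks for spectacle-corrected vision (CDVA), since spectacles correct
   exactly the second order. The clinical source leaves the toggle-acuity
   pairing ambiguous; this pairing is the package's documented reading.
4. Fourier-optics PSF: unit-amplitude pupil with phase `2 pi W / lambda`
   (default 550 nm), squared-modulus FFT, Strehl = peak relative to the
   diffraction-limited peak of the same aperture. `strehl_ratio()` removes
   piston and tilt first (they translate the image without degrading it)
   and interpolates the discrete peak with a 3-point parabola, which is
   what makes the metric tilt-invariant to 1e-6 and stable to 0.5% under
   grid/padding refinement at the default `grid_n = 256`, `pad_factor = 4`
   (planner scoring uses 64/2, which ranks identically in practice).

Ties within 1e-9 in Strehl break toward fewer segments, then lower total
thickness, then the lexicographic candidate code. A no-implant baseline is
always scored; a plan that cannot beat it is flagged `no_benefit`.

## Zernike machinery

Fitting is QR-based linear least squares over in-aperture grid samples
(never normal equations); missing cells are dropped and more than 20%
missing inside the aperture is an error, as is a rank-deficient design.
Pupil rescaling is analytic: within each azimuthal-frequency block the
radial polynomials are expressed in monomials, powers are scaled by the
aperture ratio, and the result is projected back; this is exact for
polynomials, so the dense-grid refit in the test-suite is a genuinely
independent oracle. RMS aberration groups (total, HOA, astigmatism,
coma-like = odd radial orders, spherical-like = (4,0) + (6,0)) are
Euclidean norms of coefficient subsets, which the unit-variance convention
makes equal to surface RMS; piston and tilt are excluded everywhere.

## Clinical metrics

Visual acuity converts as `LogMAR = -log10(decimal)`, reported to two
decimals (round-half-even). The visual-limitation grade is I (CDVA >=
0.90), II (>= 0.60), III (>= 0.40), IV (>= 0.20), Plus (< 0.20).
Simulated keratometry fits a circle (Kasa algebraic fit) to the elevation
profile of each of 180 meridians across the 3 mm zone, sampled by
Catmull-Rom bicubic interpolation, and converts the radius with the
keratometric index 1.3375; K1/K2 are the flattest/steepest meridians. The
surgical success filter marks a case successful if it gained at least one
line (0.1 LogMAR) of UDVA or CDVA, or its spherical equivalent moved at
least 2 D toward zero, or its higher-order or coma-like wavefront RMS fell
by at least 1 um. The source text states that last threshold in "mm";
RMS values are tabulated in micrometres throughout, so it is read as 1 um.
The cross-linking indication requires both >= 1 D steepest-K increase and
>= 1 D astigmatism increase between visits.

Case-record RMS fields are *corneal wavefront* RMS (elevation x 0.376),
matching the scale of published keratoconus tables (coma-like of a few
micrometres at 6 mm).

## The surrogate network

A feedforward network trained by full-batch backpropagation with momentum
(`dw_t = -lr * grad + momentum * dw_{t-1}`; defaults lr 0.01, momentum
0.9, 2000 epochs, one hidden layer of 40 tanh units, linear output,
seeded uniform fan-in-scaled initialization). Inputs and targets are
standardized per column with the statistics stored in the model. Three
design choices depart from the minimal textbook setup, each adopted after
the minimal version demonstrably failed to identify the implant effect:

* **Change targets.** The regression target is the post-minus-pre
  coefficient change; the prediction adds the pre-operative vector back,
  so the model still returns the full post-operative decomposition. With
  raw post-operative targets the pass-through variance (the cornea you
  started with) dominates the squared error and the implant effect is
  never learned.
* **Tensor implant encoding.** Each segment slot carries the family and
  arc one-hots, scaled thickness, `(sin a, cos a)` of the bisecting line,
  a presence flag, and a tensor block: per catalog type, thickness-scaled
  axis harmonics `k = 0..7`. An arc's induced elevation change rotates
  rigidly with its bisecting line, so each Zernike coefficient of the
  change is a single axis harmonic of order equal to its azimuthal
  frequency; in this basis the effect is linear and identifiable from a
  few hundred cases, where a plain `(sin, cos)` encoding would require the
  network to synthesize 7th harmonics it cannot learn at that sample size.
* **Linear bypass with ridge warm start.** A linear input-to-output
  connection is added alongside the tanh path, initialized at the
  deterministic ridge least-squares solution and exempt from the small L2
  weight decay (1e-3) applied to the hidden path. Gradient descent alone
  converges impractically slowly along the ill-conditioned directions of
  the correlated implant basis; solving the linear part in closed form and
  letting backpropagation refine everything removes that bottleneck.

Training refuses any case that fails the success filter (the filter is
part of the method, not an option) and fewer than 10 cases; a non-finite
loss aborts with the offending learning rate named. Identical seed, data
and hyperparameters reproduce bit-identical weights; models serialize to
versioned JSON at full precision.

## The synthetic cornea generator

Clinical elevation maps cannot be redistributed, so the package ships a
generator that emulates keratoconic anterior surfaces: a conicoid base
(apical radius 6-9 mm, conic constant Q in \[-0.6, -0.1\]), a Gaussian
cone bump (amplitude 15-60 um, width 0.9-1.6 mm, apex 0.4-1.5 mm off
axis), a toric term realizing 0.5-4 D of keratometric astigmatism, and
seeded Gaussian noise (SD 0.5 um, the repeatability scale of Scheimpflug
elevation). Corneas are parameterized keratometrically: a target mean
Sim-K is drawn (default 47.56 +/- 3.8 D, an advanced-keratoconus regime
matching published ICRS cohorts) and hit by a one-step curvature
correction. Cone amplitudes are chosen so coma-like wavefront RMS lands in
the clinical range of a few micrometres and dominates the HOA budget, as
it does in keratoconus.

The mechanistic ring effect subtracts a closed-form sag field per segment,
linear in thickness and arc coverage: a Gaussian ridge on the segment
track (radius = model diameter / 2, width 1.2 mm) windowed to the arc with
a cosine taper and a 0.25 floor, plus a mid-peripheral component
(radius 1.1 mm) active only on the segment's side
(`max(cos(theta - bisect), 0)`). Subtracting peripheral sag relative to
the apex flattens central keratometry by ~2 D for a 210-degree,
300 um segment; the one-sided component cancels cone asymmetry when the
bisecting line points at the cone, reproducing the clinical pattern of
coma-like reduction with a spherical-like increase. The effect on fitted
coefficients is exactly additive and segment-only, which the validation
suite exploits.

Cohort generation rejection-samples surgeries until the requested number
pass the success filter (default 75, the training-set size of the guiding
clinical work). Segment axes are drawn uniformly on a 5-degree protractor
grid: if training axes always tracked the cone meridian, axis information
would be collinear with the pre-operative coma and the implant effect
would be unidentifiable. Acuities come from a documented proxy --- LogMAR
clamped to \[0, 1.3\] as `-0.25 + 0.22 * (-log10 Strehl)` plus 0.05
LogMAR noise, with UDVA scored on the full wavefront and CDVA on the
HOA-only wavefront --- and the spherical equivalent from the paraxial
defocus relation `SE = -4 sqrt(3) c20 / r^2` applied to the wavefront
defocus in excess of a 7.5 mm (45 D) emmetropic reference cornea; the raw
corneal defocus encodes the cornea's entire ~43 D of power, so the
reference subtraction is what puts the formula on the clinical SE scale.
Both proxies are modelling devices for cohort generation, not clinical
claims. All randomness descends from one explicit seed.

What the generator does **not** emulate: posterior-surface and pachymetry
changes (no tomography), biomechanical coupling (the effect is additive,
so there is no cornea-implant interaction for the network to discover),
epithelial remodelling, or measurement artifacts beyond white noise.
Passing the validation suite therefore shows the pipeline is correct and
the estimator identifiable under these conditions; it does not certify
predictive accuracy on clinical corneas.

## Validation problem sizes and numerical choices

The shipped validation suite uses: orthonormality quadrature on a 512^2
disk with fractional edge weights (tolerance 1e-3); fit round-trips to
1e-8; Marechal agreement within 2% up to sigma = lambda/14; a 95-case
cohort (75 train / 20 held out) for the surrogate accuracy check, passing
at held-out RMSE < 20% of output SD; and a 300-case cohort with 8000
training epochs for the planner study, where the planned candidate's true
mechanistic Strehl is within 5% of the true optimum on at least 80% of 50
seeded test corneas (a singles-only, 30-degree-axis, two-thickness
candidate grid keeps the brute-force optimum computable). Degenerate
inputs fail loudly: empty catalogs, non-dividing axis steps, upscaling
rescales, pupils larger than the fitted aperture, and cohort acceptance
rates below 1% all raise errors rather than warnings.

## Known limitations

The surrogate is only as good as its training distribution; the planner
enumerates but does not extrapolate thickness beyond the configured set;
Strehl is a monochromatic, on-axis metric (no polychromatic PSF,
Stiles-Crawford apodization, or retinal sampling); and the second-order
toggle's acuity pairing, while documented, remains an assumption.
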