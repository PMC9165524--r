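---
title: "Parallel-beam reconstruction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parallel-beam reconstruction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parbeam)
```

## The measurement model

A 2D object $f(x,y)$ scanned in first-generation (translate/rotate)
parallel-beam geometry yields the Radon transform

$$p(t, \theta) = \int\!\!\int f(x,y)\,
  \delta(x\cos\theta + y\sin\theta - t)\,dx\,dy,$$

sampled at detector offsets $t_n = (n - (K-1)/2)\,d$, $n = 0,\dots,K-1$,
and view angles $\theta_m = m\Delta$, $m = 0,\dots,M-1$. Defaults are
$M = 180$ views over a half turn ($\Delta = \pi/180$), the usual
acquisition count for parallel-beam scans, and a detector pitch of one
pixel ($d = 2/N$) with an odd number of bins spanning the grid diagonal so
that $t = 0$ falls exactly on a bin center. Half-turn coverage suffices
because $p(t,\theta+\pi) = p(-t,\theta)$.

Images live on an $N \times N$ grid over $[-1,1]^2$ with *centered* pixel
coordinates $x_i = (i - (N-1)/2)\cdot 2/N$: the grid center is exactly
$(0,0)$ for every $N$, which makes symmetry properties testable to machine
precision. All lengths are in units of the image half-width; intensities
are dimensionless attenuation values.

Two forward projectors are provided and kept deliberately distinct:

* `radon_analytic()` evaluates exact chord lengths through each ellipse of
  an analytic phantom — the reference for accuracy, free of discretization.
* `radon_discrete()` spreads each pixel's value onto the two detector bins
  bracketing its ray coordinate with linear weights. It is, by
  construction, the exact transpose of the back-projector's interpolation
  footprint, which is what makes the iterative reconstructor's convergence
  provable rather than empirical. Its raw output is in interpolation-weight
  units; multiplying by $\mathrm{spacing}^2/d$ converts to line-integral
  units (the SIRT driver does this internally).

## Back-projection and its discretization

The back-projector assigns each pixel the average over views of the
projection value of the ray through that pixel. For pixel $(x_i, y_j)$ and
view $\theta_m$ the ray coordinate $t = x_i\cos\theta_m + y_j\sin\theta_m$
rarely hits a sampled offset, so it is split as $t = (n_0 + \delta)d$ with
$n_0$ integer and $\delta \in [0,1)$, and the projection is linearly
interpolated:

$$\tilde p(t,\theta_m) = (1-\delta)\,p[n_0] + \delta\,p[n_0+1], \qquad
  f(i,j) = \frac{1}{M}\sum_{m=0}^{M-1} \tilde p(t_m(i,j),\, \theta_m).$$

Rays that fall off the detector contribute zero (they are flagged, not
errors). A ray landing exactly on the last bin is handled as
$(n_0, \delta) = (K-2, 1)$ so the upper-neighbour index stays in range with
weight 1. The vectorized implementation performs the same floating-point
operations in the same order as the defining triple loop, and the test
suite pins that equivalence bit-for-bit on grids up to $32^2$.

## Filters

Filtered back-projection convolves each projection with a ramp-type filter
before back-projecting. Filters are built in the frequency domain on a
zero-padded grid of length $K_{\mathrm{pad}}$, the next power of two at or
above $2K$, so that DFT multiplication implements a padded (non-wrapping)
convolution:

* **Ram-Lak**: response $|\nu|$ up to the detector Nyquist frequency
  $\nu_N = 1/(2d)$ — the ideal band-limited ramp, sharpest but
  noise-amplifying.
* **Shepp–Logan**: $|\nu| \cdot \mathrm{sinc}(\nu / 2\nu_N)$. This is the
  frequency-domain form of convolving the ramp with $\sin(x)/x$; the sinc
  window rolls off the high frequencies where measurement noise dominates,
  at a small cost in edge sharpness. At Nyquist its response is
  $(2/\pi)\nu_N$.
* **none**: the identity, giving plain (blurry) back-projection.

Because the response is expressed in physical frequency units, the inverse
DFT of the sampled ramp equals $d \cdot h(nd)$, where $h$ is the
band-limited closed form $h(0) = 1/(4d^2)$, $h(n\ \mathrm{odd}) =
-1/(\pi^2 n^2 d^2)$, $h(n\ \mathrm{even}) = 0$; the stored spatial kernel is
normalized to $h(nd)$ itself and is verified against that closed form. The
frequency path thus already carries the Riemann weight $d$ of the
convolution sum.

**Normalization.** Plain `back_project()` keeps the plain $1/M$ average so
the accumulation can be tested literally in isolation. The continuous
inversion integral $f = \int_0^\pi q_\theta\,d\theta$ requires the angular
Riemann weight $\pi/M$ instead, so `fbp_reconstruct()` rescales by $\pi$.
With both weights in place FBP is amplitude-correct: the mean reconstructed
level of a constant disc is reproduced within 2%, which the suite asserts.

Pixels outside the inscribed unit circle are zeroed after reconstruction
(standard practice; detector coverage there is incomplete), except in plain
`back_project()`, which remains the literal accumulation.

## Direct Fourier inversion

The central slice theorem — the 1D FT of a projection equals the radial
slice of the object's 2D FT at the same angle — gives the second
reconstructor. Each projection is zero-padded to four times the detector
length and transformed (with the phase shift accounting for the centered
detector); those polar samples are placed on the Cartesian DFT grid by
bilinear interpolation in angle and radius, using conjugate symmetry for
negative radii and angle wrap-around at $\pi$; frequencies beyond the
detector Nyquist are set to zero; a 2D inverse DFT (with the centered-pixel
phase) returns the image. The Cartesian frequency grid is oversampled
twofold (reconstruct at $2N$, crop the center $N$): polar-to-Cartesian
interpolation error is the method's dominant artifact source, and the finer
grid roughly halves its RMSE for negligible cost. Even so the method is
kept as the *comparison* reconstructor: FBP remains the core.

## SIRT

The iterative reconstructor treats the discrete system $Af = p$ with the
simultaneous update

$$f \leftarrow f + \lambda\, C A^{\mathsf T} R\,(p - Af),$$

where $R$ and $C$ are the inverse row-sum and column-sum weights of $A$,
$f_0 = 0$, and $\lambda \in (0, 2]$ (default 1). SIRT was chosen over ART
as the iterative method because with the matched adjoint pair its data
residual $\lVert Af - p\rVert$ is monotone nonincreasing — a provable
property that becomes a test — whereas row-action methods are
order-dependent. Rays or pixels with zero weight sums receive zero inverse
weight (they cannot be updated). Convergence is fast on the low spatial
frequencies and slow on edges: consistent data from a smooth test image
reach a residual below 1% of $\lVert p\rVert$ within 50 iterations on a
$16^2$ grid, while edge-rich phantoms converge more slowly — a property of
the algorithm, not a defect of the implementation.

## The synthetic vessel generator

The cohort experiment needs ground truth, so the generator builds vessel
cross-sections analytically from at most six ellipses (keeping the exact
projector applicable):

* a background disc (radius 0.95, intensity 0.1) standing in for soft
  tissue;
* a contrast-filled lumen: an ellipse of intensity 1 over background with
  half-length 10 — far beyond the field of view, so the vessel walls are
  parallel to within 0.15% over the measurement range — and height equal to
  the reference diameter (default 0.4);
* for stenosis $s$%, a symmetric pair of negative-intensity indentations
  spanning exactly $[m/2,\ b]$ in $|y|$ at the midpoint, with
  $m = \mathrm{reference}\cdot(1 - s/100)$, so the analytic minimal
  diameter is exact by construction;
* optional plaque ellipses ($0.12 \times 0.05$) on the outer wall at the
  narrowing, separated from the lumen by a 0.03 wall gap: calcified plaque
  at twice the lumen intensity (hyperintense), noncalcified at 0.4 of it
  (between background and lumen). The paper-style plaque dichotomy fixes
  only the ordering hyper/hypo-intense; the specific levels are this
  package's choice and are configurable.

What the generator does *not* emulate: curved or branching vessels,
eccentric (asymmetric) stenoses, Hounsfield-calibrated intensities, partial
volume in depth, beam hardening, or Poisson transmission noise — noise is
additive Gaussian on the line integrals, chosen because the filter
comparison only needs a seedable, level-controlled perturbation. Passing
cohort tests therefore demonstrates that the pipeline's statistics machinery
is correct and that filter ordering behaves as theory predicts, not that
clinical sensitivities would take these values.

## Measurement operators

`measure_stenosis()` segments the lumen along profiles perpendicular to the
vessel axis by half-maximum thresholding: the threshold sits midway between
the background level (image median) and lumen level (0.98 quantile), and a
profile's width is the above-threshold run *containing the axis*, with
sub-pixel linear interpolation of the edge crossings. Taking only the axis
run keeps bright wall plaque — separated from the lumen by the wall — out of
the diameter, mirroring how a reader would not count calcium into the
lumen. Reference diameter is the median profile width over $|x| \le 0.5$,
minimal diameter the smallest; percent stenosis follows. On $256^2$
ground-truth rasters the mean absolute error over 10–90% stenosis is about
1.3 percentage points, dominated by pixel quantization of the two
diameters. A uniform image raises a "vessel not found" error rather than
returning a number.

Grading uses the standard clinical cut-offs — mild $< 50 \le$ moderate
$< 70 \le$ severe, configurable — since the mild/moderate/severe vocabulary
fixes no numbers by itself.

`detect_plaque()` searches wall regions just outside the measured lumen
surface at the narrowing, offset by 0.03 to skip the partial-volume/blur
band at the lumen edge: calcified plaque is called when the region maximum
exceeds background plus 1.5 times the background-to-lumen step;
noncalcified when at least 30% of region pixels fall in the intermediate
window (0.2–0.75 of the step). On noise-free ground-truth rasters both
detectors are exact (100% sensitivity and specificity, asserted by the
suite); under noise and reconstruction blur they degrade — which is
precisely what the cohort harness is for.

## The cohort experiment

`run_cohort_experiment()` draws per-case stenosis uniformly from a range
(default 10–90%) and independent plaque flags (default prevalence 0.3
each), projects each phantom analytically, adds seeded noise, reconstructs
with every configured arm, measures, and tallies contingency tables per
plaque type plus a grade confusion matrix, using the generator's truth as
gold standard. All randomness flows from the single seed; identical
`(config, seed)` reproduce identical per-case tables. A case whose
measurement fails becomes a row with its error message — denominators
never shrink silently. A "truth" arm measures the ground-truth raster
directly, isolating the measurement operator from reconstruction error.

## Numerical choices and degenerate inputs

* Rasterization is pixel-center point sampling (bit-reproducible,
  exactly additive); `supersample = s` averages $s^2$ subsamples when a
  smoother reference is wanted.
* Ellipse containment uses $\le$, so boundary points belong to the ellipse;
  overlapping ellipses always add.
* `add_noise()` saves and restores the caller's RNG state; sigma = 0
  returns the input object unchanged.
* Detectors shorter than the grid diagonal warn (truncation) rather than
  error; out-of-range rays contribute zero everywhere.
* Filters reject unknown kinds and mismatched sinogram dimensions;
  `psnr()` reports identical images as infinite rather than dividing by
  zero; contingency rates with zero denominators are `NA`, never 0.

## Problem sizes

The test suite and the acceptance script run at $N = 128$ (reconstruction
fidelity, $M = 30/60/180$), $N = 256$ (slice theorem, stenosis recovery,
noise-free cohort), and $16^2$–$32^2$ for the bit-exact oracle and SIRT
checks — sizes at which every property of interest is already
well-resolved while the whole suite stays interactive.

## Known limitations

Parallel-beam only (no fan/cone rebinning); half-turn geometry assumes an
ideal detector with no point spread, scatter, or dead time; the direct
Fourier method uses bilinear polar interpolation rather than gridding with
a kernel-density correction, so it trails FBP in accuracy by design; SIRT
has no regularization; and the clinical realism of the vessel generator is
deliberately limited to what the six-ellipse analytic model can express.
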