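# parbeam

Parallel-beam tomographic reconstruction in R, with synthetic
coronary-vessel phantoms and a diagnostic-accuracy harness.

Computed tomography and MR angiography form cross-sectional images by
measuring line integrals of an object — the Radon transform
`p(t, θ) = ∫ f(x, y) δ(x cos θ + y sin θ − t) dx dy` — and inverting them.
`parbeam` implements that pipeline end to end for 2D parallel-beam
geometry, for people who want a small, fully inspectable reconstruction
stack: methods researchers benchmarking filters, and teachers demonstrating
why filtered back-projection works and what noise does to it.

## What is inside

**Phantoms.** Analytic, additive ellipse phantoms: the canonical 10-ellipse
Shepp–Logan head phantom and a configurable coronary-vessel cross-section
with a bright lumen, a chosen percent-diameter stenosis
(`100·(1 − minimal/reference)`), and optional calcified (hyperintense) or
noncalcified (hypointense) wall plaque. Phantoms rasterize by pixel-center
sampling onto a centered `[−1, 1]²` grid.

**Forward model.** An exact projector using closed-form ellipse chord
lengths, a discrete pixel-driven projector that is the matched adjoint of
the back-projector (needed for provable iterative convergence), and seeded
Gaussian noise on the line integrals.

**Reconstruction.** The core is back-projection with linear detector
interpolation: each ray offset is split as `t = (n₀ + δ)d` and the
projection interpolated as `(1−δ)p[n₀] + δp[n₀+1]`, then averaged over view
angles. Filtered back-projection convolves each projection with a ramp
filter first: Ram-Lak (`|ν|` up to Nyquist, sharpest) or Shepp–Logan —
the ramp convolved with `sin(x)/x`, i.e. `|ν|·sinc(ν/(2ν_N))` in frequency —
which trades a little resolution for noise suppression. Two comparison
reconstructors are included: direct Fourier inversion via the central slice
theorem, and SIRT (`f ← f + λ C Aᵀ R (p − A f)`), whose data residual is
monotone nonincreasing thanks to the matched adjoint pair.

**Evaluation.** RMSE/PSNR, diagnostic contingency tables
(sensitivity/specificity/accuracy), automated lumen-diameter stenosis
measurement by half-maximum profile thresholding, 50/70% stenosis grading
(mild/moderate/severe), plaque detection, and a seeded synthetic cohort
experiment that scores every reconstruction method against the generator's
ground truth.

## Worked example

```r
library(parbeam)

ph    <- shepp_logan_phantom()
truth <- rasterize(ph, 128)
geom  <- standard_geometry(128, M = 180)
geom
#> proj_geometry: M = 180 angles (Delta = 0.017453 rad), K = 183 bins (d = 0.015625, span 2.859)

sino <- add_noise(radon_analytic(ph, geom), sigma = 0.1, seed = 1)
rec  <- fbp_reconstruct(sino, filter = "shepp-logan", N = 128)
mask <- circle_mask(128, 0.95)
sprintf("RMSE %.3f, PSNR %.1f dB, Pearson r %.3f",
        rmse(rec, truth, mask), psnr(rec, truth, mask),
        cor(rec$values[mask], truth$values[mask]))
#> RMSE 0.269, PSNR 17.4 dB, Pearson r 0.887
```

The RMSE is against the rasterized ground truth inside the reconstruction
circle; at this noise level (about 4% of the sinogram maximum) the
Shepp–Logan filter beats Ram-Lak, and both beat unfiltered back-projection.

Vessel measurement and a small diagnostic cohort:

```r
m <- measure_stenosis(rasterize(vessel_phantom(stenosis_pct = 64)$phantom, 256))
m
#> stenosis_measurement: reference 0.4062, minimal 0.1406 -> 65.4% (moderate)

cfg <- cohort_config(n = 20, sigma = 0.05,
                     methods = list(list(method = "fbp", filter = "shepp-logan")))
run_cohort_experiment(cfg, seed = 1)
#> cohort_result: 20 cases x 1 method(s), sigma = 0.05, seed = 1
#>   [fbp-shepp-logan] grade accuracy 100.0%
#>     calcified    sens 100.0%  spec 100.0%  acc 100.0%
#>     noncalcified sens 100.0%  spec  68.8%  acc  75.0%
```

Each cohort case is a vessel phantom with known stenosis and plaque status
(the gold standard), imaged through the noisy forward model, reconstructed,
and measured automatically; the tables report how often the automated
reading agrees with the truth. The imperfect noncalcified-plaque
specificity under noise is the kind of effect the harness exists to expose.

A command-line interface covering the same pipeline
(`phantom`, `project`, `reconstruct`, `evaluate`, `cohort`, `demo`) is
installed at `system.file("cli", "parbeam", package = "parbeam")`.

## Documentation

The methods vignette (`vignettes/parallel-beam-reconstruction.Rmd`)
describes the discretization, the filter constructions, normalization
choices, the synthetic-data generator's design and its limitations.
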