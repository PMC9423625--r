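# speckleddf

Directional dark-field retrieval from speckle-based X-ray imaging, in R.

## What problem this solves

Speckle-based X-ray imaging records a random diffuser pattern with and
without a sample, at one or more diffuser positions. The sample attenuates
the pattern (transmittance *T*), shifts it (refraction → differential
phase) and blurs it (ultra-small-angle scattering → dark field). When the
scattering structure is anisotropic — carbon fibres, collagen, wood grain —
the blur is directional, and its orientation reveals the structure's axis
even though the structure itself is far below the detector resolution.

`speckleddf` models the blur as an anisotropic Gaussian kernel

    K_alpha(x, y) = A exp[-(alpha1 x^2 + 2 alpha2 xy + alpha3 y^2) / 2]

and estimates `(T, u, alpha)` per pixel by minimising the windowed
least-squares cost

    L(r0) = sum_r sum_j Gamma(r - r0) | I_j(r) - T [I0_j * K_alpha](r + u) |^2

over all N diffuser positions (Hamming window `Gamma`, multi-resolution
coarse-to-fine solver). From the kernel it derives the three dark-field
observables per pixel:

* mean width `sigma^2 = (sigma_M^2 + sigma_m^2)/2`,
* directionality `eps = (sigma_M^2 - sigma_m^2)/(sigma_M^2 + sigma_m^2)`,
* orientation `theta` of the wide axis (axial, degrees),

plus transmittance, refraction-angle maps `u * pixel_size / d`, and an HSV
composite (hue = orientation, saturation = directionality, value = width).
A synthetic near-field speckle generator (spiral diffuser stepping,
known-phantom ground truth, Poisson noise, reference averaging) provides a
full validation bed without beamline data, and axial circular statistics
quantify orientation accuracy and the precision scaling law
`sigma_theta = A * P^B` with `P = window_pixels x N`.

Intended users: synchrotron/lab X-ray imaging scientists processing
speckle data stacks, and method developers who need a tested reference
implementation with oracle-grade tests.

## Worked example

Four tube pieces of unidirectional fibre composite, fibres vertical,
horizontal and diagonal; scattering is orthogonal to the fibres.

```r
library(speckleddf)

ph  <- four_tube_phantom(c(192, 192))          # truth: theta = phi + 90
ds  <- synthesize_dataset(
  pattern_spec(c(192, 192), mean_counts = 1e4, seed = 1), ph,
  acquisition_spec(n_positions = 25, noise = TRUE, seed = 2))

cfg  <- solver_config(window = 31, levels = c(4, 2, 1), max_shift = 3,
                      step = 8)
maps <- multires_solve(ds$frames, cfg)
df   <- darkfield_summary(maps)

rois <- list(roi_spec(c(56, 56), 36), roi_spec(c(56, 136), 36),
             roi_spec(c(136, 56), 36), roi_spec(c(136, 136), 36))
roi_report(df$theta, rois, ph$regions$fibre_angle, mask = maps$mask)
```

Output from this exact run (seed 1):

```
  roi phi_deg phi_err_deg theta_mean_deg theta_sd_deg deviation_deg
1   1      90          NA         0.0498       0.0709       0.04981
2   2       0          NA        89.9989       0.0888      -0.00106
3   3      45          NA       -45.0211       0.0815      -0.02109
4   4     -45          NA        45.0112       0.0379       0.01119
```

Each region's mean scattering direction sits within 0.05 degrees of the
orthogonal to its fibre axis (`deviation_deg` is
`<theta> - phi - 90`, wrapped); `theta_sd_deg` is the axial standard
deviation across the ROI — at `P = 31^2 x 25 = 24025` independent
measurements it is under a tenth of a degree on this synthetic data.

Precision scales with `P` as a power law close to the theoretical
`P^-0.5`; on the default phantom the fitted exponent is about `-0.56`:

```r
fit_power_law(P, sigma_theta)
#> precision scaling: sigma_theta = A * P^B
#>   A = 21.38 +/- 2.2   B = -0.5627 +/- 0.015   (n = 4, P >= 50)
```

Command-line equivalents:

```sh
Rscript inst/scripts/ddf-simulate.R    --output sim --shape 192,192 --seed 1
Rscript inst/scripts/ddf-reconstruct.R --bundle sim.rds --window 31 \
        --levels 4,2,1 --step 8 --output maps/
```

`maps/` then holds float32 TIFFs (`T`, `ux`, `uy`, `sigma`,
`eccentricity`, `theta_deg`, `residual`), an 8-bit `mask`, the RGB
`composite_rgb.tif`, and `maps.rds` with the full configuration.

## Conventions

Images are `[row, col]` matrices; `x` = column, `y` = row; shifts
`u = (ux, uy)` in pixels. `theta` is the axial angle of the kernel's wide
axis from +x toward +y in `(-90, 90]` degrees — displayed with row 1 at
the top, positive angles appear clockwise. Geometry defaults
(`pixel_size = 21.5e-6` m, `distance_d = 6.65` m) correspond to a
synchrotron full-field microscope setup and are fully configurable.
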