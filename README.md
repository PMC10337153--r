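# zpeel

Surface-guided "peeling" of 3D fluorescence microscopy z-stacks before 2D
projection.

A plain maximum-intensity projection (MIP) of a z-stack collapses every
depth into one image. For curved specimens — fish embryos during epiboly,
plant gemmae, any tissue layer wrapped on a sphere-like or bent surface —
this means a bright superficial cell layer occludes everything beneath it.
`zpeel` removes a geometrically defined sub-volume first ("peeling") and
only then projects, so that structures on or under a curved surface become
visible and quantifiable. It is a scriptable library plus a small CLI,
aimed at microscopists and image analysts who need reproducible,
parameter-logged projections rather than interactive ones.

Two surface models are supported:

* **Fitted sphere.** Foreground voxels (Otsu threshold τ by default) are
  fitted with a sphere by minimizing the L1 norm of the algebraic
  residuals

  $$\min_{x_0,y_0,z_0,r_0}\ \sum_{i:\,I(V_i)>\tau}
  \bigl|(X_i-x_0)^2+(Y_i-y_0)^2+(Z_i-z_0)^2-r_0^2\bigr|,$$

  robust to bright outliers. The peel keeps the ball of radius
  $\alpha r_0$, $\alpha\in[0,1]$, or its complement. Time-lapse stacks get
  independent per-frame fits.

* **User-guided cubic-spline surface.** Depths annotated on a regular
  $g\times g$ grid ($g\in\{3,4,5\}$, borders included) are interpolated by
  a tensor-product natural cubic spline $S(x,y)$; the volume is cut into
  the half-spaces above and below it (the lower volume keeps voxels with
  $S(X,Y)\le Z$). For time series, control points at two or more frames
  are interpolated linearly per node across the whole series.

After peeling ($I^p = I\cdot T$ with binary mask $T$), the MIP is taken
per channel and frame; fully peeled columns are flagged in an explicit
validity mask. TIFF I/O understands ImageJ-style hyperstack metadata
(channels / slices / frames). A synthetic two-sheet benchmark generator
with ground truth, plus RMSE and Dice metrics, round out the package; the
methods vignette (`vignettes/peeling-methods.Rmd`) documents the models,
parameter defaults, and numerical choices.

## Worked example

Generate a synthetic volume in which a dim sheet (intensity 128) is hidden
below a bright one (255), peel below the mid-surface, and project:

```r
library(zpeel)

spec <- synthetic_spec(w = 128, h = 128, d = 50, seed = 1)
gen  <- make_two_sheet_volume(spec)
gen$volume
#> <volume_stack> 128 x 128 x 50 voxels, 1 channel(s), 1 frame(s), float
#>   intensity range: [0, 255]

grid <- default_experiment_grid(spec, target = "S2", grid_size = 5)
res  <- run_pipeline(gen$volume, "spline", grids = grid, side = attr(grid, "side"))
res
#> <peel_result> mode: spline
#> <projection2d> 128 x 128 pixels, 1 channel(s), 1 frame(s), float; 85.2% valid
#>  side: lower, 1 surface(s)

rmse_vs_constant(res$projection, 128, domain = gen$truth$domain2)
#> [1] 25.39
rmse_vs_constant(max_projection(gen$volume), 128, domain = gen$truth$domain2)
#> [1] 118.77
```

The peeled projection sits near the dim sheet's intensity (RMSE ≈ 25, the
noise level), while the plain MIP reports the occluding bright sheet
instead (RMSE ≈ 119): only the peeled projection retrieves the hidden
layer. The validity mask marks the 15 % of columns where the cut lies
below the stack, so nothing was kept.

Sphere fitting on a shell phantom recovers the geometry to sub-voxel
accuracy:

```r
ph  <- make_sphere_phantom(center = c(32, 30, 31), radius = 20, dims = c(64, 64, 64))
fit_sphere(ph)
#> <sphere_model> center (32.000, 30.000, 31.000), radius 20.025 [voxels]
#>   L1 objective 4.965e+04 over 5034 voxels (threshold 0.9961)
```

The same operations are available from the shell via the launcher in
`inst/cli/` (`zpeel synth | sphere | spline | eval | benchmark`); every
run writes a provenance JSON with its parameters and seeds next to its
outputs.

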